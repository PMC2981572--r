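#' @importFrom rlang .data
NULL

# Enrichment results are tibbles with one row per tested gene-set:
#   dataset   character  which enrichment run the record belongs to
#   set_id    character  gene-set identifier (unique within a dataset)
#   p_value   double     nominal enrichment p-value in [0, 1]
#   q_value   double     FDR q-value in [0, 1], NA when not available
#   direction integer    +1 / -1 = phenotype (class) of enrichment, 0 = one-class
#   score     double     enrichment score (NES for GSEA-sourced records), NA else

new_enrichment_result <- function(dataset, set_id, p_value, q_value,
                                  direction, score = NA_real_) {
  x <- tibble::tibble(
    dataset = as.character(dataset),
    set_id = as.character(set_id),
    p_value = as.numeric(p_value),
    q_value = as.numeric(q_value),
    direction = as.integer(direction),
    score = as.numeric(score)
  )
  if (any(is.na(x$p_value))) stop("missing p-values", call. = FALSE)
  if (any(x$p_value < 0 | x$p_value > 1)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  bad_q <- !is.na(x$q_value) & (x$q_value < 0 | x$q_value > 1)
  if (any(bad_q)) stop("q-values outside [0, 1]", call. = FALSE)
  if (!all(x$direction %in% c(-1L, 0L, 1L))) {
    stop("direction must be -1, 0 or +1", call. = FALSE)
  }
  dup <- duplicated(x[c("dataset", "set_id")])
  if (any(dup)) {
    stop("duplicate enrichment record for set_id: ",
         paste(unique(x$set_id[dup]), collapse = ", "), call. = FALSE)
  }
  x
}

read_tsv_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

parse_numeric_col <- function(x, col, path, blank_as = NA_real_) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x == "" | toupper(x) == "NA"] <- blank_as
  bad <- which(is.na(out) & x != "" & toupper(x) != "NA")
  if (length(bad) > 0) {
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "', row ", bad[1], " of ", path, call. = FALSE)
  }
  out
}

#' Read a pair of GSEA enrichment report tables
#'
#' GSEA writes one report per phenotype; records from the positive-phenotype
#' report get direction +1 and records from the negative-phenotype report
#' direction -1. Empty `NOM p-val` cells are parsed as 0: GSEA prints an
#' empty cell when the permutation p-value falls below its resolution
#' (p < 1/number of permutations), so such records must always pass a
#' significance filter. A set appearing in both reports is a format error.
#'
#' @param pos_path,neg_path Paths to the tab-separated GSEA report tables
#'   (columns `NAME`, `SIZE`, `ES`, `NES`, `NOM p-val`, `FDR q-val` required;
#'   extra columns ignored).
#' @param dataset_name Label stored in the `dataset` column.
#' @return An enrichment result tibble with columns `dataset`, `set_id`,
#'   `p_value`, `q_value`, `direction`, `score` (the NES).
#' @export
read_gsea_reports <- function(pos_path, neg_path, dataset_name = "dataset") {
  read_one <- function(path, dir) {
    tab <- read_tsv_chr(path)
    required <- c("NAME", "SIZE", "ES", "NES", "NOM p-val", "FDR q-val")
    missing <- setdiff(required, names(tab))
    if (length(missing) > 0) {
      stop("GSEA report ", path, " lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tibble::tibble(
      set_id = tab$NAME,
      p_value = parse_numeric_col(tab[["NOM p-val"]], "NOM p-val", path,
                                  blank_as = 0),
      q_value = parse_numeric_col(tab[["FDR q-val"]], "FDR q-val", path),
      direction = dir,
      score = parse_numeric_col(tab$NES, "NES", path)
    )
  }
  pos <- read_one(pos_path, 1L)
  neg <- read_one(neg_path, -1L)
  both <- intersect(pos$set_id, neg$set_id)
  if (length(both) > 0) {
    stop("gene-set(s) present in both GSEA reports: ",
         paste(utils::head(both, 5), collapse = ", "), call. = FALSE)
  }
  rec <- dplyr::bind_rows(pos, neg)
  new_enrichment_result(dataset_name, rec$set_id, rec$p_value, rec$q_value,
                        rec$direction, rec$score)
}

#' Read a generic enrichment table
#'
#' Tab-separated with a header; required columns `id` and `pvalue`
#' (`set_id` / `p_value` accepted as synonyms), optional `description`,
#' `fdr` and `direction`. A missing `fdr` column leaves q-values `NA`; a
#' missing `direction` column yields direction 0 (one-class analysis).
#' `direction` may hold +1/-1 values or two phenotype labels, in which case
#' the first label seen maps to +1.
#'
#' @param path Path to the table.
#' @param dataset_name Label stored in the `dataset` column.
#' @return An enrichment result tibble (see [read_gsea_reports()]).
#' @export
read_generic_table <- function(path, dataset_name = "dataset") {
  tab <- read_tsv_chr(path)
  names(tab) <- tolower(names(tab))
  alias <- c(set_id = "id", p_value = "pvalue", p = "pvalue",
             q_value = "fdr", qvalue = "fdr")
  for (i in seq_along(alias)) {
    if (names(alias)[i] %in% names(tab) && !alias[i] %in% names(tab)) {
      names(tab)[names(tab) == names(alias)[i]] <- alias[i]
    }
  }
  missing <- setdiff(c("id", "pvalue"), names(tab))
  if (length(missing) > 0) {
    stop("generic enrichment table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- parse_numeric_col(tab$pvalue, "pvalue", path)
  if (any(is.na(p))) {
    stop("missing p-value in row ", which(is.na(p))[1], " of ", path,
         call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-value outside [0, 1] in row ", which(p < 0 | p > 1)[1],
         " of ", path, call. = FALSE)
  }
  q <- if ("fdr" %in% names(tab)) {
    parse_numeric_col(tab$fdr, "fdr", path)
  } else {
    NA_real_
  }
  dir <- if ("direction" %in% names(tab)) {
    parse_direction(tab$direction)
  } else {
    0L
  }
  new_enrichment_result(dataset_name, tab$id, p, q, dir)
}

# +1/-1/0 pass through; otherwise values are phenotype labels and the
# first-seen label maps to +1 (deterministic without configuration).
parse_direction <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(sub("^\\+", "", x)))
  if (all(!is.na(num))) {
    if (!all(num %in% c(-1, 0, 1))) {
      stop("numeric direction values must be -1, 0 or +1", call. = FALSE)
    }
    return(as.integer(num))
  }
  labels <- unique(x)
  if (length(labels) > 2) {
    stop("more than two phenotype labels in direction column: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  ifelse(x == labels[1], 1L, -1L)
}

#' Write an enrichment result as a generic table
#'
#' Serialises to the generic TSV dialect accepted by [read_generic_table()]
#' (columns `id`, `pvalue`, `fdr`, `direction`); reading the file back
#' reproduces the records.
#'
#' @param result An enrichment result tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(result, path) {
  out <- tibble::tibble(
    id = result$set_id,
    pvalue = format_num(result$p_value),
    fdr = format_num(result$q_value),
    direction = result$direction
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Full-precision decimal rendering so numeric round trips are exact.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, "")
  out
}

#' Filter enrichment records for significance
#'
#' Keeps records with `p_value < p_max` and, when a q-value is present,
#' `q_value < q_max` (strict inequalities). Records without a q-value are
#' filtered on the p-value alone. Defaults are the conservative thresholds
#' commonly used to select gene-sets for display: nominal p < 0.001 and
#' FDR < 5%.
#'
#' @param result An enrichment result tibble.
#' @param p_max,q_max Thresholds in `(0, 1]`.
#' @return The significant subset, a tibble; idempotent.
#' @export
filter_significant <- function(result, p_max = 0.001, q_max = 0.05) {
  for (thr in list(p_max, q_max)) {
    if (length(thr) != 1 || is.na(thr) || thr <= 0 || thr > 1) {
      stop("thresholds must be single values in (0, 1]", call. = FALSE)
    }
  }
  dplyr::filter(result,
                .data$p_value < p_max,
                is.na(.data$q_value) | .data$q_value < q_max)
}

#' Fisher's exact over-representation test of a gene list
#'
#' The enrichment mode for naturally discrete gene lists: for each gene-set
#' (restricted to the universe) the one-tailed Fisher's exact p-value of its
#' overlap with the query list is computed from the hypergeometric
#' distribution. With universe size `N`, restricted set size `n`, query size
#' `m` and overlap `k`, `p = P(X >= k)` for `X ~ Hypergeometric(N, n, m)`.
#' Benjamini-Hochberg q-values over all tested sets are attached; records
#' carry direction 0 (one-class analysis).
#'
#' @param query_genes Character vector of query gene identifiers. Genes
#'   outside the universe are dropped with a warning.
#' @param collection A gene-set collection tibble; each set is restricted to
#'   the universe first and sets that become empty are not tested.
#' @param universe Character vector: the background gene population.
#' @param dataset_name Label stored in the `dataset` column.
#' @return An enrichment result tibble with extra columns `overlap_size`
#'   (the `k` of each test) and `set_size` (restricted `n`).
#' @examples
#' sets <- gene_sets("S1", list(letters[1:5]))
#' fisher_enrichment(letters[1:5], sets, letters[1:10])$p_value # 1/252
#' @export
fisher_enrichment <- function(query_genes, collection, universe,
                              dataset_name = "fisher") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  query_genes <- unique(as.character(query_genes))
  if (length(query_genes) == 0) stop("query gene list is empty", call. = FALSE)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query_genes <- intersect(query_genes, universe)
  }
  if (length(query_genes) == 0) {
    stop("no query genes left after restriction to the universe",
         call. = FALSE)
  }
  restricted <- restrict_to_universe(collection, universe)
  if (nrow(restricted) == 0) {
    stop("no gene-sets overlap the universe", call. = FALSE)
  }
  N <- length(universe)
  m <- length(query_genes)
  n <- lengths(restricted$genes)
  k <- vapply(restricted$genes,
              function(g) length(intersect(g, query_genes)), 0L)
  p <- hyper_tail_p(k, n, m, N)
  out <- new_enrichment_result(dataset_name, restricted$set_id, p,
                               stats::p.adjust(p, method = "BH"), 0L)
  out$overlap_size <- as.integer(k)
  out$set_size <- as.integer(n)
  out
}

# Upper hypergeometric tail P(X >= k); k = 0 gives exactly 1.
hyper_tail_p <- function(k, n, m, N) {
  pmin(1, stats::phyper(k - 1, n, N - n, m, lower.tail = FALSE))
}
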