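#' Construct a gene-set collection tibble
#'
#' A gene-set collection is an ordinary tibble with one row per gene-set and
#' three columns: `set_id` (unique character key), `description` (free text,
#' may be empty) and `genes` (a list-column of character vectors of unique
#' gene identifiers). All collection-level functions in the package take and
#' return this shape, so they compose with dplyr verbs and the pipe.
#'
#' @param set_id Character vector of unique, non-empty set identifiers.
#' @param genes List of character vectors of gene identifiers (duplicates
#'   within a set are removed).
#' @param description Character vector of free-text descriptions, recycled.
#' @return A tibble with columns `set_id`, `description`, `genes`.
#' @examples
#' gene_sets(c("S1", "S2"), list(c("a", "b"), c("b", "c", "d")))
#' @export
gene_sets <- function(set_id, genes, description = "") {
  if (!is.list(genes)) genes <- list(genes)
  x <- tibble::tibble(
    set_id = as.character(set_id),
    description = rep_len(as.character(description), length(set_id)),
    genes = lapply(genes, function(g) unique(as.character(g[!is.na(g) & g != ""])))
  )
  validate_gene_sets(x)
}

# Enforce the collection invariants: unique non-empty ids, deduplicated
# non-empty genes, every set non-empty.
validate_gene_sets <- function(x, arg = "collection") {
  if (!is.data.frame(x) || !all(c("set_id", "genes") %in% names(x))) {
    stop(arg, " must be a data frame with columns 'set_id' and 'genes'",
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"description" %in% names(x)) x$description <- ""
  x$description[is.na(x$description)] <- ""
  if (any(is.na(x$set_id) | x$set_id == "")) {
    stop("set_id must be non-empty", call. = FALSE)
  }
  dup <- x$set_id[duplicated(x$set_id)]
  if (length(dup) > 0) {
    stop("duplicate set_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(x$genes)
  if (any(sizes == 0)) {
    stop("gene-sets with no genes: ",
         paste(x$set_id[sizes == 0], collapse = ", "), call. = FALSE)
  }
  x[c("set_id", "description", "genes")]
}

#' Read a GMT gene-set file
#'
#' Parses the Broad GMT dialect: one tab-separated line per gene-set,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`, no header. Windows line
#' endings and trailing empty fields are tolerated; duplicate genes within a
#' line are removed; duplicate set ids are an error.
#'
#' @param path Path to a GMT file.
#' @param uppercase If `TRUE`, gene identifiers are uppercased on read (GSEA
#'   conventionally uppercases gene symbols). Default `FALSE`: identifiers
#'   are compared case-sensitively, the only assumption-free default.
#' @return A gene-set collection tibble (see [gene_sets()]), rows in file
#'   order.
#' @seealso [write_gmt()], [filter_by_size()], [restrict_to_universe()]
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- lines != ""
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line ", lineno[bad[1]], " in ", path,
         ": expected at least 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    stop("duplicate set_id '", ids[dup[1]], "' at line ", lineno[dup[1]],
         " in ", path, call. = FALSE)
  }
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[g != ""]
    if (uppercase) g <- toupper(g)
    unique(g)
  })
  empty <- which(lengths(genes) == 0)
  if (length(empty) > 0) {
    stop("GMT line ", lineno[empty[1]], " in ", path, " has no genes",
         call. = FALSE)
  }
  gene_sets(ids, genes, vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection to a GMT file
#'
#' Genes are written in sorted order so the output is deterministic:
#' two writes of the same collection are byte-identical, and
#' `read_gmt(write_gmt(x))` reproduces `x` up to within-set gene order.
#'
#' @param collection A gene-set collection tibble (non-empty).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- validate_gene_sets(collection)
  if (nrow(collection) == 0) stop("collection is empty", call. = FALSE)
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$description[i],
            sort(collection$genes[[i]], method = "radix")),
          collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Filter gene-sets by size
#'
#' Discards gene-sets annotating fewer than `min_size` or more than
#' `max_size` genes; bounds are inclusive, so sets of exactly `min_size` or
#' `max_size` genes are kept. The defaults (10, 500) are the routine
#' pre-processing choice for enrichment analysis: very large sets rarely
#' convey specific biological meaning and very small sets are prone to
#' spurious enrichment.
#'
#' @param collection A gene-set collection tibble.
#' @param min_size,max_size Inclusive size bounds, `1 <= min_size <= max_size`.
#' @return The sub-collection with sizes in `[min_size, max_size]`, input
#'   order preserved.
#' @export
filter_by_size <- function(collection, min_size = 10, max_size = 500) {
  collection <- validate_gene_sets(collection)
  if (length(min_size) != 1 || length(max_size) != 1 ||
      is.na(min_size) || is.na(max_size) || min_size < 1) {
    stop("min_size and max_size must be scalars with min_size >= 1",
         call. = FALSE)
  }
  if (min_size > max_size) {
    stop("min_size (", min_size, ") exceeds max_size (", max_size, ")",
         call. = FALSE)
  }
  sizes <- lengths(collection$genes)
  collection[sizes >= min_size & sizes <= max_size, ]
}

#' Restrict gene-sets to a gene universe
#'
#' Intersects every set with the given universe (e.g. the genes actually
#' measured in an experiment) and drops sets that become empty. Downstream
#' similarity and Fisher computations should use restricted sets so that
#' overlap statistics refer to the measured gene population.
#'
#' @param collection A gene-set collection tibble.
#' @param universe Non-empty character vector of gene identifiers.
#' @return The restricted collection; never increases any set's size.
#' @export
restrict_to_universe <- function(collection, universe) {
  collection <- validate_gene_sets(collection)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  collection$genes <- lapply(collection$genes, intersect, y = universe)
  collection[lengths(collection$genes) > 0, ]
}

#' Gene-set sizes
#'
#' @param collection A gene-set collection tibble.
#' @return A tibble with columns `set_id` and `size`.
#' @export
set_sizes <- function(collection) {
  collection <- validate_gene_sets(collection)
  tibble::tibble(set_id = collection$set_id,
                 size = lengths(collection$genes))
}

# Union of all genes in a collection, used as the default universe.
collection_universe <- function(collection) {
  unique(unlist(collection$genes, use.names = FALSE))
}
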