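# Expression matrices are stored as a light S3 object: a numeric matrix
# (genes x samples, identifiers as dimnames) plus an optional named vector
# of sample class labels. Scoring functions return tidy tibbles.

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames). Values on the scale provided (typically
#'   log2 rma signals).
#' @param classes Optional named character vector mapping every sample to a
#'   class label; exactly two distinct labels are required for scoring.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, classes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (!is.null(classes)) {
    classes <- classes[colnames(values)]
    if (anyNA(classes)) {
      stop("every sample needs a class label", call. = FALSE)
    }
    names(classes) <- colnames(values)
  }
  structure(list(values = values, classes = classes), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples", sep = "")
  if (!is.null(x$classes)) {
    cat(" (classes: ", paste(unique(x$classes), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read an expression matrix with sample classes
#'
#' Accepts GCT (the GSEA companion format, `#1.2` preamble) or a headered
#' TSV whose first column holds gene identifiers. Class labels come from a
#' CLS file or a two-column TSV (`sample<TAB>class`).
#'
#' @param matrix_path Path to the GCT or TSV matrix.
#' @param class_path Optional path to a CLS file or two-column TSV.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(matrix_path, class_path = NULL) {
  first <- readLines(matrix_path, n = 1, warn = FALSE)
  values <- if (startsWith(first, "#1.2")) {
    read_gct(matrix_path)
  } else {
    tab <- readr::read_tsv(matrix_path,
                           col_types = readr::cols(
                             readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab[[1]]
    m
  }
  classes <- NULL
  if (!is.null(class_path)) {
    classes <- read_classes(class_path, samples = colnames(values))
  }
  expr_matrix(values, classes)
}

read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("truncated GCT file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  header <- strsplit(sub("\r$", "", lines[3]), "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:2)]
  body <- strsplit(sub("\r$", "", lines[-(1:3)]), "\t", fixed = TRUE)
  body <- body[lengths(body) > 0]
  if (length(body) != dims[1] || length(samples) != dims[2]) {
    stop("GCT dimension mismatch in ", path, ": preamble declares ",
         dims[1], " x ", dims[2], ", body has ", length(body), " x ",
         length(samples), call. = FALSE)
  }
  genes <- vapply(body, `[[`, "", 1L)
  m <- t(vapply(body, function(f) as.numeric(f[-(1:2)]),
                numeric(length(samples))))
  if (length(samples) == 1) m <- matrix(m, ncol = 1)
  rownames(m) <- genes
  colnames(m) <- samples
  m
}

# CLS: "n_samples n_classes 1" / "# label1 label2" / one token per sample
# (either a declared label or a 0-based index into the declared labels).
# Two-column TSV (sample, class) is also accepted.
read_classes <- function(path, samples) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) >= 2 && startsWith(trimws(lines[2]), "#")) {
    head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    labels <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
    toks <- strsplit(trimws(lines[3]), "\\s+")[[1]]
    if (length(toks) != length(samples) ||
        length(toks) != as.integer(head[1])) {
      stop("CLS sample count does not match the expression matrix",
           call. = FALSE)
    }
    cls <- if (all(toks %in% labels)) {
      toks
    } else {
      labels[as.integer(toks) + 1]
    }
    stats::setNames(cls, samples)
  } else {
    tab <- readr::read_tsv(path, col_names = c("sample", "class"),
                           col_types = "cc", progress = FALSE)
    if (identical(tab$sample[1], "sample")) tab <- tab[-1, ]
    stats::setNames(tab$class, tab$sample)[samples]
  }
}

#' Write an expression matrix as GCT
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gct <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- expr$values
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t"),
               paste(c("NAME", "Description", colnames(m)), collapse = "\t")),
             con, sep = "\n")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], "na", sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Write sample class labels as CLS
#'
#' @param classes Named character vector (sample -> class label).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cls <- function(classes, path) {
  labels <- unique(classes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(length(classes), length(labels), 1),
               paste("#", paste(labels, collapse = " ")),
               paste(classes, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

check_two_classes <- function(expr, class_case, class_control, min_per_class) {
  if (is.null(expr$classes)) {
    stop("expression matrix has no class labels", call. = FALSE)
  }
  for (cl in c(class_case, class_control)) {
    n <- sum(expr$classes == cl)
    if (n < min_per_class) {
      stop("class '", cl, "' has ", n, " sample(s); at least ",
           min_per_class, " required", call. = FALSE)
    }
  }
}

#' Score genes by the two-sample t statistic
#'
#' Per gene, the Welch (unequal-variance) two-sample t statistic comparing
#' `class_case` against `class_control`; positive when the case mean is
#' higher. A variance floor of `var_floor` per class guards against division
#' by zero on constant genes. Genes are returned ranked by descending
#' statistic (ties broken by gene id, ascending, for determinism), ready for
#' RNK export ([write_rnk()]) and downstream rank-based enrichment.
#'
#' @param expr An `expr_matrix` with class labels.
#' @param class_case,class_control The two class labels to compare; default
#'   the first and second label in sample order.
#' @param var_floor Lower bound on each class variance (default 1e-8).
#' @param pooled If `TRUE`, use the pooled-variance (Student) form instead
#'   of Welch.
#' @return A tibble with columns `gene`, `statistic`, `mean_case`,
#'   `mean_control`, sorted by descending statistic.
#' @export
score_genes_ttest <- function(expr, class_case = NULL, class_control = NULL,
                              var_floor = 1e-8, pooled = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  cls <- default_classes(expr, class_case, class_control)
  check_two_classes(expr, cls[1], cls[2], min_per_class = 2)
  x <- expr$values[, expr$classes == cls[1], drop = FALSE]
  y <- expr$values[, expr$classes == cls[2], drop = FALSE]
  n1 <- ncol(x); n0 <- ncol(y)
  m1 <- rowMeans(x); m0 <- rowMeans(y)
  v1 <- pmax(apply(x, 1, stats::var), var_floor)
  v0 <- pmax(apply(y, 1, stats::var), var_floor)
  se <- if (pooled) {
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    sqrt(sp * (1 / n1 + 1 / n0))
  } else {
    sqrt(v1 / n1 + v0 / n0)
  }
  tibble::tibble(gene = rownames(expr$values),
                 statistic = unname((m1 - m0) / se),
                 mean_case = unname(m1), mean_control = unname(m0)) |>
    dplyr::arrange(dplyr::desc(.data$statistic), .data$gene)
}

#' Score genes by the ratio of class means
#'
#' The simpler alternative gene score: `mean(case) / mean(control)` per
#' gene, on the values as given (no re-exponentiation of log-scale data
#' unless `exponentiate = TRUE`). Genes whose control mean is zero have an
#' undefined ratio and are excluded with a warning.
#'
#' @inheritParams score_genes_ttest
#' @param exponentiate If `TRUE`, apply `2^x` to the values before taking
#'   class means (for log2-scale input where a true fold-change is wanted).
#' @return A tibble with columns `gene`, `statistic` (the ratio),
#'   `mean_case`, `mean_control`, sorted by descending ratio.
#' @export
score_genes_ratio <- function(expr, class_case = NULL, class_control = NULL,
                              exponentiate = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  cls <- default_classes(expr, class_case, class_control)
  check_two_classes(expr, cls[1], cls[2], min_per_class = 1)
  vals <- if (exponentiate) 2^expr$values else expr$values
  m1 <- rowMeans(vals[, expr$classes == cls[1], drop = FALSE])
  m0 <- rowMeans(vals[, expr$classes == cls[2], drop = FALSE])
  zero <- m0 == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero control mean excluded: ",
            paste(utils::head(rownames(expr$values)[zero], 5), collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(gene = rownames(expr$values)[!zero],
                 statistic = unname((m1 / m0)[!zero]),
                 mean_case = unname(m1[!zero]),
                 mean_control = unname(m0[!zero])) |>
    dplyr::arrange(dplyr::desc(.data$statistic), .data$gene)
}

default_classes <- function(expr, class_case, class_control) {
  if (is.null(expr$classes)) {
    stop("expression matrix has no class labels", call. = FALSE)
  }
  labels <- unique(expr$classes)
  if (is.null(class_case)) class_case <- labels[1]
  if (is.null(class_control)) class_control <- setdiff(labels, class_case)[1]
  if (is.na(class_control)) stop("need two distinct classes", call. = FALSE)
  c(class_case, class_control)
}

#' Write a ranked gene list in RNK format
#'
#' @param scores A tibble with columns `gene` and `statistic`, as returned
#'   by [score_genes_ttest()] or [score_genes_ratio()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rnk <- function(scores, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(scores$gene, sprintf("%.17g", scores$statistic),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Extract heat-map data for a gene-set
#'
#' Pulls the expression submatrix underlying an enrichment result for one
#' gene-set: rows are the set's genes present in the matrix, ordered by
#' descending t statistic (case vs control); columns are grouped by class
#' (case first) preserving input order within class. Optional per-row
#' normalisation.
#'
#' @param gene_set Character vector of gene identifiers (one gene-set).
#' @param expr An `expr_matrix` with two-class labels.
#' @param normalization `"none"`, `"row_zscore"` (each row to mean 0,
#'   sd 1; constant rows become all-zero) or `"log2"`.
#' @param class_case,class_control Class labels, defaulting as in
#'   [score_genes_ttest()].
#' @return A tibble, first column `gene`, one column per sample in display
#'   order, with attributes `missing_genes` (set genes absent from the
#'   matrix), `normalization` and `classes` (the column class labels).
#' @export
heatmap_data <- function(gene_set, expr,
                         normalization = c("none", "row_zscore", "log2"),
                         class_case = NULL, class_control = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  normalization <- match.arg(normalization)
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, rownames(expr$values))
  if (length(present) == 0) {
    stop("no gene of the set is present in the expression matrix",
         call. = FALSE)
  }
  cls <- default_classes(expr, class_case, class_control)
  scores <- score_genes_ttest(expr, cls[1], cls[2])
  row_order <- scores$gene[scores$gene %in% present]
  col_order <- c(names(expr$classes)[expr$classes == cls[1]],
                 names(expr$classes)[expr$classes == cls[2]])
  m <- expr$values[row_order, col_order, drop = FALSE]
  if (normalization == "row_zscore") {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    m <- (m - mu) / ifelse(sd > 0, sd, 1)
  } else if (normalization == "log2") {
    m <- log2(m)
  }
  out <- tibble::as_tibble(m, rownames = "gene")
  attr(out, "missing_genes") <- setdiff(gene_set, present)
  attr(out, "normalization") <- normalization
  attr(out, "classes") <- stats::setNames(expr$classes[col_order], col_order)
  out
}

#' Write heat-map data as TSV
#'
#' @param hm A tibble from [heatmap_data()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path) {
  readr::write_tsv(hm, path, progress = FALSE)
  invisible(path)
}
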