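#' Jaccard coefficient between two gene-sets
#'
#' `JC(A, B) = |A intersect B| / |A union B|`. The Jaccard coefficient
#' penalises size mismatch, so it tends to link gene-sets of similar size;
#' parent-child pairs in hierarchical collections score only
#' `|child| / |parent|`.
#'
#' @param a,b Character vectors of gene identifiers (non-empty; duplicates
#'   ignored).
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @examples
#' jaccard(c("a", "b", "c", "d"), c("c", "d", "e", "f")) # 1/3
#' @export
jaccard <- function(a, b) {
  ab <- check_set_pair(a, b)
  length(intersect(ab$a, ab$b)) / length(union(ab$a, ab$b))
}

#' Overlap coefficient between two gene-sets
#'
#' `OC(A, B) = |A intersect B| / min(|A|, |B|)`. Any subset relation scores
#' exactly 1, so with the overlap coefficient every parent-child pair of a
#' hierarchical collection (such as GO) receives the maximal score and is
#' guaranteed an edge at any cutoff at most 1. `OC >= JC` always.
#'
#' @inheritParams jaccard
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @examples
#' overlap_coeff(c("a", "b", "c", "d"), c("c", "d", "e", "f")) # 1/2
#' @export
overlap_coeff <- function(a, b) {
  ab <- check_set_pair(a, b)
  length(intersect(ab$a, ab$b)) / min(length(ab$a), length(ab$b))
}

check_set_pair <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) {
    stop("gene-sets must be non-empty", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Build the thresholded similarity edge list of a collection
#'
#' Computes the chosen coefficient for every unordered pair of gene-sets and
#' keeps the pairs whose coefficient is at least `cutoff` (inclusive: with
#' the overlap metric and any cutoff at most 1, parent-child pairs, which
#' score exactly 1, always receive an edge). Pairs are canonicalised so that
#' `a < b` lexicographically, and the edge list is sorted by `(a, b)`, making
#' it invariant under permutation of the collection's row order.
#'
#' @param collection A gene-set collection tibble with at least one set.
#' @param metric `"overlap"` (default) or `"jaccard"`.
#' @param cutoff Similarity threshold in `(0, 1]`; default 0.5, the usual
#'   operating point for GO-derived collections.
#' @return A tibble with columns `a`, `b`, `metric`, `coefficient`,
#'   `intersection_size`; zero rows if no pair passes.
#' @export
build_similarity_edges <- function(collection,
                                   metric = c("overlap", "jaccard"),
                                   cutoff = 0.5) {
  collection <- validate_gene_sets(collection)
  metric <- match.arg(metric)
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must be a single value in (0, 1]", call. = FALSE)
  }
  if (nrow(collection) == 0) stop("collection is empty", call. = FALSE)
  empty <- tibble::tibble(a = character(), b = character(),
                          metric = character(), coefficient = double(),
                          intersection_size = integer())
  n <- nrow(collection)
  if (n < 2) return(empty)

  # Inverted index: only pairs sharing at least one gene can pass a positive
  # cutoff, so enumerate candidate pairs from co-membership.
  sizes <- lengths(collection$genes)
  gene2set <- tibble::tibble(
    gene = unlist(collection$genes, use.names = FALSE),
    idx = rep.int(seq_len(n), sizes)
  )
  pairs <- gene2set |>
    dplyr::inner_join(gene2set, by = "gene", relationship = "many-to-many") |>
    dplyr::filter(.data$idx.x < .data$idx.y) |>
    dplyr::count(.data$idx.x, .data$idx.y, name = "k")
  if (nrow(pairs) == 0) return(empty)

  coef <- if (metric == "jaccard") {
    pairs$k / (sizes[pairs$idx.x] + sizes[pairs$idx.y] - pairs$k)
  } else {
    pairs$k / pmin(sizes[pairs$idx.x], sizes[pairs$idx.y])
  }
  keep <- coef >= cutoff
  ida <- collection$set_id[pairs$idx.x[keep]]
  idb <- collection$set_id[pairs$idx.y[keep]]
  swap <- ida > idb
  tibble::tibble(
    a = ifelse(swap, idb, ida),
    b = ifelse(swap, ida, idb),
    metric = metric,
    coefficient = coef[keep],
    intersection_size = as.integer(pairs$k[keep])
  ) |>
    dplyr::arrange(.data$a, .data$b)
}
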