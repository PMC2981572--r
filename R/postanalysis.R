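#' Fisher's exact overlap test between a query set and map nodes
#'
#' The query-set post-analysis: a user-supplied gene list (e.g. known
#' disease genes, targets of a regulator) is linked to every map node whose
#' gene-set it significantly overlaps, scored with the one-tailed Fisher's
#' exact test p-value as in [fisher_enrichment()]. Edges are returned only
#' for nominal p below `alpha` (default 1e-4; no multiple-testing
#' correction, matching the nominal-threshold convention of this analysis),
#' with display width `-log10(p)` so thickness encodes significance.
#'
#' @param network An `enrichment_map`.
#' @param query Character vector of query gene identifiers, or a named list
#'   of such vectors for multiple query sets (each tested independently at
#'   the nominal threshold).
#' @param collection The gene-set collection the map was built from.
#' @param universe Background gene population; default the union of all
#'   genes in `collection`, overridable (e.g. to the expression platform's
#'   gene list).
#' @param alpha Nominal significance threshold on p (default 1e-4).
#' @param log_base Base of the width logarithm, 10 by default (`exp(1)` for
#'   natural log).
#' @param query_id Name for an unnamed single query.
#' @return A tibble with columns `query_id`, `set_id`, `p_fisher`,
#'   `overlap_count`, `overlap_genes` (list-column), `width`; one row per
#'   passing (query, node) pair.
#' @export
query_overlap_test <- function(network, query, collection, universe = NULL,
                               alpha = 1e-4, log_base = 10,
                               query_id = "query") {
  stopifnot(inherits(network, "enrichment_map"))
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  }
  collection <- validate_gene_sets(collection)
  if (is.null(universe)) universe <- collection_universe(collection)
  universe <- unique(as.character(universe))
  queries <- if (is.list(query)) query else stats::setNames(list(query), query_id)
  if (is.null(names(queries)) || any(names(queries) == "")) {
    stop("multiple query sets must be named", call. = FALSE)
  }

  node_ids <- network$nodes$set_id[network$nodes$role == "geneset"]
  subcol <- restrict_to_universe(
    collection[collection$set_id %in% node_ids, ], universe
  )
  N <- length(universe)

  purrr::map_dfr(names(queries), function(qid) {
    q <- intersect(unique(as.character(queries[[qid]])), universe)
    if (length(q) == 0) {
      stop("query '", qid, "' is empty after restriction to the universe",
           call. = FALSE)
    }
    ov <- lapply(subcol$genes, intersect, y = q)
    k <- lengths(ov)
    p <- hyper_tail_p(k, lengths(subcol$genes), length(q), N)
    keep <- p < alpha
    tibble::tibble(
      query_id = qid,
      set_id = subcol$set_id[keep],
      p_fisher = p[keep],
      overlap_count = as.integer(k[keep]),
      overlap_genes = lapply(ov[keep], sort),
      width = -log(p[keep], base = log_base)
    )
  })
}

#' Attach a query signature to an enrichment map
#'
#' Adds one signature node per query set (role `"signature"`, triangle
#' shape, yellow colour hint, distinct from the enrichment gradient) and the
#' passing overlap edges (role `"signature"`, pink colour hint, width as
#' computed by [query_overlap_test()]). Existing nodes and similarity edges
#' are untouched. A signature node is placed at the centroid of its linked
#' nodes when the map has coordinates.
#'
#' @param network An `enrichment_map`.
#' @param query Character vector or named list, as given to
#'   [query_overlap_test()].
#' @param edges The tibble returned by [query_overlap_test()] on this
#'   network.
#' @param query_id Name for an unnamed single query.
#' @return The augmented `enrichment_map`.
#' @export
attach_signature <- function(network, query, edges, query_id = "query") {
  stopifnot(inherits(network, "enrichment_map"))
  queries <- if (is.list(query)) query else stats::setNames(list(query), query_id)
  clash <- intersect(names(queries), network$nodes$set_id)
  if (length(clash) > 0) {
    stop("signature id collides with an existing node: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  if (!"color" %in% names(network$nodes)) {
    network$nodes$color <- NA_character_
  }
  if (!"color" %in% names(network$edges)) {
    network$edges$color <- NA_character_
  }
  for (extra in c("p_fisher", "overlap_count")) {
    if (!extra %in% names(network$edges)) {
      network$edges[[extra]] <- if (extra == "overlap_count") NA_integer_ else NA_real_
    }
  }

  n_slots <- sum(grepl("^significant[0-9]+$", names(network$nodes)))
  for (qid in names(queries)) {
    qedges <- edges[edges$query_id == qid, ]
    if (nrow(qedges) == 0) {
      warning("query '", qid, "' has no passing overlap edges; ",
              "signature node added without edges", call. = FALSE)
    }
    partner <- match(qedges$set_id, network$nodes$set_id)
    node <- tibble::tibble(
      set_id = qid, label = qid,
      size = length(unique(queries[[qid]])),
      role = "signature", shape = "triangle"
    )
    for (d in seq_len(n_slots)) {
      node[[paste0("p", d)]] <- NA_real_
      node[[paste0("q", d)]] <- NA_real_
      node[[paste0("direction", d)]] <- NA_integer_
      node[[paste0("significant", d)]] <- FALSE
      node[[paste0("color_score", d)]] <- 0
    }
    has_xy <- length(partner) > 0 && !anyNA(network$nodes$x[partner])
    node$x <- if (has_xy) mean(network$nodes$x[partner]) else NA_real_
    node$y <- if (has_xy) mean(network$nodes$y[partner]) else NA_real_
    node$node_size <- NA_real_
    node$color <- "yellow"
    network$nodes <- dplyr::bind_rows(network$nodes, node)
    if (nrow(qedges) > 0) {
      network$edges <- dplyr::bind_rows(
        network$edges,
        tibble::tibble(
          a = qid, b = qedges$set_id,
          metric = NA_character_, coefficient = NA_real_,
          intersection_size = qedges$overlap_count,
          width = qedges$width, role = "signature", color = "pink",
          p_fisher = qedges$p_fisher, overlap_count = qedges$overlap_count
        )
      )
    }
  }
  network
}
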