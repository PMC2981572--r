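#' Signed colour score of an enrichment record
#'
#' Maps a record to the diverging red/white/blue gradient used on map nodes:
#' `score = direction * (1 - p_value)`, so colour intensity grows with
#' enrichment significance and the hue encodes the enriched class (+1 red,
#' -1 blue). Direction 0 (one-class analysis) is treated as +1. A
#' non-significant record maps to exactly 0 (white), as does p = 1. The
#' linear `1 - p` form keeps the score bounded in `[-1, 1]`; an unbounded
#' `-log10(p)` alternative is available for viewers that rescale themselves.
#'
#' @param p_value Numeric vector of nominal p-values.
#' @param direction Integer vector in \{-1, 0, +1\}, recycled.
#' @param significant Logical vector, recycled; `FALSE` forces the score
#'   to 0.
#' @param intensity `"linear"` (default, `1 - p`) or `"log"` (`-log10(p)`,
#'   unbounded).
#' @return Numeric vector; in `[-1, 1]` for the linear intensity.
#' @examples
#' color_score(c(0, 0.001, 1), c(1, -1, -1))
#' @export
color_score <- function(p_value, direction, significant = TRUE,
                        intensity = c("linear", "log")) {
  intensity <- match.arg(intensity)
  n <- max(length(p_value), length(direction), length(significant))
  p <- rep_len(as.numeric(p_value), n)
  dir <- rep_len(as.integer(direction), n)
  sig <- rep_len(as.logical(significant), n)
  dir[dir == 0L] <- 1L
  mag <- if (intensity == "linear") 1 - p else -log10(pmax(p, .Machine$double.xmin))
  out <- dir * mag
  out[!sig | is.na(p)] <- 0
  out
}

#' Build an enrichment map network
#'
#' Assembles the similarity network of significantly enriched gene-sets:
#' nodes are the union, over one or two datasets, of gene-sets passing the
#' significance filter (union semantics, so a set significant in either
#' dataset appears, with the other dataset's slot marked not significant);
#' edges are the similarity pairs among included nodes whose coefficient
#' passes the cutoff. Each node carries one slot per dataset holding the
#' dataset's (unfiltered) record, a significance flag, and the signed colour
#' score ([color_score()]), which is forced to 0 where the record failed the
#' filter or is absent.
#'
#' @param results An enrichment result tibble (its `dataset` column may hold
#'   one or two dataset names) or a list of one or two such tibbles.
#' @param collection The gene-set collection tibble defining node identity
#'   and gene membership; apply [filter_by_size()] /
#'   [restrict_to_universe()] beforehand. Significant records whose set_id
#'   is not in the collection are skipped with a warning and counted in
#'   `metadata$n_unresolved`.
#' @param metric,cutoff Similarity metric and threshold, see
#'   [build_similarity_edges()].
#' @param p_max,q_max Significance thresholds, see [filter_significant()].
#' @return An `enrichment_map` object: a list with tibbles `nodes` and
#'   `edges` plus a `metadata` list (metric, cutoff, thresholds, dataset
#'   names, unresolved count, layout seed once laid out).
#' @examples
#' sets <- gene_sets(c("S1", "S2"), list(letters[1:10], letters[3:12]))
#' res <- tibble::tibble(dataset = "d1", set_id = c("S1", "S2"),
#'                       p_value = c(1e-4, 2e-4), q_value = c(0.01, 0.01),
#'                       direction = c(1L, 1L))
#' build_map(res, sets)
#' @export
build_map <- function(results, collection,
                      metric = c("overlap", "jaccard"), cutoff = 0.5,
                      p_max = 0.001, q_max = 0.05) {
  metric <- match.arg(metric)
  collection <- validate_gene_sets(collection)
  if (is.data.frame(results)) {
    ds_names <- unique(results$dataset)
    results <- lapply(ds_names, function(d) results[results$dataset == d, ])
  } else if (is.list(results)) {
    ds_names <- vapply(results, function(r) r$dataset[1], "")
  } else {
    stop("results must be an enrichment tibble or a list of them",
         call. = FALSE)
  }
  if (length(results) < 1 || length(results) > 2) {
    stop("build_map supports one or two datasets, got ", length(results),
         call. = FALSE)
  }

  sig <- lapply(results, filter_significant, p_max = p_max, q_max = q_max)
  sig_ids <- unique(unlist(lapply(sig, `[[`, "set_id")))
  unresolved <- setdiff(sig_ids, collection$set_id)
  if (length(unresolved) > 0) {
    warning(length(unresolved),
            " significant set_id(s) not found in the collection, skipped: ",
            paste(utils::head(unresolved, 5), collapse = ", "),
            call. = FALSE)
  }
  node_ids <- collection$set_id[collection$set_id %in% sig_ids]
  if (length(node_ids) == 0) {
    stop("empty map: no gene-set passes the significance thresholds ",
         "(p < ", p_max, ", q < ", q_max, ") and resolves in the collection",
         call. = FALSE)
  }
  subcol <- collection[match(node_ids, collection$set_id), ]

  nodes <- tibble::tibble(
    set_id = subcol$set_id,
    label = subcol$description,
    size = lengths(subcol$genes),
    role = "geneset",
    shape = "ellipse"
  )
  for (d in seq_along(results)) {
    full <- results[[d]]
    i <- match(nodes$set_id, full$set_id)
    significant <- nodes$set_id %in% sig[[d]]$set_id
    nodes[[paste0("p", d)]] <- full$p_value[i]
    nodes[[paste0("q", d)]] <- full$q_value[i]
    nodes[[paste0("direction", d)]] <- full$direction[i]
    nodes[[paste0("significant", d)]] <- significant
    nodes[[paste0("color_score", d)]] <-
      color_score(full$p_value[i], dplyr::coalesce(full$direction[i], 0L),
                  significant)
  }
  nodes$x <- NA_real_
  nodes$y <- NA_real_
  nodes$node_size <- NA_real_

  edges <- build_similarity_edges(subcol, metric = metric, cutoff = cutoff)
  edges$width <- NA_real_
  edges$role <- rep("similarity", nrow(edges))

  structure(
    list(
      nodes = nodes,
      edges = edges,
      metadata = list(metric = metric, cutoff = cutoff, p_max = p_max,
                      q_max = q_max, datasets = as.character(ds_names),
                      n_unresolved = length(unresolved), seed = NA_integer_,
                      iterations = NA_integer_)
    ),
    class = "enrichment_map"
  )
}

#' @export
print.enrichment_map <- function(x, ...) {
  md <- x$metadata
  n_sig_edges <- sum(x$edges$role == "signature")
  cat("Enrichment map: ", sum(x$nodes$role == "geneset"), " gene-set nodes, ",
      nrow(x$edges) - n_sig_edges, " similarity edges",
      if (n_sig_edges > 0) paste0(", ", n_sig_edges, " signature edges"),
      "\n", sep = "")
  cat("  metric=", md$metric, " cutoff=", md$cutoff,
      " p<", md$p_max, " q<", md$q_max,
      " datasets: ", paste(md$datasets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attach display-size and edge-width style attributes
#'
#' Node display size is an affine, monotone map of the gene-set size onto
#' `size_range` over the map's size range (the smallest set gets the lower
#' bound, the largest the upper; equal-sized maps get the midpoint). Edge
#' width is an affine map of the similarity coefficient from
#' `[cutoff, 1]` onto `width_range`, so thickness is proportional to the
#' overlap between gene-sets. Signature edges keep their own
#' significance-derived widths.
#'
#' @param network An `enrichment_map`.
#' @param size_range,width_range Length-2 numeric display ranges
#'   (arbitrary units, e.g. pixels/points).
#' @return The network with `nodes$node_size` and `edges$width` filled.
#' @export
style_attributes <- function(network, size_range = c(20, 65),
                             width_range = c(0.5, 5)) {
  stopifnot(inherits(network, "enrichment_map"))
  gs <- network$nodes$role == "geneset"
  network$nodes$node_size[gs] <-
    affine_map(network$nodes$size[gs],
               range(network$nodes$size[gs]), size_range)
  sim <- network$edges$role == "similarity"
  if (any(sim)) {
    network$edges$width[sim] <-
      affine_map(network$edges$coefficient[sim],
                 c(network$metadata$cutoff, 1), width_range)
  }
  network
}

# Monotone affine map of `from` onto `to`; a degenerate source range maps
# everything to the midpoint, except the exact upper endpoint which keeps
# the upper bound (so coefficient 1 always gets maximal width).
affine_map <- function(x, from, to) {
  if (from[2] > from[1]) {
    out <- to[1] + (x - from[1]) / (from[2] - from[1]) * (to[2] - to[1])
  } else {
    out <- ifelse(x >= from[2], to[2], mean(to))
  }
  pmin(pmax(out, min(to)), max(to))
}

#' Weighted force-directed layout of an enrichment map
#'
#' Computes node coordinates with a Fruchterman-Reingold force-directed
#' layout in weighted mode: the similarity coefficient is the edge weight,
#' so strongly overlapping gene-sets are pulled together and redundant sets
#' form visual clusters. Each connected component is laid out independently
#' and components are placed on a well-separated grid (largest first);
#' singleton nodes go on a peripheral grid below the map. The result is
#' deterministic given `(seed, iterations)`; both are recorded in the
#' metadata. A single-node map is placed at the origin.
#'
#' @param network An `enrichment_map`.
#' @param seed Integer RNG seed (default 42).
#' @param iterations Force-directed iterations (default 100).
#' @return The network with `nodes$x`, `nodes$y` filled.
#' @export
layout_map <- function(network, seed = 42, iterations = 100) {
  stopifnot(inherits(network, "enrichment_map"))
  nodes <- network$nodes
  edges <- network$edges
  n <- nrow(nodes)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  if (n == 1) {
    network$nodes$x <- 0
    network$nodes$y <- 0
    network$metadata$seed <- as.integer(seed)
    network$metadata$iterations <- as.integer(iterations)
    return(network)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b,
               weight = dplyr::coalesce(edges$coefficient, 1)),
    directed = FALSE,
    vertices = data.frame(name = nodes$set_id)
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  coords <- matrix(0, nrow = n, ncol = 2)

  big <- which(sizes >= 2)
  # deterministic component order: size desc, then smallest member id
  first_id <- vapply(big, function(ci) {
    min(nodes$set_id[comp$membership == ci])
  }, "")
  big <- big[order(-sizes[big], first_id, method = "radix")]

  radii <- sqrt(pmax(sizes[big], 1))
  cell <- if (length(big) > 0) 2 * max(radii) + 6 else 0
  ncols <- max(1, ceiling(sqrt(length(big))))

  withr::with_seed(as.integer(seed), {
    for (j in seq_along(big)) {
      ci <- big[j]
      members <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(g, members)
      xy <- igraph::layout_with_fr(sub, niter = iterations,
                                   weights = igraph::E(sub)$weight)
      # centre, then scale to a radius ~ sqrt(component size)
      xy <- sweep(xy, 2, colMeans(xy))
      r <- max(sqrt(rowSums(xy^2)), .Machine$double.eps)
      xy <- xy * (sqrt(length(members)) / max(r))
      row <- (j - 1) %/% ncols
      col <- (j - 1) %% ncols
      xy[, 1] <- xy[, 1] + col * cell
      xy[, 2] <- xy[, 2] - row * cell
      coords[members, ] <- xy
    }
  })

  # singletons: peripheral grid below the laid-out components
  singles <- which(comp$membership %in% which(sizes == 1))
  singles <- singles[order(nodes$set_id[singles], method = "radix")]
  if (length(singles) > 0) {
    base_y <- if (length(big) > 0) min(coords[-singles, 2]) - cell else 0
    step <- 3
    per_row <- max(1, ceiling(sqrt(length(singles))))
    for (j in seq_along(singles)) {
      coords[singles[j], 1] <- ((j - 1) %% per_row) * step
      coords[singles[j], 2] <- base_y - ((j - 1) %/% per_row) * step
    }
  }

  network$nodes$x <- coords[, 1]
  network$nodes$y <- coords[, 2]
  network$metadata$seed <- as.integer(seed)
  network$metadata$iterations <- as.integer(iterations)
  network
}
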