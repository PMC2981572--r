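# GraphML import/export. The headless substitute for interactive rendering:
# all node/edge attributes (enrichment slots, colour scores, style, layout
# coordinates, role tags) travel in the file, so a round trip reproduces the
# network exactly and any GraphML-aware viewer can render the map.

graphml_type <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "int"
  else if (is.numeric(x)) "double"
  else "string"
}

graphml_format <- function(v) {
  if (is.na(v)) return(NA_character_)
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.double(v)) return(sprintf("%.17g", v))
  as.character(v)
}

graphml_parse <- function(s, type, na = TRUE) {
  if (is.na(s)) {
    return(switch(type, boolean = NA, int = NA_integer_,
                  double = NA_real_, NA_character_))
  }
  switch(type,
         boolean = identical(s, "true"),
         int = as.integer(s),
         double = as.numeric(s),
         s)
}

#' Export an enrichment map to GraphML
#'
#' Writes GraphML 1.0 with every node attribute (label, gene-set size,
#' per-dataset p/q/direction/significance/colour score, layout coordinates,
#' display size, role and shape hints) and edge attribute (metric,
#' coefficient, intersection size, width, role, and Fisher statistics for
#' signature edges) declared as typed keys. [import_graphml()] reproduces
#' the network losslessly.
#'
#' @param network An `enrichment_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "enrichment_map"))
  nodes <- network$nodes
  edges <- network$edges
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  node_cols <- names(nodes)
  edge_cols <- setdiff(names(edges), c("a", "b"))
  for (i in seq_along(node_cols)) {
    xml2::xml_add_child(doc, "key", id = paste0("n", i), "for" = "node",
                        attr.name = node_cols[i],
                        attr.type = graphml_type(nodes[[node_cols[i]]]))
  }
  for (i in seq_along(edge_cols)) {
    xml2::xml_add_child(doc, "key", id = paste0("e", i), "for" = "edge",
                        attr.name = edge_cols[i],
                        attr.type = graphml_type(edges[[edge_cols[i]]]))
  }
  xml2::xml_add_child(doc, "key", id = "meta", "for" = "graph",
                      attr.name = "metadata", attr.type = "string")
  graph <- xml2::xml_add_child(doc, "graph", id = "enrichment_map",
                               edgedefault = "undirected")
  meta <- xml2::xml_add_child(graph, "data", key = "meta")
  xml2::xml_text(meta) <- as.character(
    jsonlite::toJSON(network$metadata, auto_unbox = TRUE, digits = NA,
                     na = "null")
  )
  for (r in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$set_id[r])
    for (i in seq_along(node_cols)) {
      v <- graphml_format(nodes[[node_cols[i]]][r])
      if (!is.na(v)) {
        d <- xml2::xml_add_child(nd, "data", key = paste0("n", i))
        xml2::xml_text(d) <- v
      }
    }
  }
  for (r in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = edges$a[r], target = edges$b[r])
    for (i in seq_along(edge_cols)) {
      v <- graphml_format(edges[[edge_cols[i]]][r])
      if (!is.na(v)) {
        d <- xml2::xml_add_child(ed, "data", key = paste0("e", i))
        xml2::xml_text(d) <- v
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an enrichment map from GraphML
#'
#' Reads a file written by [export_graphml()] back into an
#' `enrichment_map` object.
#'
#' @param path Path to the GraphML file.
#' @return An `enrichment_map`.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  keys <- xml2::xml_find_all(doc, "./key")
  key_for <- xml2::xml_attr(keys, "for")
  key_id <- xml2::xml_attr(keys, "id")
  key_name <- xml2::xml_attr(keys, "attr.name")
  key_type <- xml2::xml_attr(keys, "attr.type")

  read_elems <- function(elems, which_for, id_attrs) {
    idx <- which(key_for == which_for)
    cols <- lapply(idx, function(i) {
      vals <- vapply(elems, function(el) {
        d <- xml2::xml_find_first(el, paste0("./data[@key='", key_id[i], "']"))
        if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
      }, "")
      tp <- key_type[i]
      template <- switch(tp, boolean = logical(1), int = integer(1),
                         double = double(1), character(1))
      vapply(vals, graphml_parse, template, type = tp, USE.NAMES = FALSE)
    })
    names(cols) <- key_name[idx]
    front <- lapply(id_attrs, function(a) {
      vapply(elems, xml2::xml_attr, "", attr = a)
    })
    tibble::as_tibble(c(front, cols))
  }

  node_elems <- xml2::xml_find_all(doc, "./graph/node")
  edge_elems <- xml2::xml_find_all(doc, "./graph/edge")
  nodes <- read_elems(node_elems, "node", list())
  edges <- read_elems(edge_elems, "edge",
                      list(a = "source", b = "target"))

  meta_el <- xml2::xml_find_first(doc, "./graph/data[@key='meta']")
  md_raw <- jsonlite::fromJSON(xml2::xml_text(meta_el), simplifyVector = TRUE)
  scalar_or_na <- function(v, as) if (is.null(v)) as(NA) else as(v)
  metadata <- list(
    metric = as.character(md_raw$metric),
    cutoff = as.numeric(md_raw$cutoff),
    p_max = as.numeric(md_raw$p_max),
    q_max = as.numeric(md_raw$q_max),
    datasets = as.character(md_raw$datasets),
    n_unresolved = as.integer(md_raw$n_unresolved),
    seed = scalar_or_na(md_raw$seed, as.integer),
    iterations = scalar_or_na(md_raw$iterations, as.integer)
  )
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "enrichment_map")
}

#' Export an enrichment map as plain tables
#'
#' Writes `node.tsv` and `edge.tsv` (all attributes) plus `map.sif`
#' (`a<TAB>overlaps<TAB>b` for similarity edges, `a<TAB>signature<TAB>b`
#' for query-set edges) into a directory.
#'
#' @param network An `enrichment_map`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_tables <- function(network, dir) {
  stopifnot(inherits(network, "enrichment_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(network$nodes, file.path(dir, "node.tsv"), progress = FALSE)
  readr::write_tsv(network$edges, file.path(dir, "edge.tsv"), progress = FALSE)
  rel <- ifelse(network$edges$role == "signature", "signature", "overlaps")
  sif <- paste(network$edges$a, rel, network$edges$b, sep = "\t")
  writeLines(sif, file.path(dir, "map.sif"))
  invisible(dir)
}
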