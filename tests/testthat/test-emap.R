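make_three_node_fixture <- function() {
  # S1/S2 overlap strongly; S3 is far from both
  col <- gene_sets(c("S1", "S2", "S3"),
                   list(sprintf("a%02d", 1:10),
                        c(sprintf("a%02d", 1:8), "b1", "b2"),
                        sprintf("c%02d", 1:10)))
  res <- enr_tbl(c("S1", "S2", "S3"), p = c(1e-4, 2e-4, 3e-4))
  list(col = col, res = res)
}

test_that("build_map assembles nodes from significant sets and edges", {
  fx <- make_three_node_fixture()
  map <- build_map(fx$res, fx$col)
  expect_s3_class(map, "enrichment_map")
  expect_equal(nrow(map$nodes), 3)
  expect_equal(nrow(map$edges), 1)
  expect_equal(map$edges$a, "S1")
  expect_equal(map$edges$b, "S2")
  expect_equal(map$nodes$size, c(10L, 10L, 10L))
  expect_true(all(map$nodes$significant1))

  # non-significant records excluded from nodes, kept out of edges
  res2 <- fx$res
  res2$p_value[3] <- 0.5
  map2 <- build_map(res2, fx$col)
  expect_equal(map2$nodes$set_id, c("S1", "S2"))

  # zero significant sets is an explanatory error
  res3 <- fx$res
  res3$p_value <- 0.9
  expect_error(build_map(res3, fx$col), "empty map")

  # unresolvable significant ids: warning + skip + metadata count
  res4 <- dplyr::bind_rows(fx$res, enr_tbl("GHOST", p = 1e-5))
  expect_warning(map4 <- build_map(res4, fx$col), "GHOST")
  expect_equal(map4$metadata$n_unresolved, 1L)
  expect_equal(nrow(map4$nodes), 3)
})

test_that("two-dataset maps use union semantics and swap symmetrically", {
  fx <- make_three_node_fixture()
  ds1 <- fx$res
  ds2 <- enr_tbl(c("S1", "S2", "S3"), p = c(1e-4, 0.5, 0.7),
                 dataset = "ds2")
  map <- build_map(dplyr::bind_rows(ds1, ds2), fx$col)
  expect_equal(map$metadata$datasets, c("ds1", "ds2"))
  expect_equal(nrow(map$nodes), 3) # union: S2, S3 significant only in ds1

  s2 <- map$nodes[map$nodes$set_id == "S2", ]
  expect_true(s2$significant1)
  expect_false(s2$significant2)
  expect_equal(s2$color_score2, 0)     # not significant -> white
  expect_equal(s2$p2, 0.5)             # unfiltered record kept in the slot

  swapped <- build_map(dplyr::bind_rows(ds2, ds1), fx$col)
  expect_equal(swapped$metadata$datasets, c("ds2", "ds1"))
  expect_equal(swapped$edges, map$edges)
  expect_equal(swapped$nodes$set_id, map$nodes$set_id)
  for (colname in c("p", "q", "direction", "significant", "color_score")) {
    expect_equal(swapped$nodes[[paste0(colname, 1)]],
                 map$nodes[[paste0(colname, 2)]])
    expect_equal(swapped$nodes[[paste0(colname, 2)]],
                 map$nodes[[paste0(colname, 1)]])
  }
})

test_that("color_score encodes direction and significance", {
  expect_equal(color_score(0, 1L), 1)
  expect_equal(color_score(1, -1L), 0)
  expect_equal(color_score(0.001, -1L), -0.999)
  # one-class analyses colour as the positive hue
  expect_equal(color_score(0.2, 0L), 0.8)
  # non-significant records are forced to white
  expect_equal(color_score(0.0001, 1L, significant = FALSE), 0)

  # odd in direction, strictly decreasing in p for fixed direction
  p <- seq(0, 1, by = 0.05)
  expect_equal(color_score(p, 1L), -color_score(p, -1L))
  expect_true(all(diff(color_score(p, 1L)) < 0))
  expect_equal(sign(color_score(c(0.2, 0.2), c(1L, -1L))), c(1, -1))
})

test_that("style attributes are monotone affine maps with fixed endpoints", {
  sizes <- c(10, 100, 500)
  col <- gene_sets(paste0("S", sizes),
                   lapply(sizes, function(n) sprintf("g%03d", seq_len(n))))
  res <- enr_tbl(col$set_id, p = rep(1e-4, 3))
  map <- build_map(res, col) |> style_attributes(size_range = c(20, 65))
  ns <- map$nodes$node_size
  expect_equal(ns[1], 20)
  expect_equal(ns[3], 65)
  expect_true(ns[1] < ns[2] && ns[2] < ns[3])

  # degenerate size range: all nodes get one display size
  eq <- gene_sets(c("A", "B"), list(sprintf("g%d", 1:10),
                                    sprintf("h%d", 1:10)))
  eqmap <- build_map(enr_tbl(c("A", "B"), p = c(1e-4, 1e-4)), eq) |>
    style_attributes()
  expect_equal(length(unique(eqmap$nodes$node_size)), 1)

  # edge widths: coefficient = cutoff -> min, = 1 -> max
  fx <- make_three_node_fixture()
  map <- build_map(fx$res, fx$col, cutoff = 0.2, metric = "jaccard") |>
    style_attributes(width_range = c(0.5, 5))
  w <- map$edges$width
  co <- map$edges$coefficient
  expect_equal(w, 0.5 + (co - 0.2) / 0.8 * 4.5)
})

test_that("layout is deterministic, separates cliques, handles singletons", {
  # two 5-set cliques with no cross edges
  mk_clique <- function(prefix, genes) {
    gene_sets(sprintf("%s%d", prefix, 1:5),
              lapply(1:5, function(i) c(genes, sprintf("%s_own%d", prefix, i))))
  }
  col <- dplyr::bind_rows(mk_clique("A", sprintf("ca%d", 1:10)),
                          mk_clique("B", sprintf("cb%d", 1:10)))
  res <- enr_tbl(col$set_id, p = rep(1e-4, 10))
  map <- build_map(res, col) |> layout_map(seed = 7, iterations = 80)
  expect_false(anyNA(map$nodes$x))

  xy <- as.matrix(map$nodes[c("x", "y")])
  isA <- startsWith(map$nodes$set_id, "A")
  d <- as.matrix(dist(xy))
  within <- mean(d[isA, isA][upper.tri(d[isA, isA])]) +
    mean(d[!isA, !isA][upper.tri(d[!isA, !isA])])
  between <- mean(d[isA, !isA])
  expect_lt(within / 2, between)

  # determinism
  map2 <- build_map(res, col) |> layout_map(seed = 7, iterations = 80)
  expect_equal(map$nodes$x, map2$nodes$x)
  expect_equal(map$nodes$y, map2$nodes$y)
  map3 <- build_map(res, col) |> layout_map(seed = 8, iterations = 80)
  expect_false(identical(map$nodes$x, map3$nodes$x))

  # single node at the origin
  single <- build_map(enr_tbl("A1", 1e-4), col[1, ]) |> layout_map()
  expect_equal(single$nodes$x, 0)
  expect_equal(single$nodes$y, 0)

  # singletons get placed too (peripheral grid, no NAs, no overlap)
  lone <- gene_sets("L", list(c("zz1", "zz2", "zz3")))
  res_l <- dplyr::bind_rows(res, enr_tbl("L", 1e-4))
  mixed <- build_map(res_l, dplyr::bind_rows(col, lone)) |> layout_map()
  expect_false(anyNA(mixed$nodes$x))
})

test_that("GraphML and table export round-trip the network", {
  fx <- make_three_node_fixture()
  map <- build_map(fx$res, fx$col) |>
    style_attributes() |>
    layout_map(seed = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(map, path)

  # parses under a standard XML parser with 3 node elements
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  expect_length(xml2::xml_find_all(doc, "./graph/node"), 3)

  back <- import_graphml(path)
  expect_equal(back$nodes, map$nodes)
  expect_equal(back$edges, map$edges)
  expect_equal(back$metadata, map$metadata)

  # empty edge list still round-trips as valid GraphML
  far <- gene_sets(c("X", "Y"), list(sprintf("x%d", 1:10),
                                     sprintf("y%d", 1:10)))
  emap <- build_map(enr_tbl(c("X", "Y"), c(1e-4, 1e-4)), far) |>
    style_attributes() |> layout_map()
  export_graphml(emap, path)
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  expect_length(xml2::xml_find_all(doc, "./graph/edge"), 0)
  back <- import_graphml(path)
  expect_equal(back$nodes, emap$nodes)
  expect_equal(nrow(back$edges), 0)

  dir <- withr::local_tempdir()
  export_tables(map, dir)
  expect_true(all(file.exists(file.path(dir, c("node.tsv", "edge.tsv",
                                               "map.sif")))))
  sif <- readLines(file.path(dir, "map.sif"))
  expect_equal(sif, "S1\toverlaps\tS2")
})

test_that("tidy, glance and autoplot expose the map", {
  fx <- make_three_node_fixture()
  map <- build_map(fx$res, fx$col) |> style_attributes() |> layout_map()
  expect_equal(tidy(map), map$nodes)
  expect_equal(tidy(map, "edges"), map$edges)
  g <- glance(map)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_edges, 1L)
  expect_equal(g$n_significant1, 3L)
  p <- autoplot(map)
  expect_s3_class(p, "ggplot")
})
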