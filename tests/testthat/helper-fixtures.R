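# Fixture builders and independent oracles shared across tests.

random_collection <- function(n_sets, universe_size = 200, min_g = 3,
                              max_g = 30, seed = 1) {
  withr::with_seed(seed, {
    universe <- sprintf("u%03d", seq_len(universe_size))
    genes <- lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(min_g:max_g, 1))
    })
    gene_sets(sprintf("R%03d", seq_len(n_sets)), genes)
  })
}

# Literal set-arithmetic oracle for the two coefficients, independent of the
# package's edge-list machinery.
brute_jc <- function(a, b) {
  length(intersect(a, b)) / length(unique(c(a, b)))
}
brute_oc <- function(a, b) {
  length(intersect(a, b)) / min(length(unique(a)), length(unique(b)))
}

# Exhaustive combinatorial oracle for the one-tailed overlap p-value:
# enumerate every possible query draw of size m from a universe of size N
# whose first n elements form the gene-set, and count draws overlapping the
# set in at least k elements.
enum_hyper_p <- function(N, n, m, k) {
  draws <- utils::combn(N, m)
  mean(colSums(draws <= n) >= k)
}

write_gsea_fixture <- function(path, name, p, q, nes = 1.5) {
  header <- paste("NAME", "GS<br> follows gene set", "GS DETAILS", "SIZE",
                  "ES", "NES", "NOM p-val", "FDR q-val", "FWER p-val",
                  "RANK AT MAX", "LEADING EDGE", sep = "\t")
  rows <- paste(name, "", "", 20, 0.5, rep_len(nes, length(name)),
                p, q, 0.1, 100, "tags=50%", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

# Minimal enrichment result tibble for map-building tests.
enr_tbl <- function(set_id, p, q = 0.01, direction = 1L,
                    dataset = "ds1") {
  tibble::tibble(dataset = dataset, set_id = set_id,
                 p_value = p, q_value = rep_len(q, length(set_id)),
                 direction = as.integer(rep_len(direction, length(set_id))),
                 score = NA_real_)
}

# Connected components of a map's similarity edges, as a membership table.
map_components <- function(map) {
  sim <- map$edges[map$edges$role == "similarity", ]
  g <- igraph::graph_from_data_frame(
    sim[c("a", "b")], directed = FALSE,
    vertices = map$nodes$set_id[map$nodes$role == "geneset"])
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

small_expr <- function(n_genes = 10, n_per_class = 3, seed = 1,
                       de_genes = character(0), effect = 3) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    samples <- c(sprintf("case_%d", seq_len(n_per_class)),
                 sprintf("ctrl_%d", seq_len(n_per_class)))
    m <- matrix(rnorm(n_genes * 2 * n_per_class, 7, 0.5),
                nrow = n_genes, dimnames = list(genes, samples))
    m[genes %in% de_genes, seq_len(n_per_class)] <-
      m[genes %in% de_genes, seq_len(n_per_class)] + effect
    expr_matrix(m, stats::setNames(rep(c("case", "control"),
                                       each = n_per_class), samples))
  })
}
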