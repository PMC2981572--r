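test_that("make_collection plants disjoint-core clusters and parent/child", {
  spec <- synth_spec(k_clusters = 2, core_size = 20, peripheral_size = 5,
                     sets_per_cluster = 4, seed = 71)
  made <- make_collection(spec)
  col <- made$collection
  truth <- made$truth

  # within-cluster OC >= core/(core+peripheral); between-cluster OC = 0
  for (i in seq_len(nrow(col) - 1)) {
    for (j in (i + 1):nrow(col)) {
      oc <- overlap_coeff(col$genes[[i]], col$genes[[j]])
      same <- truth$cluster[i] == truth$cluster[j]
      if (same) expect_gte(oc, 20 / 25) else expect_equal(oc, 0)
    }
  }

  # parent/child pairs: child strictly inside parent, OC exactly 1
  for (k in 1:2) {
    parent <- col$genes[[match(sprintf("C%d_parent", k), col$set_id)]]
    child <- col$genes[[match(sprintf("C%d_child", k), col$set_id)]]
    expect_true(all(child %in% parent))
    expect_lt(length(child), length(parent))
    expect_equal(overlap_coeff(parent, child), 1)
  }

  expect_error(make_collection(synth_spec(n_genes = 30, k_clusters = 3,
                                          core_size = 20)),
               "infeasible")
})

test_that("generators are pure functions of the spec (byte-identical files)", {
  spec <- synth_spec(k_clusters = 2, seed = 73, n_genes = 500)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synth_fixtures(spec, d1, two_datasets = TRUE)
  write_synth_fixtures(spec, d2, two_datasets = TRUE)
  for (f in c("sets.gmt", "enrichment.tsv", "enrichment2.tsv", "expr.gct",
              "classes.cls", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_synth_fixtures(synth_spec(k_clusters = 2, seed = 74, n_genes = 500), d3)
  expect_false(identical(readLines(file.path(d1, "sets.gmt")),
                         readLines(file.path(d3, "sets.gmt"))))
})

test_that("planted enrichment respects thresholds by construction", {
  spec <- synth_spec(k_clusters = 2, seed = 75, n_genes = 500)
  made <- make_collection(spec)
  enr <- make_enrichment(spec, made$collection, made$truth)
  planted <- attr(enr, "planted")
  sig <- filter_significant(enr)
  expect_setequal(sig$set_id, planted)

  # frac_significant = 0 -> nothing passes
  spec0 <- synth_spec(k_clusters = 2, frac_significant = 0, seed = 75,
                      n_genes = 500)
  enr0 <- make_enrichment(spec0, made$collection, made$truth)
  expect_equal(nrow(filter_significant(enr0)), 0)

  # mixed scheme plants both directions
  specm <- synth_spec(k_clusters = 2, direction_scheme = "mixed",
                      seed = 76, n_genes = 500)
  enrm <- make_enrichment(specm, made$collection, made$truth)
  expect_setequal(unique(enrm$direction), c(-1L, 1L))
})

test_that("second-dataset perturbation flips the expected share of calls", {
  # binomial check within 3 sigma, aggregated over several seeds
  flips <- 0; planted_total <- 0
  for (seed in 81:85) {
    spec <- synth_spec(k_clusters = 3, sets_per_cluster = 10,
                       perturb_fraction = 0.1, n_genes = 2000, seed = seed)
    made <- make_collection(spec)
    enr <- make_enrichment(spec, made$collection, made$truth,
                           two_datasets = TRUE)
    s1 <- filter_significant(enr[enr$dataset == "ds1", ])$set_id
    s2 <- filter_significant(enr[enr$dataset == "ds2", ])$set_id
    flips <- flips + length(setdiff(s1, s2))
    planted_total <- planted_total + length(s1)
  }
  expect_gt(planted_total, 0)
  p <- 0.1
  sigma <- sqrt(planted_total * p * (1 - p))
  expect_lt(abs(flips - planted_total * p), 3 * sigma)
})

test_that("planted differential expression separates from the null", {
  spec <- synth_spec(k_clusters = 2, effect_size = 5, noise_sd = 0.5,
                     seed = 91, n_genes = 300)
  made <- make_collection(spec)
  expr <- make_expression(spec, made$collection, de_sets = "C1_S1",
                          universe = made$universe)
  de <- attr(expr, "de_genes")
  sc <- score_genes_ttest(expr)
  # all planted DE genes rank above all null genes
  expect_equal(sort(sc$gene[seq_along(de)]), sort(de))

  # under the null (effect 0) statistics hover around zero
  spec0 <- synth_spec(k_clusters = 2, effect_size = 0, seed = 92,
                      n_genes = 300)
  expr0 <- make_expression(spec0, made$collection, de_sets = "C1_S1",
                           universe = made$universe)
  sc0 <- score_genes_ttest(expr0)
  expect_lt(mean(abs(sc0$statistic)), 2)
  # Welch t with 4 df has heavy tails: P(|t| > 6) ~ 4e-3, so allow the
  # binomially expected handful of exceedances rather than none
  expect_lt(sum(abs(sc0$statistic) > 6), 0.03 * nrow(sc0))
})

test_that("end-to-end: map components recover the planted clusters", {
  spec <- synth_spec(k_clusters = 3, seed = 95)
  made <- make_collection(spec)
  enr <- make_enrichment(spec, made$collection, made$truth)
  map <- build_map(enr, made$collection, metric = "overlap", cutoff = 0.5)
  comps <- map_components(map)
  planted <- split(made$truth$set_id, made$truth$cluster)
  norm <- function(groups) {
    unname(lapply(groups[order(vapply(groups, min, ""))], sort))
  }
  expect_equal(norm(comps), norm(planted))
})
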