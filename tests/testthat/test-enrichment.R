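test_that("read_gsea_reports maps fields, signs directions, handles blanks", {
  pos <- withr::local_tempfile(fileext = ".tsv")
  neg <- withr::local_tempfile(fileext = ".tsv")
  write_gsea_fixture(pos, sprintf("P%d", 1:6),
                     p = c(0.002, "", 0.5, 0.01, 0, 0.3),
                     q = c(0.04, 0.01, 0.9, 0.2, 0.001, 0.5))
  write_gsea_fixture(neg, sprintf("N%d", 1:4),
                     p = c(0.1, 0.2, 0.3, 0.4), q = c(0.5, 0.6, 0.7, 0.8),
                     nes = -1.2)
  res <- read_gsea_reports(pos, neg, "estrogen_24h")
  expect_equal(nrow(res), 10)
  expect_equal(sum(res$direction == 1L), 6)
  expect_equal(sum(res$direction == -1L), 4)
  expect_equal(res$p_value[res$set_id == "P1"], 0.002)
  expect_equal(res$q_value[res$set_id == "P1"], 0.04)
  # GSEA prints an empty cell for p below permutation resolution -> 0
  expect_equal(res$p_value[res$set_id == "P2"], 0)
  expect_true(all(res$dataset == "estrogen_24h"))

  # duplicate set across phenotype files is a format error
  write_gsea_fixture(neg, c("P1", "N1"), p = c(0.1, 0.2), q = c(0.3, 0.4))
  expect_error(read_gsea_reports(pos, neg), "both GSEA reports")

  # missing required column is named in the error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NAME\tSIZE\tES\tNES", "S1\t10\t0.5\t1.2"), bad)
  expect_error(read_gsea_reports(bad, neg), "NOM p-val")
})

test_that("read_generic_table handles optional columns and bad values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpvalue\tfdr\tdirection",
               "S1\t0.0005\t0.01\t+1",
               "S2\t0.2\t0.5\t-1"), path)
  res <- read_generic_table(path, "d1")
  expect_equal(res$set_id, c("S1", "S2"))
  expect_equal(res$p_value, c(0.0005, 0.2))
  expect_equal(res$q_value, c(0.01, 0.5))
  expect_equal(res$direction, c(1L, -1L))

  writeLines(c("id\tpvalue", "S1\t0.01"), path)
  res <- read_generic_table(path)
  expect_true(is.na(res$q_value))
  expect_equal(res$direction, 0L)

  writeLines(c("id\tpvalue\tdirection",
               "S1\t0.01\ttreated", "S2\t0.02\tuntreated",
               "S3\t0.03\ttreated"), path)
  res <- read_generic_table(path)
  expect_equal(res$direction, c(1L, -1L, 1L))

  writeLines(c("id\tpvalue", "S1\t1.5"), path)
  expect_error(read_generic_table(path), "row 1")
  writeLines(c("id\tpvalue", "S1\tnotanumber"), path)
  expect_error(read_generic_table(path), "non-numeric")
  writeLines(c("id\tother", "S1\t1"), path)
  expect_error(read_generic_table(path), "pvalue")
})

test_that("enrichment tables round-trip through the generic writer", {
  res <- new_res <- tibble::tibble(
    dataset = "d1", set_id = sprintf("S%02d", 1:20),
    p_value = withr::with_seed(4, runif(20)),
    q_value = c(NA, withr::with_seed(5, runif(19))),
    direction = rep(c(1L, -1L, 0L, 1L), 5), score = NA_real_
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_generic_table(path, "d1")
  expect_equal(back, res)
})

test_that("filter_significant applies strict thresholds and is idempotent", {
  # boundary straddle: strict inequality on both thresholds
  res <- enr_tbl(c("keep", "p_at", "q_at", "p_over"),
                 p = c(0.0005, 0.001, 0.0005, 0.002),
                 q = c(0.01, 0.01, 0.05, 0.01))
  kept <- filter_significant(res)
  expect_equal(kept$set_id, "keep")
  expect_equal(filter_significant(kept), kept)

  # missing q is filtered on p alone
  res$q_value <- NA_real_
  expect_equal(filter_significant(res)$set_id, c("keep", "q_at"))

  # brute-force predicate scan on random records
  rand <- withr::with_seed(21, enr_tbl(
    sprintf("S%03d", 1:500),
    p = sample(c(runif(250), runif(125, 0, 0.002), rep(0.001, 125))),
    q = sample(c(runif(250), runif(125, 0, 0.1), rep(0.05, 125)))
  ))
  kept <- filter_significant(rand, 0.001, 0.05)
  brute <- rand$set_id[rand$p_value < 0.001 &
                         (is.na(rand$q_value) | rand$q_value < 0.05)]
  expect_equal(kept$set_id, brute)
  expect_error(filter_significant(rand, 0, 0.05), "thresholds")
})

test_that("fisher_enrichment matches exact hypergeometric values", {
  sets <- gene_sets("S1", list(letters[1:5]))
  res <- fisher_enrichment(letters[1:5], sets, letters[1:10])
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$direction, 0L)

  # zero overlap -> p = 1
  res <- fisher_enrichment(letters[6:10], sets, letters[1:10])
  expect_equal(res$p_value, 1)

  # BH q-values over all tested sets
  col <- gene_sets(c("A", "B"), list(letters[1:5], letters[6:10]))
  res <- fisher_enrichment(letters[1:5], col, letters[1:10])
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))

  expect_error(fisher_enrichment(character(0), sets, letters[1:10]),
               "empty")
  expect_error(fisher_enrichment(letters[1:3], sets, character(0)),
               "empty")
  expect_warning(
    fisher_enrichment(c("a", "zzz"), sets, letters[1:10]),
    "outside the universe")
})

test_that("fisher p is non-increasing in the overlap and in (0,1]", {
  N <- 40; n <- 12; m <- 9
  p <- vapply(0:9, function(k) {
    sets <- gene_sets("S", list(sprintf("u%02d", seq_len(n))))
    q <- c(sprintf("u%02d", seq_len(k)),
           sprintf("x%02d", seq_len(m - k)))
    fisher_enrichment(q, sets, c(sprintf("u%02d", seq_len(n)),
                                 sprintf("x%02d", seq_len(N - n))))$p_value
  }, 0)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})
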