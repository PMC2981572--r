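#' Specification for synthetic fixture generation
#'
#' Describes a synthetic study with known planted structure: a gene
#' universe partitioned into `k_clusters` gene-disjoint clusters, each
#' cluster holding `sets_per_cluster` gene-sets that share a `core_size`
#' core plus `peripheral_size` private genes (so within-cluster overlap
#' coefficients are at least `core_size / (core_size + peripheral_size)`
#' and between-cluster coefficients are exactly 0), enrichment results with
#' planted significance, and a two-class expression matrix with planted
#' differential expression. All generators are pure functions of the spec,
#' including its seed.
#'
#' Defaults mirror a small two-class microarray study: 3 replicates per
#' class, log2-scale baseline around 7, noise sd 0.5, and a 2 log2-unit
#' shift in differentially expressed genes.
#'
#' @param n_genes Universe size.
#' @param k_clusters Planted cluster count.
#' @param sets_per_cluster Gene-sets per cluster (in addition to one
#'   parent/child pair per cluster).
#' @param core_size Genes shared by all sets of a cluster.
#' @param peripheral_size Private genes per set.
#' @param frac_significant Fraction of planted sets given significant
#'   enrichment records.
#' @param direction_scheme `"all_up"` or `"mixed"`.
#' @param n_samples_per_class Samples per class in the expression matrix.
#' @param effect_size Mean shift (expression units) added to case samples
#'   for genes of differentially expressed sets.
#' @param noise_sd Standard deviation of baseline expression noise.
#' @param perturb_fraction Fraction of planted significance calls flipped in
#'   the second dataset of a two-dataset enrichment (emulating a
#'   time-course contrast).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_genes = 2000, k_clusters = 3, sets_per_cluster = 6,
                       core_size = 20, peripheral_size = 5,
                       frac_significant = 1,
                       direction_scheme = c("all_up", "mixed"),
                       n_samples_per_class = 3, effect_size = 2,
                       noise_sd = 0.5, perturb_fraction = 0.1, seed = 42) {
  direction_scheme <- match.arg(direction_scheme)
  spec <- list(n_genes = as.integer(n_genes),
               k_clusters = as.integer(k_clusters),
               sets_per_cluster = as.integer(sets_per_cluster),
               core_size = as.integer(core_size),
               peripheral_size = as.integer(peripheral_size),
               frac_significant = frac_significant,
               direction_scheme = direction_scheme,
               n_samples_per_class = as.integer(n_samples_per_class),
               effect_size = effect_size, noise_sd = noise_sd,
               perturb_fraction = perturb_fraction, seed = as.integer(seed))
  counts <- unlist(spec[c("n_genes", "k_clusters", "sets_per_cluster",
                          "core_size", "peripheral_size",
                          "n_samples_per_class")])
  if (any(is.na(counts) | counts < 1)) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (is.na(spec$frac_significant) || spec$frac_significant < 0 ||
      spec$frac_significant > 1) {
    stop("frac_significant must be in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "synth_spec")
}

synth_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a gene-set collection with planted clusters
#'
#' Each cluster draws a private gene pool (clusters are gene-disjoint, so
#' between-cluster overlap is exactly 0); its sets share the cluster core
#' and add private peripheral genes. One parent/child pair per cluster
#' (child a strict subset of the parent) exercises the maximal
#' overlap-coefficient property.
#'
#' @param spec A [synth_spec()].
#' @return A list with `collection` (gene-set tibble), `truth` (tibble
#'   `set_id`, `cluster`) and `universe` (all gene ids).
#' @export
make_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  pool_size <- spec$core_size + spec$sets_per_cluster * spec$peripheral_size
  if (spec$core_size < 2) {
    stop("core_size must be at least 2 (the child set must be a strict, ",
         "non-empty subset of the parent core)", call. = FALSE)
  }
  if (spec$core_size + spec$peripheral_size > spec$n_genes / spec$k_clusters ||
      pool_size * spec$k_clusters > spec$n_genes) {
    stop("infeasible sizes: clusters need ", pool_size * spec$k_clusters,
         " genes but the universe has ", spec$n_genes, call. = FALSE)
  }
  universe <- synth_gene_ids(spec$n_genes)
  withr::with_seed(spec$seed, {
    shuffled <- sample(universe)
    ids <- character(0); genes <- list(); cluster <- character(0)
    for (k in seq_len(spec$k_clusters)) {
      pool <- shuffled[((k - 1) * pool_size + 1):(k * pool_size)]
      core <- pool[seq_len(spec$core_size)]
      periph <- pool[-seq_len(spec$core_size)]
      for (s in seq_len(spec$sets_per_cluster)) {
        own <- periph[((s - 1) * spec$peripheral_size + 1):
                        (s * spec$peripheral_size)]
        ids <- c(ids, sprintf("C%d_S%d", k, s))
        genes <- c(genes, list(c(core, own)))
        cluster <- c(cluster, sprintf("C%d", k))
      }
      # parent = full core, child = strict subset of it (OC exactly 1)
      ids <- c(ids, sprintf("C%d_parent", k), sprintf("C%d_child", k))
      child_n <- min(spec$core_size - 1L, max(2L, spec$core_size %/% 2L))
      genes <- c(genes, list(core), list(core[seq_len(child_n)]))
      cluster <- c(cluster, sprintf("C%d", k), sprintf("C%d", k))
    }
  })
  list(
    collection = gene_sets(ids, genes,
                           description = paste("synthetic set", ids)),
    truth = tibble::tibble(set_id = ids, cluster = cluster),
    universe = universe
  )
}

#' Generate enrichment results with planted significance
#'
#' Planted-significant sets draw p ~ Uniform(0, 0.0005) and
#' q ~ Uniform(0, 0.04) — inside the default thresholds with a margin, so
#' boundary flakiness cannot occur; the remaining sets draw
#' p ~ Uniform(0.01, 1) and q ~ Uniform(0.06, 1). Directions follow the
#' spec's scheme. With `two_datasets = TRUE`, the second dataset
#' independently flips each planted significance call with probability
#' `perturb_fraction`, emulating a two-time-point contrast.
#'
#' @param spec A [synth_spec()].
#' @param collection The collection from [make_collection()].
#' @param truth The truth tibble from [make_collection()] (its sets are the
#'   planted candidates).
#' @param two_datasets If `TRUE`, return records for two datasets
#'   (`"ds1"`, `"ds2"`) in one tibble.
#' @return An enrichment result tibble; the planted significant ids are in
#'   `attr(, "planted")`.
#' @export
make_enrichment <- function(spec, collection, truth, two_datasets = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  collection <- validate_gene_sets(collection)
  ids <- collection$set_id
  planted_pool <- intersect(ids, truth$set_id)
  withr::with_seed(spec$seed + 1L, {
    n_sig <- round(spec$frac_significant * length(planted_pool))
    planted <- sort(sample(planted_pool, n_sig))
    draw <- function(sig) {
      p <- ifelse(sig, stats::runif(length(ids), 0, 0.0005),
                  stats::runif(length(ids), 0.01, 1))
      q <- ifelse(sig, stats::runif(length(ids), 0, 0.04),
                  stats::runif(length(ids), 0.06, 1))
      list(p = p, q = q)
    }
    dir <- if (spec$direction_scheme == "all_up") {
      rep(1L, length(ids))
    } else {
      sample(c(-1L, 1L), length(ids), replace = TRUE)
    }
    sig1 <- ids %in% planted
    d1 <- draw(sig1)
    res <- new_enrichment_result("ds1", ids, d1$p, d1$q, dir)
    if (two_datasets) {
      flip <- stats::runif(length(ids)) < spec$perturb_fraction
      sig2 <- ifelse(sig1, sig1 & !flip, sig1)
      d2 <- draw(sig2)
      res <- dplyr::bind_rows(
        res, new_enrichment_result("ds2", ids, d2$p, d2$q, dir))
    }
  })
  attr(res, "planted") <- planted
  res
}

#' Generate a two-class expression matrix with planted DE gene-sets
#'
#' Baseline values are Normal(7, `noise_sd`) per cell (a log2-rma-like
#' scale); genes belonging to any of `de_sets` are shifted by
#' `+effect_size` in the case class. Class labels are `"case"` and
#' `"control"`, `n_samples_per_class` each.
#'
#' @param spec A [synth_spec()].
#' @param collection The collection from [make_collection()].
#' @param de_sets Character vector of set_ids whose genes are
#'   differentially expressed.
#' @param universe Gene ids to include as matrix rows (default: the
#'   collection's union).
#' @return An `expr_matrix` with classes; planted DE gene ids in
#'   `attr(, "de_genes")`.
#' @export
make_expression <- function(spec, collection, de_sets,
                            universe = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  collection <- validate_gene_sets(collection)
  if (is.null(universe)) universe <- collection_universe(collection)
  de_genes <- unique(unlist(
    collection$genes[collection$set_id %in% de_sets], use.names = FALSE))
  n <- spec$n_samples_per_class
  samples <- c(sprintf("case_%d", seq_len(n)),
               sprintf("control_%d", seq_len(n)))
  classes <- stats::setNames(rep(c("case", "control"), each = n), samples)
  withr::with_seed(spec$seed + 2L, {
    m <- matrix(stats::rnorm(length(universe) * 2 * n, mean = 7,
                             sd = spec$noise_sd),
                nrow = length(universe),
                dimnames = list(universe, samples))
    m[rownames(m) %in% de_genes, seq_len(n)] <-
      m[rownames(m) %in% de_genes, seq_len(n)] + spec$effect_size
  })
  out <- expr_matrix(m, classes)
  attr(out, "de_genes") <- intersect(universe, de_genes)
  out
}

#' Write a full synthetic fixture set to disk
#'
#' Emits `sets.gmt`, `enrichment.tsv` (and `enrichment2.tsv` for two
#' datasets), `expr.gct`, `classes.cls` and `truth.json` (planted labels)
#' into a directory. Everything is a pure function of the spec, so a fixed
#' seed reproduces identical files.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @param two_datasets Generate one or two enrichment tables.
#' @return The directory, invisibly.
#' @export
write_synth_fixtures <- function(spec, dir, two_datasets = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  made <- make_collection(spec)
  enr <- make_enrichment(spec, made$collection, made$truth,
                         two_datasets = two_datasets)
  de_sets <- made$truth$set_id[made$truth$cluster == made$truth$cluster[1]]
  expr <- make_expression(spec, made$collection, de_sets,
                          universe = made$universe)
  write_gmt(made$collection, file.path(dir, "sets.gmt"))
  write_enrichment(enr[enr$dataset == "ds1", ],
                   file.path(dir, "enrichment.tsv"))
  if (two_datasets) {
    write_enrichment(enr[enr$dataset == "ds2", ],
                     file.path(dir, "enrichment2.tsv"))
  }
  write_gct(expr, file.path(dir, "expr.gct"))
  write_cls(expr$classes, file.path(dir, "classes.cls"))
  jsonlite::write_json(
    list(clusters = split(made$truth$set_id, made$truth$cluster),
         planted_significant = attr(enr, "planted"),
         de_sets = de_sets),
    file.path(dir, "truth.json"), pretty = TRUE
  )
  invisible(dir)
}
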