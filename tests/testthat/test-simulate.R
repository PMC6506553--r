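test_that("the simulator is deterministic and validates its configuration", {
  cfg <- simulation_config(n_genes = 300, states = c(E = 10, L = 8),
                           modules = data.frame(size = 50, loading_early = 1.5,
                                                loading_late = 0, mean_early = 6,
                                                mean_late = 6),
                           n_shift = 20, seed = 7)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$genes, s2$truth$genes)
  s3 <- simulate_counts(simulation_config(n_genes = 300, states = c(E = 10, L = 8),
                                          modules = cfg$modules, n_shift = 20,
                                          seed = 8))
  expect_false(identical(s1$counts$counts, s3$counts$counts))

  expect_error(simulation_config(seed = 1, n_genes = 100), "exceed")
  expect_error(simulation_config(n_genes = 100), "seed")
  tg <- s1$truth$genes
  expect_equal(sum(tg$dvc_flag), 50)
  expect_equal(sum(tg$shift_flag), 20)
  expect_true(all(table(tg$module[tg$module != "none"]) == 50))
})

test_that("planted loadings drive within-module correlation monotonically", {
  mean_abs_r <- sapply(c(0, 0.5, 1.0, 1.5), function(l) {
    cfg <- simulation_config(n_genes = 80, states = c(E = 92, L = 10),
                             modules = data.frame(size = 40, loading_early = l,
                                                  loading_late = 0,
                                                  mean_early = 6, mean_late = 6),
                             n_shift = 0, seed = 13)
    sim <- simulate_counts(cfg)
    em <- cpm_log2(sim$counts, factors = rep(1, 102))
    r <- cor(t(em$values[1:40, sim$counts$states == "E"]))
    mean(abs(r[upper.tri(r)]))
  })
  expect_true(all(diff(mean_abs_r) > 0))
  # zero loading: only sampling noise at n = 92 (checked over 20 seeds)
  null_r <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 60, states = c(E = 92, L = 10),
                             modules = data.frame(size = 30, loading_early = 0,
                                                  loading_late = 0,
                                                  mean_early = 6, mean_late = 6),
                             n_shift = 0, seed = 100 + s)
    sim <- simulate_counts(cfg)
    em <- cpm_log2(sim$counts, factors = rep(1, 102))
    r <- cor(t(em$values[1:30, sim$counts$states == "E"]))
    mean(abs(r[upper.tri(r)]))
  })
  expect_true(all(null_r <= 0.15))
})

test_that("marginal count means match the configured baseline within Monte-Carlo error", {
  means <- sapply(1:50, function(s) {
    cfg <- simulation_config(n_genes = 40, states = c(E = 30, L = 10),
                             modules = data.frame(size = 40, loading_early = 0,
                                                  loading_late = 0,
                                                  mean_early = 5, mean_late = 5),
                             n_shift = 0, seed = 200 + s)
    sim <- simulate_counts(cfg)
    # remove the library-size tilt before comparing with 2^mean_early
    sw <- sweep(sim$counts$counts, 2,
                sim$truth$lib_sizes / exp(cfg$libsize_log_mean +
                                            cfg$libsize_log_sd^2 / 2), "/")
    mean(sw)
  })
  se <- sd(means) / sqrt(length(means))
  expect_lte(abs(mean(means) - 2^5), 3 * se)
})

test_that("planted DVC genes lose variability after the transition in nearly all seeds", {
  drops <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 150, states = c(E = 92, L = 22),
                             modules = data.frame(size = 60, loading_early = 1.5,
                                                  loading_late = 0,
                                                  mean_early = 6, mean_late = 6),
                             n_shift = 0, seed = 300 + s)
    sim <- simulate_counts(cfg)
    em <- cpm_log2(suppressMessages(filter_low_expression(sim$counts)))
    v <- differential_variability(em, "E", "L")
    planted <- sim$truth$genes$gene[sim$truth$genes$dvc_flag]
    mean(v$sd_early[v$gene %in% planted] > v$sd_late[v$gene %in% planted])
  })
  expect_gte(mean(drops), 0.95)
})

test_that("regulatory tracks wire the designated TF to planted genes", {
  cfg <- simulation_config(n_genes = 500, states = c(E = 10, L = 8),
                           modules = data.frame(size = 100, loading_early = 1.5,
                                                loading_late = 0, mean_early = 6,
                                                mean_late = 6),
                           n_shift = 0, seed = 19)
  sim <- simulate_counts(cfg)
  tracks <- simulate_regulatory_tracks(cfg, sim$truth, n_tf = 4, n_targets = 60)
  expect_identical(tracks$regulator, "TF01")
  planted <- sim$truth$genes$gene[sim$truth$genes$dvc_flag]
  expect_true(all(tracks$tf_targets$TF01 %in% planted))

  # the interval route reconstructs exactly the intended target sets
  for (tf in names(tracks$peaks)) {
    ov <- intersect_intervals(tracks$peaks[[tf]], tracks$dnase)
    got <- genes_near_regions(ov, tracks$loci, window = 1e6)
    expect_identical(got, tracks$tf_targets[[tf]])
  }

  # peaks far from every gene yield an empty target set
  far <- data.frame(chrom = "chr99", start = 1, end = 500)
  ov <- suppressWarnings(intersect_intervals(far, tracks$dnase))
  expect_equal(nrow(ov), 0)

  # enrichment ranks the designated regulator first
  universe <- sim$truth$genes$gene
  tf_sets <- lapply(names(tracks$peaks), function(tf)
    genes_near_regions(intersect_intervals(tracks$peaks[[tf]], tracks$dnase),
                       tracks$loci, 1e6))
  names(tf_sets) <- names(tracks$peaks)
  res <- tf_target_enrichment(planted, tf_sets, universe)
  expect_identical(res$set[1], "TF01")
})

test_that("a written simulation reloads identically through both count formats", {
  cfg <- simulation_config(n_genes = 120, states = c(E = 6, L = 5),
                           modules = data.frame(size = 30, loading_early = 1.5,
                                                loading_late = 0, mean_early = 6,
                                                mean_late = 6),
                           n_shift = 10, seed = 23)
  sim <- simulate_counts(cfg)
  tracks <- simulate_regulatory_tracks(cfg, sim$truth, n_tf = 2, n_targets = 10)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, cfg, tracks)
  expect_true(all(file.exists(file.path(dir, c("counts.tsv", "counts.mtx",
                                               "states.tsv", "truth_genes.tsv",
                                               "dnase.bed", "gene_loci.tsv",
                                               "tf_targets.gmt",
                                               "simulation.json")))))
  cm_tsv <- read_counts(file.path(dir, "counts.tsv"), "tsv",
                        states_file = file.path(dir, "states.tsv"),
                        state_order = c("E", "L"))
  cm_mtx <- read_counts(file.path(dir, "counts.mtx"), "mtx",
                        states_file = file.path(dir, "states.tsv"),
                        genes_file = file.path(dir, "genes.tsv"),
                        cells_file = file.path(dir, "cells.tsv"),
                        state_order = c("E", "L"))
  expect_identical(cm_tsv$counts, sim$counts$counts)
  expect_equal(cm_mtx$counts, sim$counts$counts)
  prov <- jsonlite::read_json(file.path(dir, "simulation.json"))
  expect_equal(prov$seed, 23)
})
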