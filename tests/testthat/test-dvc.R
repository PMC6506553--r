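test_that("Levene statistic matches hand computation and degenerate cases", {
  expect_equal(levene_two_sample(c(0, 2), c(5, 7)), list(stat = 0, p = 1))

  x <- 1:6; y <- 3 * (1:6)
  # longhand: deviations from the group means
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  zbar <- mean(c(zx, zy))
  ssb <- 6 * (mean(zx) - zbar)^2 + 6 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  f_hand <- (12 - 2) * ssb / ssw
  res <- levene_two_sample(x, y)
  expect_equal(res$stat, f_hand)
  expect_equal(res$stat, 6.75)
  expect_equal(res$p, pf(6.75, 1, 10, lower.tail = FALSE))

  skip_if_not_installed("car")
  g <- factor(rep(c("a", "b"), each = 6))
  ref <- car::leveneTest(c(x, y), g, center = mean)
  expect_equal(res$stat, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(res$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
  ref_m <- car::leveneTest(c(x, y), g, center = median)
  res_m <- levene_two_sample(x, y, center = "median")
  expect_equal(res_m$stat, ref_m[1, "F value"], tolerance = 1e-12)
})

test_that("Levene test holds its nominal type-I error rate", {
  set.seed(99)
  reps <- 10000
  xe <- matrix(rnorm(reps * 20), reps, 20)
  xl <- matrix(rnorm(reps * 20), reps, 20)
  p <- dvcscan:::.levene_rows(xe, xl)$p
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  # vectorized path agrees with the scalar op
  idx <- c(1, 500, 9999)
  for (i in idx)
    expect_equal(p[i], levene_two_sample(xe[i, ], xl[i, ])$p, tolerance = 1e-12)
})

test_that("differential variability calls planted variance-drop genes", {
  # 100 planted SD-ratio-3 genes among 900 nulls, 40 cells per state;
  # recovery and false calls averaged over 10 fixed replicates to damp
  # Monte-Carlo noise on the power estimate
  n <- 1000
  stats <- sapply(1:10, function(seed) {
    set.seed(seed)
    xe <- matrix(rnorm(n * 40, sd = rep(c(3, 1), c(100, 900))), n, 40)
    xl <- matrix(rnorm(n * 40, sd = 1), n, 40)
    vals <- cbind(xe, xl)
    dimnames(vals) <- list(sprintf("g%04d", 1:n), sprintf("c%02d", 1:80))
    em <- expr_from_values(vals, rep(c("E", "L"), each = 40))
    var <- differential_variability(em, "E", "L", alpha = 0.001)
    c(hits = sum(var$direction[1:100] == "decreased"),
      false = sum(var$direction[101:1000] != "none"))
  })
  expect_gte(mean(stats["hits", ]), 90)
  expect_lte(mean(stats["false", ]), 2)

  # delta_v sign and value on one instance
  set.seed(1)
  xe <- matrix(rnorm(n * 40, sd = rep(c(3, 1), c(100, 900))), n, 40)
  xl <- matrix(rnorm(n * 40, sd = 1), n, 40)
  vals <- cbind(xe, xl)
  dimnames(vals) <- list(sprintf("g%04d", 1:n), sprintf("c%02d", 1:80))
  em <- expr_from_values(vals, rep(c("E", "L"), each = 40))
  var <- differential_variability(em, "E", "L", alpha = 0.001)
  expect_equal(var$delta_v, log2(var$sd_early / var$sd_late))

  # identical value sets: no direction, delta 0
  same <- expr_from_values(cbind(vals[, 1:40], vals[, 1:40]),
                           rep(c("E", "L"), each = 40))
  colnames(same$values) <- sprintf("c%02d", 1:80)
  v0 <- differential_variability(same, "E", "L")
  expect_true(all(v0$delta_v == 0))
  expect_true(all(v0$direction == "none"))

  # constant gene in one state: capped and flagged
  vals2 <- vals
  vals2[1, 41:80] <- 7
  emc <- expr_from_values(vals2, rep(c("E", "L"), each = 40))
  vc <- differential_variability(emc, "E", "L")
  expect_equal(vc$delta_v[1], 20)
  expect_true(vc$capped[1])
})

test_that("BH adjustment equals the brute-force step-up rule and bounds p", {
  set.seed(55)
  for (i in 1:20) {
    p <- runif(200)^2
    q <- p.adjust(p, "BH")   # the path differential_variability uses
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("delta_v and delta_c are antisymmetric under state swap", {
  cfg <- simulation_config(
    n_genes = 500, states = c(E = 30, L = 30),
    modules = data.frame(size = 80, loading_early = 1.2, loading_late = 0.2,
                         mean_early = 6, mean_late = 6),
    n_shift = 0, seed = 61)
  sim <- simulate_counts(cfg)
  em <- cpm_log2(suppressMessages(filter_low_expression(sim$counts)))
  v1 <- differential_variability(em, "E", "L")
  v2 <- differential_variability(em, "L", "E")
  expect_equal(v1$delta_v, -v2$delta_v)
  expect_equal(v1$levene_p, v2$levene_p)

  pc <- pairwise_pcc(zscore_per_state(em), "E")
  mods <- cut_tree_dynamic(cluster_tree(pc), pc, min_size = 50)
  c1 <- differential_correlation(em, mods, "E", "L")
  c2 <- differential_correlation(em, mods, "L", "E")
  expect_equal(c1$delta_c, -c2$delta_c)
})

test_that("differential correlation uses early-state modules in both states", {
  # module of exact copies in both states: c stays 1, delta 0
  set.seed(71)
  base_e <- rnorm(10); base_l <- rnorm(10)
  vals <- rbind(g1 = c(base_e, base_l), g2 = c(base_e, base_l),
                g3 = c(base_e, base_l),
                noise1 = rnorm(20), noise2 = rnorm(20))
  colnames(vals) <- paste0("c", 1:20)
  em <- expr_from_values(vals, rep(c("E", "L"), each = 10))
  mods <- structure(data.frame(gene = rownames(vals),
                               module = c("black", "black", "black",
                                          "unassigned", "unassigned"),
                               stringsAsFactors = FALSE),
                    class = c("dvc_modules", "data.frame"),
                    min_size = 3, source_state = "E")
  cc <- differential_correlation(em, mods, "E", "L")
  expect_equal(cc$c_early[1:3], rep(1, 3))
  expect_equal(cc$c_late[1:3], rep(1, 3))
  expect_equal(cc$delta_c[1:3], rep(0, 3))
  # unassigned genes carry missing values
  expect_true(all(is.na(cc$delta_c[4:5])))

  # planted module correlated early, independent late
  cfg <- simulation_config(
    n_genes = 400, states = c(E = 40, L = 40),
    modules = data.frame(size = 100, loading_early = 1.5, loading_late = 0,
                         mean_early = 6, mean_late = 6),
    n_shift = 0, seed = 72)
  sim <- simulate_counts(cfg)
  emp <- cpm_log2(suppressMessages(filter_low_expression(sim$counts)))
  pc <- pairwise_pcc(zscore_per_state(emp), "E")
  modsp <- cut_tree_dynamic(cluster_tree(pc), pc, min_size = 80)
  ccp <- differential_correlation(emp, modsp, "E", "L")
  planted <- sim$truth$genes$gene[sim$truth$genes$module != "none"]
  expect_gte(mean(ccp$delta_c[ccp$gene %in% planted], na.rm = TRUE), 0.6)
})

test_that("STS combiners rank by the stated formulas with deterministic ties", {
  tab_v <- structure(
    data.frame(gene = sprintf("g%02d", 1:10),
               sd_early = 2, sd_late = 1,
               delta_v = c(0.0, 0.9, 0.5, 0.1, 0.7, 0.3, 0.2, 0.8, 0.4, 0.6),
               levene_stat = 1, levene_p = 0.5, levene_q = 0.5,
               direction = "none", capped = FALSE, stringsAsFactors = FALSE),
    class = c("dvc_variability", "data.frame"),
    states = c(early = "E", late = "L"))
  tab_c <- structure(
    data.frame(gene = sprintf("g%02d", 1:10), module = "black",
               c_early = 0.8, c_late = 0.2,
               delta_c = c(0.0, 0.8, 0.3, 0.2, 0.9, 0.1, 0.4, 0.7, 0.5, 0.6),
               c_ratio = 1, stringsAsFactors = FALSE),
    class = c("dvc_corr_change", "data.frame"))
  sts <- compute_sts(tab_v, tab_c)
  # brute-force rank-sum oracle
  rs <- (rank(tab_v$delta_v) + rank(tab_c$delta_c)) / (2 * 10)
  expect_equal(sts$sts[match(tab_v$gene, sts$gene)], rs)
  expect_identical(sts$gene[1], "g02")   # highest combined change
  expect_identical(sts$gene[10], "g01")  # zero-change gene at the bottom
  expect_identical(sts$rank, 1:10)
  expect_true(all(diff(sts$sts) <= 0))

  prod <- compute_sts(tab_v, tab_c, combiner = "product")
  expect_equal(prod$sts, sort(pmax(tab_v$delta_v, 0) * pmax(tab_c$delta_c, 0),
                              decreasing = TRUE))
  expect_error(compute_sts(tab_v, tab_c, combiner = "nope"))

  # rank_sum is invariant to strictly monotone transforms of the deltas
  tab_v2 <- tab_v; tab_v2$delta_v <- exp(3 * tab_v$delta_v)
  tab_c2 <- tab_c; tab_c2$delta_c <- tab_c$delta_c^3
  sts2 <- compute_sts(tab_v2, tab_c2)
  expect_identical(sts$gene, sts2$gene)

  # gene-order invariance
  perm <- sample(1:10)
  sts3 <- compute_sts(tab_v[perm, ], tab_c)
  expect_identical(sts$gene, sts3$gene)
  expect_equal(sts$sts, sts3$sts)
})

test_that("DVC gene selection is deterministic and guards its arguments", {
  tab_v <- structure(
    data.frame(gene = sprintf("g%02d", 1:10), sd_early = 2, sd_late = 1,
               delta_v = seq(1, 0.1, by = -0.1), levene_stat = 1,
               levene_p = 0.5, levene_q = 0.5, direction = "none",
               capped = FALSE, stringsAsFactors = FALSE),
    class = c("dvc_variability", "data.frame"),
    states = c(early = "E", late = "L"))
  tab_c <- structure(
    data.frame(gene = sprintf("g%02d", 1:10), module = "black",
               c_early = 0.8, c_late = 0.2, delta_c = seq(1, 0.1, by = -0.1),
               c_ratio = 1, stringsAsFactors = FALSE),
    class = c("dvc_corr_change", "data.frame"))
  sts <- compute_sts(tab_v, tab_c)
  expect_length(attr(select_dvc_genes(sts, top_n = 0), "dvc_genes"), 0)
  expect_length(attr(select_dvc_genes(sts, top_n = 10), "dvc_genes"), 10)
  expect_identical(attr(select_dvc_genes(sts, top_n = 5), "dvc_genes"),
                   sprintf("g%02d", 1:5))
  expect_warning(sel <- select_dvc_genes(sts, top_n = 99), "exceeds")
  expect_length(attr(sel, "dvc_genes"), 10)
  expect_error(select_dvc_genes(sts), "exactly one")
  expect_error(select_dvc_genes(sts, top_n = 2, sts_min = 0.5), "exactly one")
})

test_that("Welch baseline matches t.test and finds mean shifts, not variance changes", {
  set.seed(81)
  n <- 300
  vals_e <- matrix(rnorm(n * 30, mean = 5), n, 30)
  vals_l <- matrix(rnorm(n * 30, mean = 5), n, 30)
  vals_l[1:30, ] <- vals_l[1:30, ] + 2       # 2-SD mean shift
  vals_e[31:60, ] <- 5 + 3 * (vals_e[31:60, ] - 5)  # variance change only
  vals <- cbind(vals_e, vals_l)
  dimnames(vals) <- list(sprintf("g%03d", 1:n), sprintf("c%02d", 1:60))
  em <- expr_from_values(vals, rep(c("E", "L"), each = 30))
  deg <- deg_baseline(em, "E", "L", alpha = 0.05)
  for (i in c(1, 31, 200)) {
    tt <- t.test(vals_e[i, ], vals_l[i, ])
    expect_equal(deg$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(deg$t[i], tt$statistic[[1]], tolerance = 1e-12)
  }
  # the qualitative contrast: the mean-level baseline finds the shift
  # genes and misses the variance genes; the variability test reverses it
  expect_gte(mean(deg$deg_flag[1:30]), 0.9)          # mean-shift genes found
  expect_lte(mean(deg$deg_flag[31:60]), 0.1)         # variance genes missed
  var <- differential_variability(em, "E", "L", alpha = 0.001)
  expect_gte(mean(var$direction[31:60] == "decreased"), 0.6)
  expect_gt(mean(var$direction[31:60] == "decreased"), mean(deg$deg_flag[31:60]))
  expect_lte(mean(var$direction[1:30] != "none"), 0.1)
})
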