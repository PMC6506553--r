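#' Two-sample Levene test for equality of variances
#'
#' Classic Levene test on the absolute deviations from the group center
#' (mean by default; median gives the Brown-Forsythe variant). For two
#' groups the statistic follows F(1, n - 2) under the null; the reported p
#' is the upper tail, which for the one-way deviation ANOVA is the
#' two-sided test of equal spread.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param center `"mean"` or `"median"`.
#' @return list with `stat` and `p`. Degenerate inputs (all deviations
#'   zero in both groups) give `stat = 0, p = 1`.
#' @export
levene_two_sample <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(x) < 2 || length(y) < 2) .stopf("each sample needs >= 2 values")
  cf <- if (center == "mean") mean else stats::median
  zx <- abs(x - cf(x))
  zy <- abs(y - cf(y))
  n1 <- length(zx); n2 <- length(zy); n <- n1 + n2
  zbar <- (sum(zx) + sum(zy)) / n
  ssb <- n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (ssb == 0 && ssw == 0) return(list(stat = 0, p = 1))
  if (ssw == 0) return(list(stat = Inf, p = 0))
  stat <- (n - 2) * ssb / ssw
  list(stat = stat, p = stats::pf(stat, 1, n - 2, lower.tail = FALSE))
}

# vectorized two-group Levene over the rows of two matrices
.levene_rows <- function(xe, xl, center = "mean") {
  cen <- function(m) if (center == "mean") rowMeans(m)
                     else apply(m, 1, stats::median)
  ze <- abs(xe - cen(xe))
  zl <- abs(xl - cen(xl))
  n1 <- ncol(ze); n2 <- ncol(zl); n <- n1 + n2
  me <- rowMeans(ze); ml <- rowMeans(zl)
  zbar <- (n1 * me + n2 * ml) / n
  ssb <- n1 * (me - zbar)^2 + n2 * (ml - zbar)^2
  ssw <- rowSums((ze - me)^2) + rowSums((zl - ml)^2)
  stat <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), (n - 2) * ssb / ssw)
  p <- ifelse(ssw == 0, ifelse(ssb == 0, 1, 0),
              stats::pf(stat, 1, n - 2, lower.tail = FALSE))
  list(stat = stat, p = p)
}

#' Per-gene differential variability between two states
#'
#' Computes for every gene the standard deviation of log2-CPM across the
#' cells of each state, the log2 SD ratio `delta_v = log2(sd_early /
#' sd_late)` (positive when variability drops after the transition), the
#' Levene test p-value, its Benjamini-Hochberg q-value across all genes,
#' and a direction call at `q < alpha`.
#'
#' @param em a `dvc_expr` object on the log2-CPM scale (variability is not
#'   meaningful on the per-state z-scored view, where every SD is 1).
#' @param state_early,state_late state labels to compare.
#' @param alpha significance level on q (default 0.001).
#' @param center Levene center, `"mean"` (default) or `"median"`.
#' @param cap absolute cap replacing infinite `delta_v` when one state is
#'   constant (default 20); capped genes are flagged.
#' @return data.frame of class `dvc_variability`: `gene, sd_early, sd_late,
#'   delta_v, levene_stat, levene_p, levene_q, direction, capped`.
#'   `direction` is `"decreased"`/`"increased"` (variability after the
#'   transition) when `q < alpha`, else `"none"`.
#' @export
differential_variability <- function(em, state_early, state_late,
                                     alpha = 0.001, center = c("mean", "median"),
                                     cap = 20) {
  stopifnot(inherits(em, "dvc_expr"))
  if (em$scale != "log2cpm")
    .stopf("differential_variability expects the log2cpm view")
  center <- match.arg(center)
  for (s in c(state_early, state_late))
    if (!s %in% levels(em$states)) .stopf("unknown state '%s'", s)
  xe <- em$values[, em$states == state_early, drop = FALSE]
  xl <- em$values[, em$states == state_late, drop = FALSE]
  sd_e <- .row_sds(xe)
  sd_l <- .row_sds(xl)
  delta_v <- log2(sd_e / sd_l)
  capped <- !is.finite(delta_v)
  delta_v[capped] <- sign(ifelse(sd_e[capped] > sd_l[capped], 1,
                                 ifelse(sd_e[capped] < sd_l[capped], -1, 0))) * cap
  lev <- .levene_rows(xe, xl, center)
  q <- stats::p.adjust(lev$p, method = "BH")
  direction <- ifelse(q < alpha,
                      ifelse(delta_v > 0, "decreased", "increased"),
                      "none")
  out <- data.frame(gene = rownames(em$values),
                    sd_early = sd_e, sd_late = sd_l, delta_v = delta_v,
                    levene_stat = lev$stat, levene_p = lev$p, levene_q = q,
                    direction = direction, capped = capped,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "states") <- c(early = state_early, late = state_late)
  attr(out, "alpha") <- alpha
  class(out) <- c("dvc_variability", "data.frame")
  out
}

#' Per-gene change in within-module correlation between two states
#'
#' For every gene assigned to a module, the mean Pearson correlation with
#' its co-module members is computed separately in each state (module
#' membership is fixed from the early state) and the change `delta_c =
#' c_early - c_late` (positive when co-regulation loosens after the
#' transition) is reported, together with the ratio `c_late / c_early`
#' clamped to `[-10, 10]`. Unassigned genes get `NA` and are excluded from
#' downstream scoring. `scope = "all"` averages over all analyzed genes
#' instead of co-module members.
#'
#' @param em a `dvc_expr` object (log2-CPM or z-scored; correlations agree).
#' @param modules a `dvc_modules` assignment built on the early state.
#' @param state_early,state_late state labels.
#' @param scope `"module"` (default) or `"all"`.
#' @return data.frame of class `dvc_corr_change`: `gene, module, c_early,
#'   c_late, delta_c, c_ratio`.
#' @export
differential_correlation <- function(em, modules, state_early, state_late,
                                     scope = c("module", "all")) {
  stopifnot(inherits(em, "dvc_expr"), inherits(modules, "dvc_modules"))
  scope <- match.arg(scope)
  genes <- rownames(em$values)
  mod <- stats::setNames(modules$module, modules$gene)[genes]
  mod[is.na(mod)] <- "unassigned"
  c_e <- rep(NA_real_, length(genes)); names(c_e) <- genes
  c_l <- c_e
  mean_cor_with <- function(state, members) {
    x <- em$values[members, em$states == state, drop = FALSE]
    sds <- .row_sds(x)
    ok <- sds > 0 & is.finite(sds)
    r <- suppressWarnings(stats::cor(t(x)))
    r[!ok, ] <- NA; r[, !ok] <- NA
    diag(r) <- NA
    rowMeans(r, na.rm = TRUE)
  }
  if (scope == "all") {
    groups <- list(all = genes)
  } else {
    groups <- split(names(mod)[mod != "unassigned"], mod[mod != "unassigned"])
  }
  for (members in groups) {
    if (length(members) < 2) next  # size-1 module: stays NA
    c_e[members] <- mean_cor_with(state_early, members)
    c_l[members] <- mean_cor_with(state_late, members)
  }
  c_e[is.nan(c_e)] <- NA; c_l[is.nan(c_l)] <- NA
  ratio <- pmin(pmax(c_l / c_e, -10), 10)
  out <- data.frame(gene = genes, module = unname(mod),
                    c_early = unname(c_e), c_late = unname(c_l),
                    delta_c = unname(c_e - c_l), c_ratio = unname(ratio),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "states") <- c(early = state_early, late = state_late)
  class(out) <- c("dvc_corr_change", "data.frame")
  out
}

# rank-normalization: largest value -> 1, deterministic tie-break by gene id
.rank_norm <- function(x, gene) {
  ord <- order(gene)
  r <- numeric(length(x))
  r[ord] <- rank(x[ord], ties.method = "first")
  r / length(x)
}

#' Combine variability and correlation changes into the state transition score
#'
#' The state transition score (STS) ranks genes by how strongly both their
#' expression variability and their within-module co-regulation decrease
#' from the early to the late state (oscillation-like heterogeneity that
#' settles after the transition). Combiners:
#' \describe{
#'   \item{rank_sum}{(default) mean of the rank-normalized `delta_v` and
#'     `delta_c`, each mapped so the largest decrease-from-early gets 1;
#'     scale-free and robust.}
#'   \item{product}{product of the positive parts of `delta_v`, `delta_c`.}
#'   \item{zsum}{sum of robust z-scores (median/MAD) of the two deltas.}
#' }
#' Genes missing either component (e.g. unassigned genes) are excluded.
#' With `orientation = "absolute"` the absolute changes are combined
#' instead, ranking any change in either direction highly.
#'
#' @param var a `dvc_variability` table.
#' @param corr a `dvc_corr_change` table over the same genes.
#' @param combiner `"rank_sum"`, `"product"` or `"zsum"`.
#' @param orientation `"decrease"` (default) or `"absolute"`.
#' @return data.frame of class `dvc_sts`, one row per scored gene, sorted
#'   by decreasing STS: `gene, sd_early, sd_late, delta_v, levene_p,
#'   levene_q, module, c_early, c_late, delta_c, c_ratio, sts, rank,
#'   dvc_flag` (flag all `FALSE` until [select_dvc_genes]).
#' @export
compute_sts <- function(var, corr,
                        combiner = c("rank_sum", "product", "zsum"),
                        orientation = c("decrease", "absolute")) {
  combiner <- match.arg(combiner)
  orientation <- match.arg(orientation)
  tab <- merge(as.data.frame(var)[, c("gene", "sd_early", "sd_late", "delta_v",
                                      "levene_p", "levene_q")],
               as.data.frame(corr)[, c("gene", "module", "c_early", "c_late",
                                       "delta_c", "c_ratio")],
               by = "gene")
  tab <- tab[stats::complete.cases(tab[, c("delta_v", "delta_c")]), ]
  if (nrow(tab) == 0) .stopf("no gene has both a variability and a correlation component")
  dv <- tab$delta_v; dc <- tab$delta_c
  if (orientation == "absolute") { dv <- abs(dv); dc <- abs(dc) }
  tab$sts <- switch(combiner,
    rank_sum = (.rank_norm(dv, tab$gene) + .rank_norm(dc, tab$gene)) / 2,
    product = pmax(dv, 0) * pmax(dc, 0),
    zsum = {
      rz <- function(x) {
        s <- stats::mad(x)
        if (s == 0) s <- 1
        (x - stats::median(x)) / s
      }
      rz(dv) + rz(dc)
    })
  tab <- tab[order(-tab$sts, tab$gene), ]
  tab$rank <- seq_len(nrow(tab))
  tab$dvc_flag <- FALSE
  rownames(tab) <- NULL
  attr(tab, "combiner") <- combiner
  attr(tab, "orientation") <- orientation
  attr(tab, "states") <- attr(var, "states")
  class(tab) <- c("dvc_sts", "data.frame")
  tab
}

#' Select DVC genes from an STS table
#'
#' DVC (differential variability and correlation) genes are the high-STS
#' genes. Exactly one of `top_n` / `sts_min` must be given.
#'
#' @param sts a `dvc_sts` table.
#' @param top_n keep the `top_n` highest-STS genes.
#' @param sts_min keep genes with `sts >= sts_min`.
#' @return the `dvc_sts` table with `dvc_flag` set; the selected gene ids
#'   are in `attr(, "dvc_genes")` and the rule in `attr(, "selection")`.
#' @export
select_dvc_genes <- function(sts, top_n = NULL, sts_min = NULL) {
  stopifnot(inherits(sts, "dvc_sts"))
  if (is.null(top_n) == is.null(sts_min))
    .stopf("give exactly one of top_n / sts_min")
  if (!is.null(top_n)) {
    if (top_n > nrow(sts)) {
      .warnf("top_n (%d) exceeds available genes (%d); selecting all",
             top_n, nrow(sts))
      top_n <- nrow(sts)
    }
    flag <- sts$rank <= top_n
    rule <- sprintf("top_n=%d", top_n)
  } else {
    flag <- sts$sts >= sts_min
    rule <- sprintf("sts_min=%g", sts_min)
  }
  sts$dvc_flag <- flag
  attr(sts, "dvc_genes") <- sts$gene[flag]
  attr(sts, "selection") <- rule
  sts
}

#' @export
print.dvc_sts <- function(x, n = 10, ...) {
  st <- attr(x, "states")
  cat(sprintf("dvc_sts: %d scored genes (%s -> %s, combiner %s), %d flagged\n",
              nrow(x), st["early"], st["late"], attr(x, "combiner"),
              sum(x$dvc_flag)))
  print(utils::head(as.data.frame(x)[, c("gene", "delta_v", "delta_c",
                                         "sts", "rank", "dvc_flag")], n))
  invisible(x)
}

#' Mean-expression baseline: per-gene Welch test between states
#'
#' A conventional differential-expression baseline: Welch's two-sample t
#' test on the log2-CPM means of each gene, BH-adjusted. Used to contrast
#' DVC genes (which change in variability and co-regulation, not in
#' average level) with ordinary DEGs.
#'
#' @param em a `dvc_expr` on the log2-CPM scale.
#' @param state_early,state_late state labels.
#' @param alpha significance level on q (default 0.05).
#' @return data.frame: `gene, mean_early, mean_late, delta_mean, t, df, p,
#'   q, deg_flag`.
#' @export
deg_baseline <- function(em, state_early, state_late, alpha = 0.05) {
  stopifnot(inherits(em, "dvc_expr"))
  if (em$scale != "log2cpm") .stopf("deg_baseline expects the log2cpm view")
  xe <- em$values[, em$states == state_early, drop = FALSE]
  xl <- em$values[, em$states == state_late, drop = FALSE]
  n1 <- ncol(xe); n2 <- ncol(xl)
  m1 <- rowMeans(xe); m2 <- rowMeans(xl)
  v1 <- .row_sds(xe)^2; v2 <- .row_sds(xl)^2
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(se2 == 0, ifelse(m1 == m2, 1, 0),
              2 * stats::pt(abs(t), df, lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(em$values), mean_early = m1, mean_late = m2,
             delta_mean = m1 - m2, t = t, df = df, p = p, q = q,
             deg_flag = q < alpha, stringsAsFactors = FALSE, row.names = NULL)
}
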