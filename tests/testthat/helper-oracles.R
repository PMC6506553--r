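# Independent oracle implementations used to cross-check the package.
# These deliberately use naive, transparent algorithms.

# small labelled count matrix fixture
tiny_counts <- function() {
  m <- matrix(c(5, 3, 0, 2,
                10, 8, 6, 4,
                0, 1, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3", "c4")))
  dvc_counts(m, c(c1 = "A", c2 = "A", c3 = "B", c4 = "B"),
             state_order = c("A", "B"))
}

# expression object straight from a value matrix (bypasses normalization)
expr_from_values <- function(values, states, scale = "log2cpm") {
  structure(list(values = values, scale = scale,
                 lib_sizes = rep(1e6, ncol(values)),
                 norm_factors = rep(1, ncol(values)), pseudo = 1,
                 states = factor(states, levels = unique(states))),
            class = "dvc_expr")
}

# brute-force Ward agglomeration via the Lance-Williams update,
# recomputing the full distance matrix at every step
oracle_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)          # hclust convention: negatives are leaves
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)[-length(active)]) {
      for (j in seq((i + 1), length(active))) {
        dij <- d[active[i], active[j]]
        if (dij < bestd - 1e-12) { bestd <- dij; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    merges[step, ] <- sort(c(id[ai], id[aj]))
    heights[step] <- bestd
    ni <- sizes[ai]; nj <- sizes[aj]
    for (k in active) {
      if (k == ai || k == aj) next
      nk <- sizes[k]
      dn <- ((ni + nk) * d[ai, k] + (nj + nk) * d[aj, k] - nk * bestd) /
        (ni + nj + nk)
      d[ai, k] <- dn; d[k, ai] <- dn
    }
    sizes[ai] <- ni + nj
    members[[ai]] <- c(members[[ai]], members[[aj]])
    id[ai] <- step
    active <- active[-j]
  }
  list(merge = merges, height = heights)
}

# partition of leaves after the first k merges of an hclust-style tree
partition_after <- function(merge, n, k) {
  nodes <- vector("list", nrow(merge))
  used <- logical(nrow(merge))
  for (s in seq_len(k)) {
    mem <- integer(0)
    for (x in merge[s, ]) {
      if (x < 0) mem <- c(mem, -x)
      else { mem <- c(mem, nodes[[x]]); used[x] <- TRUE }
    }
    nodes[[s]] <- mem
  }
  parts <- nodes[seq_len(k)][!used[seq_len(k)]]
  leftover <- setdiff(seq_len(n), unlist(parts))
  parts <- c(parts, as.list(leftover))
  sorted <- lapply(parts, sort)
  sorted[order(vapply(sorted, min, numeric(1)))]
}

# straight-line evaluation of the published TMM formulas
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    M <- log2((o[keep] / lib[j]) / (r[keep] / lib[ref]))
    A <- 0.5 * (log2(o[keep] / lib[j]) + log2(r[keep] / lib[ref]))
    v <- (lib[j] - o[keep]) / (lib[j] * o[keep]) +
      (lib[ref] - r[keep]) / (lib[ref] * r[keep])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  })
  fac / exp(mean(log(fac)))
}

# Benjamini-Hochberg step-up, spelled out
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# all-pairs interval intersection, merged (0-based half-open)
oracle_intersect <- function(a, b) {
  segs <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s < e) segs[[length(segs) + 1]] <- data.frame(chrom = a$chrom[i],
                                                      start = s, end = e)
  }
  if (!length(segs)) return(data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0)))
  x <- do.call(rbind, segs)
  x <- x[order(x$chrom, x$start, x$end), ]
  out <- x[1, ]
  for (i in seq_len(nrow(x))[-1]) {
    last <- nrow(out)
    if (x$chrom[i] == out$chrom[last] && x$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], x$end[i])
    } else out <- rbind(out, x[i, ])
  }
  rownames(out) <- NULL
  out
}

# minimum gap between two half-open intervals on the same chromosome
oracle_gene_window <- function(regions, loci, window) {
  hit <- vapply(seq_len(nrow(loci)), function(i) {
    any(vapply(seq_len(nrow(regions)), function(j) {
      if (loci$chrom[i] != regions$chrom[j]) return(FALSE)
      gap <- max(loci$start[i] - regions$end[j], regions$start[j] - loci$end[i], 0)
      gap <= window
    }, logical(1)))
  }, logical(1))
  sort(loci$gene[hit])
}

# adjusted Rand index (used when mclust is unavailable)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}

ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else oracle_ari(a, b)
}

# benchmark simulation shared between module and STS recovery tests
benchmark_sim <- function(seed = 101, n_genes = 10000) {
  cfg <- simulation_config(n_genes = n_genes, seed = seed)
  list(cfg = cfg, sim = simulate_counts(cfg))
}
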