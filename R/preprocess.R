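#' Construct a state-labelled count matrix
#'
#' The raw-input container of the pipeline: an integer genes x cells count
#' matrix together with one state label per cell. The order of
#' `state_order` (earliest first) defines the developmental ordering used
#' downstream: co-expression modules are always detected in the first
#' state, and state pairs are compared against it.
#'
#' @param counts integer matrix, genes in rows, cells in columns; dimnames
#'   required and unique.
#' @param states character/factor of length `ncol(counts)` giving one state
#'   label per cell, or a named vector/2-column data.frame (cell, state).
#' @param state_order character vector of state labels, earliest first.
#'   Defaults to order of first appearance in `states`.
#' @return An object of class `dvc_counts`: a list with elements `counts`
#'   (integer matrix) and `states` (factor, levels earliest first).
#' @export
dvc_counts <- function(counts, states, state_order = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must have gene row names and cell column names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    .stopf("duplicate gene ids: %s", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    .stopf("duplicate cell ids: %s", paste(dup, collapse = ", "))
  if (anyNA(counts)) .stopf("counts contain missing values")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  nonint <- which(counts != round(counts), arr.ind = TRUE)
  if (nrow(nonint) > 0)
    .stopf("non-integer count at gene '%s', cell '%s'",
           rownames(counts)[nonint[1, 1]], colnames(counts)[nonint[1, 2]])
  storage.mode(counts) <- "double"  # keeps >.Machine$integer.max sums safe

  if (is.data.frame(states)) {
    st <- stats::setNames(as.character(states[[2]]), as.character(states[[1]]))
    states <- st
  }
  if (!is.null(names(states))) {
    missing <- setdiff(colnames(counts), names(states))
    if (length(missing))
      .stopf("missing state label for cells: %s",
             paste(utils::head(missing, 5), collapse = ", "))
    states <- states[colnames(counts)]
  }
  states <- as.character(states)
  if (length(states) != ncol(counts))
    .stopf("states must give one label per cell")
  if (anyNA(states) || any(!nzchar(states)))
    .stopf("missing state labels")
  state_order <- state_order %||% unique(states)
  if (!setequal(state_order, unique(states)))
    .stopf("state_order must list exactly the observed states")
  states <- factor(states, levels = state_order)
  tab <- table(states)
  if (any(tab < 2))
    .stopf("each state needs at least 2 cells (violated: %s)",
           paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(counts = counts, states = states), class = "dvc_counts")
}

#' @export
print.dvc_counts <- function(x, ...) {
  cat(sprintf("dvc_counts: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(x$states)
  cat("states (earliest first):",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.dvc_counts <- function(x) dim(x$counts)

#' Read a count matrix with cell-state labels
#'
#' Reads either a dense TSV (first column gene id, header row of cell ids)
#' or a MatrixMarket triplet file with companion gene/cell annotation
#' files, plus a 2-column TSV of cell-state labels.
#'
#' @param path path to the counts TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param states_file 2-column TSV (cell id, state label), no header
#'   required; alternatively pass labels directly via `states`.
#' @param states optional named character vector of labels (overrides
#'   `states_file`).
#' @param genes_file,cells_file for `format = "mtx"`: one id per line (or
#'   first column of a TSV).
#' @param state_order optional explicit state ordering, earliest first.
#' @return A [dvc_counts] object; genes and cells in file order.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), states_file = NULL,
                        states = NULL, genes_file = NULL, cells_file = NULL,
                        state_order = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) .stopf("non-numeric entries in %s", path)
    rownames(m) <- gene_ids
  } else {
    if (is.null(genes_file) || is.null(cells_file))
      .stopf("mtx format needs genes_file and cells_file")
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- utils::read.delim(genes_file, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    cell_ids <- utils::read.delim(cells_file, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (length(gene_ids) != nrow(m) || length(cell_ids) != ncol(m))
      .stopf("annotation files do not match matrix dimensions")
    dimnames(m) <- list(gene_ids, cell_ids)
  }
  if (is.null(states)) {
    if (is.null(states_file)) .stopf("state labels required (states_file or states)")
    sdf <- utils::read.delim(states_file, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(sdf[1, 1])), "cell")) sdf <- sdf[-1, ]
    states <- stats::setNames(as.character(sdf[[2]]), as.character(sdf[[1]]))
  }
  dvc_counts(m, states, state_order = state_order)
}

#' Filter genes by per-state expression level
#'
#' Keeps the "commonly analyzable" genes: by the default rule, a gene is
#' retained iff its mean raw count is at least `min_mean` in *every* state.
#' Alternative readings of the threshold are selectable: `"total"` (per-state
#' total count) and `"per_cell_min"` (minimum count over all cells of each
#' state).
#'
#' @param cm a [dvc_counts] object.
#' @param min_mean threshold (default 2).
#' @param rule which per-state summary the threshold applies to.
#' @return A filtered [dvc_counts]; the retained-gene count is reported via
#'   `message()` and stored in `attr(, "n_retained")`.
#' @export
filter_low_expression <- function(cm, min_mean = 2,
                                  rule = c("mean", "total", "per_cell_min")) {
  stopifnot(inherits(cm, "dvc_counts"))
  rule <- match.arg(rule)
  per_state <- vapply(levels(cm$states), function(s) {
    x <- cm$counts[, cm$states == s, drop = FALSE]
    switch(rule,
           mean = rowMeans(x),
           total = rowSums(x),
           per_cell_min = apply(x, 1, min))
  }, numeric(nrow(cm$counts)))
  keep <- rowSums(per_state >= min_mean) == ncol(per_state)
  if (!any(keep))
    .stopf("no gene passes the filter (rule '%s', threshold %g); lower min_mean",
           rule, min_mean)
  out <- dvc_counts(cm$counts[keep, , drop = FALSE], as.character(cm$states),
                    state_order = levels(cm$states))
  message(sprintf("filter_low_expression: retained %d of %d genes (rule '%s', >= %g per state)",
                  sum(keep), nrow(cm$counts), rule, min_mean))
  attr(out, "n_retained") <- sum(keep)
  out
}

# TMM factor of one column against the reference column.
# M/A computed over genes expressed in both; weights are the inverse
# asymptotic binomial variances of M; double trim on M and A.
.tmm_one <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    .warnf("cell shares no expressed genes with the TMM reference; factor set to 1")
    return(1)
  }
  fo <- obs[keep] / lib_obs
  fr <- ref[keep] / lib_ref
  M <- log2(fo / fr)
  A <- (log2(fo) + log2(fr)) / 2
  # asymptotic binomial variance of M; weights are its inverse
  v <- (lib_obs - obs[keep]) / (lib_obs * obs[keep]) +
       (lib_ref - ref[keep]) / (lib_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)  # pure library-size change
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[sel] / v[sel], na.rm = TRUE) / sum(1 / v[sel], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes one TMM normalization factor per cell. The reference cell is
#' the one whose upper-quartile count fraction is closest to the mean
#' upper-quartile fraction; per gene, M is the log2 ratio of count
#' fractions against the reference and A the average log2 fraction, both
#' over genes with nonzero counts in both cells; M and A are each trimmed
#' symmetrically (`trim_m`, `trim_a` per tail) and the factor is 2 to the
#' weighted mean of the surviving M values, weighted by inverse asymptotic
#' binomial variances. Factors are rescaled to geometric mean 1.
#'
#' @param cm a [dvc_counts] object or a bare count matrix.
#' @param trim_m,trim_a trim fraction per tail for M (default 0.30) and A
#'   (default 0.05).
#' @return numeric vector of positive factors, one per cell, geometric
#'   mean 1.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(cm, "dvc_counts")) cm$counts else as.matrix(cm)
  lib <- colSums(counts)
  if (any(lib <= 0)) .stopf("every cell needs a positive library size")
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_one(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalize counts to log2 counts-per-million
#'
#' `value = log2(count / (lib_size * factor) * 1e6 + pseudo)`, with library
#' sizes the column sums of the (already filtered) matrix.
#'
#' @param cm a [dvc_counts] object.
#' @param factors per-cell normalization factors (default: [tmm_factors]).
#' @param pseudo pseudo-count added inside the log (default 1).
#' @return An object of class `dvc_expr`: list with `values` (genes x cells
#'   matrix), `scale = "log2cpm"`, `lib_sizes`, `norm_factors`, `states`.
#' @export
cpm_log2 <- function(cm, factors = NULL, pseudo = 1) {
  stopifnot(inherits(cm, "dvc_counts"))
  factors <- factors %||% tmm_factors(cm)
  if (any(factors <= 0)) .stopf("normalization factors must be positive")
  lib <- colSums(cm$counts)
  eff <- lib * factors
  values <- log2(sweep(cm$counts, 2, eff / 1e6, "/") + pseudo)
  structure(list(values = values, scale = "log2cpm",
                 lib_sizes = lib, norm_factors = factors,
                 pseudo = pseudo, states = cm$states),
            class = "dvc_expr")
}

#' @export
print.dvc_expr <- function(x, ...) {
  cat(sprintf("dvc_expr (%s): %d genes x %d cells, states: %s\n",
              x$scale, nrow(x$values), ncol(x$values),
              paste(levels(x$states), collapse = " -> ")))
  invisible(x)
}

#' Flag outlying cells by robust PCA score distance
#'
#' Flags cells whose score on any of the first `n_pc` principal components
#' deviates from that component's median by more than `mad_k` median
#' absolute deviations. Used to spot contaminating cell types (e.g.
#' oligodendrocyte-like cells among progenitors). Removal is a separate,
#' explicit step ([drop_cells]); nothing is removed silently.
#'
#' @param em a `dvc_expr` object (log2-CPM scale).
#' @param n_pc number of leading components examined (default 2).
#' @param mad_k robust-deviation threshold (default 5); `Inf` disables.
#' @return character vector of flagged cell ids (possibly empty), with the
#'   score matrix attached as `attr(, "scores")`.
#' @export
pca_outlier_cells <- function(em, n_pc = 2, mad_k = 5) {
  stopifnot(inherits(em, "dvc_expr"))
  if (ncol(em$values) < 3) .stopf("need at least 3 cells")
  pc <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flagged <- rep(FALSE, nrow(scores))
  for (j in seq_len(k)) {
    s <- scores[, j]
    md <- stats::median(s)
    sc <- stats::mad(s)
    if (sc > 0) flagged <- flagged | (abs(s - md) > mad_k * sc)
  }
  out <- rownames(scores)[flagged]
  attr(out, "scores") <- scores
  out
}

#' Remove cells from a count or expression object
#'
#' @param x a [dvc_counts] or `dvc_expr` object.
#' @param cells character vector of cell ids to drop.
#' @return object of the same class without those cells.
#' @export
drop_cells <- function(x, cells) {
  if (length(cells) == 0) return(x)
  if (inherits(x, "dvc_counts")) {
    keep <- !(colnames(x$counts) %in% cells)
    return(dvc_counts(x$counts[, keep, drop = FALSE],
                      as.character(x$states)[keep],
                      state_order = levels(x$states)))
  }
  stopifnot(inherits(x, "dvc_expr"))
  keep <- !(colnames(x$values) %in% cells)
  structure(list(values = x$values[, keep, drop = FALSE], scale = x$scale,
                 lib_sizes = x$lib_sizes[keep], norm_factors = x$norm_factors[keep],
                 pseudo = x$pseudo,
                 states = factor(as.character(x$states)[keep],
                                 levels = levels(x$states))),
            class = "dvc_expr")
}

#' Standardize expression per gene within each state
#'
#' Per gene and per state, subtracts the state mean and divides by the
#' state standard deviation (denominator n-1). Genes constant within a
#' state get all-zero values there and are reported in
#' `attr(, "constant_genes")`.
#'
#' @param em a `dvc_expr` object on the log2-CPM scale.
#' @return a `dvc_expr` with `scale = "zscore_per_state"`.
#' @export
zscore_per_state <- function(em) {
  stopifnot(inherits(em, "dvc_expr"))
  if (em$scale != "log2cpm") .stopf("zscore_per_state expects log2cpm input")
  values <- em$values
  flagged <- character(0)
  for (s in levels(em$states)) {
    idx <- which(em$states == s)
    if (length(idx) < 2) .stopf("state '%s' has fewer than 2 cells", s)
    x <- values[, idx, drop = FALSE]
    mu <- rowMeans(x)
    sd <- .row_sds(x)
    const <- sd == 0 | !is.finite(sd)
    sd[const] <- 1
    values[, idx] <- (x - mu) / sd
    values[const, idx] <- 0
    flagged <- union(flagged, rownames(values)[const])
  }
  out <- structure(list(values = values, scale = "zscore_per_state",
                        lib_sizes = em$lib_sizes, norm_factors = em$norm_factors,
                        pseudo = em$pseudo, states = em$states),
                   class = "dvc_expr")
  attr(out, "constant_genes") <- flagged
  out
}
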