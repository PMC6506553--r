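`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Percentage of a gene universe, rounded for reporting
#'
#' Small reporting helper used in run summaries: the percentage of
#' `universe` represented by `count`, rounded to `digits` decimal places
#' (e.g. the share of analyzed genes called differentially variable).
#'
#' @param count integer, number of genes in the category.
#' @param universe integer, size of the analyzed gene universe.
#' @param digits decimal places to round to.
#' @return numeric percentage in `[0, 100]`.
#' @examples
#' dvc_percent(3423, 12147)  # 28.2
#' @export
dvc_percent <- function(count, universe, digits = 1) {
  if (universe <= 0) .stopf("universe must be positive")
  if (count < 0 || count > universe) .stopf("count must lie in [0, universe]")
  round(100 * count / universe, digits)
}

# row-wise sd with denominator n-1, NA-free fast path
.row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
}
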