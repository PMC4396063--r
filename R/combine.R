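#' Odds-product (Graham) fusion of per-drug resistance probabilities
#'
#' Under the assumption of independent drug effects the posterior
#' probability of resistance to the combination is
#' `prod(p) / (prod(p) + prod(1 - p))`. Defined for any number of drugs;
#' a single probability is returned unchanged. Probabilities outside
#' (0, 1) are clamped to `[1e-12, 1 - 1e-12]` with a warning.
#'
#' @param p Vector of per-drug resistance probabilities, or a matrix/
#'   data.frame with one column per drug (fused row-wise).
#' @return Combined probability (vector if matrix input).
#' @export
graham_combine <- function(p) {
  if (is.matrix(p) || is.data.frame(p))
    return(apply(as.matrix(p), 1, graham_combine))
  if (length(p) == 0) stop("no probabilities supplied")
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clamped into (0, 1)")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  num <- prod(p)
  num / (num + prod(1 - p))
}

#' Naive product fusion of resistance probabilities
#'
#' The product `prod(p)`, an intentionally optimistic combiner kept for
#' comparison with the odds-product rule.
#'
#' @inheritParams graham_combine
#' @return Combined probability.
#' @export
product_combine <- function(p) {
  if (is.matrix(p) || is.data.frame(p))
    return(apply(as.matrix(p), 1, product_combine))
  if (length(p) == 0) stop("no probabilities supplied")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  prod(p)
}

#' Count-of-resistant-drugs fusion
#'
#' Counts the drugs whose resistance probability exceeds a threshold,
#' discarding the numeric value of the probabilities.
#'
#' @inheritParams graham_combine
#' @param threshold Probability cut-off (default 0.5).
#' @return Integer count (vector if matrix input).
#' @export
count_combine <- function(p, threshold = 0.5) {
  if (is.matrix(p) || is.data.frame(p))
    return(apply(as.matrix(p), 1, count_combine, threshold = threshold))
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  sum(p > threshold)
}

#' Geometric-mean fusion of per-drug resistance indices
#'
#' Combines positive resistance indices (AUC0 scale) into a single index
#' by the geometric mean, the natural combiner when the per-drug indices
#' differ in scale.
#'
#' @param index Vector of per-drug indices, or a matrix/data.frame with one
#'   column per drug (fused row-wise, rownames carried as sample ids).
#' @return Combined index.
#' @export
geometric_mean_index <- function(index) {
  if (is.matrix(index) || is.data.frame(index)) {
    m <- as.matrix(index)
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("non-positive resistance index for sample ",
           paste(unique(rownames(m)[bad[, 1]]), collapse = ", "))
    return(apply(m, 1, geometric_mean_index))
  }
  if (length(index) == 0) stop("no indices supplied")
  if (any(index <= 0)) stop("non-positive resistance index")
  exp(mean(log(index)))
}

#' Categorise patients by their assigned probabilities
#'
#' Splits patients into sensitive / intermediate / resistant thirds of the
#' observed score range (`method = "range"`, the default: cut-points at
#' `min + (max - min)/3` and `min + 2(max - min)/3`) or by the empirical
#' 33.3/66.7 percentiles (`method = "percentile"`). The upper third is
#' resistant. A degenerate zero range labels everyone intermediate with a
#' warning.
#'
#' @param p Numeric vector of per-patient probabilities (or indices).
#' @param method "range" or "percentile".
#' @return Factor with levels sensitive, intermediate, resistant.
#' @export
categorise_by_probability_range <- function(p, method = c("range", "percentile")) {
  method <- match.arg(method)
  if (length(p) < 3) stop("need at least 3 patients")
  if (any(!is.finite(p))) stop("probabilities must be finite")
  lv <- c("sensitive", "intermediate", "resistant")
  if (diff(range(p)) == 0) {
    warning("zero score range: all patients categorised intermediate")
    return(factor(rep("intermediate", length(p)), levels = lv))
  }
  cuts <- if (method == "range")
    min(p) + diff(range(p)) * c(1, 2) / 3
  else stats::quantile(p, c(1, 2) / 3, names = FALSE)
  out <- ifelse(p <= cuts[1], "sensitive",
                ifelse(p <= cuts[2], "intermediate", "resistant"))
  factor(out, levels = lv)
}
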