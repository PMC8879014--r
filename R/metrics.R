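# Performance measures: mean squared error, Pearson correlation, the
# N*ln(MSE) + 2k information criterion used for topology selection, and the
# Kling-Gupta efficiency.

.check_pair <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty input vectors", call. = FALSE)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
}

#' Mean squared error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(observed, predicted) {
  .check_pair(observed, predicted)
  mean((observed - predicted)^2)
}

#' Pearson product-moment correlation
#'
#' @param observed,predicted Equal-length numeric vectors, each with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(observed, predicted) {
  .check_pair(observed, predicted)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    stop("pearson_r undefined for zero-variance input", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Information criterion for topology selection
#'
#' `AIC = N ln(MSE) + 2 k`, where `k` is the hidden-neuron count of the
#' model being scored and `N` the dataset size. A perfect fit (`mse = 0`)
#' returns `-Inf` as a sentinel distinct from an error.
#'
#' @param n Dataset size (`>= 1`).
#' @param mse Mean squared error (`>= 0`, normalized scale).
#' @param k Hidden-neuron count (`>= 0`).
#' @return The criterion value.
#' @export
aic <- function(n, mse, k) {
  stopifnot(n >= 1, k >= 0)
  if (mse < 0) stop("mse must be nonnegative", call. = FALSE)
  if (mse == 0) return(-Inf)
  n * log(mse) + 2 * k
}

#' Kling-Gupta efficiency
#'
#' `KGE = 1 - sqrt((R - 1)^2 + (VE - 1)^2 + (BT - 1)^2)`, with `R` the
#' Pearson correlation, `VE` the variability ratio sd(predicted)/sd(observed)
#' (population standard deviations) and `BT` the bias ratio
#' mean(predicted)/mean(observed). The ideal value is 1.
#'
#' @param observed,predicted Equal-length numeric vectors; `observed` must
#'   have nonzero mean and variance.
#' @return KGE value (`<= 1`).
#' @export
kge <- function(observed, predicted) {
  .check_pair(observed, predicted)
  if (mean(observed) == 0) stop("KGE undefined: observed mean is zero", call. = FALSE)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  if (sd_pop(observed) == 0) stop("KGE undefined: observed variance is zero", call. = FALSE)
  r <- pearson_r(observed, predicted)
  ve <- sd_pop(predicted) / sd_pop(observed)
  bt <- mean(predicted) / mean(observed)
  1 - sqrt((r - 1)^2 + (ve - 1)^2 + (bt - 1)^2)
}

#' Metrics for one partition
#'
#' Convenience wrapper producing the record reported per model and
#' partition.
#'
#' @param observed,predicted Numeric vectors (normalized scale).
#' @param n Dataset size used in the information criterion.
#' @param k Hidden-neuron count used in the information criterion.
#' @param partition Label (`"train"`, `"validation"`, `"test"`, `"all"`).
#' @return One-row data frame with `partition`, `mse`, `r`, `aic`, `kge`,
#'   `n`, `k`.
#' @export
metric_record <- function(observed, predicted, n, k,
                          partition = c("train", "validation", "test", "all")) {
  partition <- match.arg(partition)
  m <- mse(observed, predicted)
  # KGE is ratio-based; on the centred normalized scale the observed mean
  # can vanish, in which case the record carries NA rather than failing.
  k_val <- tryCatch(kge(observed, predicted), error = function(e) NA_real_)
  data.frame(partition = partition, mse = m,
             r = pearson_r(observed, predicted),
             aic = aic(n, m, k),
             kge = k_val,
             n = as.integer(n), k = as.integer(k),
             stringsAsFactors = FALSE)
}
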