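# Comparison model families: three linear (ordinary multiple linear,
# Huber-robust, stepwise by information criterion) and six kernel
# regressors (epsilon-insensitive support vector regression with linear,
# quadratic, cubic, and fine/medium/coarse Gaussian kernels). All are
# fitted strictly on the training partition of the same normalized data as
# the network they are compared against.

#' Names of the supported baseline families
#' @return Character vector of nine family identifiers.
#' @export
baseline_families <- function() {
  c("linear", "robust_linear", "stepwise_linear",
    "svm_linear", "svm_quadratic", "svm_cubic",
    "svm_fine_gaussian", "svm_medium_gaussian", "svm_coarse_gaussian")
}

# Gaussian kernel scales follow the fine/medium/coarse preset convention
# sqrt(p)/4, sqrt(p), 4*sqrt(p) with p = 4 predictors; e1071's gamma is
# 1 / (2 sigma^2).
.gaussian_gamma <- function(level, p = 4) {
  sigma <- switch(level,
                  fine = sqrt(p) / 4,
                  medium = sqrt(p),
                  coarse = 4 * sqrt(p))
  1 / (2 * sigma^2)
}

#' Fit one baseline family
#'
#' @param family One of [baseline_families()].
#' @param features Normalized `n x 4` feature matrix with column names.
#' @param target Normalized length-`n` target vector.
#' @param split A [split_dataset()] result; fitting uses `split$train` only.
#' @return Object of class `baseline_result`: `family`, `predictions` (all
#'   rows), `metrics` (per-partition data frame with `mse` and `r`), and for
#'   the linear families `coefficients`.
#' @export
fit_baseline <- function(family, features, target, split) {
  if (!family %in% baseline_families()) {
    stop("unknown baseline family: ", family, call. = FALSE)
  }
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(target)
  df <- data.frame(y = y, X)
  tr <- df[split$train, , drop = FALSE]
  coefs <- NULL
  preds <- if (family == "linear") {
    fit <- stats::lm(y ~ ., data = tr)
    coefs <- stats::coef(fit)
    stats::predict(fit, newdata = df)
  } else if (family == "robust_linear") {
    fit <- MASS::rlm(y ~ ., data = tr, psi = MASS::psi.huber, k = 1.345,
                     maxit = 100)
    coefs <- stats::coef(fit)
    stats::predict(fit, newdata = df)
  } else if (family == "stepwise_linear") {
    full <- stats::lm(y ~ ., data = tr)
    fit <- MASS::stepAIC(full, direction = "both",
                         scope = list(lower = ~1, upper = stats::formula(full)),
                         trace = 0)
    coefs <- stats::coef(fit)
    stats::predict(fit, newdata = df)
  } else {
    eps <- stats::IQR(tr$y) / 13.49
    if (!is.finite(eps) || eps <= 0) eps <- 0.1
    kern <- switch(family,
                   svm_linear = list(kernel = "linear"),
                   svm_quadratic = list(kernel = "polynomial", degree = 2),
                   svm_cubic = list(kernel = "polynomial", degree = 3),
                   svm_fine_gaussian = list(kernel = "radial",
                                            gamma = .gaussian_gamma("fine")),
                   svm_medium_gaussian = list(kernel = "radial",
                                              gamma = .gaussian_gamma("medium")),
                   svm_coarse_gaussian = list(kernel = "radial",
                                              gamma = .gaussian_gamma("coarse")))
    args <- c(list(x = X[split$train, , drop = FALSE], y = tr$y,
                   type = "eps-regression", cost = 1, epsilon = eps,
                   scale = FALSE, coef0 = 1), kern)
    fit <- do.call(e1071::svm, args)
    as.numeric(stats::predict(fit, X))
  }
  metrics <- do.call(rbind, lapply(
    c("train", "validation", "test", "all"),
    function(p) {
      idx <- if (p == "all") seq_along(y) else split[[p]]
      data.frame(partition = p,
                 mse = mse(y[idx], preds[idx]),
                 r = tryCatch(pearson_r(y[idx], preds[idx]),
                              error = function(e) NA_real_),
                 stringsAsFactors = FALSE)
    }))
  structure(list(family = family, predictions = preds, metrics = metrics,
                 coefficients = coefs),
            class = "baseline_result")
}

#' Fit every baseline family
#'
#' @inheritParams fit_baseline
#' @param families Families to fit (default all nine).
#' @return Named list of `baseline_result`s.
#' @export
fit_all_baselines <- function(features, target, split,
                              families = baseline_families()) {
  stats::setNames(lapply(families, fit_baseline,
                         features = features, target = target, split = split),
                  families)
}

#' Compare a trained network against the baseline families
#'
#' Computes the ratio of the network's Pearson correlation to the best
#' correlation attained by the linear families and by the kernel (SVM)
#' families, on one partition.
#'
#' @param nn_r The network's Pearson correlation on `partition`.
#' @param baseline_results Named list from [fit_all_baselines()].
#' @param partition Partition on which all correlations are read
#'   (default `"test"`).
#' @return One-row data frame: `nn_r`, `best_linear_r`, `best_svm_r`,
#'   `ratio_nn_vs_linear`, `ratio_nn_vs_svm`.
#' @export
compare_models <- function(nn_r, baseline_results, partition = "test") {
  get_r <- function(res) {
    res$metrics$r[res$metrics$partition == partition]
  }
  fams <- names(baseline_results)
  rs <- vapply(baseline_results, get_r, numeric(1))
  lin <- rs[fams %in% c("linear", "robust_linear", "stepwise_linear")]
  svm <- rs[startsWith(fams, "svm_")]
  best_lin <- if (length(lin)) max(lin, na.rm = TRUE) else NA_real_
  best_svm <- if (length(svm)) max(svm, na.rm = TRUE) else NA_real_
  data.frame(nn_r = nn_r, best_linear_r = best_lin, best_svm_r = best_svm,
             ratio_nn_vs_linear = nn_r / best_lin,
             ratio_nn_vs_svm = nn_r / best_svm)
}
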