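# Min-max normalization to [-1, +1] and the 70/15/15 split.
#
# y = (ymax - ymin) (x - xmin) / (xmax - xmin) + ymin, with ymax = +1 and
# ymin = -1. The map is affine and is never clipped, so values outside the
# fitted range (possible when fitting on the training rows only) map outside
# [-1, 1] and remain exactly invertible.

#' Fit per-variable min-max normalization specs
#'
#' @param data Numeric matrix or data frame (one column per variable).
#' @param scope `"whole_dataset"` (default: limits from all rows, the order
#'   in which the original pipeline normalizes before splitting) or
#'   `"train_only"` (leakage-safe: limits from the training rows of `split`).
#' @param split A `split_indices` object; required when `scope = "train_only"`.
#' @param ymin,ymax Normalized-scale limits.
#' @return Object of class `norm_spec_set`: named list with per-variable
#'   `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
fit_normalizer <- function(data, scope = c("whole_dataset", "train_only"),
                           split = NULL, ymin = -1, ymax = 1) {
  scope <- match.arg(scope)
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("cannot fit a normalizer on an empty dataset", call. = FALSE)
  if (scope == "train_only") {
    if (is.null(split)) stop("scope = 'train_only' requires a split", call. = FALSE)
    data <- data[split$train, , drop = FALSE]
  }
  specs <- lapply(seq_len(ncol(data)), function(j) {
    xmin <- min(data[, j]); xmax <- max(data[, j])
    if (xmin == xmax) {
      stop(sprintf("column %s is constant (xmin = xmax = %g); cannot normalize",
                   colnames(data)[j] %||% j, xmin), call. = FALSE)
    }
    list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  })
  names(specs) <- colnames(data)
  structure(specs, class = "norm_spec_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max normalize values
#'
#' @param x Numeric vector or matrix.
#' @param spec A single spec (list with `xmin`, `xmax`, `ymin`, `ymax`) when
#'   `x` is a vector, or a `norm_spec_set` matched by column when `x` is a
#'   matrix.
#' @return Normalized values on the `[ymin, ymax]` scale (unclipped).
#' @export
normalize <- function(x, spec) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    out <- x
    for (j in seq_len(ncol(x))) {
      s <- spec[[colnames(x)[j] %||% j]] %||% spec[[j]]
      out[, j] <- normalize(x[, j], s)
    }
    return(out)
  }
  (spec$ymax - spec$ymin) * (x - spec$xmin) / (spec$xmax - spec$xmin) + spec$ymin
}

#' Invert min-max normalization
#'
#' @inheritParams normalize
#' @param y Normalized values.
#' @return Values on the natural scale; exact algebraic inverse of
#'   [normalize()].
#' @export
denormalize <- function(y, spec) {
  if (is.matrix(y) || is.data.frame(y)) {
    y <- as.matrix(y)
    out <- y
    for (j in seq_len(ncol(y))) {
      s <- spec[[colnames(y)[j] %||% j]] %||% spec[[j]]
      out[, j] <- denormalize(y[, j], s)
    }
    return(out)
  }
  (y - spec$ymin) * (spec$xmax - spec$xmin) / (spec$ymax - spec$ymin) + spec$xmin
}

#' Random train/validation/test split
#'
#' Permutes row indices under `seed` and partitions them with the rounding
#' rule train = floor(0.70 n), validation = floor(0.15 n), test = remainder,
#' which reproduces 56/12/12 at n = 80.
#'
#' @param n Number of rows (must allow each partition at least one row).
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed.
#' @return Object of class `split_indices` with integer vectors `train`,
#'   `validation`, `test` and the `seed`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) {
    stop(sprintf("n = %d too small: every partition needs at least one row", n),
         call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  structure(
    list(train = sort(perm[seq_len(n_train)]),
         validation = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[n_train + n_val + seq_len(n_test)]),
         seed = as.integer(seed)),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
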