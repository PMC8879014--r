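# Olden connection-weight sensitivity: the signed contribution of input i
# is the sum over hidden neurons of the product of its input-to-hidden
# weight and the hidden-to-output weight. Relative importance is the
# contribution normalized by the sum of absolute contributions (the signed
# grand sum in the textbook formula can vanish or change sign, so the
# percentage uses absolute normalization and the sign is reported
# alongside).

#' Olden connection-weight relative importance
#'
#' @param params Either an `nn_params` object or an `HN x p`
#'   input-to-hidden weight matrix (then `w2` must be given).
#' @param w2 Hidden-to-output weight vector when `params` is a raw matrix.
#' @param input_names Optional input labels.
#' @return Data frame with one row per input: `input`, `contribution`
#'   (signed), `ri_percent` (absolute percentages summing to 100).
#' @examples
#' olden_ri(matrix(c(2, 1), nrow = 1), w2 = 3)  # RI 66.67 / 33.33
#' @export
olden_ri <- function(params, w2 = NULL, input_names = NULL) {
  if (inherits(params, "nn_params")) {
    W1 <- params$W1
    w2 <- params$w2
    if (is.null(input_names)) input_names <- FEATURE_VARS
  } else {
    W1 <- as.matrix(params)
    if (is.null(w2)) stop("w2 is required when params is a weight matrix", call. = FALSE)
  }
  if (length(w2) != nrow(W1)) {
    stop("w2 length must equal the number of hidden neurons", call. = FALSE)
  }
  contribution <- as.vector(t(W1) %*% w2)
  denom <- sum(abs(contribution))
  if (denom == 0) {
    stop("all connection-weight contributions are zero; relative importance undefined",
         call. = FALSE)
  }
  if (is.null(input_names)) input_names <- paste0("x", seq_len(ncol(W1)))
  data.frame(input = input_names,
             contribution = contribution,
             ri_percent = 100 * abs(contribution) / denom,
             stringsAsFactors = FALSE)
}

#' Rank inputs by relative importance
#'
#' @param ri A data frame from [olden_ri()].
#' @return The same rows ordered by `ri_percent` descending, ties kept in
#'   input order.
#' @export
rank_inputs <- function(ri) {
  if (nrow(ri) == 0L) stop("empty relative-importance set", call. = FALSE)
  ri[order(-ri$ri_percent, seq_len(nrow(ri))), , drop = FALSE]
}
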