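# Feed-forward 4-HN-1 regression network with tansig (hyperbolic tangent)
# hidden units and, by default, a linear output unit. The full parameter set
# is encoded as a flat vector of length 6*HN + 1 so the swarm optimizer can
# treat training as continuous search; ordering is input weights row-major
# (per hidden neuron: its four input weights), hidden biases, output
# weights, output bias.

#' Construct network parameters
#'
#' @param W1 `HN x 4` input-to-hidden weight matrix.
#' @param b1 Length-`HN` hidden bias vector.
#' @param w2 Length-`HN` hidden-to-output weight vector.
#' @param b2 Scalar output bias.
#' @param output Output activation: `"linear"` (default) or `"tansig"`.
#' @return Object of class `nn_params`.
#' @export
nn_params <- function(W1, b1, w2, b2, output = c("linear", "tansig")) {
  output <- match.arg(output)
  W1 <- as.matrix(W1)
  hn <- nrow(W1)
  if (hn < 1 || hn > 30) stop("hidden-neuron count must be in [1, 30]", call. = FALSE)
  if (ncol(W1) != 4L) stop("W1 must have 4 columns (one per input)", call. = FALSE)
  if (length(b1) != hn || length(w2) != hn || length(b2) != 1L) {
    stop("parameter dimensions inconsistent with HN", call. = FALSE)
  }
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), hn = hn, output = output),
            class = "nn_params")
}

#' Forward pass
#'
#' Computes `b2 + w2 . tanh(W1 x + b1)` for every row `x` of `features`
#' (with a final tanh when the output unit is tansig). Inputs are expected
#' on the `[-1, 1]` normalized scale.
#'
#' @param params An `nn_params` object.
#' @param features Numeric matrix with 4 columns.
#' @return Numeric vector of predictions, one per row.
#' @export
nn_forward <- function(params, features) {
  stopifnot(inherits(params, "nn_params"))
  features <- as.matrix(features)
  if (ncol(features) != 4L) stop("features must have 4 columns", call. = FALSE)
  H <- tanh(sweep(features %*% t(params$W1), 2, params$b1, "+"))
  out <- as.vector(H %*% params$w2) + params$b2
  if (params$output == "tansig") out <- tanh(out)
  out
}

#' Encode network parameters as a flat vector
#'
#' @param params An `nn_params` object.
#' @return Numeric vector of length `6 * HN + 1`: input weights row-major,
#'   hidden biases, output weights, output bias.
#' @export
nn_encode <- function(params) {
  stopifnot(inherits(params, "nn_params"))
  c(as.vector(t(params$W1)), params$b1, params$w2, params$b2)
}

#' Decode a flat vector into network parameters
#'
#' @param vec Numeric vector of length `6 * HN + 1`.
#' @param hn Hidden-neuron count.
#' @param output Output activation.
#' @return An `nn_params` object; exact inverse of [nn_encode()].
#' @export
nn_decode <- function(vec, hn, output = c("linear", "tansig")) {
  output <- match.arg(output)
  expected <- 6L * hn + 1L
  if (length(vec) != expected) {
    stop(sprintf("flat vector has length %d; expected 6*%d + 1 = %d",
                 length(vec), hn, expected), call. = FALSE)
  }
  W1 <- matrix(vec[seq_len(4L * hn)], nrow = hn, ncol = 4L, byrow = TRUE)
  b1 <- vec[4L * hn + seq_len(hn)]
  w2 <- vec[5L * hn + seq_len(hn)]
  b2 <- vec[6L * hn + 1L]
  nn_params(W1, b1, w2, b2, output = output)
}

#' Dimension of the flat parameter vector
#'
#' @param hn Hidden-neuron count.
#' @return `6 * hn + 1`.
#' @export
nn_dim <- function(hn) 6L * as.integer(hn) + 1L
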