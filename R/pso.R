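# Particle swarm optimization of the network's flat weight/bias vector.
#
# Velocity and position updates follow the canonical form
#   V_new = w V + C_a r_a (pbest - X) + C_b r_b (gbest - X)
#   X_new = X + V_new
# with r_a, r_b fresh uniform(0,1) draws per particle and dimension,
# componentwise velocity clamping, and position clipping to a box. The
# global-best fitness is non-increasing by construction. Training minimizes
# the swarm fitness E(w, b) = (1/S) sum_k (T_k - P_k)^2, i.e. the training
# MSE of the decoded network, and early-stops on validation error; an
# optional damped Gauss-Newton (Levenberg-Marquardt) refinement polishes
# the swarm solution and is kept only when it does not worsen validation
# error.

#' PSO configuration
#'
#' @param swarm_size Number of particles (default 10).
#' @param iterations Maximum iterations (default 2000).
#' @param inertia Inertia weight applied to the previous velocity.
#' @param c_a,c_b Acceleration coefficients toward the personal and global
#'   best (defaults are the standard constriction-equivalent values).
#' @param init_range Interval for uniform position initialization.
#' @param v_init_range Interval for uniform velocity initialization.
#' @param bounds Position box; positions are clipped componentwise.
#' @param v_clamp Componentwise velocity limit.
#' @param early_stop_patience Iterations without validation improvement
#'   before training halts (ignored by [pso_minimize()] itself).
#' @param refine Logical: run Levenberg-Marquardt refinement after the
#'   swarm search.
#' @param seed Integer seed.
#' @return Object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 10L, iterations = 2000L,
                       inertia = 0.729, c_a = 1.49445, c_b = 1.49445,
                       init_range = c(-1, 1), v_init_range = c(-0.1, 0.1),
                       bounds = c(-10, 10), v_clamp = 1.0,
                       early_stop_patience = 200L, refine = TRUE,
                       seed = 1L) {
  stopifnot(swarm_size >= 1, iterations >= 1, inertia >= 0,
            c_a >= 0, c_b >= 0, v_clamp > 0)
  structure(
    list(swarm_size = as.integer(swarm_size), iterations = as.integer(iterations),
         inertia = inertia, c_a = c_a, c_b = c_b,
         init_range = init_range, v_init_range = v_init_range,
         bounds = bounds, v_clamp = v_clamp,
         early_stop_patience = as.integer(early_stop_patience),
         refine = isTRUE(refine), seed = as.integer(seed)),
    class = "pso_config"
  )
}

#' Initialize a swarm state
#'
#' @param fn Fitness function taking a numeric vector.
#' @param dim Search-space dimension.
#' @param config A [pso_config()].
#' @return Object of class `swarm_state` with positions `X`, velocities `V`,
#'   personal bests, global best, and an iteration counter. RNG draws come
#'   from the current stream (seed the stream before calling, as
#'   [pso_minimize()] does).
#' @export
pso_init <- function(fn, dim, config) {
  S <- config$swarm_size
  X <- matrix(stats::runif(S * dim, config$init_range[1], config$init_range[2]), S, dim)
  V <- matrix(stats::runif(S * dim, config$v_init_range[1], config$v_init_range[2]), S, dim)
  fit <- apply(X, 1, fn)
  g <- which.min(fit)
  structure(
    list(X = X, V = V, pbest = X, pbest_fit = fit,
         gbest = X[g, ], gbest_fit = fit[g], iter = 0L),
    class = "swarm_state"
  )
}

#' One particle-swarm update step
#'
#' Applies the velocity and position updates, clamps velocities, clips
#' positions, re-evaluates fitness and updates personal/global bests (the
#' global-best fitness never increases).
#'
#' @param state A `swarm_state`.
#' @param fn Fitness function.
#' @param config A [pso_config()].
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, fn, config) {
  S <- nrow(state$X); D <- ncol(state$X)
  Ra <- matrix(stats::runif(S * D), S, D)
  Rb <- matrix(stats::runif(S * D), S, D)
  G <- matrix(state$gbest, S, D, byrow = TRUE)
  V <- config$inertia * state$V +
    config$c_a * Ra * (state$pbest - state$X) +
    config$c_b * Rb * (G - state$X)
  V <- pmin(pmax(V, -config$v_clamp), config$v_clamp)
  X <- pmin(pmax(state$X + V, config$bounds[1]), config$bounds[2])
  fit <- apply(X, 1, fn)
  improved <- fit < state$pbest_fit
  state$pbest[improved, ] <- X[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  g <- which.min(state$pbest_fit)
  if (state$pbest_fit[g] < state$gbest_fit) {
    state$gbest <- state$pbest[g, ]
    state$gbest_fit <- state$pbest_fit[g]
  }
  state$X <- X
  state$V <- V
  state$iter <- state$iter + 1L
  state
}

#' Minimize a function by particle swarm
#'
#' @param fn Objective function of a numeric vector, to minimize.
#' @param dim Dimension of the search space.
#' @param config A [pso_config()].
#' @param monitor Optional `function(iteration, gbest, gbest_fit)` called
#'   after every step; returning `TRUE` stops the search (used for early
#'   stopping on validation error).
#' @param track Logical: record the full per-iteration position/fitness
#'   history (memory-heavy; for diagnostics and small runs).
#' @return List with `par` (best position), `value` (its fitness),
#'   `history` (per-iteration gbest fitness), `iterations`, and, when
#'   `track = TRUE`, `positions`/`fitness` arrays.
#' @export
pso_minimize <- function(fn, dim, config = pso_config(), monitor = NULL,
                         track = FALSE) {
  withr::with_seed(config$seed, {
    state <- pso_init(fn, dim, config)
    init_X <- state$X
    init_fit <- state$pbest_fit
    history <- numeric(config$iterations)
    pos_hist <- if (track) vector("list", config$iterations) else NULL
    fit_hist <- if (track) vector("list", config$iterations) else NULL
    n_done <- 0L
    for (it in seq_len(config$iterations)) {
      state <- pso_step(state, fn, config)
      history[it] <- state$gbest_fit
      if (track) {
        pos_hist[[it]] <- state$X
        fit_hist[[it]] <- apply(state$X, 1, fn)
      }
      n_done <- it
      if (!is.null(monitor) && isTRUE(monitor(it, state$gbest, state$gbest_fit))) break
    }
    out <- list(par = state$gbest, value = state$gbest_fit,
                history = history[seq_len(n_done)], iterations = n_done)
    if (track) {
      out$init_positions <- init_X
      out$init_fitness <- init_fit
      out$positions <- pos_hist[seq_len(n_done)]
      out$fitness <- fit_hist[seq_len(n_done)]
      out$final_pbest_fit <- state$pbest_fit
      out$final_gbest_fit <- state$gbest_fit
    }
    out
  })
}

#' Swarm fitness of a flat parameter vector
#'
#' The fitness E = (1/S) sum over training samples of the squared error of
#' the decoded network; with a single output neuron this equals the training
#' mean squared error.
#'
#' @param vec Flat parameter vector of length `6 * hn + 1`.
#' @param hn Hidden-neuron count.
#' @param features Normalized feature matrix (training rows).
#' @param target Normalized target vector (training rows).
#' @param output Output activation.
#' @return Nonnegative fitness value.
#' @export
nn_fitness <- function(vec, hn, features, target, output = "linear") {
  if (length(target) == 0L) stop("empty training sample set", call. = FALSE)
  params <- nn_decode(vec, hn, output = output)
  mean((target - nn_forward(params, features))^2)
}

# Fast fitness closure: avoids repeated nn_params validation in the hot loop.
.make_fitness <- function(features, target, hn, output = "linear") {
  X <- as.matrix(features)
  y <- as.numeric(target)
  i_w1 <- seq_len(4L * hn)
  i_b1 <- 4L * hn + seq_len(hn)
  i_w2 <- 5L * hn + seq_len(hn)
  i_b2 <- 6L * hn + 1L
  tansig_out <- identical(output, "tansig")
  function(vec) {
    W1 <- matrix(vec[i_w1], nrow = hn, ncol = 4L, byrow = TRUE)
    H <- tanh(sweep(X %*% t(W1), 2, vec[i_b1], "+"))
    p <- as.vector(H %*% vec[i_w2]) + vec[i_b2]
    if (tansig_out) p <- tanh(p)
    mean((y - p)^2)
  }
}

# Residuals and analytic Jacobian for the Levenberg-Marquardt refinement.
.nn_residuals <- function(vec, hn, X, y, output = "linear") {
  y - nn_forward(nn_decode(vec, hn, output = output), X)
}

.nn_jacobian <- function(vec, hn, X, y, output = "linear") {
  W1 <- matrix(vec[seq_len(4L * hn)], nrow = hn, ncol = 4L, byrow = TRUE)
  b1 <- vec[4L * hn + seq_len(hn)]
  w2 <- vec[5L * hn + seq_len(hn)]
  b2 <- vec[6L * hn + 1L]
  A <- sweep(X %*% t(W1), 2, b1, "+")
  H <- tanh(A)                                   # n x hn
  G <- (1 - H^2) * matrix(w2, nrow(X), hn, byrow = TRUE)
  # d pred / d W1[j, l] = G[, j] * X[, l]; columns ordered row-major like
  # the flat encoding.
  J_W1 <- G[, rep(seq_len(hn), each = 4L), drop = FALSE] *
    X[, rep(1:4, hn), drop = FALSE]
  Jp <- cbind(J_W1, G, H, 1)
  if (identical(output, "tansig")) {
    out <- tanh(as.vector(H %*% w2) + b2)
    Jp <- Jp * (1 - out^2)
  }
  -Jp  # residual = y - pred
}

#' Damped Gauss-Newton least-squares minimization
#'
#' Levenberg-Marquardt iteration on a residual vector: steps solve
#' `(J'J + lambda diag(J'J)) delta = -J'r`, with the damping factor
#' adapted multiplicatively on acceptance/rejection. Handles the
#' overparameterized case (more parameters than residuals) that arises for
#' wide hidden layers on small training sets.
#'
#' @param par Numeric start vector.
#' @param resid_fn Function returning the residual vector.
#' @param jac_fn Function returning the residual Jacobian (rows =
#'   residuals, columns = parameters).
#' @param maxiter Maximum outer iterations.
#' @param tol Relative decrease of the sum of squares below which iteration
#'   stops.
#' @param monitor Optional function called with the accepted parameter
#'   vector after every accepted step (used to snapshot the best-by-
#'   validation iterate).
#' @return List with `par`, `sse` (final sum of squares), `iterations`.
#' @export
lm_least_squares <- function(par, resid_fn, jac_fn, maxiter = 50L, tol = 1e-12,
                             monitor = NULL) {
  r <- resid_fn(par)
  sse <- sum(r^2)
  lambda <- 1e-3
  it <- 0L
  p <- length(par)
  while (it < maxiter) {
    it <- it + 1L
    J <- jac_fn(par)
    A <- crossprod(J)
    g <- crossprod(J, r)
    d <- diag(A)
    d[d < 1e-12] <- 1e-12
    accepted <- FALSE
    for (try in 1:12) {
      step <- tryCatch(solve(A + lambda * diag(d, p), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- par + as.vector(step)
        rc <- resid_fn(cand)
        sc <- sum(rc^2)
        if (is.finite(sc) && sc < sse) {
          par <- cand; r <- rc
          improved <- (sse - sc) / max(sse, 1e-300)
          sse <- sc
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          if (!is.null(monitor)) monitor(par)
          if (improved < tol) it <- maxiter  # converged
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
  }
  list(par = par, sse = sse, iterations = it)
}

#' Levenberg-Marquardt refinement of a trained network
#'
#' Damped Gauss-Newton least squares (with analytic Jacobian) started from
#' the swarm solution, on the same training fitness. When validation rows
#' are supplied, the validation error is evaluated after every accepted
#' step and the returned parameters are the snapshot at its minimum
#' (early stopping at the moment of lowest error); the input model is
#' returned unchanged if no iterate improves on it.
#'
#' @param params An `nn_params` object (the swarm solution).
#' @param features,target Normalized training rows.
#' @param val_features,val_target Optional validation rows used for the
#'   non-worsening guard; when omitted the guard uses training fitness.
#' @param maxiter Maximum LM iterations.
#' @param decay Weight-decay (ridge) strengths to try; the candidate with
#'   the lowest guard error wins. Decay regularizes the small-sample fit
#'   of wide hidden layers: the least-squares objective becomes
#'   `sum r^2 + decay * S * |par|^2` with `S` the number of training rows.
#' @return A list with `params` (possibly refined), `train_mse`, `val_mse`
#'   (NA when no validation rows were supplied), and `refined` (logical).
#' @export
nn_refine <- function(params, features, target,
                      val_features = NULL, val_target = NULL, maxiter = 60L,
                      decay = c(0, 1e-4, 1e-3, 1e-2)) {
  stopifnot(inherits(params, "nn_params"))
  X <- as.matrix(features); y <- as.numeric(target)
  hn <- params$hn; output <- params$output
  npar <- nn_dim(hn)
  guard <- function(p) {
    if (is.null(val_features)) mean((y - nn_forward(p, X))^2)
    else mean((as.numeric(val_target) - nn_forward(p, as.matrix(val_features)))^2)
  }
  best_guard <- guard(params)
  best_vec <- NULL
  snapshot <- function(v) {
    g <- guard(nn_decode(v, hn, output = output))
    if (g < best_guard) {
      best_guard <<- g
      best_vec <<- v
    }
    invisible(NULL)
  }
  start <- nn_encode(params)
  for (dk in decay) {
    pen <- sqrt(dk * nrow(X))
    lm_least_squares(
      start,
      resid_fn = function(v) c(.nn_residuals(v, hn, X, y, output), pen * v),
      jac_fn = function(v) rbind(.nn_jacobian(v, hn, X, y, output),
                                 diag(pen, npar)),
      maxiter = maxiter, monitor = snapshot
    )
  }
  keep <- !is.null(best_vec)
  best <- if (keep) nn_decode(best_vec, hn, output = output) else params
  list(params = best,
       train_mse = mean((y - nn_forward(best, X))^2),
       val_mse = if (is.null(val_features)) NA_real_ else best_guard,
       refined = keep)
}

#' Train a network by hybrid swarm optimization
#'
#' Runs the particle swarm over the flat weight/bias vector against the
#' training-MSE fitness, tracking the validation MSE of the global best at
#' every iteration. Training halts after `early_stop_patience` iterations
#' without validation improvement, and the returned parameters are the
#' global-best snapshot at the minimum validation error. When
#' `config$refine` is set, a Levenberg-Marquardt polish is applied and kept
#' only if it does not worsen validation MSE.
#'
#' @param features Normalized `n x 4` feature matrix (all rows).
#' @param target Normalized length-`n` target vector.
#' @param split A [split_dataset()] result.
#' @param hn Hidden-neuron count in `[1, 30]`.
#' @param config A [pso_config()].
#' @param output Output activation.
#' @return Object of class `trained_model`: `params`, `hn`, `history`
#'   (data frame of iteration, gbest fitness, validation MSE), `val_mse`,
#'   `train_mse`, `refined`, `seed`.
#' @export
train_nnpso <- function(features, target, split, hn, config = pso_config(),
                        output = "linear") {
  stopifnot(hn >= 1, hn <= 30)
  X <- as.matrix(features); y <- as.numeric(target)
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$validation, , drop = FALSE]; yva <- y[split$validation]
  fn <- .make_fitness(Xtr, ytr, hn, output)
  val_fn <- .make_fitness(Xva, yva, hn, output)

  best_val <- Inf
  best_par <- NULL
  last_gbest_fit <- Inf
  last_val <- NA_real_
  since_improve <- 0L
  val_trace <- numeric(config$iterations)

  monitor <- function(it, gbest, gbest_fit) {
    if (gbest_fit < last_gbest_fit) {
      last_gbest_fit <<- gbest_fit
      last_val <<- val_fn(gbest)
    }
    val_trace[it] <<- last_val
    if (last_val < best_val - 1e-15) {
      best_val <<- last_val
      best_par <<- gbest
      since_improve <<- 0L
    } else {
      since_improve <<- since_improve + 1L
    }
    since_improve >= config$early_stop_patience
  }

  run <- pso_minimize(fn, nn_dim(hn), config, monitor = monitor)
  if (is.null(best_par)) best_par <- run$par
  params <- nn_decode(best_par, hn, output = output)
  train_mse <- fn(best_par)
  val_mse <- val_fn(best_par)
  refined <- FALSE
  if (config$refine) {
    ref <- nn_refine(params, Xtr, ytr, Xva, yva)
    params <- ref$params
    refined <- ref$refined
    if (refined) {
      val_mse <- ref$val_mse
      train_mse <- mean((ytr - nn_forward(params, Xtr))^2)
    }
  }
  structure(
    list(params = params, hn = as.integer(hn),
         history = data.frame(iteration = seq_len(run$iterations),
                              gbest_fitness = run$history,
                              val_mse = val_trace[seq_len(run$iterations)]),
         val_mse = val_mse, train_mse = train_mse,
         refined = refined, seed = config$seed),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> 4-%d-1 network: train MSE %.3g, validation MSE %.3g (%d PSO iterations%s)\n",
              x$hn, x$train_mse, x$val_mse, nrow(x$history),
              if (x$refined) ", LM-refined" else ""))
  invisible(x)
}
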