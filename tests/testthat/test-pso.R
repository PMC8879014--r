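test_that("a single update step reproduces the hand-computed formula", {
  # X = 1, V = 0.5, inertia 1, no attraction: V_new = 0.5, X_new = 1.5
  cfg <- pso_config(swarm_size = 1, inertia = 1, c_a = 0, c_b = 0,
                    v_clamp = 1, bounds = c(-10, 10))
  state <- structure(
    list(X = matrix(1, 1, 1), V = matrix(0.5, 1, 1),
         pbest = matrix(1, 1, 1), pbest_fit = 0,
         gbest = 1, gbest_fit = 0, iter = 0L),
    class = "swarm_state")
  out <- pso_step(state, function(x) 99, cfg)
  expect_equal(out$V[1, 1], 0.5)
  expect_equal(out$X[1, 1], 1.5)
})

test_that("zero coefficients freeze the swarm; a particle at both bests stays put", {
  cfg <- pso_config(swarm_size = 3, inertia = 0, c_a = 0, c_b = 0, seed = 4)
  f <- function(x) sum(x^2)
  state <- withr::with_seed(4, pso_init(f, 2, cfg))
  out <- pso_step(state, f, cfg)
  expect_equal(out$V, matrix(0, 3, 2))
  expect_equal(out$X, state$X)
  # single particle sitting at pbest = gbest with zero velocity
  cfg1 <- pso_config(swarm_size = 1, inertia = 0.7, seed = 1)
  st <- structure(
    list(X = matrix(c(1, 2), 1, 2), V = matrix(0, 1, 2),
         pbest = matrix(c(1, 2), 1, 2), pbest_fit = f(c(1, 2)),
         gbest = c(1, 2), gbest_fit = f(c(1, 2)), iter = 0L),
    class = "swarm_state")
  out1 <- pso_step(st, f, cfg1)
  expect_equal(out1$X, st$X)
  expect_equal(out1$V, matrix(0, 1, 2))
})

test_that("with no attraction the velocity decays geometrically", {
  cfg <- pso_config(swarm_size = 1, inertia = 0.8, c_a = 0, c_b = 0,
                    v_clamp = 10, bounds = c(-100, 100), seed = 2)
  f <- function(x) 0
  v0 <- 0.9
  st <- structure(
    list(X = matrix(0, 1, 1), V = matrix(v0, 1, 1),
         pbest = matrix(0, 1, 1), pbest_fit = 0,
         gbest = 0, gbest_fit = 0, iter = 0L),
    class = "swarm_state")
  for (t in 1:12) {
    st <- pso_step(st, f, cfg)
    expect_equal(st$V[1, 1], v0 * 0.8^t, tolerance = 1e-12)
    expect_equal(st$X[1, 1], v0 * sum(0.8^(1:t)), tolerance = 1e-12)
  }
})

test_that("the swarm solves the 10-dimensional sphere benchmark", {
  res <- pso_minimize(function(x) sum(x^2), 10,
                      pso_config(swarm_size = 10, iterations = 2000, seed = 42))
  expect_lt(sqrt(sum(res$par^2)), 1e-3)
  expect_true(all(diff(res$history) <= 0))
  res2 <- pso_minimize(function(x) sum(x^2), 10,
                       pso_config(swarm_size = 10, iterations = 2000, seed = 42))
  expect_identical(res$par, res2$par)
})

test_that("pbest/gbest bookkeeping matches brute-force recomputation", {
  f <- function(x) sum((x - 0.3)^2) + 0.1 * sum(abs(x))
  res <- pso_minimize(f, 3, pso_config(swarm_size = 5, iterations = 20, seed = 6),
                      track = TRUE)
  fits <- rbind(res$init_fitness,
                do.call(rbind, res$fitness))  # (1 + iters) x swarm
  expect_equal(res$final_pbest_fit, apply(fits, 2, min))
  expect_equal(res$final_gbest_fit, min(fits))
  expect_equal(res$value, min(fits))
})

test_that("velocity clamping and position bounds are enforced", {
  cfg <- pso_config(swarm_size = 8, iterations = 30, v_clamp = 0.2,
                    bounds = c(-0.5, 0.5), seed = 3)
  res <- pso_minimize(function(x) sum((x - 10)^2), 4, cfg, track = TRUE)
  for (P in res$positions) expect_true(all(P >= -0.5 & P <= 0.5))
  expect_equal(max(abs(res$par)), 0.5)  # optimum outside the box: stuck at bound
})

test_that("swarm fitness equals the metrics-module MSE on the training rows", {
  X <- withr::with_seed(1, matrix(stats::runif(30 * 4, -1, 1), 30, 4))
  y <- withr::with_seed(2, stats::rnorm(30))
  for (s in 1:20) {
    hn <- (s %% 5) + 1
    v <- withr::with_seed(400 + s, stats::rnorm(nn_dim(hn)))
    pred <- nn_forward(nn_decode(v, hn), X)
    expect_lt(abs(nn_fitness(v, hn, X, y) - mse(y, pred)), 1e-12)
    perm <- withr::with_seed(s, sample.int(30))
    expect_equal(nn_fitness(v, hn, X[perm, ], y[perm]), nn_fitness(v, hn, X, y))
  }
  p <- random_params(2, seed = 1)
  y_exact <- nn_forward(p, X)
  expect_equal(nn_fitness(nn_encode(p), 2, X, y_exact), 0)
  expect_error(nn_fitness(rep(0, 7), 1, X[0, ], numeric(0)))
})

test_that("training is reproducible and tracks a non-increasing global best", {
  cam <- small_campaign()
  yn <- normalize(cam$ds$targets[, "ni"], cam$norm$ni)
  cfg <- pso_config(iterations = 120, swarm_size = 8, seed = 5, refine = FALSE)
  m1 <- train_nnpso(cam$Xn, yn, cam$split, hn = 4, cfg)
  m2 <- train_nnpso(cam$Xn, yn, cam$split, hn = 4, cfg)
  expect_equal(nn_encode(m1$params), nn_encode(m2$params))
  expect_true(all(diff(m1$history$gbest_fitness) <= 0))
})

test_that("early stopping halts training when validation stalls", {
  cam <- small_campaign()
  yn <- normalize(cam$ds$targets[, "cr"], cam$norm$cr)
  cfg <- pso_config(iterations = 2000, swarm_size = 8, seed = 5,
                    early_stop_patience = 30, refine = FALSE)
  m <- train_nnpso(cam$Xn, yn, cam$split, hn = 3, cfg)
  expect_lt(nrow(m$history), 2000)
})

test_that("parameters of a known 4-2-1 network are recovered from noisy data", {
  true <- random_params(2, seed = 5)
  X <- withr::with_seed(6, matrix(stats::runif(80 * 4, -1, 1), 80, 4))
  y <- nn_forward(true, X) + withr::with_seed(7, stats::rnorm(80, sd = 0.01))
  split <- split_dataset(80, seed = 9)
  m <- train_nnpso(X, y, split, hn = 2,
                   pso_config(iterations = 500, swarm_size = 10, seed = 4))
  pred <- nn_forward(m$params, X)
  expect_gt(pearson_r(y[split$validation], pred[split$validation]), 0.99)
})
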