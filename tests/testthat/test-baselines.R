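test_that("exactly-linear targets are fit perfectly by the linear family", {
  X <- withr::with_seed(1, matrix(stats::runif(400, -1, 1), 100, 4))
  colnames(X) <- c("temp", "ph", "ec", "tds")
  y <- 0.3 - 0.5 * X[, 1] + 2 * X[, 2] + 0.7 * X[, 4]
  split <- split_dataset(100, seed = 2)
  res <- fit_baseline("linear", X, y, split)
  expect_equal(res$metrics$r[res$metrics$partition == "test"], 1, tolerance = 1e-9)
  expect_equal(unname(res$coefficients),
               c(0.3, -0.5, 2, 0, 0.7), tolerance = 1e-9)
})

test_that("stepwise selection keeps the informative predictor", {
  X <- withr::with_seed(3, matrix(stats::runif(400, -1, 1), 100, 4))
  colnames(X) <- c("temp", "ph", "ec", "tds")
  y <- 1.5 * X[, "ph"] + withr::with_seed(4, stats::rnorm(100, sd = 0.05))
  split <- split_dataset(100, seed = 5)
  res <- fit_baseline("stepwise_linear", X, y, split)
  expect_true("ph" %in% names(res$coefficients))
})

test_that("a quadratic kernel recovers targets quadratic in the features", {
  X <- withr::with_seed(6, matrix(stats::runif(800, -1, 1), 200, 4))
  colnames(X) <- c("temp", "ph", "ec", "tds")
  y <- 0.5 * X[, "ph"]^2 + X[, "ec"] * X[, "tds"] - 0.3 * X[, "temp"]
  split <- split_dataset(200, seed = 7)
  res <- fit_baseline("svm_quadratic", X, y, split)
  expect_gt(res$metrics$r[res$metrics$partition == "test"], 0.99)
})

test_that("all nine families fit and are fitted on the training rows only", {
  cam <- small_campaign()
  yn <- normalize(cam$ds$targets[, "cu"], cam$norm$cu)
  res <- fit_all_baselines(cam$Xn, yn, cam$split)
  expect_setequal(names(res), baseline_families())
  for (r in res) expect_identical(dim(r$metrics), c(4L, 3L))
  # leakage check: permuting test targets changes test metrics but not the fit
  y2 <- yn
  y2[cam$split$test] <- withr::with_seed(8, sample(y2[cam$split$test]))
  r1 <- fit_baseline("linear", cam$Xn, yn, cam$split)
  r2 <- fit_baseline("linear", cam$Xn, y2, cam$split)
  expect_equal(r1$coefficients, r2$coefficients)
  expect_equal(r1$predictions, r2$predictions)
  expect_false(isTRUE(all.equal(
    r1$metrics$mse[r1$metrics$partition == "test"],
    r2$metrics$mse[r2$metrics$partition == "test"])))
  expect_error(fit_baseline("random_forest", cam$Xn, yn, cam$split))
})

test_that("comparison ratios follow their definition", {
  fake <- function(r_test) {
    structure(list(family = "x", predictions = NULL,
                   metrics = data.frame(partition = "test", mse = 0, r = r_test)),
              class = "baseline_result")
  }
  res <- list(linear = fake(0.5), robust_linear = fake(0.45),
              stepwise_linear = fake(0.4), svm_linear = fake(0.5),
              svm_fine_gaussian = fake(0.62))
  cmp <- compare_models(0.8, res)
  expect_equal(cmp$ratio_nn_vs_linear, 1.6)
  expect_equal(cmp$ratio_nn_vs_svm, 0.8 / 0.62)
  cmp2 <- compare_models(0.5, res["linear"])
  expect_equal(cmp2$ratio_nn_vs_linear, 1)
})

test_that("the network beats the ordinary linear baseline on nonlinear responses", {
  # directional sanity by majority over several seeds
  wins <- 0L
  for (s in 1:5) {
    cam <- small_campaign(seed = 20 + s)
    yn <- normalize(cam$ds$targets[, "cr"], cam$norm$cr)
    m <- train_nnpso(cam$Xn, yn, cam$split, hn = 8,
                     pso_config(iterations = 200, swarm_size = 8, seed = s))
    nn_r <- pearson_r(yn[cam$split$test],
                      nn_forward(m$params, cam$Xn)[cam$split$test])
    lin <- fit_baseline("linear", cam$Xn, yn, cam$split)
    lin_r <- lin$metrics$r[lin$metrics$partition == "test"]
    if (nn_r >= lin_r) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
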