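test_that("default specs transcribe the published campaign tables", {
  sp <- default_specs("dry", "surface")
  expect_length(sp, 12L)
  expect_equal(vapply(sp[hnpso:::FEATURE_VARS], `[[`, "", "role"),
               rep("feature", 4), ignore_attr = TRUE)
  expect_equal(sp$ph$min, 2.9)
  expect_equal(sp$ph$max, 9.4)
  expect_equal(sp$ph$mean, 6.28)
  expect_equal(sp$cu$mean, 7.67426)
  pb <- default_specs("wet", "ground")$pb
  expect_equal(c(pb$min, pb$max, pb$mean), c(0.05496, 0.12178, 0.11831))
  zn <- default_specs("dry", "ground")$zn
  expect_equal(zn$mean, 13.95211)
  fe <- default_specs("wet", "surface")$fe
  expect_equal(fe$mean, 21.74808)
  for (sp in default_specs("wet", "surface")) {
    expect_lt(sp$min, sp$max)
    expect_gte(sp$mean, sp$min)
    expect_lte(sp$mean, sp$max)
  }
})

test_that("unsupported season or water type is rejected", {
  expect_error(default_specs("dry", "lake"))
  expect_error(default_specs("monsoon", "surface"))
  expect_error(variable_spec("ph", "feature", min = 3, max = 2, mean = 2.5))
  expect_error(variable_spec("ph", "feature", min = 2, max = 9, mean = 10))
})

test_that("feature sampling respects bounds, determinism and the empty case", {
  cfg <- generator_config("dry", "surface", seed = 7L)
  empty <- sample_features(cfg, 0)
  expect_identical(dim(empty), c(0L, 4L))
  X1 <- sample_features(cfg, 200)
  X2 <- sample_features(cfg, 200)
  expect_identical(X1, X2)
  for (v in hnpso:::FEATURE_VARS) {
    sp <- cfg$specs[[v]]
    expect_true(all(X1[, v] >= sp$min & X1[, v] <= sp$max))
  }
})

test_that("marginal means are calibrated to the published tables", {
  # sample mean within 2 standard errors of the table mean at n = 20000
  for (key in list(c("dry", "surface"), c("wet", "ground"))) {
    cfg <- generator_config(key[1], key[2], seed = 7L)
    X <- sample_features(cfg, 20000)
    Y <- generate_targets(X, cfg)
    vals <- cbind(X, Y)
    for (v in colnames(vals)) {
      sp <- cfg$specs[[v]]
      se <- stats::sd(vals[, v]) / sqrt(nrow(vals))
      expect_lt(abs(mean(vals[, v]) - sp$mean), 2 * se + 1e-12,
                label = sprintf("|mean - %g| for %s %s %s", sp$mean,
                                key[1], key[2], v))
    }
  }
})

test_that("configured dependence structure is realized with the right sign", {
  n <- 5000
  for (wt in c("surface", "ground")) {
    cfg <- generator_config("dry", wt, seed = 11L)
    X <- sample_features(cfg, n)
    Y <- generate_targets(X, cfg)
    expect_gt(stats::cor(X[, "ec"], X[, "tds"], method = "spearman"), 0.3)
    pairs <- if (wt == "surface") {
      list(c("cr", "cd"), c("cu", "zn"), c("cd", "cu"), c("cd", "pb"), c("ni", "pb"))
    } else {
      list(c("cr", "cd"), c("cr", "ni"), c("cr", "pb"), c("cd", "ni"),
           c("cd", "pb"), c("fe", "zn"))
    }
    for (p in pairs) {
      expect_gt(stats::cor(Y[, p[1]], Y[, p[2]], method = "spearman"), 0.3,
                label = sprintf("spearman(%s, %s) in %s water", p[1], p[2], wt))
    }
  }
})

test_that("a negative pH response term yields a negative pH-metal correlation", {
  resp <- hnpso:::.default_response("surface")
  resp$cu$w[] <- c(0, -1, 0, 0)
  resp$cu$int_w <- 0
  cfg <- generator_config("dry", "surface", response = resp, seed = 5L,
                          noise_rel_sd = 0)
  X <- sample_features(cfg, 5000)
  Y <- generate_targets(X, cfg)
  expect_lt(stats::cor(X[, "ph"], Y[, "cu"], method = "spearman"), -0.9)
})

test_that("targets are deterministic at zero noise, bounded, and noise perturbs them", {
  cfg0 <- generator_config("wet", "ground", noise_rel_sd = 0, seed = 9L)
  X <- sample_features(cfg0, 150)
  Y1 <- generate_targets(X, cfg0)
  Y2 <- generate_targets(X, cfg0)
  expect_identical(Y1, Y2)
  for (m in colnames(Y1)) {
    sp <- cfg0$specs[[m]]
    expect_true(all(Y1[, m] >= sp$min & Y1[, m] <= sp$max))
  }
  cfgn <- generator_config("wet", "ground", noise_rel_sd = 0.05, seed = 9L)
  expect_false(identical(generate_targets(X, cfgn), Y1))
  expect_error(generate_targets(X[, 1:3], cfg0))
})

test_that("make_dataset composes the stages reproducibly", {
  d1 <- make_dataset("dry", "surface", n = 80, seed = 7)
  d2 <- make_dataset("dry", "surface", n = 80, seed = 7)
  expect_equal(d1$features, d2$features)
  expect_equal(d1$targets, d2$targets)
  expect_identical(dim(d1$features), c(80L, 4L))
  expect_identical(dim(d1$targets), c(80L, 8L))
  d3 <- make_dataset("dry", "surface", n = 80, seed = 8)
  expect_false(identical(d1$features, d3$features))
  expect_error(make_dataset("dry", "surface", n = 0))
})

test_that("CSV round trip preserves the data and provenance", {
  ds <- make_dataset("wet", "surface", n = 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_water_csv(ds, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_water_csv(path)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_equal(back$targets, ds$targets, tolerance = 1e-12)
  expect_identical(back$season, "wet")
  expect_identical(back$seed, 3L)
})

test_that("a flexible regressor recovers the noise-free response", {
  # validation R > 0.99 is attainable on a zero-noise dataset
  cam <- small_campaign(seed = 7L, noise_rel_sd = 0)
  yn <- normalize(cam$ds$targets[, "cu"], cam$norm$cu)
  m <- train_nnpso(cam$Xn, yn, cam$split, hn = 10,
                   pso_config(iterations = 300, swarm_size = 10, seed = 2))
  pred <- nn_forward(m$params, cam$Xn)
  expect_gt(pearson_r(yn[cam$split$validation], pred[cam$split$validation]), 0.99)
})
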