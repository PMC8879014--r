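# Synthetic water-sample generator.
#
# Marginals: scaled Beta on [min, max] with the mean matched to the published
# campaign mean and a fixed concentration alpha + beta = 6 (bounded support,
# exact mean match from the three published numbers).
# Dependence among the features: Gaussian copula with the EC-TDS rank
# correlation set positive. Metal-metal dependence arises from shared
# response-surface weights (see .default_response), which keeps each target
# a deterministic function of the features at zero noise.

DEFAULT_CONCENTRATION <- 6

# Rank-correlation targets among variables, by water type. rho is a Spearman
# correlation; pairs not listed default to independence in the copula.
.default_cor_pairs <- function(water_type) {
  data.frame(var1 = "ec", var2 = "tds", rho = 0.6,
             stringsAsFactors = FALSE)
}

# Per-metal response surfaces: a linear combination of tanh-transformed
# standardized features plus one pairwise interaction of those terms.
# Metals expected to co-vary within a campaign (e.g. Cr-Cd everywhere;
# Cu-Zn, Cd-Cu, Cd-Pb, Ni-Pb in surface water; Cr-Ni, Cr-Pb, Cd-Ni, Cd-Pb,
# Fe-Zn in groundwater) share near-identical weight vectors. Negative pH
# weights encode the acid-mine-drainage chemistry: metal loads rise as pH
# falls and dissolved ions (EC/TDS) rise.
.default_response <- function(water_type) {
  w <- if (water_type == "surface") {
    list(
      cr = list(w = c(0.35, -1.00, 0.75, 0.45), int_pair = c("ph", "ec"),  int_w = 0.30),
      cd = list(w = c(0.25, -0.95, 0.65, 0.55), int_pair = c("ph", "ec"),  int_w = 0.25),
      fe = list(w = c(0.80, -0.40, -0.30, 0.60), int_pair = c("temp", "tds"), int_w = 0.30),
      mn = list(w = c(-0.50, 0.60, 0.40, -0.30), int_pair = c("temp", "ec"),  int_w = -0.25),
      zn = list(w = c(0.30, -0.90, 0.80, 0.40), int_pair = c("ec", "tds"),  int_w = 0.20),
      ni = list(w = c(0.20, -1.05, 0.70, 0.50), int_pair = c("ph", "tds"),  int_w = 0.25),
      pb = list(w = c(0.30, -1.00, 0.60, 0.60), int_pair = c("ph", "ec"),   int_w = 0.20),
      cu = list(w = c(0.40, -0.90, 0.70, 0.45), int_pair = c("temp", "ph"), int_w = -0.20)
    )
  } else {
    list(
      cr = list(w = c(0.25, -0.90, 0.80, 0.40), int_pair = c("ph", "ec"),   int_w = 0.25),
      cd = list(w = c(0.20, -0.85, 0.75, 0.50), int_pair = c("ph", "ec"),   int_w = 0.20),
      fe = list(w = c(0.60, 0.50, -0.40, 0.70), int_pair = c("temp", "tds"), int_w = 0.25),
      mn = list(w = c(-0.40, -0.60, 0.50, 0.30), int_pair = c("temp", "ec"), int_w = 0.20),
      zn = list(w = c(0.55, 0.55, -0.35, 0.65), int_pair = c("temp", "tds"), int_w = 0.30),
      ni = list(w = c(0.30, -0.95, 0.70, 0.45), int_pair = c("ph", "tds"),  int_w = 0.20),
      pb = list(w = c(0.25, -0.90, 0.65, 0.55), int_pair = c("ph", "ec"),   int_w = 0.30),
      cu = list(w = c(0.70, 0.30, 0.40, -0.60), int_pair = c("ec", "tds"),  int_w = -0.25)
    )
  }
  for (m in names(w)) names(w[[m]]$w) <- FEATURE_VARS
  w
}

# Derive a 31-bit substream seed from a root seed; keeps every stage of a
# run on its own reproducible stream.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 65011 + 1) * 30011 + k * 101) %% 2147483647L
}

# Beta shape parameters for a mean-matched scaled Beta with fixed
# concentration kappa = alpha + beta.
.beta_shapes <- function(spec, kappa = DEFAULT_CONCENTRATION) {
  m <- (spec$mean - spec$min) / (spec$max - spec$min)
  if (m <= 0 || m >= 1) {
    stop(sprintf("variable '%s': mean on the boundary of [min, max]", spec$name),
         call. = FALSE)
  }
  c(alpha = kappa * m, beta = kappa * (1 - m))
}

# Analytic moments of the scaled Beta marginal, used to standardize features
# inside the response surface.
.beta_moments <- function(spec, kappa = DEFAULT_CONCENTRATION) {
  sh <- .beta_shapes(spec, kappa)
  m <- sh[["alpha"]] / kappa
  v <- m * (1 - m) / (kappa + 1)
  range <- spec$max - spec$min
  c(mean = spec$mean, sd = range * sqrt(v))
}

#' Generator configuration for synthetic water-sample data
#'
#' Bundles the marginal specs, rank-correlation targets, per-metal response
#' surfaces and noise level that define one synthetic sampling campaign.
#'
#' @param season `"dry"` or `"wet"`.
#' @param water_type `"surface"` or `"ground"`.
#' @param specs Named list of [variable_spec()]s; defaults to
#'   [default_specs()] for the campaign.
#' @param cor_pairs Data frame with columns `var1`, `var2`, `rho` giving
#'   Spearman rank-correlation targets between feature variables.
#' @param response Named list (one element per metal) with fields `w`
#'   (length-4 weights on tanh-transformed standardized features),
#'   `int_pair` (two feature names) and `int_w` (interaction weight).
#' @param noise_rel_sd Nonnegative noise level: standard deviation of the
#'   latent-score noise relative to the score's spread. `0` gives a fully
#'   deterministic feature-to-metal map.
#' @param seed Integer root seed for the campaign.
#' @param concentration Beta concentration (alpha + beta) of every marginal.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(season, water_type,
                             specs = default_specs(season, water_type),
                             cor_pairs = .default_cor_pairs(water_type),
                             response = .default_response(water_type),
                             noise_rel_sd = 0.05,
                             seed = 1L,
                             concentration = DEFAULT_CONCENTRATION) {
  season <- match.arg(season, c("dry", "wet"))
  water_type <- match.arg(water_type, c("surface", "ground"))
  if (noise_rel_sd < 0) stop("noise_rel_sd must be >= 0", call. = FALSE)
  all_vars <- names(specs)
  bad <- unique(c(cor_pairs$var1, cor_pairs$var2))
  bad <- bad[!bad %in% all_vars]
  if (length(bad)) {
    stop("cor_pairs names unknown variables: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (m in names(response)) {
    r <- response[[m]]
    stopifnot(length(r$w) == 4L, length(r$int_pair) == 2L,
              all(r$int_pair %in% FEATURE_VARS), length(r$int_w) == 1L)
  }
  structure(
    list(season = season, water_type = water_type, specs = specs,
         cor_pairs = cor_pairs, response = response,
         noise_rel_sd = noise_rel_sd, seed = as.integer(seed),
         concentration = concentration),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %s season, %s water; %d variables, noise %.3g, seed %d\n",
              x$season, x$water_type, length(x$specs), x$noise_rel_sd, x$seed))
  invisible(x)
}

# Latent Gaussian correlation matrix for the feature copula. Spearman
# targets are converted to the Pearson correlation of the latent normals
# (r = 2 sin(pi * rho / 6)) and the result projected to the nearest
# correlation matrix when the assembled matrix is not positive semidefinite.
.feature_latent_cor <- function(config) {
  p <- length(FEATURE_VARS)
  R <- diag(p)
  dimnames(R) <- list(FEATURE_VARS, FEATURE_VARS)
  cp <- config$cor_pairs
  if (!is.null(cp) && nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      a <- cp$var1[i]; b <- cp$var2[i]
      if (!(a %in% FEATURE_VARS && b %in% FEATURE_VARS)) next
      if (abs(cp$rho[i]) >= 1) {
        stop("rank-correlation targets must have |rho| < 1", call. = FALSE)
      }
      r <- 2 * sin(pi * cp$rho[i] / 6)
      R[a, b] <- R[b, a] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation-target matrix is not positive semidefinite", call. = FALSE)
    }
  }
  R
}

#' Sample feature matrix from the calibrated copula
#'
#' Draws temperature, pH, EC and TDS from mean-matched scaled-Beta marginals
#' coupled by a Gaussian copula with the configured rank correlations.
#'
#' @param config A [generator_config()].
#' @param n Number of rows (sites); `n = 0` returns an empty 4-column matrix.
#' @param seed Seed; defaults to the config's seed.
#' @return `n x 4` numeric matrix with columns `temp`, `ph`, `ec`, `tds`,
#'   every value inside its spec's `[min, max]`.
#' @export
sample_features <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"), n >= 0)
  p <- length(FEATURE_VARS)
  if (n == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = p,
                  dimnames = list(NULL, FEATURE_VARS)))
  }
  R <- .feature_latent_cor(config)
  L <- chol(R + diag(1e-12, p))
  Z <- withr::with_seed(derive_seed(seed, 1L), {
    matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  }) %*% L
  U <- stats::pnorm(Z)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, FEATURE_VARS))
  for (j in seq_len(p)) {
    spec <- config$specs[[FEATURE_VARS[j]]]
    sh <- .beta_shapes(spec, config$concentration)
    X[, j] <- spec$min + (spec$max - spec$min) *
      stats::qbeta(U[, j], sh[["alpha"]], sh[["beta"]])
  }
  X
}

# Latent response score for one metal given standardized tanh features.
.metal_score <- function(tz, resp) {
  s <- as.vector(tz %*% resp$w)
  s + resp$int_w * tz[, resp$int_pair[1]] * tz[, resp$int_pair[2]]
}

#' Generate metal concentrations from features
#'
#' Each metal column is a monotone rescaling (through the metal's calibrated
#' scaled-Beta quantile function) of a smooth latent score of the
#' standardized features, optionally perturbed by latent-scale noise. With
#' `noise_rel_sd = 0` the map is a deterministic function of the features.
#'
#' @param features Feature matrix produced by [sample_features()] under the
#'   same config.
#' @param config A [generator_config()].
#' @param seed Seed for the noise stream; defaults to the config's seed.
#' @return `n x m` matrix of concentrations (mg/L), one column per metal in
#'   the config's response list, every value inside its spec's `[min, max]`.
#' @export
generate_targets <- function(features, config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (ncol(features) != 4L) {
    stop("features must have exactly 4 columns (temp, ph, ec, tds)", call. = FALSE)
  }
  n <- nrow(features)
  metals <- names(config$response)
  Y <- matrix(NA_real_, n, length(metals), dimnames = list(NULL, metals))
  if (n == 0) return(Y)
  # standardize features by their analytic marginal moments
  tz <- features
  for (j in seq_len(4L)) {
    mom <- .beta_moments(config$specs[[FEATURE_VARS[j]]], config$concentration)
    tz[, j] <- tanh((features[, j] - mom[["mean"]]) / mom[["sd"]])
  }
  colnames(tz) <- FEATURE_VARS
  eps <- if (config$noise_rel_sd > 0) {
    withr::with_seed(derive_seed(seed, 2L), {
      matrix(stats::rnorm(n * length(metals)), n, length(metals))
    })
  } else {
    matrix(0, n, length(metals))
  }
  for (k in seq_along(metals)) {
    spec <- config$specs[[metals[k]]]
    sh <- .beta_shapes(spec, config$concentration)
    s <- .metal_score(tz, config$response[[metals[k]]])
    scale <- if (n > 1) stats::sd(s) else abs(s)
    if (!is.finite(scale) || scale == 0) scale <- 1
    s <- s + config$noise_rel_sd * scale * eps[, k]
    u <- rank(s, ties.method = "first") / (n + 1)
    Y[, k] <- spec$min + (spec$max - spec$min) *
      stats::qbeta(u, sh[["alpha"]], sh[["beta"]])
  }
  Y
}

#' Generate a complete synthetic water-sample dataset
#'
#' Composes [default_specs()], [sample_features()] and [generate_targets()]
#' for one sampling campaign and records provenance (seed and config digest).
#'
#' @param season `"dry"` or `"wet"`.
#' @param water_type `"surface"` or `"ground"`.
#' @param n Number of sites (default 80, the published campaign size).
#' @param seed Integer root seed.
#' @param ... Overrides passed to [generator_config()] (e.g. `noise_rel_sd`,
#'   `response`).
#' @return An object of class `water_dataset` with elements `features`
#'   (`n x 4`), `targets` (`n x m`), `specs`, `season`, `water_type`,
#'   `seed`, `config`.
#' @examples
#' ds <- make_dataset("dry", "surface", n = 20, seed = 7)
#' dim(ds$features); dim(ds$targets)
#' @export
make_dataset <- function(season, water_type, n = 80L, seed = 1L, ...) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  config <- generator_config(season, water_type, seed = seed, ...)
  features <- sample_features(config, n)
  targets <- generate_targets(features, config)
  structure(
    list(features = features, targets = targets, specs = config$specs,
         season = config$season, water_type = config$water_type,
         seed = as.integer(seed), config = config,
         digest = .config_digest(config)),
    class = "water_dataset"
  )
}

# Cheap structural digest of a generator config (no external digest dep).
.config_digest <- function(config) {
  key <- paste(
    config$season, config$water_type, config$noise_rel_sd, config$seed,
    config$concentration,
    paste(vapply(config$specs, function(s) sprintf("%s:%g:%g:%g", s$name, s$min, s$max, s$mean), ""),
          collapse = ";"),
    sep = "|"
  )
  sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1)) %% 1e9
}

#' @export
print.water_dataset <- function(x, ...) {
  cat(sprintf("<water_dataset> %s season, %s water: %d sites, %d features, %d metals (seed %d)\n",
              x$season, x$water_type, nrow(x$features), ncol(x$features),
              ncol(x$targets), x$seed))
  invisible(x)
}

#' Write a water dataset as CSV plus a JSON provenance sidecar
#'
#' @param dataset A `water_dataset`.
#' @param path Output CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_water_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "water_dataset"))
  df <- data.frame(
    site_id = seq_len(nrow(dataset$features)),
    season = dataset$season, water_type = dataset$water_type,
    stringsAsFactors = FALSE
  )
  for (v in colnames(dataset$features)) df[[CSV_COLUMNS[[v]]]] <- dataset$features[, v]
  for (v in colnames(dataset$targets)) df[[CSV_COLUMNS[[v]]]] <- dataset$targets[, v]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = dataset$seed, digest = dataset$digest,
         season = dataset$season, water_type = dataset$water_type,
         noise_rel_sd = dataset$config$noise_rel_sd),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a water dataset written by [write_water_csv()]
#'
#' @param path CSV path.
#' @return A `water_dataset` (provenance restored from the sidecar when
#'   present).
#' @export
read_water_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  season <- df$season[1]; water_type <- df$water_type[1]
  inv <- stats::setNames(names(CSV_COLUMNS), CSV_COLUMNS)
  feat_cols <- CSV_COLUMNS[FEATURE_VARS]
  metal_cols <- CSV_COLUMNS[METAL_VARS]
  metal_cols <- metal_cols[metal_cols %in% names(df)]
  features <- as.matrix(df[, feat_cols])
  colnames(features) <- FEATURE_VARS
  targets <- as.matrix(df[, metal_cols])
  colnames(targets) <- unname(inv[metal_cols])
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list(seed = NA_integer_)
  structure(
    list(features = features, targets = targets,
         specs = default_specs(season, water_type),
         season = season, water_type = water_type,
         seed = if (is.null(prov$seed)) NA_integer_ else as.integer(prov$seed),
         config = NULL, digest = prov$digest),
    class = "water_dataset"
  )
}
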