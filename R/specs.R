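#' @keywords internal
"_PACKAGE"

# Variable layout shared across the package. Feature columns are always in
# this order; metal columns likewise.
FEATURE_VARS <- c("temp", "ph", "ec", "tds")
METAL_VARS   <- c("cr", "cd", "fe", "mn", "zn", "ni", "pb", "cu")

VARIABLE_UNITS <- c(
  temp = "°C", ph = "pH units", ec = "µS/cm", tds = "mg/L",
  cr = "mg/L", cd = "mg/L", fe = "mg/L", mn = "mg/L",
  zn = "mg/L", ni = "mg/L", pb = "mg/L", cu = "mg/L"
)

# CSV column names used by write_water_csv()/read_water_csv().
CSV_COLUMNS <- c(
  temp = "temp_c", ph = "ph", ec = "ec_us_cm", tds = "tds_mg_l",
  cr = "cr_mg_l", cd = "cd_mg_l", fe = "fe_mg_l", mn = "mn_mg_l",
  zn = "zn_mg_l", ni = "ni_mg_l", pb = "pb_mg_l", cu = "cu_mg_l"
)

# Published descriptive statistics (min, max, mean; n = 80 per variable) for
# the four season x water-type campaigns on an acid-mine-drainage-impacted
# island aquifer/river system. Rows: temp, ph, ec, tds, then the eight
# metals. All metals in mg/L.
.SPEC_TABLES <- list(
  dry_surface = matrix(c(
    26.0,     36.4,     30.58,
    2.9,      9.4,      6.28,
    130.0,    6000.0,   2617.21,
    60.0,     3000.0,   1377.66,
    0.00029,  0.03766,  0.01820,
    0.00706,  0.06122,  0.04315,
    0.45237,  2.76195,  2.32390,
    0.00049,  11.09783, 2.07269,
    0.00047,  9.58050,  1.69057,
    0.00413,  0.12689,  0.10156,
    0.00339,  0.05608,  0.03851,
    0.02763,  17.16567, 7.67426
  ), ncol = 3, byrow = TRUE),
  wet_surface = matrix(c(
    26.7,     33.7,     30.26,
    3.1,      8.4,      5.94,
    90.0,     5380.0,   2211.00,
    40.0,     2670.0,   1142.35,
    0.00023,  0.03766,  0.02937,
    0.00040,  0.06122,  0.04459,
    0.06915,  53.01624, 21.74808,
    0.00361,  0.01769,  0.01027,
    0.02480,  0.07430,  0.03922,
    0.00415,  0.12689,  0.08820,
    0.00680,  0.05607,  0.03458,
    0.00690,  0.20730,  0.09144
  ), ncol = 3, byrow = TRUE),
  dry_ground = matrix(c(
    26.3,     49.6,     37.72,
    6.1,      7.9,      7.01,
    80.0,     2350.0,   1140.45,
    30.0,     1150.0,   499.12,
    0.01733,  0.17182,  0.07527,
    0.00055,  0.10389,  0.06879,
    0.00038,  54.68567, 11.50116,
    0.00009,  8.71857,  2.44137,
    0.00098,  56.96133, 13.95211,
    0.00013,  0.12530,  0.08955,
    0.01560,  0.12178,  0.10676,
    0.03711,  0.26050,  0.21542
  ), ncol = 3, byrow = TRUE),
  wet_ground = matrix(c(
    26.2,     36.7,     30.25,
    5.6,      7.9,      6.85,
    20.0,     2840.0,   1185.05,
    10.0,     1400.0,   601.20,
    0.01638,  0.17179,  0.14767,
    0.00055,  0.10389,  0.04458,
    0.16390,  13.58610, 9.82432,
    0.00405,  0.14579,  0.04089,
    0.02480,  0.51992,  0.26563,
    0.00101,  0.12490,  0.10005,
    0.05496,  0.12178,  0.11831,
    0.00690,  0.02759,  0.02257
  ), ncol = 3, byrow = TRUE)
)

#' Construct a variable specification
#'
#' A variable spec records the support and mean of one water-quality variable
#' on its natural scale, as tabulated for one sampling campaign
#' (season x water type, n = 80 sites each).
#'
#' @param name Variable identifier (e.g. `"ph"`, `"cu"`).
#' @param role Either `"feature"` (in-situ physicochemical parameter) or
#'   `"target"` (heavy-metal concentration).
#' @param min,max,mean Minimum, maximum and mean on the natural scale.
#' @param units Measurement units.
#' @param n_reference Number of sites behind the published summary.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, role, min, max, mean,
                          units = VARIABLE_UNITS[[name]], n_reference = 80L) {
  stopifnot(is.character(name), length(name) == 1L)
  role <- match.arg(role, c("feature", "target"))
  if (!(is.finite(min) && is.finite(max) && is.finite(mean))) {
    stop("min, max and mean must be finite numbers", call. = FALSE)
  }
  if (!(min < max)) stop("variable_spec: min must be < max", call. = FALSE)
  if (mean < min || mean > max) {
    stop("variable_spec: mean must lie in [min, max]", call. = FALSE)
  }
  if (n_reference <= 0) stop("n_reference must be positive", call. = FALSE)
  structure(
    list(name = name, units = units, role = role,
         min = min, max = max, mean = mean,
         n_reference = as.integer(n_reference)),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s, %s): min %g, max %g, mean %g (n = %d)\n",
              x$name, x$units, x$role, x$min, x$max, x$mean, x$n_reference))
  invisible(x)
}

.dataset_key <- function(season, water_type) {
  season <- match.arg(season, c("dry", "wet"))
  water_type <- match.arg(water_type, c("surface", "ground"))
  paste(season, water_type, sep = "_")
}

#' Default variable specs for one sampling campaign
#'
#' Returns the twelve variable specs (four physicochemical features and eight
#' total-metal concentrations) transcribed from the published descriptive
#' statistics of the matching campaign.
#'
#' @param season `"dry"` or `"wet"`.
#' @param water_type `"surface"` or `"ground"`.
#' @return Named list of [variable_spec()] objects in canonical column order.
#' @examples
#' default_specs("dry", "surface")$ph
#' @export
default_specs <- function(season, water_type) {
  key <- .dataset_key(season, water_type)
  tab <- .SPEC_TABLES[[key]]
  vars <- c(FEATURE_VARS, METAL_VARS)
  specs <- lapply(seq_along(vars), function(i) {
    variable_spec(
      name = vars[i],
      role = if (vars[i] %in% FEATURE_VARS) "feature" else "target",
      min = tab[i, 1], max = tab[i, 2], mean = tab[i, 3]
    )
  })
  names(specs) <- vars
  specs
}
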