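#' Land-use class codes used throughout the package
#'
#' Integer codes for the six land-use classes of the assessment system.
#' All raster-facing functions interpret cell values through this coding
#' unless told otherwise.
#'
#' @return Named integer vector: construction = 1, arable = 2, grassland = 3,
#'   forest = 4, water = 5, unused = 6.
#' @export
#' @examples
#' landuse_classes()
landuse_classes <- function() {
  c(construction = 1L, arable = 2L, grassland = 3L,
    forest = 4L, water = 5L, unused = 6L)
}

#' Define a synthetic study scenario
#'
#' A scenario bundles every knob of the synthetic data generator: the zone
#' lattice (counties), per-zone raster dimensions, epochs, land-cover class
#' proportions, the spatial autocorrelation and temporal persistence of the
#' simulated land cover, the driver fields, and the true local regression
#' coefficient surfaces used to generate a response with known ground truth.
#'
#' The defaults emulate a province-scale karst panel: 88 zones on an 8 x 11
#' lattice, five epochs (2000-2020 in 5-year steps), 100 x 100 cells per zone,
#' a forest-dominated class mix, and smoothly varying coefficient surfaces
#' bounded away from zero so that the sign of each driver's effect is
#' well defined everywhere.
#'
#' @param n_zones Number of zones; must factor into a near-square lattice.
#' @param grid_shape Integer vector (rows, cols) of cells per zone raster.
#' @param years Strictly increasing integer epoch labels.
#' @param class_codes Named integer vector of raster class codes.
#' @param class_props Target class proportions (named like `class_codes`,
#'   summing to 1), or a function `(u, v, t)` of the normalized zone centroid
#'   and years since the first epoch returning such a vector, allowing
#'   spatially and temporally structured landscape composition. The default,
#'   [default_class_props()], drifts construction land up and arable land
#'   down over time (urbanization plus cropland retirement) with forest
#'   share increasing northward.
#' @param autocorr_range Correlation length (in cells) of the latent Gaussian
#'   field thresholded into land cover.
#' @param persistence Fraction in [0, 1] of the latent field carried over
#'   between consecutive epochs (1 = static landscape).
#' @param drivers Named list of functions `(u, v, t)` giving the smooth mean
#'   surface of each driver covariate; `u`, `v` are normalized centroid
#'   coordinates in [0, 1] and `t` is years since the first epoch.
#' @param driver_autocorr_range Correlation length (in zone-lattice units) of
#'   the stochastic component added to each driver surface.
#' @param driver_noise_sd Standard deviation of that stochastic component.
#' @param coef_surfaces Named list of functions `(u, v, t)`: one entry
#'   `intercept` plus one per driver, giving the true local coefficients of
#'   the data-generating regression.
#' @param noise_sd Standard deviation of the Gaussian response noise.
#' @param cellsize Side length of a raster cell in map units.
#' @param seed Integer RNG seed; every generator is a pure function of the
#'   scenario including this seed.
#'
#' @return An object of class `"ehi_scenario"` (a validated list).
#' @export
#' @examples
#' sc <- synthetic_scenario(n_zones = 9, grid_shape = c(20, 20), seed = 1)
#' sc$lattice
synthetic_scenario <- function(n_zones = 88L,
                               grid_shape = c(100L, 100L),
                               years = c(2000L, 2005L, 2010L, 2015L, 2020L),
                               class_codes = landuse_classes(),
                               class_props = default_class_props(),
                               autocorr_range = 6,
                               persistence = 0.85,
                               drivers = default_driver_fields(),
                               driver_autocorr_range = 1,
                               driver_noise_sd = 1,
                               coef_surfaces = default_coef_surfaces(),
                               noise_sd = 0.3,
                               cellsize = 1,
                               seed = 1L) {
  n_zones <- as.integer(n_zones)
  if (n_zones < 9L) stop("n_zones must be at least 9")
  lat <- zone_lattice_dims(n_zones)
  if (length(grid_shape) != 2L || any(grid_shape < 2L))
    stop("grid_shape must be two integers >= 2")
  if (length(years) < 1L || is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (persistence < 0 || persistence > 1)
    stop("persistence must lie in [0, 1]")
  if (!is.function(class_props)) {
    check_props(class_props, names(class_codes))
  }
  if (!is.null(coef_surfaces)) {
    need <- c("intercept", names(drivers))
    if (!setequal(names(coef_surfaces), need))
      stop("coef_surfaces names must be 'intercept' plus the driver names; ",
           "missing: ", paste(setdiff(need, names(coef_surfaces)), collapse = ", "),
           "; extra: ", paste(setdiff(names(coef_surfaces), need), collapse = ", "))
  }
  structure(list(
    n_zones = n_zones, lattice = lat, grid_shape = as.integer(grid_shape),
    years = as.integer(years), class_codes = class_codes,
    class_props = class_props, autocorr_range = autocorr_range,
    persistence = persistence, drivers = drivers,
    driver_autocorr_range = driver_autocorr_range,
    driver_noise_sd = driver_noise_sd,
    coef_surfaces = coef_surfaces, noise_sd = noise_sd,
    cellsize = cellsize, seed = as.integer(seed)
  ), class = "ehi_scenario")
}

check_props <- function(p, class_names) {
  if (is.null(names(p)) || !setequal(names(p), class_names))
    stop("class proportions must be named after the land-use classes")
  if (any(p < 0)) stop("class proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8)
    stop("class proportions must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

# Factor n into the lattice (r, c) with r <= c and r as large as possible,
# i.e. the most nearly square factorization.
zone_lattice_dims <- function(n) {
  r <- floor(sqrt(n))
  while (r >= 1 && n %% r != 0L) r <- r - 1L
  if (r < 2L)
    stop("n_zones = ", n, " cannot be laid out on a rectangular lattice ",
         "with both dimensions >= 2; choose a composite zone count")
  c(rows = as.integer(r), cols = as.integer(n / r))
}

#' @export
print.ehi_scenario <- function(x, ...) {
  cat("Synthetic EHI scenario\n")
  cat(sprintf("  zones     : %d (%d x %d lattice), %d x %d cells each\n",
              x$n_zones, x$lattice[1], x$lattice[2],
              x$grid_shape[1], x$grid_shape[2]))
  cat(sprintf("  epochs    : %s\n", paste(x$years, collapse = ", ")))
  cat(sprintf("  landcover : range %.1f cells, persistence %.2f\n",
              x$autocorr_range, x$persistence))
  cat(sprintf("  drivers   : %s\n", paste(names(x$drivers), collapse = ", ")))
  cat(sprintf("  noise_sd  : %.3g   seed: %d\n", x$noise_sd, x$seed))
  invisible(x)
}

#' Default land-cover composition surface
#'
#' Target class proportions as a smooth function of the normalized zone
#' centroid `(u, v)` and years since the first epoch `t`: forest share
#' increases with `v` and over time, construction land grows with `u` and
#' over time, arable land declines — the composition drift typical of karst
#' provinces under reforestation programs and urbanization.
#'
#' @return A function `(u, v, t)` returning a named proportion vector
#'   summing to 1.
#' @export
default_class_props <- function() {
  function(u, v, t) {
    ts <- t / 20
    w <- c(construction = 0.04 + 0.05 * u + 0.03 * ts,
           arable       = 0.28 - 0.08 * v - 0.02 * ts,
           grassland    = 0.20 - 0.03 * u,
           forest       = 0.30 + 0.12 * v + 0.03 * ts,
           water        = 0.05,
           unused       = 0.07 - 0.03 * v)
    w / sum(w)
  }
}

#' Default driver mean surfaces for the synthetic panel
#'
#' Smooth deterministic surfaces of (u, v, t) for the nine candidate drivers
#' of the assessment (population, NDVI, slope, precipitation, temperature,
#' relative humidity, vegetation cover fraction, GDP, nighttime lights).
#' Units are arbitrary standardized scales; spatial gradients differ across
#' drivers so the design is well conditioned.
#'
#' @return Named list of functions `(u, v, t)`.
#' @export
default_driver_fields <- function() {
  list(
    pop   = function(u, v, t) 1.2 * u - 0.6 * v + 0.010 * t,
    ndvi  = function(u, v, t) 0.8 * v + 0.4 * sin(pi * u) + 0.012 * t,
    slope = function(u, v, t) 1.5 * (1 - u) * (1 - v) + 0 * t,
    pre   = function(u, v, t) 0.9 * v + 0.3 * u + 0.015 * t,
    tem   = function(u, v, t) 1.1 * u - 0.4 * v + 0.020 * t,
    rhu   = function(u, v, t) 0.7 * cos(pi * u / 2) + 0.5 * v + 0 * t,
    fvc   = function(u, v, t) 0.6 * v - 0.5 * u + 0.015 * t,
    gdp   = function(u, v, t) 1.4 * u * v + 0.030 * t,
    nli   = function(u, v, t) 1.0 * u + 0.8 * u * v + 0.025 * t
  )
}

#' Default true coefficient surfaces of the synthetic regression
#'
#' True local coefficients beta_l(u, v, t) used by [generate_driver_panel()]
#' to build the response. Signs mirror the direction of each driver's effect
#' on ecosystem health found in karst assessments (precipitation, humidity
#' and nighttime lights positive; temperature, vegetation-cover fraction and
#' slope negative), and every surface is bounded away from zero so sign
#' recovery is well posed.
#'
#' @return Named list of functions `(u, v, t)` including `intercept`.
#' @export
default_coef_surfaces <- function() {
  ts <- function(t) t / 20   # epochs span 20 years
  list(
    intercept = function(u, v, t) 0.5 + 0.2 * ts(t),
    pop   = function(u, v, t) -(0.4 + 0.8 * u),
    ndvi  = function(u, v, t)  (0.5 + 0.8 * v),
    slope = function(u, v, t) -(0.3 + 0.6 * (1 - v)),
    pre   = function(u, v, t)  (0.8 + 1.6 * u),
    tem   = function(u, v, t) -(0.6 + 1.2 * v),
    rhu   = function(u, v, t)  (0.5 + 0.8 * ts(t)),
    fvc   = function(u, v, t) -(0.5 + 1.2 * u),
    gdp   = function(u, v, t) -(0.3 + 0.6 * u * v),
    nli   = function(u, v, t)  (0.4 + 1.0 * v)
  )
}

# Evaluate code under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
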