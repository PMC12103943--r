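# Smoothed standard-Gaussian random field on an nr x nc grid. A white-noise
# matrix is convolved with a separable Gaussian kernel of standard deviation
# `range` cells (row-normalized, so edges are handled without padding bias),
# then restandardized to zero mean / unit variance.
gaussian_field <- function(nr, nc, range) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range > 0) {
    smoother <- function(n) {
      d <- outer(seq_len(n), seq_len(n), "-")
      k <- exp(-d^2 / (2 * range^2))
      k / rowSums(k)
    }
    z <- smoother(nr) %*% z %*% t(smoother(nc))
  }
  s <- stats::sd(z)
  if (s > 0) (z - mean(z)) / s else z
}

# Threshold a continuous field into class codes at quantiles matching the
# target proportions (classes ordered as in class_codes; zero-proportion
# classes receive no cells).
threshold_field <- function(field, props, class_codes) {
  cum <- cumsum(props) / sum(props)
  breaks <- stats::quantile(field, cum[-length(cum)], names = FALSE, type = 7)
  idx <- findInterval(field, breaks, left.open = TRUE) + 1L
  matrix(class_codes[idx], nrow(field), ncol(field))
}

#' Generate the synthetic land-use raster panel
#'
#' For every zone, a latent Gaussian random field with correlation length
#' `autocorr_range` is thresholded at quantiles matching the target class
#' proportions, producing a categorical mosaic with realistic spatial
#' clumping. For epoch t+1 the latent field is a blend
#' `persistence * field_t + (1 - persistence) * fresh field`, so land cover
#' evolves gradually; `persistence = 1` yields a static landscape.
#' The generator is a pure function of the scenario (including its seed).
#'
#' @param scenario An [synthetic_scenario()] object.
#' @param zone_map Optional precomputed [generate_zone_map()] result.
#' @return Named list with one element per zone-year (names
#'   `"<zone_id>:<year>"`), each an [lu_raster()] positioned at the zone's
#'   rectangle.
#' @export
#' @examples
#' sc <- synthetic_scenario(n_zones = 9, grid_shape = c(15, 15), seed = 7)
#' panel <- generate_landuse_panel(sc)
#' length(panel)  # 9 zones x 5 years
generate_landuse_panel <- function(scenario, zone_map = generate_zone_map(scenario)) {
  stopifnot(inherits(scenario, "ehi_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  with_seed(scenario$seed, {
    out <- vector("list", scenario$n_zones * length(scenario$years))
    nm <- character(length(out))
    k <- 0L
    tvals <- scenario$years - scenario$years[1]
    for (z in seq_len(scenario$n_zones)) {
      field <- gaussian_field(nr, nc, scenario$autocorr_range)
      for (y in seq_along(scenario$years)) {
        props <- if (is.function(scenario$class_props)) {
          p <- scenario$class_props(zone_map$u01[z], zone_map$v01[z], tvals[y])
          check_props(p, names(scenario$class_codes))
        } else scenario$class_props
        props <- props[names(scenario$class_codes)]
        if (y > 1L && scenario$persistence < 1) {
          fresh <- gaussian_field(nr, nc, scenario$autocorr_range)
          field <- scenario$persistence * field +
            (1 - scenario$persistence) * fresh
          field <- (field - mean(field)) / stats::sd(field)
        }
        k <- k + 1L
        out[[k]] <- lu_raster(
          threshold_field(field, props, scenario$class_codes),
          cellsize = scenario$cellsize,
          origin = c(zone_map$xmin[z], zone_map$ymin[z]))
        nm[k] <- paste0(zone_map$zone_id[z], ":", scenario$years[y])
      }
    }
    names(out) <- nm
    out
  })
}

#' Generate the synthetic driver panel with sealed ground truth
#'
#' Drivers are drawn as smooth zone-level fields: the deterministic mean
#' surface from `scenario$drivers` evaluated at each normalized zone centroid
#' and epoch, plus a spatially autocorrelated Gaussian field on the zone
#' lattice (correlation length `driver_autocorr_range` lattice units,
#' standard deviation `driver_noise_sd`), redrawn each epoch. The response is
#' generated from the true local coefficient surfaces,
#' `y = beta_0(u,v,t) + sum_l beta_l(u,v,t) x_l + eps`,
#' `eps ~ N(0, noise_sd^2)`.
#'
#' The observable panel and the true coefficients are returned as separate
#' elements: the panel holds nothing derivable only from the truth record,
#' so recovery tests cannot leak.
#'
#' @param scenario An [synthetic_scenario()] object with `coef_surfaces`.
#' @param zone_map Optional precomputed [generate_zone_map()] result.
#' @return List with `panel` (data frame: `zone_id`, `year`, `t`, `u`, `v`,
#'   one column per driver, `response`) and `truth` (matrix of true local
#'   coefficients, one row per observation, columns `intercept` + drivers).
#' @export
generate_driver_panel <- function(scenario, zone_map = generate_zone_map(scenario)) {
  stopifnot(inherits(scenario, "ehi_scenario"))
  if (is.null(scenario$coef_surfaces))
    stop("scenario has no coef_surfaces; a response cannot be generated")
  drv <- scenario$drivers
  lat <- scenario$lattice
  years <- scenario$years
  tvals <- years - years[1]
  nz <- scenario$n_zones
  n <- nz * length(years)

  with_seed(scenario$seed + 1L, {
    panel <- data.frame(
      zone_id = rep(zone_map$zone_id, times = length(years)),
      year = rep(years, each = nz),
      t = rep(tvals, each = nz),
      u = rep(zone_map$u01, times = length(years)),
      v = rep(zone_map$v01, times = length(years))
    )
    X <- matrix(NA_real_, n, length(drv),
                dimnames = list(NULL, names(drv)))
    for (l in seq_along(drv)) {
      mu <- drv[[l]](panel$u, panel$v, panel$t)
      noise <- numeric(0)
      for (y in seq_along(years)) {
        f <- gaussian_field(lat[1], lat[2], scenario$driver_autocorr_range)
        # zone order is row-major over the lattice (zrow, then zcol)
        noise <- c(noise, as.vector(t(f)) * scenario$driver_noise_sd)
      }
      X[, l] <- mu + noise
    }
    beta <- matrix(NA_real_, n, length(drv) + 1L,
                   dimnames = list(NULL, c("intercept", names(drv))))
    beta[, "intercept"] <-
      scenario$coef_surfaces$intercept(panel$u, panel$v, panel$t)
    for (l in names(drv))
      beta[, l] <- scenario$coef_surfaces[[l]](panel$u, panel$v, panel$t)
    eps <- stats::rnorm(n, 0, scenario$noise_sd)
    panel$response <- beta[, "intercept"] +
      rowSums(beta[, names(drv), drop = FALSE] * X) + eps
    panel <- cbind(panel[c("zone_id", "year", "t", "u", "v")],
                   as.data.frame(X), response = panel$response)
    list(panel = panel, truth = beta)
  })
}
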