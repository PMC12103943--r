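#' Variance-inflation-factor screening of a driver panel
#'
#' Iteratively removes the driver with the highest VIF while any exceeds the
#' threshold. `VIF_l = 1 / (1 - R2_l)` where `R2_l` comes from regressing
#' driver l on the remaining drivers; a perfectly collinear driver has
#' infinite VIF and is removed first.
#'
#' @param panel Data frame holding the driver columns.
#' @param drivers Character vector of candidate driver column names.
#' @param threshold VIF above which a driver is discarded (default 7.5).
#' @return List of class `"vif_screen"`: `retained`, `removed` (in removal
#'   order), `vif` (final VIFs of retained drivers), `steps` (list of VIF
#'   vectors at each iteration).
#' @export
vif_screen <- function(panel, drivers, threshold = 7.5) {
  if (length(drivers) < 2L) stop("VIF screening needs at least 2 drivers")
  X <- as.matrix(panel[drivers])
  if (nrow(X) <= length(drivers) + 1L)
    stop("too few observations for VIF screening")
  vif_of <- function(cols) {
    vapply(cols, function(l) {
      if (stats::sd(X[, l]) == 0) return(Inf)  # constant column: degenerate
      others <- setdiff(cols, l)
      r2 <- suppressWarnings(
        summary(stats::lm(X[, l] ~ X[, others, drop = FALSE]))$r.squared)
      if (!is.finite(r2) || r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- drivers
  removed <- character(0)
  steps <- list()
  repeat {
    v <- vif_of(keep)
    steps[[length(steps) + 1L]] <- v
    if (max(v) <= threshold || length(keep) <= 2L) break
    worst <- keep[which.max(v)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  structure(list(retained = keep, removed = removed, vif = vif_of(keep),
                 threshold = threshold, steps = steps),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("VIF screening (threshold", x$threshold, ")\n")
  cat("  removed :", if (length(x$removed)) paste(x$removed, collapse = ", ")
      else "none", "\n")
  cat("  retained:\n")
  print(round(x$vif, 2))
  invisible(x)
}

#' Spatiotemporal kernel weights
#'
#' Gaussian kernel over the combined space-time distance:
#' `w = exp(-d2 / h^2)` with `d2 = (du^2 + dv^2) + tau * dt^2`. The
#' space-time ratio `tau` converts squared time units into squared map units;
#' `tau = 0` ignores time (pure GWR weighting), and `h -> Inf` gives every
#' observation weight 1 (global regression). The target observation always
#' has weight 1.
#'
#' @param u0,v0,t0 Target coordinates and time.
#' @param u,v,t Coordinates and times of all observations.
#' @param h Spatial bandwidth (> 0), in map units.
#' @param tau Space-time ratio (>= 0).
#' @return Numeric weight vector in (0, 1].
#' @export
st_weights <- function(u0, v0, t0, u, v, t, h, tau = 0) {
  if (!is.finite(u0) || !is.finite(v0) || !is.finite(t0) ||
      any(!is.finite(u)) || any(!is.finite(v)) || any(!is.finite(t)))
    stop("non-finite coordinates in spatiotemporal weighting")
  if (h <= 0) stop("bandwidth h must be positive")
  if (tau < 0) stop("tau must be nonnegative")
  d2 <- (u - u0)^2 + (v - v0)^2 + tau * (t - t0)^2
  exp(-d2 / h^2)
}

#' Fit a geographically and temporally weighted regression
#'
#' At each observation i, a weighted least-squares fit
#' `Y = X beta(u_i, v_i, t_i) + delta` is solved with [st_weights()] kernel
#' weights centered on i, yielding local coefficient surfaces. Reports
#' fitted values, residuals, the hat-matrix diagonal, the corrected Akaike
#' criterion (AICc) and R-squared.
#'
#' @param panel Data frame with coordinate, time, response and driver columns.
#' @param response Name of the response column.
#' @param drivers Character vector of driver column names.
#' @param h Spatial bandwidth.
#' @param tau Space-time ratio (default 0 = spatial weighting only).
#' @param coords,time Names of the coordinate and time columns.
#' @return List of class `"gtwr_fit"`: `coefficients` (matrix n x (k+1),
#'   column `intercept` first), `fitted`, `residuals`, `hat`, `trace_s`,
#'   `rss`, `aicc`, `r_squared`, `h`, `tau`, plus the inputs needed to
#'   reproduce the fit.
#' @export
fit_gtwr <- function(panel, response = "response", drivers,
                     h, tau = 0, coords = c("u", "v"), time = "t") {
  X <- cbind(intercept = 1, as.matrix(panel[drivers]))
  y <- panel[[response]]
  u <- panel[[coords[1]]]; v <- panel[[coords[2]]]; tt <- panel[[time]]
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("more parameters than observations")
  beta <- matrix(NA_real_, n, k, dimnames = list(NULL, colnames(X)))
  fitted <- hat_d <- numeric(n)
  for (i in seq_len(n)) {
    w <- st_weights(u[i], v[i], tt[i], u, v, tt, h = h, tau = tau)
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    R <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps) * max(diag(R)))
      stop("weighted design is rank deficient at observation ", i,
           " (h = ", format(h), "); increase the bandwidth")
    chol_solve <- function(b) backsolve(R, forwardsolve(t(R), b))
    beta[i, ] <- chol_solve(crossprod(Xw, y))
    fitted[i] <- sum(X[i, ] * beta[i, ])
    # own weight is 1, so the hat diagonal is x_i' (X'WX)^-1 x_i
    hat_d[i] <- sum(X[i, ] * chol_solve(X[i, ]))
  }
  res <- y - fitted
  rss <- sum(res^2)
  trS <- sum(hat_d)
  sigma2 <- rss / n
  aicc <- n * log(sigma2) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  structure(list(coefficients = beta, fitted = fitted, residuals = res,
                 hat = hat_d, trace_s = trS, rss = rss, aicc = aicc,
                 r_squared = r2, h = h, tau = tau, drivers = drivers,
                 response = response, coords = coords, time = time,
                 n = n),
            class = "gtwr_fit")
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf("GTWR fit: n = %d, h = %.4g, tau = %.4g\n", x$n, x$h, x$tau))
  cat(sprintf("  AICc = %.2f, R2 = %.4f, trace(S) = %.2f\n",
              x$aicc, x$r_squared, x$trace_s))
  cat("  median local coefficients:\n")
  print(round(apply(x$coefficients, 2, stats::median), 4))
  invisible(x)
}

#' Select the GTWR bandwidth and space-time ratio
#'
#' For each candidate `tau`, the AICc profile over `h` is bracketed on a
#' log-spaced grid and refined by golden-section search; the (`h`, `tau`)
#' pair minimizing AICc (or the leave-one-out CV score) is returned. The
#' search is deterministic. When the grid profile is not unimodal the best
#' grid point still brackets the refinement; if the optimum sits on the grid
#' boundary a warning is issued and the boundary point returned.
#'
#' @inheritParams fit_gtwr
#' @param tau_grid Candidate space-time ratios. The default scales
#'   `(spatial diameter / time range)^2` by {0, 1/4, 1, 4}, covering "time
#'   ignored" through "time dominating".
#' @param h_range Bandwidth search interval; defaults to 5%-200% of the
#'   spatial diameter.
#' @param criterion `"aicc"` (default) or `"cv"` (leave-one-out squared
#'   error).
#' @param n_grid Coarse grid size per tau.
#' @param tol Relative golden-section tolerance on h.
#' @return List of class `"gtwr_bandwidth"`: `h`, `tau`, `score`,
#'   `criterion`, `profile` (data frame of grid evaluations).
#' @export
select_bandwidth <- function(panel, response = "response", drivers,
                             coords = c("u", "v"), time = "t",
                             tau_grid = NULL, h_range = NULL,
                             criterion = c("aicc", "cv"),
                             n_grid = 8, tol = 0.02) {
  criterion <- match.arg(criterion)
  if (nrow(panel) < 10L) stop("bandwidth selection needs >= 10 observations")
  u <- panel[[coords[1]]]; v <- panel[[coords[2]]]; tt <- panel[[time]]
  diam <- sqrt(diff(range(u))^2 + diff(range(v))^2)
  if (diam <= 0) stop("zero spatial extent")
  if (is.null(h_range)) h_range <- c(0.05, 2) * diam
  if (is.null(tau_grid)) {
    tr <- diff(range(tt))
    base <- if (tr > 0) (diam / tr)^2 else 0
    tau_grid <- unique(base * c(0, 0.25, 1, 4))
  }
  score_of <- function(h, tau) {
    f <- tryCatch(fit_gtwr(panel, response, drivers, h = h, tau = tau,
                           coords = coords, time = time),
                  error = function(e) NULL)
    if (is.null(f)) return(Inf)
    if (criterion == "aicc") {
      if (f$trace_s >= f$n - 2) Inf else f$aicc
    } else {
      # leave-one-out CV from the hat diagonal
      if (any(abs(1 - f$hat) < 1e-10)) return(Inf)
      sum((f$residuals / (1 - f$hat))^2)
    }
  }
  best <- list(score = Inf, boundary = FALSE)
  profile <- NULL
  hs <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = n_grid))
  for (tau in tau_grid) {
    sc <- vapply(hs, score_of, numeric(1), tau = tau)
    profile <- rbind(profile, data.frame(tau = tau, h = hs, score = sc))
    j <- which.min(sc)
    lo <- hs[max(1L, j - 1L)]; hi <- hs[min(n_grid, j + 1L)]
    gr <- golden_section(function(h) score_of(h, tau), lo, hi, tol = tol)
    if (gr$score < best$score)
      best <- list(h = gr$x, tau = tau, score = gr$score,
                   boundary = FALSE)
    if (sc[j] < best$score)
      best <- list(h = hs[j], tau = tau, score = sc[j],
                   boundary = j == 1L || j == n_grid)
  }
  if (best$boundary)
    warning("criterion optimum sits at the h search boundary (h = ",
            format(best$h), "); the profile may not be unimodal or the ",
            "optimum lies outside h_range")
  if (!is.finite(best$score))
    stop("the ", criterion, " criterion was not finite for any candidate ",
         "(h, tau); the weighted design may be rank deficient everywhere")
  structure(c(best, list(criterion = criterion, profile = profile)),
            class = "gtwr_bandwidth")
}

golden_section <- function(f, lo, hi, tol = 0.02, max_iter = 40L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  iter <- 0L
  while ((b - a) > tol * a && iter < max_iter) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
                    x1 <- b - phi * (b - a); f1 <- f(x1) }
    else          { a <- x1; x1 <- x2; f1 <- f2
                    x2 <- a + phi * (b - a); f2 <- f(x2) }
    iter <- iter + 1L
  }
  if (f1 <= f2) list(x = x1, score = f1) else list(x = x2, score = f2)
}

#' @export
print.gtwr_bandwidth <- function(x, ...) {
  cat(sprintf("GTWR bandwidth: h = %.4g, tau = %.4g (%s = %.3f)\n",
              x$h, x$tau, toupper(x$criterion), x$score))
  invisible(x)
}

#' Classify local coefficients into quantile levels
#'
#' Bins each driver's local coefficients into `k` quantile classes (per year
#' when a `year` vector is supplied), reporting the coefficient sign
#' separately so positive/negative driving can be mapped independently of
#' the magnitude level.
#'
#' @param fit A `"gtwr_fit"` or a coefficient matrix.
#' @param k Number of quantile classes (default 4).
#' @param year Optional vector of years (one per observation) for per-year
#'   binning.
#' @return Data frame: `obs`, `year`, `driver`, `coefficient`, `sign`,
#'   `level` (ordered factor `L1 < ... < Lk`). Fewer than `k` distinct values
#'   collapse to fewer levels with a warning.
#' @export
classify_coefficients <- function(fit, k = 4, year = NULL) {
  if (k < 2) stop("k must be at least 2")
  B <- if (inherits(fit, "gtwr_fit")) {
    fit$coefficients[, fit$drivers, drop = FALSE]
  } else as.matrix(fit)
  n <- nrow(B)
  if (is.null(year)) year <- rep(NA_integer_, n)
  out <- NULL
  for (d in colnames(B)) {
    for (yr in unique(year)) {
      sel <- if (is.na(yr)) is.na(year) else !is.na(year) & year == yr
      x <- B[sel, d]
      qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1),
                                   names = FALSE))
      if (length(qs) < k + 1)
        warning("driver '", d, "': fewer distinct coefficient values than ",
                k, " classes; using ", max(1, length(qs) - 1), " bins")
      lev <- if (length(qs) > 1) {
        cut(x, breaks = qs, include.lowest = TRUE,
            labels = paste0("L", seq_len(length(qs) - 1)))
      } else factor(rep("L1", length(x)))
      out <- rbind(out, data.frame(
        obs = which(sel), year = yr, driver = d, coefficient = x,
        sign = ifelse(x >= 0, "positive", "negative"), level = lev))
    }
  }
  rownames(out) <- NULL
  out
}
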