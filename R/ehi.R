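#' Orientation of the eight PSR indicators
#'
#' Population pressure is the single negatively oriented indicator (more
#' people, more pressure, lower health); the seven state/response indicators
#' are positive.
#'
#' @return Named character vector, indicator -> "positive"/"negative".
#' @export
indicator_orientations <- function() {
  c(pop = "negative", ndvi = "positive", shdi = "positive",
    shei = "positive", cohesion = "positive", esv = "positive",
    contag = "positive", frac_mn = "positive")
}

#' Criterion-layer membership of the PSR indicators
#'
#' @return Named character vector, indicator -> "pressure"/"state"/"response".
#' @export
indicator_criteria <- function() {
  c(pop = "pressure", ndvi = "state", shdi = "state", shei = "state",
    cohesion = "state", esv = "response", contag = "response",
    frac_mn = "response")
}

#' Min-max normalize an indicator panel
#'
#' Positive indicators map to `(x - min) / (max - min)`, negative indicators
#' to `(max - x) / (max - min)`, so that 1 is always "healthier". Extrema
#' are pooled over all zone-year observations by default, which keeps scores
#' comparable across years (per-year pooling available). A constant column
#' normalizes to all zeros with a warning; its entropy weight downstream is
#' then zero.
#'
#' @param panel Data frame holding the indicator columns (any id columns are
#'   ignored).
#' @param indicators Character vector of indicator column names; defaults to
#'   the eight PSR indicators present in `panel`.
#' @param orientation Named vector of "positive"/"negative" per indicator.
#' @param pooling `"pooled"` (extrema over all observations, default) or
#'   `"by_year"` (extrema within each year; requires a `year` column).
#' @return Numeric matrix (observations x indicators) in [0, 1].
#' @export
normalize_indicators <- function(panel,
                                 indicators = intersect(names(indicator_orientations()),
                                                        names(panel)),
                                 orientation = indicator_orientations(),
                                 pooling = c("pooled", "by_year")) {
  pooling <- match.arg(pooling)
  if (length(indicators) == 0L) stop("no indicator columns found in panel")
  missing_or <- setdiff(indicators, names(orientation))
  if (length(missing_or))
    stop("no orientation given for: ", paste(missing_or, collapse = ", "))
  X <- as.matrix(panel[indicators])
  if (anyNA(X)) stop("indicator panel contains missing values")
  norm_block <- function(B) {
    out <- B
    for (j in seq_len(ncol(B))) {
      lo <- min(B[, j]); hi <- max(B[, j])
      if (hi - lo <= 0) {
        warning("indicator '", colnames(B)[j],
                "' is constant; normalized to 0 (weight will be 0)")
        out[, j] <- 0
      } else if (orientation[colnames(B)[j]] == "negative") {
        out[, j] <- (hi - B[, j]) / (hi - lo)
      } else {
        out[, j] <- (B[, j] - lo) / (hi - lo)
      }
    }
    out
  }
  if (pooling == "pooled") {
    Y <- norm_block(X)
  } else {
    if (is.null(panel$year)) stop("by_year pooling requires a 'year' column")
    Y <- X
    for (yr in unique(panel$year)) {
      sel <- panel$year == yr
      Y[sel, ] <- norm_block(X[sel, , drop = FALSE])
    }
  }
  rownames(Y) <- NULL
  Y
}

#' Entropy weights of a normalized indicator matrix
#'
#' Shannon-entropy weighting over the pooled observations: with
#' `f_ij = Y_ij / sum_j Y_ij`, entropy `E_i = -k * sum_j f_ij log f_ij`
#' (`k = 1/log(n)`, `0 log 0 = 0`), difference coefficient `d_i = 1 - E_i`,
#' and weights `w_i = d_i / sum(d_i)`. Indicators with greater dispersion
#' across observations (lower entropy) receive larger weights. An all-zero
#' column gets `d = 0`, hence weight 0.
#'
#' @param Y Nonnegative matrix, observations in rows, indicators in columns
#'   (typically from [normalize_indicators()]).
#' @return List of class `"entropy_weights"`: `weights`, `entropy`, `d`,
#'   `k`, `n`.
#' @export
#' @examples
#' Y <- cbind(a = c(1, 0, 1), b = c(0, 1, 1))
#' entropy_weights(Y)$weights   # symmetric: 0.5, 0.5
entropy_weights <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("normalized matrix must be nonnegative")
  n <- nrow(Y)
  if (n < 2L) stop("entropy weights need at least 2 observations (k = 1/log(n))")
  k <- 1 / log(n)
  csum <- colSums(Y)
  E <- vapply(seq_len(ncol(Y)), function(j) {
    if (csum[j] <= 0) return(1)        # empty column: no information
    f <- Y[, j] / csum[j]
    f <- f[f > 0]
    -k * sum(f * log(f))
  }, numeric(1))
  d <- 1 - E
  d[csum <= 0] <- 0
  if (sum(d) <= 0)
    stop("all indicators are uniform; entropy weights are undefined")
  w <- d / sum(d)
  names(w) <- names(E) <- names(d) <- colnames(Y)
  structure(list(weights = w, entropy = E, d = d, k = k, n = n),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat(sprintf("Entropy weights (n = %d, k = %.4f)\n", x$n, x$k))
  print(round(rbind(entropy = x$entropy, d = x$d, weight = x$weights), 4))
  invisible(x)
}

#' Criterion-layer weights from indicator weights
#'
#' Sums entropy weights over the pressure/state/response layers.
#'
#' @param weights Named weight vector (or an `"entropy_weights"` object).
#' @param criteria Named map indicator -> criterion layer.
#' @return Named numeric vector of layer weights.
#' @export
criterion_weights <- function(weights, criteria = indicator_criteria()) {
  if (inherits(weights, "entropy_weights")) weights <- weights$weights
  grp <- criteria[names(weights)]
  if (anyNA(grp))
    stop("no criterion layer for: ",
         paste(names(weights)[is.na(grp)], collapse = ", "))
  tapply(weights, factor(grp, levels = c("pressure", "state", "response")),
         sum)
}

#' Composite ecosystem health index
#'
#' `EHI_j = sum_i w_i * Y_ij`: the weighted sum of normalized indicators per
#' observation; lies in [0, 1] when `Y` does and weights sum to 1.
#'
#' @param Y Normalized matrix (observations x indicators).
#' @param weights Weight vector matching `Y`'s columns (or an
#'   `"entropy_weights"` object).
#' @return Numeric vector of EHI values, one per observation.
#' @export
compute_ehi <- function(Y, weights) {
  if (inherits(weights, "entropy_weights")) weights <- weights$weights
  Y <- as.matrix(Y)
  if (length(weights) != ncol(Y))
    stop("length(weights) != ncol(Y): ", length(weights), " vs ", ncol(Y))
  if (!is.null(names(weights)) && !is.null(colnames(Y))) {
    if (!setequal(names(weights), colnames(Y)))
      stop("weight names do not match indicator columns")
    weights <- weights[colnames(Y)]
  }
  as.numeric(Y %*% weights)
}

#' Classify EHI values into the four health grades
#'
#' Grade I (bad) on [0, 0.5), II (fair) on [0.5, 0.55), III (good) on
#' [0.55, 0.6), IV (excellent) on [0.6, 1]. Boundaries are half-open and
#' assigned upward so every value in [0, 1] receives exactly one grade.
#'
#' @param value Numeric EHI values in [0, 1].
#' @return Factor with levels I < II < III < IV.
#' @export
#' @examples
#' classify_ehi(c(0.45, 0.5, 0.57, 0.7))
classify_ehi <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE))
    stop("EHI values must lie in [0, 1]")
  cut(value, breaks = c(-Inf, 0.5, 0.55, 0.6, Inf), right = FALSE,
      labels = c("I", "II", "III", "IV"), ordered_result = TRUE)
}

#' Classify the EHI change over the study period
#'
#' Change levels for `delta = EHI_last - EHI_first`: I on [0.06, 0.08), II on
#' [0.08, 0.10), III on [0.10, 0.13]. Values outside [0.06, 0.13] are
#' labelled `"out-of-range"` rather than forced into a band.
#'
#' @param delta Numeric EHI differences.
#' @return Factor with levels I, II, III, out-of-range.
#' @export
#' @examples
#' classify_delta(c(0.09, 0.05, 0.12))
classify_delta <- function(delta) {
  lab <- ifelse(is.na(delta), NA_character_,
         ifelse(delta < 0.06, "out-of-range",
         ifelse(delta < 0.08, "I",
         ifelse(delta < 0.10, "II",
         ifelse(delta <= 0.13, "III", "out-of-range")))))
  factor(lab, levels = c("I", "II", "III", "out-of-range"))
}

#' Score an indicator panel end to end
#'
#' Normalizes, weights, scores and grades a zone-year indicator panel, and
#' classifies the per-zone EHI change between the first and last year.
#'
#' @param panel Data frame with `zone_id`, `year` and the indicator columns.
#' @param indicators,orientation,pooling Passed to [normalize_indicators()].
#' @return List of class `"ehi_result"`: `normalized` matrix, `weights`
#'   (`"entropy_weights"`), `criterion_weights`, `scores` (data frame
#'   `zone_id`, `year`, `ehi`, `grade`), `delta` (data frame `zone_id`,
#'   `delta_ehi`, `change_level`).
#' @export
ehi_assess <- function(panel,
                       indicators = intersect(names(indicator_orientations()),
                                              names(panel)),
                       orientation = indicator_orientations(),
                       pooling = "pooled") {
  stopifnot(all(c("zone_id", "year") %in% names(panel)))
  Y <- normalize_indicators(panel, indicators, orientation, pooling)
  w <- entropy_weights(Y)
  e <- compute_ehi(Y, w)
  scores <- data.frame(zone_id = panel$zone_id, year = panel$year,
                       ehi = e, grade = classify_ehi(e))
  yrs <- sort(unique(panel$year))
  first <- scores[scores$year == yrs[1], c("zone_id", "ehi")]
  last <- scores[scores$year == yrs[length(yrs)], c("zone_id", "ehi")]
  dd <- merge(first, last, by = "zone_id", suffixes = c("_first", "_last"))
  delta <- data.frame(zone_id = dd$zone_id,
                      delta_ehi = dd$ehi_last - dd$ehi_first)
  delta$change_level <- classify_delta(delta$delta_ehi)
  cw <- tryCatch(criterion_weights(w), error = function(e) NULL)
  structure(list(normalized = Y, weights = w, criterion_weights = cw,
                 scores = scores, delta = delta),
            class = "ehi_result")
}

#' @export
print.ehi_result <- function(x, ...) {
  cat("EHI assessment:", nrow(x$scores), "zone-year observations\n")
  print(round(x$weights$weights, 4))
  cat("EHI range:", paste(round(range(x$scores$ehi), 4), collapse = " - "), "\n")
  print(table(year = x$scores$year, grade = x$scores$grade))
  invisible(x)
}
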