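#' Contiguity-based spatial weights for a zone map
#'
#' Queen contiguity links zones whose rectangles share any boundary point
#' (edge or corner); rook requires a shared edge of positive length. The
#' binary matrix is symmetric with a zero diagonal and is row-standardized
#' for analysis; islands (zones with no neighbors) keep a zero row and are
#' reported with a warning.
#'
#' @param zone_map A [generate_zone_map()] result or any data frame with
#'   `zone_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @param type `"queen"` (default) or `"rook"`.
#' @param tol Geometric tolerance for boundary contact.
#' @return List of class `"spatial_weights"`: `B` binary adjacency, `W`
#'   row-standardized matrix, `n`, `islands`, `type`.
#' @export
#' @examples
#' zm <- generate_zone_map(synthetic_scenario(n_zones = 9, grid_shape = c(5, 5)))
#' w <- queen_weights(zm)
#' rowSums(w$B)   # corners 3, edges 5, center 8
queen_weights <- function(zone_map, type = c("queen", "rook"), tol = 1e-9) {
  type <- match.arg(type)
  n <- nrow(zone_map)
  if (n < 2L) stop("at least 2 zones are required")
  B <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      # closed-interval overlap lengths along each axis
      ox <- min(zone_map$xmax[i], zone_map$xmax[j]) -
            max(zone_map$xmin[i], zone_map$xmin[j])
      oy <- min(zone_map$ymax[i], zone_map$ymax[j]) -
            max(zone_map$ymin[i], zone_map$ymin[j])
      touch <- if (type == "queen") {
        ox >= -tol && oy >= -tol
      } else {
        (ox >= -tol && oy > tol) || (oy >= -tol && ox > tol)
      }
      if (touch) B[i, j] <- B[j, i] <- 1
    }
  }
  rs <- rowSums(B)
  islands <- zone_map$zone_id[rs == 0]
  if (length(islands))
    warning("island zone(s) with no neighbors: ",
            paste(islands, collapse = ", "))
  W <- B / ifelse(rs > 0, rs, 1)
  dimnames(B) <- dimnames(W) <- list(zone_map$zone_id, zone_map$zone_id)
  structure(list(B = B, W = W, n = n, islands = islands, type = type),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("%s contiguity weights: %d zones, %d links, %d island(s)\n",
              x$type, x$n, sum(x$B) / 2, length(x$islands)))
  invisible(x)
}

as_weight_matrix <- function(weights) {
  if (inherits(weights, "spatial_weights")) weights$W
  else as.matrix(weights)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij W_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Reports the expectation `-1/(n-1)`, the analytic z-score under the
#' randomization assumption, and a pseudo p-value from seeded value
#' permutations (directional: toward the observed side of the expectation).
#'
#' @param values Numeric vector, one value per zone; must be non-constant.
#' @param weights A `"spatial_weights"` object or weight matrix (typically
#'   row-standardized).
#' @param n_perm Number of permutations for the pseudo p-value (0 disables).
#' @param seed RNG seed for the permutations.
#' @return List of class `"moran_test"`: `I`, `expectation`, `variance`, `z`,
#'   `p_norm` (analytic, two-sided), `p_perm`, `n_perm`, `seed`.
#' @export
global_moran <- function(values, weights, n_perm = 999, seed = 1L) {
  W <- as_weight_matrix(weights)
  n <- length(values)
  if (nrow(W) != n) stop("length(values) does not match the weight matrix")
  if (stats::sd(values) == 0)
    stop("values are constant; Moran's I is undefined (zero variance)")
  z <- values - mean(values)
  S0 <- sum(W)
  I_of <- function(z) n * sum(W * tcrossprod(z)) / (S0 * sum(z^2))
  I <- I_of(z)

  EI <- -1 / (n - 1)
  # randomization (permutation) variance, standard closed form
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
         b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  p_norm <- 2 * stats::pnorm(-abs(zscore))

  p_perm <- NA_real_
  if (n_perm > 0) {
    Iperm <- with_seed(seed, vapply(seq_len(n_perm),
                                    function(k) I_of(sample(z)), numeric(1)))
    hits <- if (I >= EI) sum(Iperm >= I) else sum(Iperm <= I)
    p_perm <- (hits + 1) / (n_perm + 1)
  }
  structure(list(I = I, expectation = EI, variance = VI, z = zscore,
                 p_norm = p_norm, p_perm = p_perm, n_perm = n_perm,
                 seed = seed),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, z = %.4f)\n",
              x$I, x$expectation, x$z))
  cat(sprintf("  analytic p = %.4g; permutation p = %.4g (%d permutations)\n",
              x$p_norm, x$p_perm, x$n_perm))
  invisible(x)
}

#' Local Moran's I (LISA) with cluster typing
#'
#' `I_i = (z_i / m2) * sum_j W_ij z_j` with `z` the mean deviations and
#' `m2 = sum(z^2) / n`. Inference is by conditional permutation: holding
#' zone i's value fixed, the remaining values are permuted among its
#' neighbors. Zones significant at `alpha` are typed by the quadrant of
#' `(z_i, lag_i)`: H-H, L-L, H-L or L-H; the rest are "not significant".
#'
#' @inheritParams global_moran
#' @param alpha Significance level for cluster labeling.
#' @return Data frame of class `"lisa_result"`: `zone`, `local_i`, `z_value`,
#'   `lag`, `p_perm`, `cluster`.
#' @export
local_moran <- function(values, weights, n_perm = 999, seed = 1L,
                        alpha = 0.05) {
  W <- as_weight_matrix(weights)
  n <- length(values)
  if (nrow(W) != n) stop("length(values) does not match the weight matrix")
  if (stats::sd(values) == 0)
    stop("values are constant; local Moran's I is undefined")
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- as.numeric(W %*% z)
  Ii <- z / m2 * lag

  p <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      wi <- W[i, -i]
      nz <- which(wi != 0)
      if (length(nz) == 0L) next
      others <- z[-i]
      perm <- vapply(seq_len(n_perm), function(k) {
        sum(wi[nz] * sample(others, length(nz)))
      }, numeric(1))
      Iperm <- z[i] / m2 * perm
      hits <- if (Ii[i] >= 0) sum(Iperm >= Ii[i]) else sum(Iperm <= Ii[i])
      p[i] <- (hits + 1) / (n_perm + 1)
    }
  })
  quad <- ifelse(z >= 0 & lag >= 0, "H-H",
          ifelse(z < 0 & lag < 0, "L-L",
          ifelse(z >= 0 & lag < 0, "H-L", "L-H")))
  cluster <- ifelse(!is.na(p) & p < alpha, quad, "not significant")
  out <- data.frame(zone = if (!is.null(rownames(W))) rownames(W) else seq_len(n),
                    local_i = Ii, z_value = z, lag = lag, p_perm = p,
                    cluster = factor(cluster,
                                     levels = c("H-H", "L-L", "H-L", "L-H",
                                                "not significant")))
  class(out) <- c("lisa_result", "data.frame")
  out
}
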