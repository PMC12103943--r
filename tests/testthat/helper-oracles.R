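# Independent brute-force oracles used to validate the package implementations.
# These deliberately use naive cell-by-cell algorithms, not the vectorized /
# graph-based code paths of the package.

# Connected components by explicit queue-based flood fill.
flood_fill_patches <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(NA_integer_, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j]) || !is.na(lab[i, j])) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nbrs))) {
        a <- cell[1] + nbrs[q, 1]; b <- cell[2] + nbrs[q, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            is.na(lab[a, b]) && !is.na(m[a, b]) &&
            m[a, b] == m[cell[1], cell[2]]) {
          lab[a, b] <- cur
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# Patch table (class, area, perimeter) from the flood-fill labels, counting
# perimeter cell side by cell side.
oracle_patch_table <- function(m, connectivity = 8) {
  lab <- flood_fill_patches(m, connectivity)
  nr <- nrow(m); nc <- ncol(m)
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- data.frame(patch = ids, class_code = NA_integer_,
                    area = NA_integer_, perimeter = NA_integer_)
  for (k in seq_along(ids)) {
    cells <- which(lab == ids[k], arr.ind = TRUE)
    per <- 0L
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- i + d[1]; b <- j + d[2]
        if (a < 1 || a > nr || b < 1 || b > nc || is.na(m[a, b]) ||
            m[a, b] != m[i, j]) per <- per + 1L
      }
    }
    out$class_code[k] <- m[cells[1, 1], cells[1, 2]]
    out$area[k] <- nrow(cells)
    out$perimeter[k] <- per
  }
  out
}

oracle_cohesion <- function(m, connectivity = 8) {
  tab <- oracle_patch_table(m, connectivity)
  n_cells <- sum(!is.na(m))
  100 * (1 - sum(tab$perimeter) / sum(tab$perimeter * sqrt(tab$area))) /
    (1 - 1 / sqrt(n_cells))
}

# Contagion from explicit pairwise adjacency counting (double count).
oracle_contag <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  cls <- sort(unique(m[!is.na(m)]))
  mm <- length(cls)
  g <- matrix(0, mm, mm, dimnames = list(cls, cls))
  dirs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    dirs <- c(dirs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) next
    for (d in dirs) {
      a <- i + d[1]; b <- j + d[2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc && !is.na(m[a, b])) {
        ci <- as.character(m[i, j]); ck <- as.character(m[a, b])
        g[ci, ck] <- g[ci, ck] + 1
      }
    }
  }
  P <- as.numeric(table(factor(m[!is.na(m)], levels = cls))) / sum(!is.na(m))
  s <- 0
  for (i in seq_len(mm)) for (k in seq_len(mm)) {
    if (g[i, k] > 0) {
      q <- P[i] * g[i, k] / sum(g[i, ])
      s <- s + q * log(q)
    }
  }
  100 * (1 + s / (2 * log(mm)))
}

# Global Moran's I by explicit double loop.
oracle_moran <- function(x, W) {
  n <- length(x); xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  n * num / (sum(W) * sum((x - xb)^2))
}

# All 3x3 two-class rasters (including single-class ones).
all_3x3_two_class <- function() {
  grid <- expand.grid(rep(list(c(1L, 2L)), 9))
  lapply(seq_len(nrow(grid)), function(i) matrix(unlist(grid[i, ]), 3, 3))
}

# VIFs via the correlation-matrix inverse (independent of lm-based screening).
oracle_vif <- function(X) {
  R <- stats::cor(X)
  diag(solve(R))
}

# Plain GWR: per-target weighted least squares with spatial Gaussian weights,
# written directly with lm.wfit.
oracle_gwr <- function(X, y, u, v, h) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, ncol(X))
  for (i in seq_len(n)) {
    w <- exp(-((u - u[i])^2 + (v - v[i])^2) / h^2)
    fit <- stats::lm.wfit(X, y, w)
    out[i, ] <- fit$coefficients
  }
  out
}

# Small deterministic test rasters.
checkerboard <- function(n, classes = c(1L, 2L)) {
  outer(seq_len(n), seq_len(n), function(i, j) classes[(i + j) %% 2 + 1L])
}
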