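#' Delineate patches of a categorical raster
#'
#' Connected components per land-use class under 4- or 8-neighbor
#' connectivity. A patch's perimeter is the number of cell edges adjacent to
#' a different class, a nodata cell, or the raster boundary, in cell-edge
#' units (multiply by the cell size for map units). Nodata (NA) cells belong
#' to no patch but do contribute to the perimeter of their neighbors.
#'
#' @param raster An [lu_raster()] or integer matrix; NA = nodata.
#' @param connectivity 4 or 8 (default 8, the Fragstats convention).
#' @return A list of class `"patch_set"`: `patches` (data frame `patch_id`,
#'   `class_code`, `area` in cells, `perimeter` in cell edges), `membership`
#'   (integer matrix of patch ids, NA on nodata), `n_cells`, `connectivity`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 2, 2), 2, 2)
#' delineate_patches(m, connectivity = 4)$patches
delineate_patches <- function(raster, connectivity = 8) {
  m <- raster_values(raster)
  connectivity <- match.arg(as.character(connectivity), c("4", "8"))
  conn8 <- connectivity == "8"
  nr <- nrow(m); nc <- ncol(m)
  ok <- !is.na(m)
  if (!any(ok)) stop("raster is entirely nodata; no patches to delineate")

  idx <- matrix(seq_len(nr * nc), nr, nc)
  # candidate neighbor offsets (row step, col step): right, down (+ diagonals)
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (conn8) steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in steps) {
    if (nr - s[1] < 1L || nc - abs(s[2]) < 1L) next
    ri <- seq_len(nr - s[1])
    ci <- if (s[2] >= 0L) seq_len(nc - s[2]) else seq.int(1L - s[2], nc)
    a <- as.vector(idx[ri, ci, drop = FALSE])
    b <- as.vector(idx[ri + s[1], ci + s[2], drop = FALSE])
    keep <- ok[a] & ok[b] & m[a] == m[b]
    keep[is.na(keep)] <- FALSE
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  comp[!ok] <- NA_integer_
  # renumber patches 1..K over non-nodata cells only
  lev <- sort(unique(comp[ok]))
  memb <- matrix(match(comp, lev), nr, nc)

  # per-cell perimeter contribution: 4 sides, each exposed if the rook
  # neighbor is missing (boundary), nodata, or a different class
  exposed <- matrix(0L, nr, nc)
  shift_cmp <- function(dr, dc) {
    nb <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rs_src <- rs + dr; cs_src <- cs + dc
    vr <- rs_src >= 1L & rs_src <= nr
    vc <- cs_src >= 1L & cs_src <= nc
    nb[rs[vr], cs[vc]] <- m[rs_src[vr], cs_src[vc]]
    is.na(nb) | nb != m   # TRUE where side is exposed (NA-safe below)
  }
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    e <- shift_cmp(d[1], d[2])
    e[is.na(e)] <- TRUE
    exposed <- exposed + e
  }
  exposed[!ok] <- 0L

  area <- as.integer(tapply(rep(1L, sum(ok)), memb[ok], sum))
  perim <- as.integer(tapply(exposed[ok], memb[ok], sum))
  cls <- as.integer(tapply(m[ok], memb[ok], function(x) x[1]))
  patches <- data.frame(patch_id = seq_along(lev), class_code = cls,
                        area = area, perimeter = perim)
  structure(list(patches = patches, membership = memb,
                 n_cells = sum(ok), connectivity = as.integer(connectivity)),
            class = "patch_set")
}

#' Shannon diversity index (SHDI)
#'
#' `-sum(p_i * log(p_i))` over class area proportions, in nats, with the
#' convention `0 * log(0) = 0`.
#'
#' @param proportions Nonnegative class proportions summing to 1, or a
#'   categorical raster from which proportions are taken.
#' @return SHDI in nats.
#' @export
#' @examples
#' shdi(c(0.5, 0.5))   # log(2)
shdi <- function(proportions) {
  p <- as_proportions(proportions)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon evenness index (SHEI)
#'
#' SHDI divided by its maximum `log(m)` over the `m` classes present; 1 at
#' perfect evenness. A single-class landscape has no evenness to measure and
#' is assigned 0 by convention.
#'
#' @inheritParams shdi
#' @return SHEI in [0, 1].
#' @export
shei <- function(proportions) {
  p <- as_proportions(proportions)
  m <- sum(p > 0)
  if (m < 2L) return(0)
  shdi(p) / log(m)
}

as_proportions <- function(x) {
  if (inherits(x, "lu_raster") || is.matrix(x)) {
    return(class_proportions(x)$proportion)
  }
  x <- as.numeric(x)
  if (any(x < 0)) stop("proportions must be nonnegative")
  if (abs(sum(x) - 1) > 1e-8) stop("proportions must sum to 1")
  x
}

#' Patch cohesion index (COHESION)
#'
#' Landscape-wide physical connectedness of patches,
#' `100 * (1 - sum(p_ij) / sum(p_ij * sqrt(a_ij))) / (1 - 1/sqrt(Z))`,
#' with patch perimeters `p_ij` (cell edges), areas `a_ij` (cells) and `Z`
#' the number of non-nodata cells. 0 when every patch is a single cell,
#' approaching 100 as the landscape fuses into one compact patch.
#'
#' @param x A `"patch_set"` from [delineate_patches()], or a raster (then
#'   `connectivity` applies).
#' @param connectivity Passed to [delineate_patches()] when `x` is a raster.
#' @return Cohesion in percent.
#' @export
cohesion <- function(x, connectivity = 8) {
  ps <- as_patch_set(x, connectivity)
  if (ps$n_cells <= 1L)
    stop("cohesion is undefined for a single-cell landscape")
  p <- ps$patches$perimeter
  a <- ps$patches$area
  100 * (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(ps$n_cells))
}

as_patch_set <- function(x, connectivity) {
  if (inherits(x, "patch_set")) x else delineate_patches(x, connectivity)
}

#' Contagion index (CONTAG)
#'
#' Aggregation of class adjacencies:
#' `100 * (1 + sum(q_ik * log(q_ik)) / (2 * log(m)))`, where
#' `q_ik = P_i * g_ik / sum_k(g_ik)`, `P_i` is class i's area proportion and
#' `g_ik` counts cell adjacencies between classes i and k under the
#' double-count convention (each adjacent cell pair contributes once in each
#' direction). 100 = maximal clumping; low values indicate fine-grained
#' interspersion. Undefined for a single class.
#'
#' Cell adjacencies are counted in the four cardinal directions (the
#' convention of raster contagion); `connectivity = 8` adds diagonals.
#'
#' @param raster An [lu_raster()] or integer matrix.
#' @param connectivity 4 (default) or 8 adjacency directions.
#' @return Contagion in percent.
#' @export
contag <- function(raster, connectivity = 4) {
  m <- raster_values(raster)
  conn8 <- match.arg(as.character(connectivity), c("4", "8")) == "8"
  ok <- !is.na(m)
  classes <- sort(unique(m[ok]))
  nm <- length(classes)
  if (nm < 2L)
    stop("contagion is undefined for a landscape with a single class")
  g <- adjacency_counts(m, conn8)         # double-count, classes x classes
  P <- as.numeric(table(factor(m[ok], levels = classes))) / sum(ok)
  rs <- rowSums(g)
  q <- (P / ifelse(rs > 0, rs, 1)) * g    # q_ik = P_i g_ik / sum_k g_ik
  qv <- q[q > 0]
  100 * (1 + sum(qv * log(qv)) / (2 * log(nm)))
}

# Double-counted class adjacency matrix: entry (i, k) counts ordered pairs of
# adjacent non-nodata cells with classes i and k.
adjacency_counts <- function(m, conn8 = FALSE) {
  ok <- !is.na(m)
  classes <- sort(unique(m[ok]))
  f <- function(x) factor(x, levels = classes)
  nr <- nrow(m); nc <- ncol(m)
  pairs_a <- integer(0); pairs_b <- integer(0)
  collect <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    pairs_a <<- c(pairs_a, a[keep]); pairs_b <<- c(pairs_b, b[keep])
  }
  if (nc > 1) collect(m[, -nc], m[, -1])
  if (nr > 1) collect(m[-nr, ], m[-1, ])
  if (conn8 && nr > 1 && nc > 1) {
    collect(m[-nr, -nc], m[-1, -1])
    collect(m[-1, -nc], m[-nr, -1])
  }
  g <- table(f(c(pairs_a, pairs_b)), f(c(pairs_b, pairs_a)))
  matrix(as.numeric(g), length(classes), length(classes),
         dimnames = list(classes, classes))
}

#' Mean patch fractal dimension (FRAC_MN)
#'
#' Mean over patches of `2 * log(0.25 * p_ij) / log(a_ij)`; 1 for squares,
#' approaching 2 for maximally convoluted shapes. Single-cell patches
#' (`a = 1`) are assigned dimension 1 by convention before averaging.
#'
#' @inheritParams cohesion
#' @return Mean fractal dimension (dimensionless, >= 1 up to grid effects).
#' @export
frac_mn <- function(x, connectivity = 8) {
  ps <- as_patch_set(x, connectivity)
  if (nrow(ps$patches) == 0L) stop("empty patch set")
  p <- ps$patches$perimeter
  a <- ps$patches$area
  fd <- ifelse(a > 1, 2 * log(0.25 * p) / log(a), 1)
  mean(fd)
}

#' All five landscape metrics of a raster
#'
#' Convenience wrapper computing SHDI, SHEI, COHESION, CONTAG and FRAC_MN in
#' one pass. CONTAG is NA (with the single-class raster flagged) when fewer
#' than two classes are present.
#'
#' @param raster An [lu_raster()] or integer matrix.
#' @param connectivity Patch connectivity (default 8); contagion adjacency
#'   uses the four cardinal directions regardless.
#' @return One-row data frame: `shdi`, `shei`, `cohesion`, `contag`,
#'   `frac_mn`, `n_classes`.
#' @export
landscape_metrics <- function(raster, connectivity = 8) {
  ps <- delineate_patches(raster, connectivity)
  pr <- class_proportions(raster)
  ct <- if (nrow(pr) >= 2L) contag(raster) else NA_real_
  data.frame(shdi = shdi(pr$proportion),
             shei = shei(pr$proportion),
             cohesion = cohesion(ps),
             contag = ct,
             frac_mn = frac_mn(ps),
             n_classes = nrow(pr))
}
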