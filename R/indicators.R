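#' Default land-use intensity grades
#'
#' Ordinal intensity grade of each land-use class used by [lui()]:
#' construction 4, arable 3, grassland 2.5, forest 2, water 2, unused 1.
#'
#' @return Named numeric vector keyed by class code.
#' @export
default_lui_grades <- function() {
  cc <- landuse_classes()
  stats::setNames(c(4, 3, 2.5, 2, 2, 1), cc[c("construction", "arable",
                                              "grassland", "forest",
                                              "water", "unused")])
}

#' Synthetic ecosystem-service-value coefficients
#'
#' A synthetic per-area ESV coefficient table for tests and examples. Real
#' analyses must supply a published equivalent-coefficient table (e.g. the
#' national per-unit-area ESV equivalents) via `coeff_table`; these values
#' only preserve the qualitative ordering (forest and water most valuable,
#' construction land nil).
#'
#' @return Named numeric vector keyed by class code (currency per cell-area
#'   unit).
#' @export
synthetic_esv_coefficients <- function() {
  cc <- landuse_classes()
  stats::setNames(c(0, 6114.3, 6606.5, 19334.2, 28917.5, 458.6),
                  cc[c("construction", "arable", "grassland",
                       "forest", "water", "unused")])
}

lookup_by_class <- function(raster, table, what) {
  pr <- class_proportions(raster)
  key <- as.character(pr$class_code)
  missing <- setdiff(key, names(table))
  if (length(missing))
    stop("no ", what, " entry for class code(s): ",
         paste(missing, collapse = ", "))
  cbind(pr, coef = as.numeric(table[key]))
}

#' Ecosystem service value of a land-use raster
#'
#' `ESV = sum_i A_i * V_ci`: each class's area times its per-area service
#' value coefficient.
#'
#' @param raster An [lu_raster()] or integer matrix of class codes.
#' @param coeff_table Named numeric vector, class code -> coefficient
#'   (currency per squared map unit).
#' @param cell_area Area of one cell; defaults to `cellsize^2` for an
#'   `lu_raster`, 1 otherwise.
#' @return Total ESV (currency units).
#' @export
#' @examples
#' m <- matrix(c(rep(4, 60), rep(2, 40)), 10, 10)
#' esv(m, c(`4` = 5, `2` = 2))   # 60*5 + 40*2 = 380
esv <- function(raster, coeff_table, cell_area = raster_cellsize(raster)^2) {
  tab <- lookup_by_class(raster, coeff_table, "ESV coefficient")
  sum(tab$cells * cell_area * tab$coef)
}

#' Land-use intensity of a raster
#'
#' Area-weighted mean intensity grade, `LUI = sum_i A_i * S_i / S_c` with
#' grades `A_i` per class, class areas `S_i` and total area `S_c`. Bounded by
#' the minimum and maximum grade (1 and 4 with the default table).
#'
#' @param raster An [lu_raster()] or integer matrix of class codes.
#' @param grade_table Named numeric vector, class code -> intensity grade;
#'   defaults to [default_lui_grades()].
#' @return LUI (dimensionless).
#' @export
#' @examples
#' lui(matrix(1L, 10, 10))   # all construction -> 4
lui <- function(raster, grade_table = default_lui_grades()) {
  tab <- lookup_by_class(raster, grade_table, "LUI grade")
  sum(tab$proportion * tab$coef)
}

#' Zonal mean of a continuous raster
#'
#' Mean of non-nodata cells whose centers fall inside each zone rectangle.
#' A zone covering no cell centers yields NA and a warning (never a silent
#' zero).
#'
#' @param raster Numeric matrix or `lu_raster`-like list with `values`,
#'   `cellsize`, `origin` (row 1 = map bottom).
#' @param zone_map A [generate_zone_map()] result (or any data frame with
#'   `zone_id`, `xmin`, `xmax`, `ymin`, `ymax`).
#' @return Data frame `zone_id`, `mean`, `n_cells`.
#' @export
zonal_mean <- function(raster, zone_map) {
  if (inherits(raster, "lu_raster") ||
      (is.list(raster) && !is.null(raster$values))) {
    m <- raster$values; cs <- raster$cellsize; org <- raster$origin
  } else {
    m <- as.matrix(raster); cs <- 1; org <- c(0, 0)
  }
  nr <- nrow(m); nc <- ncol(m)
  cx <- org[1] + (seq_len(nc) - 0.5) * cs
  cy <- org[2] + (seq_len(nr) - 0.5) * cs
  X <- matrix(cx, nr, nc, byrow = TRUE)
  Y <- matrix(cy, nr, nc)
  out <- data.frame(zone_id = zone_map$zone_id,
                    mean = NA_real_, n_cells = 0L)
  for (i in seq_len(nrow(zone_map))) {
    inz <- X >= zone_map$xmin[i] & X < zone_map$xmax[i] &
           Y >= zone_map$ymin[i] & Y < zone_map$ymax[i] & !is.na(m)
    out$n_cells[i] <- sum(inz)
    if (out$n_cells[i] > 0L) out$mean[i] <- mean(m[inz])
  }
  if (any(out$n_cells == 0L))
    warning("zone(s) with no covered cells: ",
            paste(out$zone_id[out$n_cells == 0L], collapse = ", "),
            " (mean set to NA)")
  out
}

#' Normalized difference vegetation index from band reflectances
#'
#' `NDVI = (NIR - R) / (NIR + R)` elementwise; cells with `NIR + R == 0`
#' yield NA.
#'
#' @param nir,red Near-infrared and red reflectance (numeric, same shape).
#' @return NDVI values in [-1, 1].
#' @export
ndvi <- function(nir, red) {
  s <- nir + red
  out <- (nir - red) / s
  out[s == 0] <- NA_real_
  out
}
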