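#' Construct a land-use raster
#'
#' A light in-memory raster: an integer matrix of class codes plus grid
#' metadata. Row 1 is the bottom of the map and y increases with row index,
#' so cell (i, j) has its center at `origin + cellsize * (j - 0.5, i - 0.5)`.
#' `NA` cells are nodata.
#'
#' @param values Integer matrix of class codes (NA = nodata).
#' @param cellsize Cell side length in map units.
#' @param origin Numeric (x, y) of the lower-left corner.
#' @return An object of class `"lu_raster"`.
#' @export
lu_raster <- function(values, cellsize = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  structure(list(values = values, cellsize = cellsize,
                 origin = as.numeric(origin)),
            class = "lu_raster")
}

#' @export
print.lu_raster <- function(x, ...) {
  cat(sprintf("lu_raster: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$origin[1], x$origin[2]))
  tab <- table(x$values, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

raster_values <- function(x) {
  if (inherits(x, "lu_raster")) x$values else as.matrix(x)
}

raster_cellsize <- function(x, default = 1) {
  if (inherits(x, "lu_raster")) x$cellsize else default
}

#' Per-class cell counts and proportions of a categorical raster
#'
#' @param raster An `lu_raster` or plain matrix; NA cells are excluded.
#' @return Data frame with `class_code`, `cells`, `proportion`.
#' @export
class_proportions <- function(raster) {
  m <- raster_values(raster)
  v <- m[!is.na(m)]
  if (length(v) == 0L) stop("raster has no non-nodata cells")
  tab <- table(v)
  data.frame(class_code = as.integer(names(tab)),
             cells = as.integer(tab),
             proportion = as.numeric(tab) / length(v))
}

#' Write a categorical raster as an 8-bit TIFF
#'
#' Writes the class-code grid as a single-band 8-bit TIFF with nodata coded
#' as 255 (georeferencing tags are not written; grid metadata travels in the
#' sidecar files the pipeline emits). Requires the `tiff` package.
#'
#' @param raster An `lu_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  m <- raster_values(raster)
  m[is.na(m)] <- 255L
  # tiff expects [0,1] doubles top row first; row 1 is the map bottom
  img <- m[rev(seq_len(nrow(m))), , drop = FALSE] / 255
  tiff::writeTIFF(img, path, bits.per.sample = 8)
  invisible(path)
}
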