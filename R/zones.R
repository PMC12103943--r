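#' Lay out the zone (county) polygons of a scenario
#'
#' Zones are axis-aligned rectangles tiling a plane region on an r x c
#' lattice, each covering `grid_shape` raster cells of side `cellsize`.
#' The tiling is exact: zones cover the region without gaps or overlap, so
#' the contiguity structure is analytically known and can be verified
#' geometrically.
#'
#' @param scenario An [synthetic_scenario()] object.
#' @return A data frame of class `"zone_map"` with one row per zone:
#'   `zone_id`, lattice position (`zrow`, `zcol`), rectangle bounds
#'   (`xmin`, `xmax`, `ymin`, `ymax`), centroid (`u`, `v`) in map units and
#'   normalized centroid (`u01`, `v01`) in [0, 1].
#' @export
#' @examples
#' zm <- generate_zone_map(synthetic_scenario(n_zones = 9, grid_shape = c(10, 10)))
#' nrow(zm)   # 9
generate_zone_map <- function(scenario) {
  stopifnot(inherits(scenario, "ehi_scenario"))
  lat <- scenario$lattice
  w <- scenario$grid_shape[2] * scenario$cellsize   # zone width (x)
  h <- scenario$grid_shape[1] * scenario$cellsize   # zone height (y)
  zrow <- rep(seq_len(lat[1]), each = lat[2])
  zcol <- rep(seq_len(lat[2]), times = lat[1])
  xmin <- (zcol - 1) * w
  ymin <- (zrow - 1) * h
  u <- xmin + w / 2
  v <- ymin + h / 2
  zm <- data.frame(
    zone_id = seq_len(scenario$n_zones),
    zrow = zrow, zcol = zcol,
    xmin = xmin, xmax = xmin + w, ymin = ymin, ymax = ymin + h,
    u = u, v = v,
    u01 = if (lat[2] > 1) (zcol - 1) / (lat[2] - 1) else 0.5,
    v01 = if (lat[1] > 1) (zrow - 1) / (lat[1] - 1) else 0.5
  )
  class(zm) <- c("zone_map", "data.frame")
  zm
}

#' Write a zone map as WKT polygons
#'
#' Writes one row per zone with a `geometry` column holding the rectangle as
#' a WKT POLYGON string (CSV + WKT: a plain-text vector interchange format
#' readable by GDAL/ogr2ogr, QGIS, sf and geopandas).
#'
#' @param zone_map A [generate_zone_map()] result.
#' @param path Output CSV path.
#' @param extra Optional data frame of per-zone attributes (matched by
#'   `zone_id`) to include, e.g. LISA cluster labels.
#' @return `path`, invisibly.
#' @export
write_zone_wkt <- function(zone_map, path, extra = NULL) {
  wkt <- sprintf(
    "POLYGON ((%g %g, %g %g, %g %g, %g %g, %g %g))",
    zone_map$xmin, zone_map$ymin, zone_map$xmax, zone_map$ymin,
    zone_map$xmax, zone_map$ymax, zone_map$xmin, zone_map$ymax,
    zone_map$xmin, zone_map$ymin)
  out <- data.frame(zone_id = zone_map$zone_id, geometry = wkt)
  if (!is.null(extra)) out <- merge(out, extra, by = "zone_id", sort = TRUE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
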