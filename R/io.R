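# Plain-text interchange: ESRI ASCII grids for rasters, GeoJSON for polygons,
# CSV for tables, YAML for configuration. All formats are text so runs are
# fully diffable and portable to standard GIS tools.

#' Write a grid layer as an ESRI ASCII raster
#' @param mat Value matrix (row 1 = southernmost row).
#' @param grid The matching `grid_spec` (fine or coarse).
#' @param path Output `.asc` path.
#' @param digits Significant digits for values.
#' @export
write_ascii_grid <- function(mat, grid, path, digits = 7) {
  stopifnot(nrow(mat) == grid$n_rows, ncol(mat) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$n_cols), paste("nrows", grid$n_rows),
               paste("xllcorner", grid$origin_x),
               paste("yllcorner", grid$origin_y),
               paste("cellsize", grid$cell_size),
               "NODATA_value -9999"), con)
  vals <- mat
  vals[is.na(vals)] <- -9999
  # ASCII grids are written north-to-south
  for (r in rev(seq_len(nrow(vals))))
    writeLines(paste(signif(vals[r, ], digits), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#' @param path `.asc` path.
#' @param fine_factor Fine factor to record on the returned `grid_spec`.
#' @return List with `values` (matrix, row 1 southernmost) and `grid`.
#' @export
read_ascii_grid <- function(path, fine_factor = 1L) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  h <- stats::setNames(val, key)
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  vals[vals == h[["nodata_value"]]] <- NA
  list(values = vals,
       grid = grid_spec(h[["ncols"]], h[["nrows"]], h[["cellsize"]],
                        h[["xllcorner"]], h[["yllcorner"]], fine_factor))
}

#' Write protected-area polygons as GeoJSON
#' @param pas List of [pa_polygon()]s.
#' @param path Output path.
#' @export
write_pas_geojson <- function(pas, path) {
  feats <- lapply(pas, function(p) {
    ring <- rbind(p$coords, p$coords[1, ])
    list(type = "Feature",
         properties = list(id = p$id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read protected-area polygons from GeoJSON
#' @param path GeoJSON path (Polygon features with an `id` property).
#' @return List of [pa_polygon()]s.
#' @export
read_pas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    pa_polygon(as.character(f$properties$id), ring)
  })
}

#' Write a scenario configuration as YAML
#' @param config A `scenario_config`.
#' @param path Output path.
#' @export
write_scenario_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path YAML path.
#' @return A `scenario_config`.
#' @export
read_scenario_yaml <- function(path) {
  do.call(scenario_config, yaml::read_yaml(path))
}
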