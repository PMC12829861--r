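# Protected-area covariates and the standardised design matrix for the
# count regressions.

#' Compute covariates for one protected area
#'
#' Centroid and area come from the polygon geometry; mean elevation,
#' elevational range and the number of distinct land-cover classes are zonal
#' statistics over the fine cells sharing positive area with the polygon
#' (the same overlay rule as the suitability zonal maxima).
#'
#' @param pa A [pa_polygon()].
#' @param env Environment layers (list with `elevation`, `landcover`,
#'   `fine_grid`).
#' @return One-row data frame: `pa_id`, `centroid_easting`,
#'   `centroid_northing`, `area`, `mean_elevation`, `elevation_range`,
#'   `habitat_count`.
#' @export
compute_covariates <- function(pa, env) {
  stopifnot(inherits(pa, "pa_polygon"))
  cells <- cells_intersecting(env$fine_grid, pa)
  if (nrow(cells) == 0)
    stop("PA ", pa$id, ": no intersecting elevation cells")
  idx <- cbind(cells$row, cells$col)
  elev <- env$elevation[idx]
  ctr <- poly_centroid(pa$coords)
  data.frame(pa_id = pa$id,
             centroid_easting = ctr[1], centroid_northing = ctr[2],
             area = poly_area(pa$coords),
             mean_elevation = mean(elev),
             elevation_range = max(elev) - min(elev),
             habitat_count = length(unique(env$landcover[idx])))
}

#' Covariates for a list of protected areas
#' @param pas List of [pa_polygon()]s.
#' @param env Environment layers.
#' @return Data frame, one row per PA, input order preserved.
#' @export
compute_all_covariates <- function(pas, env) {
  res <- do.call(rbind, lapply(pas, compute_covariates, env = env))
  rownames(res) <- NULL
  res
}

design_columns <- c("log_mean_elevation", "log_elevation_range", "log_area",
                    "northing", "easting", "habitat_count")

#' Standardised design matrix of PA predictors
#'
#' Mean elevation, elevational range and area are log-transformed to mitigate
#' their strong right skew, as `log(x + offset)` with a fixed 1 m (1 m^2 for
#' area) offset so flat or sea-level PAs stay in the analysis. All six columns
#' (including the planar coordinates playing the latitude/longitude roles and
#' the habitat count) are then z-scored over the analysed PAs using the
#' population SD, so duplicating records leaves the standardised values
#' unchanged.
#'
#' @param covariates Data frame from [compute_all_covariates()].
#' @return List of class `design_matrix`: `X` (matrix, columns
#'   `log_mean_elevation`, `log_elevation_range`, `log_area`, `northing`,
#'   `easting`, `habitat_count`), `pa_ids`, `center`, `scale`, `offsets`.
#' @export
build_design_matrix <- function(covariates) {
  stopifnot(nrow(covariates) >= 2)
  raw <- cbind(log_mean_elevation = log(covariates$mean_elevation + 1),
               log_elevation_range = log(covariates$elevation_range + 1),
               log_area = log(covariates$area + 1),
               northing = covariates$centroid_northing,
               easting = covariates$centroid_easting,
               habitat_count = as.numeric(covariates$habitat_count))
  ctr <- colMeans(raw)
  # population SD, so duplicating every record leaves the z-scores unchanged
  scl <- sqrt(colMeans(sweep(raw, 2, ctr)^2))
  degenerate <- which(scl == 0)
  if (length(degenerate))
    stop("zero-variance column(s): ",
         paste(colnames(raw)[degenerate], collapse = ", "))
  X <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  structure(list(X = X, pa_ids = covariates$pa_id,
                 center = ctr, scale = scl,
                 offsets = c(mean_elevation = 1, elevation_range = 1, area = 1)),
            class = "design_matrix")
}
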