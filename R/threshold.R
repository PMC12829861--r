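# Suitability refinement, occupied-cell percentile thresholds, and per-PA
# zonal maxima for current and future periods.

#' Restrict a suitability surface to a species' preferred habitat
#'
#' A coarse cell keeps its suitability score iff at least one fine land-cover
#' cell within it carries one of the species' preferred classes; otherwise the
#' score is set to 0. This mirrors masking SDM surfaces by a much finer
#' land-cover product: sub-cell presence of suitable habitat is enough.
#'
#' @param suit A [suitability_grid()].
#' @param env Environment layers (a list with `landcover` fine matrix and
#'   `n_landcover_classes`, as from [generate_environment()] or a loader).
#' @param preferred_classes Non-empty integer vector of preferred land-cover
#'   class codes.
#' @return A [suitability_grid()] of the same shape.
#' @export
refine_by_habitat <- function(suit, env, preferred_classes) {
  stopifnot(inherits(suit, "suitability_grid"), length(preferred_classes) >= 1)
  lc <- env$landcover
  classes <- if (!is.null(env$n_landcover_classes))
    seq_len(env$n_landcover_classes) else sort(unique(as.vector(lc)))
  unknown <- setdiff(preferred_classes, classes)
  if (length(unknown))
    stop("unknown land-cover class code(s): ", paste(unknown, collapse = ", "))
  f <- nrow(lc) / suit$grid$n_rows
  stopifnot(f == round(f), ncol(lc) / suit$grid$n_cols == f)
  pref <- matrix(as.numeric(lc %in% preferred_classes), nrow(lc), ncol(lc))
  has_pref <- aggregate_fine(pref, f, max) > 0
  vals <- suit$values
  vals[!has_pref] <- 0
  suitability_grid(suit$species_id, suit$period, suit$grid, vals)
}

#' Species suitability threshold from occupied cells
#'
#' The threshold tau is a low percentile (default the 10th) of the refined
#' current suitability scores at the cells where the species was actually
#' recorded: any site at least as climatically suitable as the bulk of the
#' occupied range is treated as potentially suitable. The percentile uses
#' linear interpolation between closest order statistics (zero-based position
#' `(n - 1) * p / 100`, `stats::quantile()` type 7).
#'
#' @param refined_current The habitat-refined current-period
#'   [suitability_grid()].
#' @param occ Occupancy data frame with `cell_col`, `cell_row`.
#' @param percentile Percentile in `[0, 100]` (default 10).
#' @return List of class `species_threshold` with `species_id`, `tau`,
#'   `n_occupied_cells`, `percentile`.
#' @export
compute_threshold <- function(refined_current, occ, percentile = 10) {
  stopifnot(inherits(refined_current, "suitability_grid"),
            percentile >= 0, percentile <= 100)
  if (nrow(occ) == 0) stop("no occupied cells")
  g <- refined_current$grid
  if (any(occ$cell_col < 1 | occ$cell_col > g$n_cols |
          occ$cell_row < 1 | occ$cell_row > g$n_rows))
    stop("occupied cells outside the grid")
  v <- refined_current$values[cbind(occ$cell_row, occ$cell_col)]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no occupied cells")
  structure(list(species_id = refined_current$species_id,
                 tau = unname(stats::quantile(v, percentile / 100,
                                              type = 7, names = FALSE)),
                 n_occupied_cells = length(v),
                 percentile = percentile),
            class = "species_threshold")
}

#' Zonal maximum suitability over a protected area
#'
#' The maximum non-missing score over all cells whose half-open footprint
#' shares positive area with the polygon. A PA entirely smaller than one cell
#' inherits that cell's score.
#'
#' @param suit A [suitability_grid()].
#' @param pa A [pa_polygon()].
#' @return Maximum score, or `NA` if every intersecting cell is missing-valued.
#' @export
pa_max_suitability <- function(suit, pa) {
  stopifnot(inherits(suit, "suitability_grid"), inherits(pa, "pa_polygon"))
  cells <- cells_intersecting(suit$grid, pa)
  if (nrow(cells) == 0) stop("PA outside modelled domain")
  v <- suit$values[cbind(cells$row, cells$col)]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  max(v)
}

#' Per-(species, PA) zonal suitability table
#'
#' Batches [pa_max_suitability()] over every species and protected area for
#' both periods and attaches each species' threshold.
#'
#' @param species_grids Named list (by species id); each element a list with
#'   `current` and `future` refined [suitability_grid()]s.
#' @param pas List of [pa_polygon()]s.
#' @param thresholds Named list (by species id) of [compute_threshold()]
#'   results.
#' @return Data frame `pa_id`, `species_id`, `max_current`, `max_future`,
#'   `tau`, ordered by `(species_id, pa_id)`.
#' @export
build_pa_suitability_table <- function(species_grids, pas, thresholds) {
  sids <- sort(names(species_grids))
  pa_ids <- vapply(pas, function(p) p$id, "")
  out <- vector("list", length(sids))
  for (k in seq_along(sids)) {
    sid <- sids[k]
    sg <- species_grids[[sid]]
    if (is.null(sg$current) || is.null(sg$future))
      stop("missing current or future grid for species ", sid)
    ord <- order(pa_ids)
    mc <- numeric(length(pas)); mf <- numeric(length(pas))
    for (i in seq_along(pas)) {
      res <- tryCatch(
        c(pa_max_suitability(sg$current, pas[[i]]),
          pa_max_suitability(sg$future, pas[[i]])),
        error = function(e) stop("PA ", pas[[i]]$id, ": ", conditionMessage(e),
                                 call. = FALSE))
      mc[i] <- res[1]; mf[i] <- res[2]
    }
    out[[k]] <- data.frame(pa_id = pa_ids[ord], species_id = sid,
                           max_current = mc[ord], max_future = mf[ord],
                           tau = thresholds[[sid]]$tau)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
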