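# Refugia classification of protected areas and the species-level summary
# table with its headline aggregate statistics.

#' Is a protected area currently occupied?
#'
#' A PA counts as occupied iff its polygon shares positive area with the
#' footprint of at least one occupied hectad. Any-intersection is the only
#' workable rule when most PAs are far smaller than one recording cell.
#'
#' @param pa A [pa_polygon()].
#' @param occ Occupancy data frame with `cell_col`, `cell_row`.
#' @param grid The recording `grid_spec`.
#' @return Logical flag.
#' @export
mark_occupied <- function(pa, occ, grid) {
  if (nrow(occ) == 0) return(FALSE)
  cells <- cells_intersecting(grid, pa)
  if (nrow(cells) == 0) return(FALSE)
  any(paste(cells$col, cells$row) %in% paste(occ$cell_col, occ$cell_row))
}

#' Classify one (species, PA) pair
#'
#' An occupied PA is at risk if its future zonal maximum falls below the
#' species' threshold and an in situ refugium otherwise (occupancy is itself
#' evidence of current suitability, so occupied PAs are judged on the future
#' period alone). An unoccupied PA is an ex situ refugium iff both periods meet
#' the threshold, and `"none"` otherwise.
#'
#' @param rec One-row slice of the zonal suitability table (`pa_id`,
#'   `species_id`, `max_current`, `max_future`).
#' @param occupied Logical occupancy flag for this PA and species.
#' @param threshold The species' [compute_threshold()] result.
#' @return Data frame row: `pa_id`, `species_id`, `occupied`, `status`
#'   (one of `"at_risk"`, `"in_situ"`, `"ex_situ"`, `"none"`).
#' @export
classify_pa <- function(rec, occupied, threshold) {
  if (!identical(rec$species_id, threshold$species_id))
    stop("species mismatch: record is ", rec$species_id,
         ", threshold is ", threshold$species_id)
  tau <- threshold$tau
  status <- if (occupied) {
    if (rec$max_future >= tau) "in_situ" else "at_risk"
  } else {
    if (rec$max_current >= tau && rec$max_future >= tau) "ex_situ" else "none"
  }
  data.frame(pa_id = rec$pa_id, species_id = rec$species_id,
             occupied = occupied, status = status)
}

#' Classify every (species, PA) pair of a zonal suitability table
#'
#' Pairs whose zonal maxima are missing (all intersecting cells missing-valued)
#' are excluded with a message.
#'
#' @param suit_table Output of [build_pa_suitability_table()].
#' @param occupancy Data frame `species_id`, `cell_col`, `cell_row` covering
#'   all species.
#' @param pas List of [pa_polygon()]s.
#' @param grid Recording `grid_spec`.
#' @param thresholds Named list of [compute_threshold()] results.
#' @return Data frame of statuses (`pa_id`, `species_id`, `occupied`,
#'   `status`).
#' @export
classify_refugia <- function(suit_table, occupancy, pas, grid, thresholds) {
  pa_lookup <- stats::setNames(pas, vapply(pas, function(p) p$id, ""))
  out <- vector("list", length(unique(suit_table$species_id)))
  k <- 0L
  for (sid in unique(suit_table$species_id)) {
    occ <- occupancy[occupancy$species_id == sid, , drop = FALSE]
    sub <- suit_table[suit_table$species_id == sid, , drop = FALSE]
    bad <- is.na(sub$max_current) | is.na(sub$max_future)
    if (any(bad)) {
      message("species ", sid, ": excluding ", sum(bad),
              " PA(s) with missing zonal suitability")
      sub <- sub[!bad, , drop = FALSE]
    }
    occ_flags <- vapply(sub$pa_id, function(pid)
      mark_occupied(pa_lookup[[pid]], occ, grid), logical(1))
    rows <- lapply(seq_len(nrow(sub)), function(i)
      classify_pa(sub[i, ], occ_flags[i], thresholds[[sid]]))
    k <- k + 1L
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a species summary row from counts
#'
#' @param species_id Species identifier.
#' @param n_occupied,n_at_risk,n_in_situ,n_ex_situ PA counts by class;
#'   `n_occupied` must equal `n_at_risk + n_in_situ`.
#' @return One-row data frame with `pct_at_risk` (1 decimal; `NA` when no PA
#'   is occupied).
#' @export
species_summary_row <- function(species_id, n_occupied, n_at_risk,
                                n_in_situ, n_ex_situ) {
  if (n_occupied != n_at_risk + n_in_situ)
    stop("occupied count must equal at-risk + in-situ for ", species_id)
  data.frame(species_id = species_id,
             n_occupied = n_occupied, n_at_risk = n_at_risk,
             pct_at_risk = if (n_occupied > 0)
               round(100 * n_at_risk / n_occupied, 1) else NA_real_,
             n_in_situ = n_in_situ, n_ex_situ = n_ex_situ)
}

#' Summarise refugia statuses for one species
#'
#' @param statuses Status rows for a single species (as from
#'   [classify_refugia()]), or a one-row data frame of counts with columns
#'   `n_occupied`, `n_at_risk`, `n_in_situ`, `n_ex_situ` (e.g. a published
#'   summary row re-entered as data).
#' @return One-row data frame: counts by class and `pct_at_risk` to 1 decimal.
#' @export
summarize_species <- function(statuses) {
  if (all(c("n_occupied", "n_at_risk", "n_in_situ", "n_ex_situ") %in%
          names(statuses))) {
    stopifnot(nrow(statuses) == 1)
    return(species_summary_row(statuses$species_id, statuses$n_occupied,
                               statuses$n_at_risk, statuses$n_in_situ,
                               statuses$n_ex_situ))
  }
  sid <- unique(statuses$species_id)
  if (length(sid) > 1) stop("statuses must belong to a single species")
  if (length(sid) == 0) sid <- NA_character_
  n <- function(s) sum(statuses$status == s)
  species_summary_row(sid, sum(statuses$occupied), n("at_risk"),
                      n("in_situ"), n("ex_situ"))
}

#' Summary table across species with headline statistics
#'
#' Computes the per-column averages (1 decimal), the share of identified
#' refugia that are ex situ (currently unoccupied), the mean per-species
#' retention (percentage of occupied PAs remaining suitable, 1 decimal) and
#' the pooled retention (average in situ count over average occupied count,
#' nearest integer).
#'
#' @param rows Data frame of [summarize_species()] rows (one per species).
#' @return List of class `refugia_summary` with `rows`, `averages`,
#'   `pct_ex_situ_of_refugia`, `mean_retention_pct`, `pooled_retention_pct`.
#' @export
summarize_table <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  occ_rows <- rows[rows$n_occupied > 0, , drop = FALSE]
  # the percentage average uses unrounded per-species ratios
  averages <- c(n_occupied = round(mean(rows$n_occupied), 1),
                n_at_risk = round(mean(rows$n_at_risk), 1),
                pct_at_risk = if (nrow(occ_rows) > 0)
                  round(mean(100 * occ_rows$n_at_risk / occ_rows$n_occupied), 1)
                else NA_real_,
                n_in_situ = round(mean(rows$n_in_situ), 1),
                n_ex_situ = round(mean(rows$n_ex_situ), 1))
  n_ref <- sum(rows$n_in_situ) + sum(rows$n_ex_situ)
  structure(list(
    rows = rows,
    averages = averages,
    pct_ex_situ_of_refugia = if (n_ref > 0)
      round(100 * sum(rows$n_ex_situ) / n_ref) else NA_real_,
    mean_retention_pct = if (nrow(occ_rows) > 0)
      round(mean(100 * occ_rows$n_in_situ / occ_rows$n_occupied), 1)
    else NA_real_,
    pooled_retention_pct = if (mean(rows$n_occupied) > 0)
      round(100 * mean(rows$n_in_situ) / mean(rows$n_occupied)) else NA_real_),
    class = "refugia_summary")
}

#' @export
print.refugia_summary <- function(x, ...) {
  df <- x$rows
  df$pct_at_risk <- sprintf("%.1f", df$pct_at_risk)
  print(df, row.names = FALSE)
  cat(sprintf("Average: %s\n",
              paste(sprintf("%.1f", x$averages), collapse = "  ")))
  cat(sprintf("ex situ share of refugia: %d%%; mean retention: %.1f%%; pooled retention: %d%%\n",
              x$pct_ex_situ_of_refugia, x$mean_retention_pct,
              x$pooled_retention_pct))
  invisible(x)
}

#' Number of species per PA with a given refugium status
#'
#' @param statuses Full status table from [classify_refugia()].
#' @param mode `"in_situ"` or `"ex_situ"`.
#' @return Data frame `pa_id`, `count` covering every PA present in
#'   `statuses`, zeros included.
#' @export
count_species_per_pa <- function(statuses, mode = c("in_situ", "ex_situ")) {
  mode <- match.arg(mode)
  pa_ids <- sort(unique(statuses$pa_id))
  hit <- statuses[statuses$status == mode, , drop = FALSE]
  counts <- table(factor(hit$pa_id, levels = pa_ids))
  data.frame(pa_id = pa_ids, count = as.integer(counts))
}
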