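# Small, fast fixtures used across test files. Everything is generated in
# code; the small domain gets a proportionally smaller poleward shift so the
# scenario keeps the structure of the full-size system.

small_grid <- function() grid_spec(20, 20, cell_size = 10000, fine_factor = 4)

small_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_species = 3, n_pas = 60,
                   warming_shift = 50000, n_landcover_nuclei = 40)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# a tiny suitability grid with hand-set values; row 1 is the southernmost row
manual_grid <- function(values, cell_size = 10, species_id = "spA",
                        period = "current", fine_factor = 1) {
  g <- grid_spec(ncol(values), nrow(values), cell_size = cell_size,
                 fine_factor = fine_factor)
  suitability_grid(species_id, period, g, values)
}

# independent percentile oracle: sort + linear interpolation at zero-based
# position (n - 1) * p / 100, written without stats::quantile
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  pos <- (n - 1) * p / 100
  lo <- floor(pos)
  frac <- pos - lo
  if (lo + 2 > n) return(x[n])
  x[lo + 1] * (1 - frac) + x[lo + 2] * frac
}

# interval-arithmetic oracle for rectangle PAs: cells overlapping with
# positive area, computed without any polygon clipping code
rect_cells_oracle <- function(grid, xmin, ymin, xmax, ymax) {
  out <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    b <- refugia:::cell_bounds(grid, out$col[i], out$row[i])
    ox <- min(xmax, b["xmax"]) - max(xmin, b["xmin"])
    oy <- min(ymax, b["ymax"]) - max(ymin, b["ymin"])
    keep[i] <- ox > 0 && oy > 0
  }
  out[keep, ]
}
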