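# Synthetic study system: a planar Britain-like landscape with a south-north
# elevation ramp, patchy land cover, species suitability surfaces that shift
# poleward and upslope between periods, occupancy concentrated in currently
# suitable habitat, and strongly right-skewed protected-area sizes.

#' Scenario configuration for the synthetic landscape
#'
#' Defaults describe the emulated study system: hectad-scale (10 km) grids over
#' a 600 x 600 km domain, 12 focal species, a poleward displacement of each
#' species' climatic optimum of 150 km accompanied by a 170 m upslope shift of
#' its preferred elevation between the baseline and future period (the
#' field-standard equivalence of roughly 145 km latitude per 167 m elevation
#' per degree of warming), and log-normal protected-area sizes with median
#' under 1 km^2, as holds for most British SSSIs.
#'
#' @param seed Root integer seed; every generator derives its own stream from it.
#' @param n_species Number of focal species.
#' @param warming_shift Poleward displacement (m) of each species' suitability
#'   optimum between periods.
#' @param elevation_shift Upslope displacement (m) of the preferred elevation
#'   between periods.
#' @param elevation_lapse Suitability-elevation coupling (1/m): the inverse
#'   width of the quadratic elevation term of the suitability logit.
#' @param occupancy_cut Suitability score above which a cell can be recorded
#'   occupied.
#' @param occupancy_rate Probability in (0, 1] that a sufficiently suitable
#'   cell is recorded occupied. The low default reflects rare species whose
#'   realised occurrence set is much smaller than their climatic envelope,
#'   which is what makes most identified refugia unoccupied (ex situ).
#' @param n_pas Number of protected areas.
#' @param pa_area_log_mean,pa_area_log_sd Log-normal parameters of PA area (m^2).
#'   Defaults give a median of ~1 km^2 with a long right tail, mirroring an
#'   estate in which most reserves are small but a few are very large.
#' @param n_landcover_classes Number of land-cover classes.
#' @param n_landcover_nuclei Number of seed points of the nearest-centroid
#'   land-cover mosaic (controls patch size).
#' @param ramp_max Elevation (m) reached by the latitudinal ramp at the
#'   northern edge.
#' @param grf_amplitude Standard deviation (m) of the smooth random component
#'   of elevation. Zero gives the pure ramp.
#' @param grf_bandwidth Gaussian smoothing bandwidth, in fine cells.
#' @param roughness Amplitude (m) of fine-scale terrain relief. Its local
#'   strength is modulated by an independent smooth field, so within-cell
#'   elevational span varies across the landscape independently of mean
#'   elevation (rugged lowland coasts and smooth upland plateaux both occur).
#' @param suitability_noise_sd SD of per-(species, cell) residual variation on
#'   the suitability logit, shared between the two periods. Emulates the
#'   cell-scale heterogeneity of real SDM surfaces (local climate, data and
#'   habitat effects) that smooth analytic niches lack.
#' @param true_beta Length-7 coefficient vector (intercept + 6 predictors) used
#'   by forward simulations of the count model for parameter-recovery work.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_species = 12L,
                            warming_shift = 150000,
                            elevation_shift = 170,
                            elevation_lapse = 1 / 150,
                            occupancy_cut = 0.5,
                            occupancy_rate = 0.1,
                            n_pas = 2500L,
                            pa_area_log_mean = 13.8,
                            pa_area_log_sd = 2.2,
                            n_landcover_classes = 10L,
                            n_landcover_nuclei = 150L,
                            ramp_max = 500,
                            grf_amplitude = 200,
                            grf_bandwidth = 15,
                            roughness = 150,
                            suitability_noise_sd = 0.6,
                            true_beta = c(0.5, 0.3, -0.2, 0.4, 0.15, -0.3, 0.1)) {
  stopifnot(occupancy_rate > 0, occupancy_rate <= 1, n_pas >= 1,
            warming_shift >= 0, n_species >= 1, n_landcover_classes >= 1,
            pa_area_log_sd >= 0, grf_amplitude >= 0, roughness >= 0)
  structure(as.list(environment()), class = "scenario_config")
}

#' Default coarse grid of the synthetic scenario (60 x 60 hectads)
#' @return A `grid_spec`.
#' @export
default_grid <- function() grid_spec(60, 60)

# Deterministic per-stage seed derived from the root seed; kept below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973) %% 2147483629)
}

# Row-normalised banded Gaussian smoothing matrix (edge-corrected).
smooth_matrix <- function(n, bw) {
  if (bw <= 0) return(diag(n))
  w <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * bw^2))
  w / rowSums(w)
}

# Smooth zero-mean, unit-variance Gaussian random field using the current
# RNG stream. Centring before scaling matters: when the bandwidth approaches
# the grid size the smoothed field is nearly constant, and rescaling an
# uncentred near-constant field would blow its mean up.
gaussian_field <- function(nr, nc, bw) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- smooth_matrix(nr, bw) %*% z %*% t(smooth_matrix(nc, bw))
  s <- stats::sd(as.vector(f))
  if (s > 0) (f - mean(f)) / s else f
}

#' Generate elevation and land-cover layers
#'
#' Elevation is a non-negative field on the fine grid: a latitudinal ramp plus
#' a smooth Gaussian random field, plus fine-scale relief whose local
#' amplitude is modulated by an independent smooth field (so ruggedness is
#' not a proxy of elevation). Land cover assigns each fine cell the class of
#' its nearest randomly seeded class nucleus, giving spatially coherent
#' patches.
#'
#' @param grid Coarse `grid_spec`.
#' @param config A `scenario_config`.
#' @return List with `elevation` (matrix, m), `landcover` (integer matrix),
#'   `fine_grid` (the fine `grid_spec`) and `n_landcover_classes`.
#' @export
generate_environment <- function(grid, config) {
  stopifnot(inherits(grid, "grid_spec"), inherits(config, "scenario_config"))
  fg <- fine_grid(grid)
  nrf <- fg$n_rows; ncf <- fg$n_cols
  set.seed(stage_seed(config$seed, 1))
  yfrac <- (seq_len(nrf) - 0.5) / nrf
  ramp <- matrix(config$ramp_max * yfrac, nrf, ncf)
  elev <- ramp
  if (config$grf_amplitude > 0)
    elev <- elev + config$grf_amplitude * gaussian_field(nrf, ncf, config$grf_bandwidth)
  elev <- pmax(elev, 0)
  if (config$roughness > 0) {
    # fine-scale relief whose local amplitude is governed by its own smooth
    # field, independent of elevation: rugged lowlands and smooth upland
    # plateaux both occur, so within-cell elevational span is not a mere
    # proxy of mean elevation
    relief <- gaussian_field(nrf, ncf, 2.5)
    amp <- stats::pnorm(gaussian_field(nrf, ncf, config$grf_bandwidth / 3))
    elev <- pmax(elev + config$roughness * amp * relief, 0)
  }

  set.seed(stage_seed(config$seed, 2))
  k <- config$n_landcover_classes
  if (k == 1L) {
    lc <- matrix(1L, nrf, ncf)
  } else {
    nn <- max(config$n_landcover_nuclei, k)
    ext <- grid_extent(grid)
    nx <- stats::runif(nn, ext["xmin"], ext["xmax"])
    ny <- stats::runif(nn, ext["ymin"], ext["ymax"])
    ncls <- sample(rep_len(seq_len(k), nn))  # every class seeded at least once
    cc <- cell_centers(fg)
    best <- rep(Inf, nrf * ncf)
    cls <- integer(nrf * ncf)
    for (j in seq_len(nn)) {
      d2 <- (cc$x - nx[j])^2 + (cc$y - ny[j])^2
      hit <- d2 < best
      best[hit] <- d2[hit]
      cls[hit] <- ncls[j]
    }
    lc <- matrix(NA_integer_, nrf, ncf)
    lc[cbind(cc$row, cc$col)] <- cls
  }
  list(elevation = elev, landcover = lc, fine_grid = fg,
       n_landcover_classes = as.integer(config$n_landcover_classes))
}

species_id_for <- function(i) sprintf("sp%02d", i)

species_index_from_id <- function(species_id) {
  d <- suppressWarnings(as.integer(gsub("\\D", "", species_id)))
  if (is.na(d)) sum(utf8ToInt(species_id)) else d
}

# Species-specific niche parameters, deterministic in (seed, species_index).
species_params <- function(grid, config, species_index) {
  set.seed(stage_seed(config$seed, 100 + species_index))
  ext <- grid_extent(grid)
  list(opt_x = stats::runif(1, ext["xmin"] + 0.15 * diff(ext[1:2]),
                            ext["xmax"] - 0.15 * diff(ext[1:2])),
       opt_y = stats::runif(1, ext["ymin"] + 0.20 * diff(ext[3:4]),
                            ext["ymin"] + 0.70 * diff(ext[3:4])),
       pref_elev = stats::runif(1, 50, 450),
       sigma_xy = stats::runif(1, 0.30, 0.50) * diff(ext[1:2]),
       alpha = 2.5)
}

#' Generate current and future suitability surfaces for one species
#'
#' Suitability is the inverse logit of a quadratic function of the distance to
#' a species-specific climatic optimum, combining planar location and a
#' preferred elevation. The elevation distance is measured from the preferred
#' elevation to the span of elevations actually present within the cell
#' (zero when the preferred band occurs anywhere in the cell): topographically
#' varied cells offer microclimates to species with many different elevation
#' preferences, which is the mechanism hypothesised to make rugged protected
#' areas disproportionately valuable refugia. The future surface uses the same
#' function with the optimum displaced poleward by `warming_shift` and the
#' preferred elevation raised by `elevation_shift`.
#'
#' @param grid Coarse `grid_spec`.
#' @param config A `scenario_config`.
#' @param species_index Integer in `1:n_species`.
#' @param env Environment layers from [generate_environment()]; regenerated
#'   deterministically from the config when omitted.
#' @return List with `current` and `future` [suitability_grid()] objects.
#' @export
generate_species_surfaces <- function(grid, config, species_index, env = NULL) {
  stopifnot(species_index >= 1, species_index <= config$n_species)
  if (is.null(env)) env <- generate_environment(grid, config)
  f <- grid$fine_factor
  elev_lo <- aggregate_fine(env$elevation, f, min)
  elev_hi <- aggregate_fine(env$elevation, f, max)
  pars <- species_params(grid, config, species_index)
  cc <- cell_centers(grid)
  xm <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  ym <- xm
  xm[cbind(cc$row, cc$col)] <- cc$x
  ym[cbind(cc$row, cc$col)] <- cc$y

  surf <- function(opt_y, pref_elev, eps) {
    d2 <- (xm - pars$opt_x)^2 + (ym - opt_y)^2
    # distance from the preferred elevation to the cell's elevation interval
    elev_dist <- pmax(elev_lo - pref_elev, pref_elev - elev_hi, 0)
    logit <- pars$alpha - d2 / pars$sigma_xy^2 -
      (elev_dist * config$elevation_lapse)^2 + eps
    stats::plogis(logit)
  }
  # cell-scale residual variation, shared between periods so persistent local
  # features (not period-specific noise) distinguish neighbouring cells
  set.seed(stage_seed(config$seed, 150 + species_index))
  eps <- matrix(stats::rnorm(grid$n_rows * grid$n_cols,
                             sd = config$suitability_noise_sd),
                grid$n_rows, grid$n_cols)

  sid <- species_id_for(species_index)
  list(current = suitability_grid(sid, "current", grid,
                                  surf(pars$opt_y, pars$pref_elev, eps)),
       future = suitability_grid(sid, "future",  grid,
                                 surf(pars$opt_y + config$warming_shift,
                                      pars$pref_elev + config$elevation_shift,
                                      eps)))
}

#' Generate hectad occupancy records for one species
#'
#' Each cell whose (refined) current suitability exceeds the scenario's
#' occupancy cut is recorded occupied independently with probability
#' `occupancy_rate`, emulating presence records concentrated where the species
#' can actually live. The result may be empty.
#'
#' @param current A current-period [suitability_grid()] (normally
#'   habitat-refined).
#' @param config A `scenario_config`.
#' @return Data frame with `species_id`, `cell_col`, `cell_row`.
#' @export
generate_occupancy <- function(current, config) {
  stopifnot(inherits(current, "suitability_grid"))
  set.seed(stage_seed(config$seed,
                      200 + species_index_from_id(current$species_id)))
  v <- current$values
  idx <- which(!is.na(v) & v > config$occupancy_cut, arr.ind = TRUE)
  if (nrow(idx)) {
    keep <- stats::runif(nrow(idx)) <= config$occupancy_rate
    idx <- idx[keep, , drop = FALSE]
  }
  data.frame(species_id = rep(current$species_id, nrow(idx)),
             cell_col = as.integer(idx[, 2]), cell_row = as.integer(idx[, 1]))
}

#' Generate protected-area polygons
#'
#' Axis-aligned rectangles with log-normal areas and log-uniform aspect
#' ratios in `[0.1, 10]` (many British reserves are elongated features such
#' as river corridors, coastal strips and verges), centred uniformly within
#' the grid extent and clipped to it.
#'
#' @param grid Coarse `grid_spec`.
#' @param config A `scenario_config`.
#' @return List of [pa_polygon()] objects with unique ids.
#' @export
generate_pas <- function(grid, config) {
  set.seed(stage_seed(config$seed, 3))
  n <- config$n_pas
  ext <- grid_extent(grid)
  area <- stats::rlnorm(n, config$pa_area_log_mean, config$pa_area_log_sd)
  aspect <- exp(stats::runif(n, log(0.1), log(10)))
  w <- sqrt(area * aspect); h <- sqrt(area / aspect)
  cx <- stats::runif(n, ext["xmin"], ext["xmax"])
  cy <- stats::runif(n, ext["ymin"], ext["ymax"])
  lapply(seq_len(n), function(i) {
    pa_rect(sprintf("PA%04d", i),
            max(cx[i] - w[i] / 2, ext["xmin"]), max(cy[i] - h[i] / 2, ext["ymin"]),
            min(cx[i] + w[i] / 2, ext["xmax"]), min(cy[i] + h[i] / 2, ext["ymax"]))
  })
}

#' Generate species-to-habitat preference table
#'
#' Each species is assigned up to three preferred land-cover classes; the first
#' is drawn preferentially from classes prevalent near the species' climatic
#' optimum, so occurrences and suitable habitat co-occur as in real data.
#'
#' @param grid Coarse `grid_spec`.
#' @param config A `scenario_config`.
#' @param env Environment layers (regenerated from config when omitted).
#' @return Data frame with `species_id`, `class_code` (long format).
#' @export
generate_habitat_preferences <- function(grid, config, env = NULL) {
  if (is.null(env)) env <- generate_environment(grid, config)
  set.seed(stage_seed(config$seed, 4))
  k <- config$n_landcover_classes
  f <- grid$fine_factor
  out <- lapply(seq_len(config$n_species), function(i) {
    pars <- species_params(grid, config, i)
    fg <- env$fine_grid
    col <- pmin(pmax(1L, 1L + floor((pars$opt_x - fg$origin_x) / fg$cell_size)), fg$n_cols)
    row <- pmin(pmax(1L, 1L + floor((pars$opt_y - fg$origin_y) / fg$cell_size)), fg$n_rows)
    win <- 10L * f
    rows <- max(1L, row - win):min(fg$n_rows, row + win)
    cols <- max(1L, col - win):min(fg$n_cols, col + win)
    local_cls <- as.vector(env$landcover[rows, cols])
    first <- as.integer(names(sort(table(local_cls), decreasing = TRUE))[1])
    extra <- setdiff(sample(seq_len(k)), first)[seq_len(min(2, k - 1))]
    data.frame(species_id = species_id_for(i),
               class_code = as.integer(unique(c(first, extra))))
  })
  do.call(rbind, out)
}

#' Generate a complete synthetic scenario
#'
#' @param grid Coarse `grid_spec` (default [default_grid()]).
#' @param config A `scenario_config`.
#' @return List with `grid`, `config`, `env`, `species` (per species: `current`
#'   and `future` suitability grids), `habitat_prefs` and `pas`.
#' @export
generate_scenario <- function(grid = default_grid(), config = scenario_config()) {
  env <- generate_environment(grid, config)
  species <- lapply(seq_len(config$n_species), function(i)
    generate_species_surfaces(grid, config, i, env))
  names(species) <- vapply(species, function(s) s$current$species_id, "")
  list(grid = grid, config = config, env = env, species = species,
       habitat_prefs = generate_habitat_preferences(grid, config, env),
       pas = generate_pas(grid, config))
}
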