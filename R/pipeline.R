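# End-to-end orchestration: simulate (optional) -> refine -> occupancy ->
# threshold -> zonal extraction -> classify -> summarise -> covariates ->
# count models -> report.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the refugia screening pipeline
#'
#' Runs every stage on a synthetic scenario (or a pre-built scenario object of
#' the same shape holding real data): habitat refinement, occupancy,
#' per-species suitability thresholds, zonal maxima per PA, refugia
#' classification, the species summary table, PA covariates, and the two
#' spatially explicit Poisson count models (species per PA with in situ and
#' with ex situ refugia).
#'
#' @param grid Coarse `grid_spec` (ignored when `scenario` is supplied).
#' @param config A `scenario_config` (ignored when `scenario` is supplied).
#' @param scenario Optional pre-built scenario list (as from
#'   [generate_scenario()]); supply this to run on real data.
#' @param occupancy Optional occupancy data frame (`species_id`, `cell_col`,
#'   `cell_row`); generated from the refined current surfaces when `NULL`.
#' @param percentile Threshold percentile (default 10).
#' @param glmm_config A [spatial_glmm_config()]; `NULL` uses defaults with the
#'   scenario seed.
#' @param fit_models Fit the two count models? (Set `FALSE` for
#'   classification-only runs.)
#' @param out_dir Optional directory: every intermediate table is written as
#'   CSV, polygons as GeoJSON, config and manifest as YAML.
#' @param quiet Suppress progress messages.
#' @return List with `scenario`, `occupancy`, `thresholds`, `suit_table`,
#'   `statuses`, `summary`, `covariates`, `design`, `counts`
#'   (in_situ/ex_situ), `fits` (in_situ/ex_situ or NULL), `manifest`.
#' @export
run_refugia_pipeline <- function(grid = default_grid(),
                                 config = scenario_config(),
                                 scenario = NULL, occupancy = NULL,
                                 percentile = 10, glmm_config = NULL,
                                 fit_models = TRUE, out_dir = NULL,
                                 quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  if (is.null(scenario)) {
    say("stage simulate: generating synthetic scenario")
    scenario <- with_stage("simulate", generate_scenario(grid, config))
  }
  grid <- scenario$grid
  config <- scenario$config

  say("stage refine: masking suitability by preferred habitat")
  refined <- with_stage("refine", {
    lapply(scenario$species, function(sg) {
      if (is.null(sg$current) || is.null(sg$future))
        stop("missing current or future grid for species ",
             if (!is.null(sg$current)) sg$current$species_id
             else sg$future$species_id)
      pref <- scenario$habitat_prefs$class_code[
        scenario$habitat_prefs$species_id == sg$current$species_id]
      list(current = refine_by_habitat(sg$current, scenario$env, pref),
           future = refine_by_habitat(sg$future, scenario$env, pref))
    })
  })

  if (is.null(occupancy)) {
    say("stage occupancy: sampling occurrence records")
    occupancy <- with_stage("occupancy", do.call(rbind, lapply(refined,
      function(sg) generate_occupancy(sg$current, config))))
  }

  say("stage threshold: occupied-cell percentile thresholds")
  thresholds <- with_stage("threshold", lapply(refined, function(sg) {
    occ <- occupancy[occupancy$species_id == sg$current$species_id, ,
                     drop = FALSE]
    compute_threshold(sg$current, occ, percentile)
  }))

  say("stage zonal: per-PA maximum suitability")
  suit_table <- with_stage("zonal",
    build_pa_suitability_table(refined, scenario$pas, thresholds))

  say("stage classify: refugia classification")
  statuses <- with_stage("classify",
    classify_refugia(suit_table, occupancy, scenario$pas, grid, thresholds))

  say("stage summarize: species summary table")
  summary_tab <- with_stage("summarize", {
    rows <- do.call(rbind, lapply(split(statuses, statuses$species_id),
                                  summarize_species))
    rownames(rows) <- NULL
    summarize_table(rows)
  })

  say("stage covariates: PA covariates and design matrix")
  covariates <- with_stage("covariates",
    compute_all_covariates(scenario$pas, scenario$env))
  design <- if (fit_models) {
    with_stage("covariates", build_design_matrix(covariates))
  } else {
    # classification-only runs tolerate a degenerate design (e.g. a constant
    # habitat count on a tiny landscape)
    tryCatch(build_design_matrix(covariates), error = function(e) {
      say("stage covariates: design matrix not built (", conditionMessage(e), ")")
      NULL
    })
  }

  counts <- list(
    in_situ = count_species_per_pa(statuses, "in_situ"),
    ex_situ = count_species_per_pa(statuses, "ex_situ"))
  # align counts with covariate row order
  for (mode in names(counts)) {
    counts[[mode]] <- counts[[mode]][match(covariates$pa_id,
                                           counts[[mode]]$pa_id), ]
    rownames(counts[[mode]]) <- NULL
  }

  fits <- list(in_situ = NULL, ex_situ = NULL)
  if (fit_models) {
    if (is.null(glmm_config))
      glmm_config <- spatial_glmm_config(seed = stage_seed(config$seed, 9))
    coords <- cbind(covariates$centroid_easting, covariates$centroid_northing)
    for (mode in names(counts)) {
      y <- counts[[mode]]$count
      if (sum(y) == 0) {
        say("stage fit: no ", mode, " refugia; model not fitted")
        next
      }
      say("stage fit: ", mode, " count model")
      fits[[mode]] <- with_stage(paste0("fit_", mode),
        fit_spatial_glmm(y, design, coords, glmm_config))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("refugia")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    percentile = percentile,
    config_hash = local({
      tf <- tempfile(fileext = ".yaml")
      on.exit(unlink(tf))
      yaml::write_yaml(unclass(config), tf)
      unname(tools::md5sum(tf))
    }),
    n_species = length(scenario$species),
    n_pas = length(scenario$pas),
    n_occupancy_records = nrow(occupancy),
    n_status_rows = nrow(statuses),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))

  result <- list(scenario = scenario, occupancy = occupancy,
                 thresholds = thresholds, suit_table = suit_table,
                 statuses = statuses, summary = summary_tab,
                 covariates = covariates, design = design, counts = counts,
                 fits = fits, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(result$occupancy, "occupancy.csv")
  w(result$suit_table, "pa_suitability.csv")
  w(result$statuses, "statuses.csv")
  w(result$summary$rows, "summary_table.csv")
  w(result$covariates, "covariates.csv")
  if (!is.null(result$design)) {
    w(cbind(pa_id = result$design$pa_ids, as.data.frame(result$design$X)),
      "design_matrix.csv")
    yaml::write_yaml(list(center = as.list(result$design$center),
                          scale = as.list(result$design$scale),
                          offsets = as.list(result$design$offsets)),
                     file.path(out_dir, "design_scaling.yaml"))
  }
  for (mode in names(result$counts))
    w(result$counts[[mode]], paste0("counts_", mode, ".csv"))
  for (mode in names(result$fits))
    if (!is.null(result$fits[[mode]]))
      w(result$fits[[mode]]$summary, paste0("fit_", mode, ".csv"))
  write_pas_geojson(result$scenario$pas, file.path(out_dir, "pas.geojson"))
  write_scenario_yaml(result$scenario$config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(refugia_report(result$summary, result$fits),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a plain-text report of the screening results
#'
#' Formats (no computation beyond rounding) the species summary table and the
#' posterior summaries of the two count models, with effect-direction marks
#' (`+` interval above zero, `-` below zero, `.` overlapping zero).
#'
#' @param summary A `refugia_summary` from [summarize_table()].
#' @param fits List with elements `in_situ` and `ex_situ` (each a
#'   `spatial_glmm_fit` or `NULL`).
#' @return Character vector of report lines.
#' @export
refugia_report <- function(summary, fits = list(in_situ = NULL,
                                                ex_situ = NULL)) {
  lines <- c("Refugia screening report",
             "========================", "",
             "Per-species classification of protected areas:", "")
  hdr <- sprintf("%-18s %9s %8s %10s %8s %8s", "species", "occupied",
                 "at_risk", "pct_at_risk", "in_situ", "ex_situ")
  lines <- c(lines, hdr)
  for (i in seq_len(nrow(summary$rows))) {
    r <- summary$rows[i, ]
    lines <- c(lines, sprintf("%-18s %9d %8d %10.1f %8d %8d", r$species_id,
                              r$n_occupied, r$n_at_risk, r$pct_at_risk,
                              r$n_in_situ, r$n_ex_situ))
  }
  a <- summary$averages
  lines <- c(lines,
             sprintf("%-18s %9.1f %8.1f %10.1f %8.1f %8.1f", "Average",
                     a["n_occupied"], a["n_at_risk"], a["pct_at_risk"],
                     a["n_in_situ"], a["n_ex_situ"]),
             "",
             sprintf("ex situ share of identified refugia: %s%%",
                     summary$pct_ex_situ_of_refugia),
             sprintf("mean per-species retention: %s%%",
                     summary$mean_retention_pct),
             sprintf("pooled retention: %s%%", summary$pooled_retention_pct))
  for (mode in c("in_situ", "ex_situ")) {
    title <- sprintf("%s count model", gsub("_", " ", mode))
    lines <- c(lines, "", title, strrep("-", nchar(title)))
    fit <- fits[[mode]]
    if (is.null(fit)) {
      lines <- c(lines, "not fitted")
      next
    }
    mark <- c(positive = "+", negative = "-", none = ".")
    s <- fit$summary
    for (i in seq_len(nrow(s)))
      lines <- c(lines, sprintf("%-22s %7.2f %6.2f [%7.2f, %7.2f]  %s",
                                s$parameter[i], s$mean[i], s$sd[i],
                                s$lower[i], s$upper[i],
                                mark[[s$significance[i]]]))
    if (!fit$converged) lines <- c(lines, "WARNING: non-converged")
  }
  lines
}
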