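mk_rec <- function(mc, mf, sid = "spA")
  data.frame(pa_id = "PA1", species_id = sid, max_current = mc, max_future = mf)

mk_thr <- function(tau, sid = "spA")
  structure(list(species_id = sid, tau = tau, n_occupied_cells = 10,
                 percentile = 10), class = "species_threshold")

test_that("classification follows the occupancy/threshold rules", {
  thr <- mk_thr(0.5)
  expect_equal(classify_pa(mk_rec(0.9, 0.8), TRUE, thr)$status, "in_situ")
  expect_equal(classify_pa(mk_rec(0.9, 0.3), TRUE, thr)$status, "at_risk")
  expect_equal(classify_pa(mk_rec(0.7, 0.6), FALSE, thr)$status, "ex_situ")
  # failing the current-period condition excludes an unoccupied PA
  expect_equal(classify_pa(mk_rec(0.4, 0.9), FALSE, thr)$status, "none")
  # boundary: meeting tau exactly counts as suitable
  expect_equal(classify_pa(mk_rec(0.5, 0.5), FALSE, thr)$status, "ex_situ")
  expect_error(classify_pa(mk_rec(0.9, 0.8, "spB"), TRUE, thr), "species mismatch")
})

test_that("occupancy overlay uses any positive-area intersection with occupied cells", {
  g <- grid_spec(4, 4, cell_size = 10)
  occ <- data.frame(cell_col = 2, cell_row = 3)
  expect_true(mark_occupied(pa_rect("a", 12, 23, 15, 26), occ, g))
  expect_false(mark_occupied(pa_rect("a", 12, 23, 15, 26),
                             occ[0, , drop = FALSE], g))
  # straddling one occupied and one unoccupied cell still counts
  expect_true(mark_occupied(pa_rect("b", 18, 22, 24, 26), occ, g))
  # adjacent cell only (zero-area edge contact with the occupied cell)
  expect_false(mark_occupied(pa_rect("c", 20, 20, 25, 25),
                             data.frame(cell_col = 1, cell_row = 2), g))
})

test_that("species summaries reproduce published worked examples", {
  r1 <- species_summary_row("A. annua", 192, 110, 82, 751)
  expect_equal(r1$pct_at_risk, 57.3)
  r2 <- species_summary_row("S. romanzoffiana", 13, 13, 0, 27)
  expect_equal(r2$pct_at_risk, 100.0)
  # no statuses at all: zero counts, missing percentage
  empty <- data.frame(pa_id = character(0), species_id = character(0),
                      occupied = logical(0), status = character(0))
  r3 <- summarize_species(empty)
  expect_equal(c(r3$n_occupied, r3$n_at_risk, r3$n_in_situ, r3$n_ex_situ),
               rep(0, 4))
  expect_true(is.na(r3$pct_at_risk))
  expect_error(species_summary_row("x", 5, 4, 2, 0), "must equal")
})

test_that("the summary table reproduces published averages and shares", {
  rows <- do.call(rbind, lapply(seq_len(12), function(i)
    summarize_species(example_species_counts()[i, ])))
  tab <- summarize_table(rows)
  expect_equal(unname(tab$averages),
               c(300.8, 162.7, 58.9, 138.2, 349.5))
  expect_equal(tab$pct_ex_situ_of_refugia, 72)
  expect_equal(tab$mean_retention_pct, 41.1)
  expect_equal(tab$pooled_retention_pct, 46)
  # a single row averages to itself
  one <- summarize_table(rows[1, ])
  expect_equal(unname(one$averages[c(1, 2, 4, 5)]),
               c(192, 110, 82, 751))
})

test_that("per-PA species counts keep zeros and reconcile with species totals", {
  st <- data.frame(
    pa_id = rep(c("P1", "P2", "P3"), each = 3),
    species_id = rep(c("s1", "s2", "s3"), times = 3),
    occupied = c(FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE),
    status = c("ex_situ", "ex_situ", "none",
               "none", "none", "none",
               "ex_situ", "none", "in_situ"))
  cnt <- count_species_per_pa(st, "ex_situ")
  expect_equal(cnt$count[cnt$pa_id == "P1"], 2)
  expect_equal(cnt$count[cnt$pa_id == "P2"], 0)
  expect_equal(nrow(cnt), 3)
  # conservation identity against the per-species summaries
  per_species <- do.call(rbind, lapply(split(st, st$species_id), summarize_species))
  expect_equal(sum(cnt$count), sum(per_species$n_ex_situ))
  expect_equal(sum(count_species_per_pa(st, "in_situ")$count),
               sum(per_species$n_in_situ))
})

test_that("classification satisfies the partition and disjointness invariants on seeded scenarios", {
  for (seed in c(3, 17)) {
    res <- run_refugia_pipeline(small_grid(), small_config(seed = seed),
                                fit_models = FALSE, quiet = TRUE)
    st <- res$statuses
    for (row_i in seq_len(nrow(res$summary$rows))) {
      r <- res$summary$rows[row_i, ]
      expect_equal(r$n_occupied, r$n_at_risk + r$n_in_situ)
    }
    expect_true(all(!st$occupied[st$status == "ex_situ"]))
    expect_true(all(st$occupied[st$status %in% c("at_risk", "in_situ")]))
  }
})

test_that("raising the threshold never increases refugia counts", {
  res <- run_refugia_pipeline(small_grid(), small_config(seed = 5),
                              fit_models = FALSE, quiet = TRUE)
  sc <- res$scenario
  thr <- res$thresholds
  thr_hi <- lapply(thr, function(t) { t$tau <- min(1, t$tau + 0.1); t })
  st_lo <- res$statuses
  st_hi <- classify_refugia(res$suit_table, res$occupancy, sc$pas, sc$grid, thr_hi)
  n <- function(st, s) sum(st$status == s)
  expect_lte(n(st_hi, "in_situ"), n(st_lo, "in_situ"))
  expect_lte(n(st_hi, "ex_situ"), n(st_lo, "ex_situ"))
})
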