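#' Published refugia counts for twelve threatened British plants
#'
#' Per-species counts of National Nature Reserves and SSSIs classified as
#' occupied, at risk, in situ refugia and ex situ refugia in a national
#' screening of Britain's protected-area estate against 2080 climate
#' projections. Used as the worked example for the summary-table arithmetic:
#' feeding these counts through [summarize_species()] and [summarize_table()]
#' reproduces the published per-species at-risk percentages, column averages,
#' ex situ share of refugia and retention statistics.
#'
#' @return Data frame with `species_id`, `n_occupied`, `n_at_risk`,
#'   `n_in_situ`, `n_ex_situ` (12 rows).
#' @export
example_species_counts <- function() {
  data.frame(
    species_id = c("A. annua", "T. glabra", "C. alpinum", "C. ericetorum",
                   "D. octopetala", "G. angustifolia", "J. communis",
                   "M. maritima", "B. vivipara", "R. tripartitus",
                   "S. conica", "S. romanzoffiana"),
    n_occupied = c(192L, 295L, 63L, 200L, 87L, 545L, 1482L, 45L, 402L, 138L,
                   148L, 13L),
    n_at_risk = c(110L, 235L, 9L, 190L, 30L, 322L, 711L, 21L, 100L, 109L,
                  102L, 13L),
    n_in_situ = c(82L, 60L, 54L, 10L, 57L, 223L, 771L, 24L, 302L, 29L, 46L,
                  0L),
    n_ex_situ = c(751L, 283L, 109L, 202L, 40L, 1635L, 654L, 45L, 249L, 112L,
                  87L, 27L))
}
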