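summarize_grid <- function(grid) {
  total <- grid_total(grid)
  by_grade <- grid_copd(grid, "grade")
  by_sex <- grid_copd(grid, "sex")
  by_band <- grid_copd(grid, "band")
  b <- age_band(copd_ages())
  pop_band <- vapply(copd_age_bands(),
                     function(x) sum(grid$counts[b == x, , , ]), 0)
  pop_sex <- apply(grid$counts, 2, sum)
  count <- unname(c(sum(by_grade), by_grade, by_sex, by_band))
  population <- unname(c(total, rep(total, 3), pop_sex, pop_band))
  tibble::tibble(
    year = grid$year,
    stratum_type = c("all", rep("grade", 3), rep("sex", 2), rep("band", 4)),
    stratum = c("all", names(by_grade), names(by_sex), names(by_band)),
    count = count,
    population = population,
    prevalence_per_1000 = 1000 * count / population
  )
}

#' Run the full projection
#'
#' Initializes the base-year population and advances it through annual
#' cycles to the final year. Deterministic: identical inputs give identical
#' output.
#'
#' @param demog `demography_model`.
#' @param rt Calibrated `rate_tables` (see [calibrate_rate_tables()]).
#' @param start_year,end_year Projection span (default 2005-2025).
#' @param keep_grids Keep the full `state_grid` snapshot for every year
#'   (default `FALSE`: only the base and final year are retained).
#' @param order Within-year operation order passed to [step_year()].
#' @return A `projection_result`: list with `summary` (tidy tibble of
#'   per-year counts and prevalence per 1000, overall and by GOLD grade, sex
#'   and age band), `ledgers` (one `cycle_ledger` per cycle), and `grids`.
#' @examples
#' \donttest{
#' demog <- synthesize_demography()
#' rt <- calibrate_rate_tables(default_rate_tables(), demog)
#' proj <- run_projection(demog, rt)
#' proj
#' }
#' @export
run_projection <- function(demog, rt, start_year = 2005, end_year = 2025,
                           keep_grids = FALSE,
                           order = c("mortality", "smoking", "incidence", "gold")) {
  if (start_year >= end_year) {
    copd_error(sprintf("start_year (%d) must precede end_year (%d)",
                       start_year, end_year), class = "copd_validation_error")
  }
  grid <- initialize_2005(demog, rt)
  grid$year <- as.integer(start_year)
  rows <- list(summarize_grid(grid))
  ledgers <- list()
  grids <- list(grid)
  for (y in seq_len(end_year - start_year)) {
    stepped <- step_year(grid, demog, rt, order = order)
    grid <- stepped$grid
    ledgers[[y]] <- stepped$ledger
    rows[[y + 1]] <- summarize_grid(grid)
    grids[[y + 1]] <- grid
  }
  if (!keep_grids) grids <- grids[c(1, length(grids))]
  structure(list(summary = do.call(rbind, rows), ledgers = ledgers,
                 grids = grids, start_year = start_year, end_year = end_year),
            class = "projection_result")
}

#' Extract one projected quantity from a projection result
#'
#' @param proj `projection_result`.
#' @param year Calendar year.
#' @param stratum Stratum label: `"all"`, a grade (`"G1"`, `"G2"`, `"G34"`),
#'   a sex, or an age band.
#' @param what `"prevalence_per_1000"`, `"count"` or `"population"`.
#' @return Scalar value.
#' @export
projection_value <- function(proj, year, stratum = "all",
                             what = c("prevalence_per_1000", "count", "population")) {
  what <- match.arg(what)
  s <- proj$summary
  row <- s[s$year == year & s$stratum == stratum, ]
  if (nrow(row) != 1) {
    copd_error(sprintf("no unique row for year %s, stratum '%s'", year, stratum))
  }
  unname(row[[what]])
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d-%d\n", x$start_year, x$end_year))
  print(projection_table(x))
  invisible(x)
}

#' Wide per-grade projection table
#'
#' The headline report: for each report year, the number of COPD cases and
#' the prevalence per 1000 overall and by GOLD grade.
#'
#' @param proj `projection_result`.
#' @param years Report years; default every 5th year of the span.
#' @return A tibble with columns `year`, `cases`, `prev_all`, `prev_G1`,
#'   `prev_G2`, `prev_G34`.
#' @export
projection_table <- function(proj, years = NULL) {
  years <- years %||% seq(proj$start_year, proj$end_year, by = 5)
  tibble::tibble(
    year = years,
    cases = vapply(years, function(y) projection_value(proj, y, "all", "count"), 0),
    prev_all = vapply(years, function(y) projection_value(proj, y, "all"), 0),
    prev_G1 = vapply(years, function(y) projection_value(proj, y, "G1"), 0),
    prev_G2 = vapply(years, function(y) projection_value(proj, y, "G2"), 0),
    prev_G34 = vapply(years, function(y) projection_value(proj, y, "G34"), 0)
  )
}

#' Write projection outputs to delimited files
#'
#' Writes the tidy per-year summary
#' (`year,stratum_type,stratum,count,prevalence_per_1000`) and the wide
#' per-grade report table.
#'
#' @param proj `projection_result`.
#' @param tidy_path Path of the tidy CSV.
#' @param wide_path Path of the wide per-grade CSV.
#' @param years Report years for the wide table.
#' @return Invisibly, `proj`.
#' @export
write_projection <- function(proj, tidy_path, wide_path = NULL, years = NULL) {
  s <- proj$summary[, c("year", "stratum_type", "stratum", "count",
                        "prevalence_per_1000")]
  utils::write.csv(s, tidy_path, row.names = FALSE, quote = FALSE)
  if (!is.null(wide_path)) {
    utils::write.csv(projection_table(proj, years), wide_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(proj)
}
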