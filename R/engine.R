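#' Construct a population state grid
#'
#' The model's entire population state for one calendar year: person counts
#' (continuous, fractional persons — the model is deterministic, not a
#' microsimulation) indexed by single-year age 45-110, sex, smoking status
#' and health state (`noCOPD` or GOLD grade `G1`, `G2`, `G34`). Death is a
#' flow recorded in the cycle ledger, not a compartment.
#'
#' @param year Calendar year of the snapshot.
#' @param counts 4-dimensional array `[age, sex, smoking, state]`; default
#'   all-zero.
#' @return A list of class `state_grid` with elements `year` and `counts`.
#' @export
state_grid <- function(year, counts = NULL) {
  dn <- list(age = as.character(copd_ages()), sex = copd_sexes(),
             smoking = copd_smoking(), state = copd_states())
  if (is.null(counts)) {
    counts <- array(0, dim = c(66, 2, 3, 4), dimnames = dn)
  }
  if (!is.array(counts) || !identical(dim(counts), c(66L, 2L, 3L, 4L))) {
    copd_error("counts must be a 66 x 2 x 3 x 4 array [age, sex, smoking, state]",
               class = "copd_validation_error")
  }
  dimnames(counts) <- dn
  if (any(!is.finite(counts)) || any(counts < 0)) {
    copd_error("state grid counts must be finite and non-negative",
               class = "copd_validation_error")
  }
  structure(list(year = as.integer(year), counts = counts), class = "state_grid")
}

#' Total persons in a state grid
#' @param grid A `state_grid`.
#' @return Scalar total count (all cells).
#' @export
grid_total <- function(grid) sum(grid$counts)

#' COPD cases in a state grid
#' @param grid A `state_grid`.
#' @param by `"all"`, `"grade"`, `"sex"` or `"band"`.
#' @return Scalar, or a named vector of counts by the requested stratum.
#' @export
grid_copd <- function(grid, by = c("all", "grade", "sex", "band")) {
  by <- match.arg(by)
  cc <- grid$counts[, , , copd_grades(), drop = FALSE]
  switch(by,
    all = sum(cc),
    grade = apply(cc, 4, sum),
    sex = apply(cc, 2, sum),
    band = {
      b <- age_band(copd_ages())
      vapply(copd_age_bands(), function(x) sum(cc[b == x, , , ]), 0)
    })
}

#' @export
print.state_grid <- function(x, ...) {
  cat(sprintf("<state_grid> year %d: %s persons, %s with COPD (%.2f/1000)\n",
              x$year, format(round(grid_total(x)), big.mark = ","),
              format(round(grid_copd(x)), big.mark = ","),
              1000 * grid_copd(x) / grid_total(x)))
  invisible(x)
}

# split one (age, sex) population count across smoking x state cells using
# the baseline prevalence of its age band and the non-COPD smoking structure
split_cell <- function(n, band, sex, rt) {
  cell <- matrix(0, 3, 4, dimnames = list(copd_smoking(), copd_states()))
  prev <- rt$baseline_prevalence[band, sex, , ]        # smoking x grade
  p_copd <- sum(prev)
  if (p_copd > 1) {
    copd_error(sprintf("prevalence exceeds 1 in stratum (%s, %s)", band, sex),
               class = "copd_validation_error")
  }
  cell[, copd_grades()] <- n * prev
  cell[, "noCOPD"] <- n * (1 - p_copd) * rt$smoking_structure[band, sex, ]
  cell
}

#' Initialize the base-year (2005) population state
#'
#' Splits each (age, sex) cell of the demographic pyramid across smoking
#' status and health state: the COPD share of the cell follows the
#' calibrated baseline prevalence of its age band, and the non-COPD
#' remainder is distributed over smoking status by the non-COPD smoking
#' structure. The grid total equals the pyramid total exactly.
#'
#' @param demog `demography_model`.
#' @param rt Calibrated `rate_tables`.
#' @param smoking_structure Optional override of `rt$smoking_structure`.
#' @return A `state_grid` for 2005.
#' @export
initialize_2005 <- function(demog, rt, smoking_structure = NULL) {
  if (!is.null(smoking_structure)) rt$smoking_structure <- smoking_structure
  validate_rate_tables(rt, calibrated = TRUE)
  g <- state_grid(2005L)
  bands <- as.character(age_band(copd_ages()))
  for (i in seq_along(copd_ages())) {
    for (s in copd_sexes()) {
      g$counts[i, s, , ] <- split_cell(demog$pyramid_2005[i, s], bands[i], s, rt)
    }
  }
  g
}

#' Apply one year of mortality
#'
#' Each cell loses the fraction `min(1, q_base(age, sex) * RR_smoking *
#' RR_grade)` of its mass, combining background death probabilities with the
#' multiplicative excess risks of smoking status and COPD severity (no COPD
#' has grade RR 1). The terminal age has `q_base = 1`, which closes the age
#' ladder.
#'
#' @param grid `state_grid`.
#' @param demog `demography_model` (supplies `base_mortality`).
#' @param rt `rate_tables` (supplies `rr_smoking`, `rr_gold`).
#' @return List `grid` (survivors) and `deaths` (removed counts, same shape).
#' @export
apply_mortality <- function(grid, demog, rt) {
  rr_state <- c(noCOPD = 1, rt$rr_gold)
  q <- outer(outer(demog$base_mortality, rt$rr_smoking), rr_state)
  q <- pmin(q, 1)
  deaths <- grid$counts * q
  grid$counts <- grid$counts - deaths
  list(grid = grid, deaths = deaths)
}

smoking_matrix <- function(quit, relapse, initiate = 0) {
  matrix(c(1 - initiate, 0,           initiate,
           0,            1 - relapse, relapse,
           0,            quit,        1 - quit),
         nrow = 3, byrow = TRUE,
         dimnames = list(from = copd_smoking(), to = copd_smoking()))
}

#' Apply one year of smoking-status transitions
#'
#' Within each (age, sex, state) slice, mass moves between never / ex /
#' current smoking according to the population-appropriate annual
#' probabilities: among persons with COPD, quitting 4.7% and relapse 2.6%
#' (no initiation); among persons without COPD, quitting 3.6%, relapse 6.5%
#' and initiation 0.8% (never to current). Slice totals are conserved
#' exactly.
#'
#' @param grid `state_grid`.
#' @param rt `rate_tables`.
#' @return List `grid` and `ledger` (quitters, relapsers, initiators).
#' @export
apply_smoking_transitions <- function(grid, rt) {
  M_no <- smoking_matrix(rt$smoking_transition_nocopd["quit"],
                         rt$smoking_transition_nocopd["relapse"],
                         rt$smoking_transition_nocopd["initiate"])
  M_copd <- smoking_matrix(rt$smoking_transition_copd["quit"],
                           rt$smoking_transition_copd["relapse"])
  ledger <- c(quitters = 0, relapsers = 0, initiators = 0)
  for (st in copd_states()) {
    M <- if (st == "noCOPD") M_no else M_copd
    slab <- grid$counts[, , , st]                       # age x sex x smoking
    flat <- matrix(slab, ncol = 3)                      # rows: (age, sex)
    ledger["quitters"] <- ledger["quitters"] + sum(flat[, 3]) * M["current", "ex"]
    ledger["relapsers"] <- ledger["relapsers"] + sum(flat[, 2]) * M["ex", "current"]
    ledger["initiators"] <- ledger["initiators"] + sum(flat[, 1]) * M["never", "current"]
    grid$counts[, , , st] <- array(flat %*% M, dim = dim(slab))
  }
  list(grid = grid, ledger = ledger)
}

# allocate a demand `total` across strata with availability `avail`,
# targeting shares `mix`; shortfall in capped strata is reallocated
# proportionally to the remaining target shares (water-filling).
allocate_with_mix <- function(total, avail, mix) {
  take <- numeric(length(avail))
  total <- min(total, sum(avail))
  remaining <- total
  open <- avail > 0 & mix > 0
  while (remaining > 1e-12 && any(open)) {
    share <- mix * open
    if (sum(share) == 0) break
    want <- remaining * share / sum(share)
    got <- pmin(want, avail - take)
    take <- take + got
    remaining <- remaining - sum(got)
    open <- open & (avail - take > 1e-12)
  }
  if (remaining > 1e-12) {      # mix exhausted; spread over any capacity left
    got <- pmin(remaining * (avail - take) / sum(avail - take), avail - take)
    take <- take + got
  }
  take
}

#' Apply one year of COPD incidence
#'
#' In each (age, sex) stratum the incident mass is `incidence_rate(sex) *
#' age_multiplier(age) * non-COPD count`. Incident cases are drawn from the
#' no-COPD smoking cells so the diagnosis-time smoking mix matches the
#' incident smoking distribution (63.5% current, 32.9% ex smokers), with
#' proportional reallocation when a stratum lacks enough at-risk persons;
#' they are deposited into GOLD grades by the incident grade distribution.
#' Cases keep the age, sex and smoking status of their source cell. Totals
#' are conserved.
#'
#' @param grid `state_grid`.
#' @param rt `rate_tables`.
#' @return List `grid` and `ledger` (incident cases by smoking status, plus
#'   `shortfall_reallocated`).
#' @export
apply_incidence <- function(grid, rt) {
  mult <- ifelse(copd_ages() >= 65, rt$incidence_age_multiplier["ge65"],
                 rt$incidence_age_multiplier["lt65"])
  mix <- rt$incident_smoking_dist[copd_smoking()]
  inc_by_smoking <- c(never = 0, ex = 0, current = 0)
  realloc <- 0
  for (i in seq_along(copd_ages())) {
    for (s in copd_sexes()) {
      avail <- grid$counts[i, s, , "noCOPD"]
      total <- rt$incidence_rate[s] * mult[i] * sum(avail)
      if (total <= 0) next
      take <- allocate_with_mix(total, avail, mix)
      realloc <- realloc + sum(pmax(min(total, sum(avail)) * mix - take, 0))
      grid$counts[i, s, , "noCOPD"] <- avail - take
      grid$counts[i, s, , copd_grades()] <-
        grid$counts[i, s, , copd_grades()] + outer(take, rt$incident_grade_dist)
      inc_by_smoking <- inc_by_smoking + take
    }
  }
  list(grid = grid,
       ledger = list(incident_by_smoking = inc_by_smoking,
                     incident_total = sum(inc_by_smoking),
                     shortfall_reallocated = realloc))
}

#' Apply one year of GOLD-grade transitions
#'
#' Within each (age, sex, smoking) slice the (G1, G2, G34) sub-vector is
#' propagated by the annual row-stochastic transition matrix. There is no
#' remission to no COPD, and the no-COPD cells are untouched; COPD totals
#' are conserved per slice.
#'
#' @param grid `state_grid`.
#' @param rt `rate_tables`.
#' @return List `grid` and `ledger` (`worsened`, `improved` person-moves).
#' @export
apply_gold_transitions <- function(grid, rt) {
  P <- rt$gold_transition
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    copd_error("gold_transition: row not stochastic", class = "copd_validation_error")
  }
  slab <- grid$counts[, , , copd_grades()]
  flat <- matrix(slab, ncol = 3)                    # rows: (age, sex, smoking)
  up <- P; up[lower.tri(up, diag = TRUE)] <- 0      # to-more-severe moves
  down <- P; down[upper.tri(down, diag = TRUE)] <- 0
  ledger <- c(worsened = sum(flat %*% up), improved = sum(flat %*% down))
  grid$counts[, , , copd_grades()] <- array(flat %*% P, dim = dim(slab))
  list(grid = grid, ledger = ledger)
}

#' Age the population one year and admit the entrant cohort
#'
#' Shifts every age index up by one (the terminal age was emptied by the
#' mortality step's probability-1 rule; any residual mass there is retained
#' in the absorbing top age), increments the calendar year, and admits the
#' entrant cohort — persons who were 44 the previous year — at age 45, split
#' across smoking and health states by the 45-54 band baseline prevalence
#' and non-COPD smoking structure.
#'
#' @param grid `state_grid`.
#' @param demog `demography_model` (entrant cohort sizes).
#' @param rt Calibrated `rate_tables`.
#' @return List `grid` (next year) and `entrants` (persons admitted).
#' @export
age_and_enter <- function(grid, demog, rt) {
  yr <- grid$year + 1L
  if (!as.character(yr) %in% rownames(demog$entrants)) {
    copd_error(sprintf("no entrant cohort defined for year %d", yr))
  }
  n_age <- length(copd_ages())
  shifted <- grid$counts
  shifted[2:n_age, , , ] <- grid$counts[1:(n_age - 1), , , ]
  shifted[n_age, , , ] <- shifted[n_age, , , ] + grid$counts[n_age, , , ]
  shifted[1, , , ] <- 0
  entrants <- 0
  for (s in copd_sexes()) {
    e <- demog$entrants[as.character(yr), s]
    shifted[1, s, , ] <- split_cell(e, "45-54", s, rt)
    entrants <- entrants + e
  }
  list(grid = state_grid(yr, shifted), entrants = entrants)
}

#' Advance the model by one annual cycle
#'
#' Composes the five within-year operations in the model's fixed order:
#' mortality, smoking transitions, incidence, GOLD transitions, then ageing
#' with entrant arrival. The order is part of the model contract (deaths are
#' drawn from the start-of-year pool; incident cases cannot progress in
#' their diagnosis year); it can be permuted for exploration via `order`,
#' with ageing always last.
#'
#' @param grid `state_grid` for year y.
#' @param demog `demography_model`.
#' @param rt Calibrated `rate_tables`.
#' @param order Permutation of `c("mortality", "smoking", "incidence",
#'   "gold")` controlling the within-year sequence.
#' @return List `grid` (year y+1) and `ledger`, a `cycle_ledger` whose
#'   bookkeeping reconciles exactly: start total - deaths + entrants = end
#'   total.
#' @export
step_year <- function(grid, demog, rt,
                      order = c("mortality", "smoking", "incidence", "gold")) {
  if (!setequal(order, c("mortality", "smoking", "incidence", "gold"))) {
    copd_error("order must be a permutation of mortality, smoking, incidence, gold")
  }
  start_total <- grid_total(grid)
  ledger <- list(deaths = 0, incident_cases = 0, quitters = 0, relapsers = 0,
                 initiators = 0, grade_moves = c(worsened = 0, improved = 0),
                 entrants = 0)
  for (op in order) {
    if (op == "mortality") {
      r <- apply_mortality(grid, demog, rt)
      ledger$deaths <- sum(r$deaths)
      ledger$deaths_by_state <- apply(r$deaths, 4, sum)
    } else if (op == "smoking") {
      r <- apply_smoking_transitions(grid, rt)
      ledger$quitters <- unname(r$ledger["quitters"])
      ledger$relapsers <- unname(r$ledger["relapsers"])
      ledger$initiators <- unname(r$ledger["initiators"])
    } else if (op == "incidence") {
      r <- apply_incidence(grid, rt)
      ledger$incident_cases <- r$ledger$incident_total
    } else {
      r <- apply_gold_transitions(grid, rt)
      ledger$grade_moves <- r$ledger
    }
    grid <- r$grid
  }
  r <- age_and_enter(grid, demog, rt)
  grid <- r$grid
  ledger$entrants <- r$entrants
  ledger$start_total <- start_total
  ledger$end_total <- grid_total(grid)
  class(ledger) <- "cycle_ledger"
  list(grid = grid, ledger = ledger)
}

#' @export
print.cycle_ledger <- function(x, ...) {
  cat(sprintf("<cycle_ledger> deaths %.0f, incident %.0f, entrants %.0f; %0.f -> %.0f\n",
              x$deaths, x$incident_cases, x$entrants, x$start_total, x$end_total))
  invisible(x)
}
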