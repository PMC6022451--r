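#' Bundle the editable model inputs
#'
#' A sensitivity scenario perturbs the model *inputs*, some of which exist
#' upstream of the rate tables (the prevalence marginals feeding the IPF
#' calibration, and the overall prevalence scale). This container groups
#' everything a scenario may edit: the prevalence marginals, the scalar rate
#' tables, and a baseline-prevalence scale factor.
#'
#' @param rt Scalar `rate_tables` (uncalibrated is fine).
#' @param marginals `prevalence_marginals`.
#' @param prevalence_scale Multiplier on the calibrated baseline prevalence.
#' @param smoking_structure Non-COPD smoking structure.
#' @return List of class `model_inputs`.
#' @export
model_inputs <- function(rt = default_rate_tables(),
                         marginals = default_prevalence_marginals(),
                         prevalence_scale = 1,
                         smoking_structure = default_smoking_structure()) {
  structure(list(rt = rt, marginals = marginals,
                 prevalence_scale = prevalence_scale,
                 smoking_structure = smoking_structure),
            class = "model_inputs")
}

#' Define a sensitivity scenario
#'
#' A named, declarative perturbation of the model inputs: a list of edits,
#' each addressing one input by path and applying one of the edit kinds
#' `multiply` or `set`. Distribution edits may carry
#' `renormalize = "proportional"`, meaning the *unedited* components are
#' rescaled proportionally so the distribution sums to 1 again.
#'
#' Valid edit paths: `prevalence_scale`, `marginals.grade_dist`,
#' `marginals.smoking_dist`, `marginals.age_dist`, and any `rt.<field>`
#' (optionally with a named element, e.g. `rt.incidence_rate.female`), plus
#' two structured shorthands: `rt.gold_to_worse` (sets both to-next-worse
#' entries of the GOLD matrix, returning the freed mass to the diagonal) and
#' `rt.smoking_all` (sets every smoking-transition probability).
#'
#' @param name Scenario label.
#' @param edits List of edits, each `list(path =, kind =, value =,
#'   renormalize = NULL)`.
#' @return List of class `scenario`.
#' @export
scenario <- function(name, edits = list()) {
  for (e in edits) {
    if (is.null(e$path) || is.null(e$kind) || is.null(e$value) ||
        !e$kind %in% c("multiply", "set")) {
      copd_error("each edit needs a path, a kind ('multiply' or 'set') and a value",
                 class = "copd_validation_error")
    }
  }
  structure(list(name = name, edits = edits), class = "scenario")
}

apply_edit <- function(inputs, edit) {
  parts <- strsplit(edit$path, ".", fixed = TRUE)[[1]]
  root <- parts[1]
  apply_kind <- function(old, value) {
    if (edit$kind == "multiply") old * value else value
  }
  if (root == "prevalence_scale") {
    inputs$prevalence_scale <- apply_kind(inputs$prevalence_scale, edit$value)
    return(inputs)
  }
  if (root == "marginals") {
    field <- parts[2]
    if (!field %in% names(inputs$marginals)) {
      copd_error(sprintf("scenario edit path not found: %s", edit$path),
                 class = "copd_validation_error")
    }
    inputs$marginals[[field]] <- apply_kind(inputs$marginals[[field]], edit$value)
    return(inputs)
  }
  if (root != "rt") {
    copd_error(sprintf("scenario edit path not found: %s", edit$path),
               class = "copd_validation_error")
  }
  field <- parts[2]
  if (field == "gold_to_worse") {
    P <- inputs$rt$gold_transition
    for (g in c("G1", "G2")) {
      nxt <- c(G1 = "G2", G2 = "G34")[[g]]
      new <- apply_kind(P[g, nxt], edit$value)
      P[g, g] <- P[g, g] + P[g, nxt] - new     # freed mass to the diagonal
      P[g, nxt] <- new
    }
    inputs$rt$gold_transition <- P
    return(inputs)
  }
  if (field == "smoking_all") {
    inputs$rt$smoking_transition_copd[] <-
      apply_kind(inputs$rt$smoking_transition_copd, edit$value)
    inputs$rt$smoking_transition_nocopd[] <-
      apply_kind(inputs$rt$smoking_transition_nocopd, edit$value)
    return(inputs)
  }
  if (!field %in% rate_table_fields()) {
    copd_error(sprintf("scenario edit path not found: %s", edit$path),
               class = "copd_validation_error")
  }
  cur <- inputs$rt[[field]]
  if (length(parts) == 3) {                     # one named element
    el <- parts[3]
    if (!el %in% names(cur)) {
      copd_error(sprintf("scenario edit path not found: %s", edit$path),
                 class = "copd_validation_error")
    }
    new <- cur
    new[el] <- apply_kind(cur[el], edit$value)
    if (identical(edit$renormalize, "proportional")) {
      others <- setdiff(names(cur), el)
      rest <- 1 - sum(new[el])
      if (sum(cur[others]) > 0) new[others] <- cur[others] * rest / sum(cur[others])
    }
    inputs$rt[[field]] <- new
  } else {
    inputs$rt[[field]] <- apply_kind(cur, edit$value)
  }
  inputs
}

#' Apply a scenario to the model inputs
#'
#' Applies every edit in order and re-validates the resulting rate tables
#' and marginals.
#'
#' @param inputs `model_inputs`.
#' @param scn `scenario`.
#' @return Edited, re-validated `model_inputs`.
#' @export
apply_scenario <- function(inputs, scn) {
  for (e in scn$edits) inputs <- apply_edit(inputs, e)
  validate_rate_tables(inputs$rt)
  validate_marginals(inputs$marginals)
  inputs
}

#' The built-in one-way sensitivity scenarios
#'
#' The full battery of alternative hypotheses of the sensitivity analysis:
#' baseline prevalence varied by +/-10% (about the confidence limits of the
#' 2005 estimate); the alternative prevalent severity split (51.4 / 31.5 /
#' 17.1%) and a heavier-smoking prevalent mix; incidence varied by +/-10%;
#' female incidence raised to the male rate; the severe share of incident
#' cases raised to 14% (mild-moderate mass renormalized proportionally);
#' all to-next-worse GOLD transitions cut to 5% (freed mass returned to the
#' diagonal); the GOLD mortality relative risks at the lower and upper 95%
#' confidence bounds (defaults G1 [1.2, 1.6], G2 [1.8, 2.3], G34 [2.3,
#' 3.2]; the published source reports the point estimates only, so the
#' bounds are configurable package defaults); and frozen smoking status (all
#' smoking-transition probabilities zero).
#'
#' @param rr_gold_lower,rr_gold_upper Named vectors (G1, G2, G34) used by
#'   the two mortality confidence-bound scenarios.
#' @return List of 12 `scenario` objects.
#' @export
builtin_scenarios <- function(rr_gold_lower = c(G1 = 1.2, G2 = 1.8, G34 = 2.3),
                              rr_gold_upper = c(G1 = 1.6, G2 = 2.3, G34 = 3.2)) {
  e <- function(path, kind, value, renormalize = NULL) {
    list(path = path, kind = kind, value = value, renormalize = renormalize)
  }
  list(
    scenario("prevalence +10%",
             list(e("prevalence_scale", "multiply", 1.1))),
    scenario("prevalence -10%",
             list(e("prevalence_scale", "multiply", 0.9))),
    scenario("alternative prevalent severity distribution",
             list(e("marginals.grade_dist", "set",
                    c(G1 = 0.514, G2 = 0.315, G34 = 0.171)))),
    scenario("alternative prevalent smoking distribution",
             list(e("marginals.smoking_dist", "set",
                    c(never = 0.16, ex = 0.46, current = 0.38)))),
    scenario("incidence +10%",
             list(e("rt.incidence_rate", "multiply", 1.1))),
    scenario("incidence -10%",
             list(e("rt.incidence_rate", "multiply", 0.9))),
    scenario("female incidence reaches male",
             list(e("rt.incidence_rate.female", "set", 0.006))),
    scenario("severe incident share 14%",
             list(e("rt.incident_grade_dist.G34", "set", 0.14,
                    renormalize = "proportional"))),
    scenario("GOLD progression reduced to 5%",
             list(e("rt.gold_to_worse", "set", 0.05))),
    scenario("mortality RR lower 95% CI",
             list(e("rt.rr_gold", "set", rr_gold_lower))),
    scenario("mortality RR upper 95% CI",
             list(e("rt.rr_gold", "set", rr_gold_upper))),
    scenario("no change in smoking status",
             list(e("rt.smoking_all", "set", 0)))
  )
}

scenario_rate_tables <- function(inputs, demog, reference_rt) {
  rt <- calibrate_rate_tables(inputs$rt, demog,
                              marginals = inputs$marginals,
                              smoking_structure = inputs$smoking_structure,
                              prevalence_scale = inputs$prevalence_scale)
  # the incidence age profile is an input, not an outcome: never re-calibrated
  rt$incidence_age_multiplier <- reference_rt$incidence_age_multiplier
  validate_rate_tables(rt, calibrated = TRUE)
}

#' Run the one-way sensitivity analysis
#'
#' Runs the reference projection once and each scenario once, and reports
#' the final-year overall and severe (GOLD 3-4) prevalence per 1000 together
#' with the relative percent change versus the reference,
#' `(scenario - reference) / reference * 100`.
#'
#' @param demog `demography_model`.
#' @param scenarios List of `scenario` objects; default
#'   [builtin_scenarios()].
#' @param inputs Reference `model_inputs`.
#' @param start_year,end_year Projection span.
#' @return A `sensitivity_report`: tibble with columns `scenario`,
#'   `prev_per_1000`, `rel_change_pct`, `severe_prev_per_1000`,
#'   `severe_rel_change_pct`; the first row is the reference (changes 0).
#' @export
run_sensitivity <- function(demog, scenarios = builtin_scenarios(),
                            inputs = model_inputs(),
                            start_year = 2005, end_year = 2025) {
  ref_rt <- scenario_rate_tables(inputs, demog,
                                 reference_rt = calibrate_rate_tables(
                                   inputs$rt, demog,
                                   marginals = inputs$marginals,
                                   smoking_structure = inputs$smoking_structure))
  one_run <- function(rt) {
    p <- run_projection(demog, rt, start_year, end_year)
    list(all = projection_value(p, end_year, "all"),
         severe = projection_value(p, end_year, "G34"))
  }
  ref <- one_run(ref_rt)
  rows <- list(tibble::tibble(
    scenario = "reference", prev_per_1000 = ref$all, rel_change_pct = 0,
    severe_prev_per_1000 = ref$severe, severe_rel_change_pct = 0))
  for (scn in scenarios) {
    edited <- apply_scenario(inputs, scn)
    rt <- scenario_rate_tables(edited, demog, reference_rt = ref_rt)
    v <- one_run(rt)
    rows[[length(rows) + 1]] <- tibble::tibble(
      scenario = scn$name,
      prev_per_1000 = v$all,
      rel_change_pct = (v$all - ref$all) / ref$all * 100,
      severe_prev_per_1000 = v$severe,
      severe_rel_change_pct = (v$severe - ref$severe) / ref$severe * 100)
  }
  structure(do.call(rbind, rows), class = c("sensitivity_report",
                                            class(rows[[1]])))
}

#' Write a sensitivity report to a delimited file
#'
#' @param report `sensitivity_report`.
#' @param path Output CSV path (columns `scenario, prev_per_1000,
#'   rel_change_pct, severe_prev_per_1000, severe_rel_change_pct`).
#' @return Invisibly, `report`.
#' @export
write_sensitivity <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(report)
}
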