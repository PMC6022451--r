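# Programmatic fixtures shared across test files.

# a small synthetic population, cheap enough for repeated projections
small_demog <- function(total = 2e5, entrant_size = 6500) {
  synthesize_demography(synth_demography_params(total = total,
                                                entrant_size = entrant_size))
}

# demography with hand-set pyramid/mortality on the full grid
manual_demog <- function(pyramid_cells = list(), qx_flat = 0,
                         entrants = NULL) {
  ages <- as.character(45:110)
  pyr <- matrix(0, 66, 2, dimnames = list(ages, c("male", "female")))
  for (cell in pyramid_cells) pyr[as.character(cell$age), cell$sex] <- cell$count
  qx <- matrix(qx_flat, 66, 2, dimnames = list(ages, c("male", "female")))
  qx[66, ] <- 1
  if (is.null(entrants)) {
    entrants <- matrix(0, 21, 2, dimnames = list(as.character(2006:2026),
                                                 c("male", "female")))
  }
  demography_model(pyr, entrants, qx)
}

# rate tables with everything switched off, then selectively enabled;
# baseline prevalence concentrated where the test puts it
manual_rates <- function(prev_cells = list(),
                         incidence = c(male = 0, female = 0),
                         grade_dist = c(G1 = 1, G2 = 0, G34 = 0),
                         smoking_mix = c(never = 1, ex = 0, current = 0),
                         gold = diag(3),
                         quit_copd = 0, relapse_copd = 0,
                         quit_no = 0, relapse_no = 0, initiate_no = 0,
                         rr_gold = c(G1 = 1, G2 = 1, G34 = 1),
                         rr_smoking = c(never = 1, ex = 1, current = 1),
                         never_only_structure = TRUE) {
  dimnames(gold) <- list(from = c("G1", "G2", "G34"), to = c("G1", "G2", "G34"))
  rt <- default_rate_tables(list(
    incidence_rate = incidence,
    incident_grade_dist = grade_dist,
    incident_smoking_dist = smoking_mix,
    gold_transition = gold,
    smoking_transition_copd = c(quit = quit_copd, relapse = relapse_copd),
    smoking_transition_nocopd = c(quit = quit_no, relapse = relapse_no,
                                  initiate = initiate_no),
    rr_gold = rr_gold, rr_smoking = rr_smoking
  ))
  bp <- array(0, dim = c(4, 2, 3, 3),
              dimnames = list(band = c("45-54", "55-64", "65-74", "75+"),
                              sex = c("male", "female"),
                              smoking = c("never", "ex", "current"),
                              grade = c("G1", "G2", "G34")))
  for (cell in prev_cells) {
    bp[cell$band, cell$sex, cell$smoking, cell$grade] <- cell$p
  }
  rt$baseline_prevalence <- bp
  ss <- array(if (never_only_structure) 0 else 1 / 3, dim = c(4, 2, 3),
              dimnames = dimnames(bp)[1:3])
  if (never_only_structure) ss[, , "never"] <- 1
  rt$smoking_structure <- ss
  validate_rate_tables(rt, calibrated = TRUE)
}

# a randomly-filled but valid grid + rate tables + demography, for
# property-style conservation checks
random_valid_system <- function() {
  counts <- array(stats::runif(66 * 2 * 3 * 4, 0, 1000), dim = c(66, 2, 3, 4))
  grid <- state_grid(2005L, counts)
  qx <- matrix(stats::runif(132, 0, 0.3), 66, 2,
               dimnames = list(as.character(45:110), c("male", "female")))
  qx[66, ] <- 1
  pyr <- matrix(stats::runif(132, 0, 1000), 66, 2, dimnames = dimnames(qx))
  entrants <- matrix(stats::runif(42, 0, 5000), 21, 2,
                     dimnames = list(as.character(2006:2026), c("male", "female")))
  demog <- demography_model(pyr, entrants, qx)

  rdist <- function(n) { x <- stats::runif(n); x / sum(x) }
  gold <- t(apply(matrix(stats::runif(9), 3), 1, function(r) r / sum(r)))
  dimnames(gold) <- list(from = c("G1", "G2", "G34"), to = c("G1", "G2", "G34"))
  rt <- default_rate_tables(list(
    incidence_rate = c(male = stats::runif(1, 0, 0.05),
                       female = stats::runif(1, 0, 0.05)),
    incident_grade_dist = stats::setNames(rdist(3), c("G1", "G2", "G34")),
    incident_smoking_dist = stats::setNames(rdist(3), c("never", "ex", "current")),
    gold_transition = gold,
    smoking_transition_copd = c(quit = stats::runif(1, 0, 0.2),
                                relapse = stats::runif(1, 0, 0.2)),
    smoking_transition_nocopd = c(quit = stats::runif(1, 0, 0.2),
                                  relapse = stats::runif(1, 0, 0.2),
                                  initiate = stats::runif(1, 0, 0.1)),
    rr_gold = c(G1 = stats::runif(1, 0.5, 3), G2 = stats::runif(1, 0.5, 3),
                G34 = stats::runif(1, 0.5, 4)),
    rr_smoking = c(never = 1, ex = stats::runif(1, 0.5, 2),
                   current = stats::runif(1, 0.5, 3))
  ))
  bp <- array(stats::runif(72, 0, 0.05), dim = c(4, 2, 3, 3),
              dimnames = list(band = c("45-54", "55-64", "65-74", "75+"),
                              sex = c("male", "female"),
                              smoking = c("never", "ex", "current"),
                              grade = c("G1", "G2", "G34")))
  rt$baseline_prevalence <- bp
  ss <- array(NA_real_, dim = c(4, 2, 3), dimnames = dimnames(bp)[1:3])
  for (b in 1:4) for (s in 1:2) ss[b, s, ] <- rdist(3)
  rt$smoking_structure <- ss
  list(grid = grid, demog = demog, rt = validate_rate_tables(rt, calibrated = TRUE))
}

reference_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      demog <- synthesize_demography()
      rt <- calibrate_rate_tables(default_rate_tables(), demog)
      cache <<- list(demog = demog, rt = rt)
    }
    cache
  }
})
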