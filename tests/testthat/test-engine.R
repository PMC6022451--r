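test_that("initialization splits the pyramid by prevalence and smoking structure", {
  # zero prevalence: everyone is disease-free
  demog <- small_demog()
  rt0 <- manual_rates()
  g <- initialize_2005(demog, rt0)
  expect_equal(grid_copd(g), 0)
  expect_equal(grid_total(g), sum(demog$pyramid_2005))

  # reference inputs: published grade shares among COPD
  sys <- reference_system()
  g <- initialize_2005(sys$demog, sys$rt)
  expect_equal(grid_total(g), sum(sys$demog$pyramid_2005))
  shares <- grid_copd(g, "grade") / grid_copd(g)
  expect_equal(unname(shares), c(0.584, 0.374, 0.042), tolerance = 1e-3)

  # single populated cell, prevalence 0.1 all in G1
  demog1 <- manual_demog(list(list(age = 45, sex = "male", count = 1000)))
  rt1 <- manual_rates(list(list(band = "45-54", sex = "male",
                                smoking = "never", grade = "G1", p = 0.1)))
  g1 <- initialize_2005(demog1, rt1)
  expect_equal(g1$counts["45", "male", "never", "G1"], 100)
  expect_equal(g1$counts["45", "male", "never", "noCOPD"], 900)
})

test_that("mortality combines the base probability with both relative risks", {
  demog <- manual_demog(list(list(age = 50, sex = "male", count = 1000)),
                        qx_flat = 0.01)
  rt <- manual_rates(rr_gold = c(G1 = 1.4, G2 = 2.04, G34 = 2.7),
                     rr_smoking = c(never = 1, ex = 1.3, current = 2.0))
  g <- state_grid(2005L)
  g$counts["50", "male", "never", "G2"] <- 1000
  out <- apply_mortality(g, demog, rt)
  expect_equal(sum(out$deaths), 1000 * 0.01 * 2.04)
  expect_equal(out$grid$counts["50", "male", "never", "G2"], 1000 * (1 - 0.0204))

  # null mortality leaves the grid untouched
  demog0 <- manual_demog(qx_flat = 0)
  out0 <- apply_mortality(g, demog0, rt)
  expect_equal(out0$grid$counts, g$counts)
  expect_equal(sum(out0$deaths), 0)

  # the combined probability is capped at 1 and the cell is emptied
  demog9 <- manual_demog(qx_flat = 0.9)
  g2 <- state_grid(2005L)
  g2$counts["50", "male", "current", "G34"] <- 500   # 0.9 * 2.0 * 2.7 > 1
  out2 <- apply_mortality(g2, demog9, rt)
  expect_equal(sum(out2$deaths), 500)
  expect_equal(grid_total(out2$grid), 0)
})

test_that("smoking transitions move the published annual fractions", {
  rt <- default_rate_tables()
  rt$baseline_prevalence <- manual_rates()$baseline_prevalence
  rt$smoking_structure <- manual_rates()$smoking_structure

  g <- state_grid(2005L)
  g$counts["60", "male", "current", "noCOPD"] <- 1000
  out <- apply_smoking_transitions(g, rt)
  expect_equal(out$grid$counts["60", "male", "ex", "noCOPD"], 36)
  expect_equal(out$grid$counts["60", "male", "current", "noCOPD"], 964)

  g <- state_grid(2005L)
  g$counts["60", "female", "ex", "G2"] <- 1000
  out <- apply_smoking_transitions(g, rt)
  expect_equal(out$grid$counts["60", "female", "current", "G2"], 26)

  # never-smokers with COPD cannot initiate
  g <- state_grid(2005L)
  g$counts["60", "female", "never", "G1"] <- 1000
  out <- apply_smoking_transitions(g, rt)
  expect_equal(out$grid$counts["60", "female", "never", "G1"], 1000)

  # zero probabilities: identity
  rt0 <- manual_rates()
  g$counts["60", "male", "current", "noCOPD"] <- 500
  out0 <- apply_smoking_transitions(g, rt0)
  expect_equal(out0$grid$counts, g$counts)

  # slice totals conserved under the defaults
  sys <- reference_system()
  g <- initialize_2005(sys$demog, sys$rt)
  out <- apply_smoking_transitions(g, sys$rt)
  expect_equal(apply(out$grid$counts, c(1, 2, 4), sum),
               apply(g$counts, c(1, 2, 4), sum), tolerance = 1e-12)
})

test_that("incidence draws the published rates and diagnosis mixes", {
  rt <- manual_rates(incidence = c(male = 0.006, female = 0.003),
                     grade_dist = c(G1 = 0.5816, G2 = 0.3724, G34 = 0.046),
                     smoking_mix = c(never = 0.036, ex = 0.329, current = 0.635))
  g <- state_grid(2005L)
  g$counts["50", "male", , "noCOPD"] <- c(30000, 30000, 40000)  # 100k men
  out <- apply_incidence(g, rt)
  expect_equal(out$ledger$incident_total, 600)
  expect_equal(unname(out$ledger$incident_by_smoking),
               600 * c(0.036, 0.329, 0.635))
  # grade deposition: 4.6% of incident cases arrive severe
  newly <- apply(out$grid$counts[, , , c("G1", "G2", "G34")], 4, sum)
  expect_equal(unname(newly["G34"]), 600 * 0.046)

  # zero rates: identity
  out0 <- apply_incidence(g, manual_rates())
  expect_equal(out0$grid$counts, g$counts)
  expect_equal(out0$ledger$incident_total, 0)
})

test_that("incident smoking demand beyond a stratum is reallocated, conserving totals", {
  rt <- manual_rates(incidence = c(male = 0.5, female = 0),
                     grade_dist = c(G1 = 1, G2 = 0, G34 = 0),
                     smoking_mix = c(never = 0, ex = 0, current = 1))
  g <- state_grid(2005L)
  # only 100 current smokers available but demand is 0.5 * 1100 = 550
  g$counts["50", "male", , "noCOPD"] <- c(1000, 0, 100)
  out <- apply_incidence(g, rt)
  expect_equal(out$ledger$incident_total, 550)
  expect_equal(unname(out$ledger$incident_by_smoking["current"]), 100)
  expect_equal(unname(out$ledger$incident_by_smoking["never"]), 450)
  expect_equal(grid_total(out$grid), grid_total(g))
})

test_that("GOLD transitions propagate the severity ladder and conserve cases", {
  g <- state_grid(2005L)
  g$counts["70", "female", "ex", "G1"] <- 1000

  # identity matrix: no movement
  out <- apply_gold_transitions(g, manual_rates())
  expect_equal(out$grid$counts, g$counts)

  # default matrix: 15% of a pure-G1 slice reaches G2 in one cycle
  rt <- default_rate_tables()
  out <- apply_gold_transitions(g, rt)
  expect_equal(out$grid$counts["70", "female", "ex", "G2"], 150)
  expect_equal(out$grid$counts["70", "female", "ex", "G1"], 850)

  # the reduced-progression variant sends only 5%
  slow <- rt
  slow$gold_transition <- matrix(c(0.95, 0.05, 0, 0.05, 0.90, 0.05, 0, 0.05, 0.95),
                                 3, 3, byrow = TRUE,
                                 dimnames = dimnames(rt$gold_transition))
  out <- apply_gold_transitions(g, slow)
  expect_equal(out$grid$counts["70", "female", "ex", "G2"], 50)

  # one-step matrix-vector oracle on a mixed slice
  v <- c(G1 = 300, G2 = 200, G34 = 50)
  g2 <- state_grid(2005L)
  g2$counts["55", "male", "current", c("G1", "G2", "G34")] <- v
  out2 <- apply_gold_transitions(g2, rt)
  expect_equal(out2$grid$counts["55", "male", "current", c("G1", "G2", "G34")],
               drop(v %*% rt$gold_transition), tolerance = 1e-12)
  expect_equal(grid_copd(out2$grid), sum(v))

  bad <- rt
  bad$gold_transition[1, 1] <- 0.5
  expect_error(apply_gold_transitions(g, bad), "row not stochastic")
})

test_that("ageing shifts every cohort and admits entrants at 45", {
  demog1 <- manual_demog(list(list(age = 45, sex = "male", count = 1000)))
  rt1 <- manual_rates(list(list(band = "45-54", sex = "male",
                                smoking = "never", grade = "G1", p = 0.05)))
  g <- initialize_2005(demog1, rt1)

  # zero entrants: a pure shift
  out <- age_and_enter(g, demog1, rt1)
  expect_equal(out$grid$year, 2006L)
  expect_equal(grid_total(out$grid), 1000)
  expect_equal(sum(out$grid$counts["46", , , ]), 1000)
  expect_equal(out$entrants, 0)

  # 1000 entrants at 5% all-G1 prevalence: 50 arrive with COPD
  demog2 <- manual_demog(list(list(age = 45, sex = "male", count = 1000)),
                         entrants = matrix(c(1000, 0), 1, 2,
                                           dimnames = list("2006",
                                                           c("male", "female"))))
  out2 <- age_and_enter(g, demog2, rt1)
  expect_equal(out2$grid$counts["45", "male", "never", "G1"], 50)
  expect_equal(out2$grid$counts["45", "male", "never", "noCOPD"], 950)

  # year counter and missing entrant year
  g24 <- g; g24$year <- 2024L
  expect_equal(age_and_enter(g24, demog1, rt1)$grid$year, 2025L)
  g26 <- g; g26$year <- 2026L
  expect_error(age_and_enter(g26, demog1, rt1), "no entrant cohort.*2027")
})

test_that("a full cycle with all rates off is the identity on counts", {
  demog <- manual_demog(list(list(age = 50, sex = "female", count = 800)))
  rt <- manual_rates(list(list(band = "45-54", sex = "female",
                               smoking = "never", grade = "G2", p = 0.25)))
  g <- initialize_2005(demog, rt)
  out <- step_year(g, demog, rt)
  expect_equal(grid_total(out$grid), 800)
  expect_equal(grid_copd(out$grid), 200)
  expect_equal(out$ledger$deaths, 0)
  expect_equal(out$ledger$entrants, 0)
  expect_equal(sum(out$grid$counts["51", , , ]), 800)  # aged by one year
})

test_that("reference cycles reproduce the published upward prevalence trend", {
  # The baseline case mix is old (29.5% aged 75+) and carries large mortality
  # multipliers, so the very first cycle sheds more cases than incidence and
  # entrants replace; from then on inflow wins and prevalence rises steadily,
  # matching the published trajectory shape.
  sys <- reference_system()
  proj <- run_projection(sys$demog, sys$rt)
  s <- subset(proj$summary, stratum == "all")
  prev <- s$prevalence_per_1000[order(s$year)]
  expect_true(all(diff(prev[-1]) > 0))
  expect_gt(prev[21], prev[1])
  expect_gt(s$count[s$year == 2025], s$count[s$year == 2005])
  # first-cycle bookkeeping: the case flows explain the net change exactly
  g <- initialize_2005(sys$demog, sys$rt)
  out <- step_year(g, sys$demog, sys$rt)
  l <- out$ledger
  copd_deaths <- sum(l$deaths_by_state[c("G1", "G2", "G34")])
  expect_equal(grid_copd(out$grid) - grid_copd(g),
               l$incident_cases - copd_deaths +
                 sum(sweep(sys$rt$baseline_prevalence["45-54", , , ], 1,
                           sys$demog$entrants["2006", ], `*`)),
               tolerance = 1e-9)
})

test_that("the cycle ledger reconciles on randomized valid systems", {
  set.seed(303)
  for (rep in 1:50) {
    sys <- random_valid_system()
    out <- step_year(sys$grid, sys$demog, sys$rt)
    expect_equal(out$ledger$end_total,
                 out$ledger$start_total - out$ledger$deaths + out$ledger$entrants,
                 tolerance = 1e-6)
    expect_true(all(out$grid$counts >= 0))
  }
})

test_that("permuting the within-cycle order changes the result (order is contractual)", {
  sys <- reference_system()
  g <- initialize_2005(sys$demog, sys$rt)
  default_out <- step_year(g, sys$demog, sys$rt)
  permuted <- step_year(g, sys$demog, sys$rt,
                        order = c("incidence", "gold", "smoking", "mortality"))
  expect_false(isTRUE(all.equal(grid_copd(default_out$grid),
                                grid_copd(permuted$grid))))
  expect_error(step_year(g, sys$demog, sys$rt, order = c("mortality", "gold")),
               "permutation")
})
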