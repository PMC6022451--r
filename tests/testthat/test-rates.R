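test_that("reference rate tables hold the published constants", {
  rt <- default_rate_tables()
  expect_equal(unname(rt$incidence_rate), c(0.006, 0.003))
  expect_equal(unname(rt$rr_gold), c(1.4, 2.04, 2.7))
  expect_equal(unname(rt$incident_smoking_dist), c(0.036, 0.329, 0.635))
  expect_equal(unname(rt$incident_grade_dist["G34"]), 0.046)
  expect_equal(sum(rt$incident_grade_dist[c("G1", "G2")]), 0.954)
  # mild:moderate incident split follows the prevalent G1:G2 ratio
  expect_equal(unname(rt$incident_grade_dist["G1"] / rt$incident_grade_dist["G2"]),
               0.584 / 0.374)
  expect_equal(unname(rt$smoking_transition_copd), c(0.047, 0.026))
  expect_equal(unname(rt$smoking_transition_nocopd), c(0.036, 0.065, 0.008))
})

test_that("targeted overrides change only the named element", {
  rt <- default_rate_tables(list(incidence_rate = c(female = 0.006)))
  expect_equal(unname(rt$incidence_rate), c(0.006, 0.006))
  base <- default_rate_tables()
  rt$incidence_rate <- base$incidence_rate
  expect_equal(rt, base)
  expect_error(default_rate_tables(list(nonsense = 1)),
               "unknown rate table field.*incidence_rate")
})

test_that("default_rate_tables is idempotent and side-effect free", {
  a <- default_rate_tables()
  b <- default_rate_tables()
  expect_identical(a, b)
})

test_that("the default GOLD matrix keeps to-worse transitions in the 10-20% range", {
  P <- default_rate_tables()$gold_transition
  worse <- c(P["G1", "G2"], P["G2", "G34"])
  expect_true(all(worse >= 0.10 & worse <= 0.20))
  expect_equal(P["G1", "G34"], 0)  # no two-grade jumps
  expect_equal(unname(rowSums(P)), c(1, 1, 1))
})

test_that("calibrated baseline prevalence matches every input marginal", {
  demog <- small_demog()
  m <- default_prevalence_marginals()
  prev <- calibrate_baseline_prevalence(m, demog)
  N <- t(vapply(split(seq(45, 110), age_band(45:110)), function(i) {
    colSums(demog$pyramid_2005[as.character(i), ])
  }, numeric(2)))
  cases <- sweep(prev, c(1, 2), N, `*`)
  total <- sum(cases)
  expect_equal(apply(cases, 4, sum) / total, m$grade_dist, tolerance = 1e-7)
  expect_equal(apply(cases, 3, sum) / total, m$smoking_dist, tolerance = 1e-7)
  expect_equal(unname(apply(cases, 1, sum) / total), unname(m$age_dist),
               tolerance = 1e-7)
  expect_equal(total / sum(N), m$overall_prevalence, tolerance = 1e-9)
  # male:female prevalence ratio preserved by the overall anchoring
  prev_sex <- apply(cases, 2, sum) / colSums(N)
  expect_equal(unname(prev_sex["male"] / prev_sex["female"]), 0.106 / 0.067,
               tolerance = 1e-9)
})

test_that("incompatible marginals and infeasible cells raise informative errors", {
  demog <- manual_demog(list(list(age = 45, sex = "male", count = 100)))
  m <- default_prevalence_marginals()
  # all cases must fall at 45-54 male, but the age marginal demands 75+ cases
  expect_error(calibrate_baseline_prevalence(m, demog), "exceeds 1")
})

test_that("the incidence age profile hits the 65+ diagnosis share", {
  sys <- reference_system()
  mult <- sys$rt$incidence_age_multiplier
  expect_equal(unname(mult["ge65"] / mult["lt65"]) > 1, TRUE)
  # apply one incidence cycle and check where cases arise
  grid <- initialize_2005(sys$demog, sys$rt)
  before <- grid_copd(grid, "band")
  out <- apply_incidence(grid, sys$rt)
  newly <- grid_copd(out$grid, "band") - before
  share_65 <- sum(newly[c("65-74", "75+")]) / sum(newly)
  expect_equal(share_65, 0.641, tolerance = 1e-3)
  # and the population-average rates are preserved by the profile
  atrisk <- apply(grid$counts[, , , "noCOPD"], c(1, 2), sum)
  expect_equal(sum(newly),
               sum(sweep(atrisk, 2, sys$rt$incidence_rate, `*`)),
               tolerance = 1e-6)
})

test_that("rate tables round-trip exactly through write/load", {
  sys <- reference_system()
  dir <- withr::local_tempdir()
  write_rate_tables(sys$rt, dir)
  loaded <- load_rate_tables(dir)
  for (f in names(sys$rt)) {
    expect_equal(loaded[[f]], sys$rt[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("invalid rate files are rejected with named causes", {
  sys <- reference_system()
  dir <- withr::local_tempdir()
  write_rate_tables(sys$rt, dir)

  gt <- utils::read.csv(file.path(dir, "gold_transition.csv"))
  gt$prob[gt$from_grade == "G1" & gt$to_grade == "G1"] <- 0.75  # row sums 0.9
  utils::write.csv(gt, file.path(dir, "gold_transition.csv"), row.names = FALSE)
  expect_error(load_rate_tables(dir), "row not stochastic")

  gt$prob[gt$from_grade == "G1" & gt$to_grade == "G1"] <- 0.85
  gt$from_grade[1] <- "G4"
  utils::write.csv(gt, file.path(dir, "gold_transition.csv"), row.names = FALSE)
  expect_error(load_rate_tables(dir), "G4.*allowed: G1, G2, G34")
})

test_that("non-COPD smoking structure rows are distributions", {
  ss <- default_smoking_structure()
  expect_equal(apply(ss, c(1, 2), sum), matrix(1, 4, 2, dimnames = dimnames(ss)[1:2]),
               tolerance = 1e-12)
  expect_error(default_smoking_structure(current = matrix(0.9, 4, 2),
                                         ex = matrix(0.3, 4, 2)),
               "exceeds 1")
})
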