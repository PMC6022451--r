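# Independent oracles, written before the implementations they check.

# Brute-force alternating scaling for a 2-dimensional table: explicit
# row-then-column loops, no shared code with ipf_fit().
ipf_oracle_2d <- function(seed, row_targets, col_targets,
                          sweeps = 10000, tol = 1e-12) {
  x <- seed
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nrow(x))) {
      rs <- sum(x[i, ])
      if (rs > 0) x[i, ] <- x[i, ] * row_targets[i] / rs
    }
    for (j in seq_len(ncol(x))) {
      cs <- sum(x[, j])
      if (cs > 0) x[, j] <- x[, j] * col_targets[j] / cs
    }
    err <- max(abs(rowSums(x) - row_targets), abs(colSums(x) - col_targets))
    if (err < tol) break
  }
  x
}

# Individual-based Monte Carlo simulator with the same inputs as the
# compartmental engine: the whole annual cycle re-derived at person level
# (Bernoulli/multinomial draws), sharing no code with the package engine.
microsim <- function(demog, rt, n = 10000, years = 20, seed = 1) {
  set.seed(seed)
  ages <- 45:110
  sex_l <- c("male", "female")
  smk_l <- c("never", "ex", "current")
  st_l <- c("noCOPD", "G1", "G2", "G34")
  scale <- n / sum(demog$pyramid_2005)

  # probability of each (age, sex, smoking, state) cell at baseline
  cell_prob <- function(a, s) {
    band <- if (a <= 54) "45-54" else if (a <= 64) "55-64"
            else if (a <= 74) "65-74" else "75+"
    prev <- rt$baseline_prevalence[band, s, , ]        # smoking x grade
    m <- cbind(noCOPD = (1 - sum(prev)) * rt$smoking_structure[band, s, ], prev)
    m  # rows smoking, cols noCOPD,G1,G2,G34
  }
  # draw initial cohort
  probs <- numeric(0); key <- NULL
  for (a in ages) for (s in 1:2) {
    m <- cell_prob(a, sex_l[s])
    probs <- c(probs, as.vector(m) * demog$pyramid_2005[as.character(a), s])
    key <- rbind(key, cbind(a, s, rep(1:3, 4), rep(c(1, 2, 3, 4), each = 3)))
  }
  idx <- sample(length(probs), n, replace = TRUE, prob = probs)
  pop <- data.frame(age = key[idx, 1], sex = key[idx, 2],
                    smk = key[idx, 3], st = key[idx, 4])

  mult <- function(a) ifelse(a >= 65, rt$incidence_age_multiplier["ge65"],
                             rt$incidence_age_multiplier["lt65"])
  counts <- numeric(years)
  for (y in seq_len(years)) {
    # 1. mortality
    q <- rt$rr_smoking[pop$smk] * c(1, rt$rr_gold)[pop$st] *
      demog$base_mortality[cbind(pop$age - 44, pop$sex)]
    pop <- pop[stats::runif(nrow(pop)) >= pmin(q, 1), ]
    # 2. smoking transitions
    has_copd <- pop$st > 1
    quit <- ifelse(has_copd, rt$smoking_transition_copd["quit"],
                   rt$smoking_transition_nocopd["quit"])
    rel <- ifelse(has_copd, rt$smoking_transition_copd["relapse"],
                  rt$smoking_transition_nocopd["relapse"])
    init <- ifelse(has_copd, 0, rt$smoking_transition_nocopd["initiate"])
    u <- stats::runif(nrow(pop))
    new_smk <- pop$smk
    new_smk[pop$smk == 3 & u < quit] <- 2
    new_smk[pop$smk == 2 & u < rel] <- 3
    new_smk[pop$smk == 1 & u < init] <- 3
    pop$smk <- new_smk
    # 3. incidence: per stratum, same targeting rule re-derived by hand
    mix <- rt$incident_smoking_dist
    for (a in unique(pop$age[pop$st == 1])) for (s in 1:2) {
      sel <- pop$age == a & pop$sex == s & pop$st == 1
      if (!any(sel)) next
      avail <- tabulate(pop$smk[sel], 3)
      total <- min(rt$incidence_rate[s] * mult(a) * sum(avail), sum(avail))
      take <- pmin(total * mix, avail)
      left <- total - sum(take)
      while (left > 1e-9 && any(avail - take > 1e-9 & mix > 0)) {
        open <- avail - take > 1e-9
        add <- pmin(left * mix * open / sum(mix * open), avail - take)
        take <- take + add
        left <- left - sum(add)
      }
      p_conv <- ifelse(avail > 0, take / avail, 0)
      conv <- sel & stats::runif(nrow(pop)) < p_conv[pop$smk]
      pop$st[conv] <- 1 + sample(3, sum(conv), replace = TRUE,
                                 prob = rt$incident_grade_dist)
    }
    # 4. GOLD transitions
    for (g in 2:4) {
      sel <- which(pop$st == g)
      if (length(sel)) {
        pop$st[sel] <- 1 + apply(stats::rmultinom(length(sel), 1,
                                 rt$gold_transition[g - 1, ]), 2, which.max)
      }
    }
    # 5. ageing + entrants
    pop$age <- pmin(pop$age + 1, 110)
    yr <- as.character(2005 + y)
    for (s in 1:2) {
      ne <- stats::rpois(1, demog$entrants[yr, s] * scale)
      if (ne == 0) next
      m <- cell_prob(45, sex_l[s])
      draw <- sample(12, ne, replace = TRUE, prob = as.vector(m))
      pop <- rbind(pop, data.frame(age = 45, sex = s,
                                   smk = (draw - 1) %% 3 + 1,
                                   st = (draw - 1) %/% 3 + 1))
    }
    counts[y] <- sum(pop$st > 1)
  }
  counts
}
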