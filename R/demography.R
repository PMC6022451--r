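#' Parameters for the synthetic demography generator
#'
#' The generator emulates the demographic backbone of the model — the 2005
#' population pyramid aged 45+, entrant cohorts (persons turning 45) for
#' 2006-2025, and background mortality by age and sex — from a small set of
#' interpretable parameters. Defaults reproduce the published aggregates for
#' France on 1 January 2005: 25,665,019 persons aged 45+, 54% women, and
#' 49.3% of the 45+ population aged 65+.
#'
#' The pyramid is piecewise-exponential in age with a slope change at 65: the
#' pre-65 decay rate is given (`decay_pre65`) and the post-65 rate is solved
#' numerically so the 65+ share hits `share_65plus`. Background mortality is
#' Gompertz-Makeham per sex, `q(a) = 1 - exp(-(makeham + alpha *
#' exp(beta * (a - 45))))`, with the terminal age 110 forced to `q = 1`.
#' The default coefficients give a realistic early-2000s western-European
#' life-table shape; they are synthetic stand-ins, not published values.
#'
#' @param total Total population aged `age_range[1]`+ in the base year.
#' @param female_share Share of the total that is female, in `[0, 1]`.
#' @param share_65plus Share of the total aged 65+, in `[0, 1)`.
#' @param decay_pre65 Exponential decay rate of the pyramid per year of age
#'   before 65 (non-negative).
#' @param gompertz Named list with elements `male` and `female`, each a
#'   numeric vector `c(makeham, alpha, beta)` of Gompertz-Makeham
#'   coefficients (all non-negative).
#' @param entrant_size Persons turning 45 in 2006 (both sexes combined).
#' @param entrant_drift Additive change in entrant cohort size per calendar
#'   year after 2006 (may be negative).
#' @param entrant_years Calendar years for which entrant cohorts are
#'   generated.
#' @param age_range Length-2 integer vector, the inclusive age span actually
#'   populated (the internal grid always spans 45-110; ages outside
#'   `age_range` get zero counts).
#' @param jitter_sd Relative log-normal jitter applied to pyramid cells
#'   (0 = deterministic; marginals are re-normalised after jitter so the
#'   printed aggregates still hold).
#' @param seed Integer seed, used only when `jitter_sd > 0`.
#' @return A named list of class `synth_demography_params`.
#' @seealso [synthesize_demography()]
#' @export
synth_demography_params <- function(total = 25665019,
                                    female_share = 0.54,
                                    share_65plus = 0.493,
                                    decay_pre65 = 0.005,
                                    gompertz = list(
                                      male = c(makeham = 1.0e-3, alpha = 1.5e-3, beta = 0.105),
                                      female = c(makeham = 5.0e-4, alpha = 6.0e-4, beta = 0.110)
                                    ),
                                    entrant_size = 820000,
                                    entrant_drift = 0,
                                    entrant_years = 2006:2025,
                                    age_range = c(45L, 110L),
                                    jitter_sd = 0,
                                    seed = NULL) {
  p <- list(
    total = total, female_share = female_share, share_65plus = share_65plus,
    decay_pre65 = decay_pre65, gompertz = gompertz,
    entrant_size = entrant_size, entrant_drift = entrant_drift,
    entrant_years = as.integer(entrant_years),
    age_range = as.integer(age_range), jitter_sd = jitter_sd, seed = seed
  )
  class(p) <- "synth_demography_params"
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  chk <- function(ok, field, why) {
    if (!ok) copd_error(sprintf("invalid parameter '%s': %s", field, why),
                        class = "copd_validation_error")
  }
  chk(is.numeric(p$total) && is.finite(p$total) && p$total > 0, "total",
      "must be a positive finite number")
  chk(p$female_share >= 0 && p$female_share <= 1, "female_share",
      "must lie in [0, 1]")
  chk(p$share_65plus >= 0 && p$share_65plus < 1, "share_65plus",
      "must lie in [0, 1)")
  chk(p$decay_pre65 >= 0, "decay_pre65", "must be non-negative")
  chk(p$age_range[1] >= AGE_MIN && p$age_range[2] <= AGE_MAX &&
        p$age_range[1] <= p$age_range[2], "age_range",
      sprintf("must be within [%d, %d] and ordered", AGE_MIN, AGE_MAX))
  if (p$age_range[2] < 65 && p$share_65plus > 0) {
    copd_error("invalid parameter 'share_65plus': no ages >= 65 in age_range but share_65plus > 0",
               class = "copd_validation_error")
  }
  for (s in copd_sexes()) {
    g <- p$gompertz[[s]]
    chk(is.numeric(g) && length(g) == 3 && all(g >= 0), "gompertz",
        sprintf("coefficients for %s must be 3 non-negative numbers", s))
  }
  chk(p$entrant_size >= 0, "entrant_size", "must be non-negative")
  chk(p$jitter_sd >= 0, "jitter_sd", "must be non-negative")
  invisible(p)
}

# age shape on the populated range: exp decay with a slope change at 65,
# post-65 rate solved so the 65+ share matches the target.
synth_age_shape <- function(ages, decay_pre65, share_65plus) {
  if (share_65plus == 0 || max(ages) < 65) {
    w <- exp(-decay_pre65 * (ages - min(ages)))
    if (any(ages >= 65) && share_65plus == 0) w[ages >= 65] <- 0
    return(w / sum(w))
  }
  pre <- ages[ages < 65]
  post <- ages[ages >= 65]
  w_pre <- if (length(pre)) exp(-decay_pre65 * (pre - min(ages))) else numeric(0)
  anchor <- exp(-decay_pre65 * (65 - min(ages)))
  share_fun <- function(r2) {
    w_post <- anchor * exp(-r2 * (post - 65))
    sum(w_post) / (sum(w_pre) + sum(w_post))
  }
  # share is decreasing in r2; check feasibility at the bracket ends
  lo <- 1e-9; hi <- 2
  if (share_fun(lo) < share_65plus || share_fun(hi) > share_65plus) {
    copd_error(sprintf(
      "invalid parameter 'share_65plus': %.3f not attainable with decay_pre65 = %.4f",
      share_65plus, decay_pre65), class = "copd_validation_error")
  }
  r2 <- stats::uniroot(function(r) share_fun(r) - share_65plus,
                       c(lo, hi), tol = 1e-12)$root
  w <- c(w_pre, anchor * exp(-r2 * (post - 65)))
  w / sum(w)
}

#' Synthesize a demographic backbone from printed aggregates
#'
#' Builds a [`DemographyModel`][demography_model] whose marginals reproduce
#' the three published aggregates of the 2005 French 45+ population (total,
#' female share, 65+ share), plus deterministic entrant cohorts and
#' Gompertz-Makeham background mortality. Fully deterministic for
#' `jitter_sd = 0` (the default): repeated calls are bit-identical.
#'
#' @param params A [synth_demography_params()] object.
#' @return A `demography_model` (list with `pyramid_2005`, `entrants`,
#'   `base_mortality`).
#' @examples
#' demog <- synthesize_demography()
#' sum(demog$pyramid_2005)            # 25,665,019
#' @export
synthesize_demography <- function(params = synth_demography_params()) {
  validate_synth_params(params)
  ages <- copd_ages()
  sexes <- copd_sexes()
  in_range <- ages >= params$age_range[1] & ages <= params$age_range[2]

  shape <- numeric(length(ages))
  shape[in_range] <- synth_age_shape(ages[in_range], params$decay_pre65,
                                     params$share_65plus)

  pyramid <- cbind(
    male = shape * params$total * (1 - params$female_share),
    female = shape * params$total * params$female_share
  )
  rownames(pyramid) <- as.character(ages)

  if (params$jitter_sd > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    jit <- matrix(exp(stats::rnorm(length(pyramid), 0, params$jitter_sd)),
                  nrow = nrow(pyramid))
    jit[!in_range, ] <- 1
    pyramid <- pyramid * jit
    # re-normalise so the three aggregates still hold exactly
    for (s in sexes) {
      tgt <- params$total * if (s == "female") params$female_share else 1 - params$female_share
      old65 <- ages >= 65
      if (params$share_65plus > 0 && any(in_range & old65)) {
        pyramid[in_range & old65, s] <- pyramid[in_range & old65, s] *
          (tgt * params$share_65plus / sum(pyramid[in_range & old65, s]))
        pyramid[in_range & !old65, s] <- pyramid[in_range & !old65, s] *
          (tgt * (1 - params$share_65plus) / sum(pyramid[in_range & !old65, s]))
      } else if (sum(pyramid[, s]) > 0) {
        pyramid[, s] <- pyramid[, s] * (tgt / sum(pyramid[, s]))
      }
    }
  }

  yrs <- params$entrant_years
  sizes <- params$entrant_size + params$entrant_drift * (yrs - min(yrs))
  if (any(sizes < 0)) {
    copd_error("invalid parameter 'entrant_drift': produces a negative entrant cohort",
               class = "copd_validation_error")
  }
  entrants <- cbind(male = sizes * (1 - params$female_share),
                    female = sizes * params$female_share)
  rownames(entrants) <- as.character(yrs)

  qx <- sapply(sexes, function(s) {
    g <- params$gompertz[[s]]
    mu <- g[[1]] + g[[2]] * exp(g[[3]] * (ages - AGE_MIN))
    q <- 1 - exp(-mu)
    q[length(q)] <- 1  # closed ladder at the terminal age
    q
  })
  rownames(qx) <- as.character(ages)

  demography_model(pyramid, entrants, qx)
}

#' Construct and validate a demography model
#'
#' The container for the model's demographic inputs: the base-year population
#' pyramid by single-year age (45-110) and sex, entrant cohort sizes
#' (persons turning 45) by calendar year and sex, and background annual death
#' probabilities by age and sex.
#'
#' @param pyramid_2005 Numeric matrix, ages 45-110 (rownames) by sex
#'   (colnames `male`, `female`); non-negative counts.
#' @param entrants Numeric matrix, calendar years (rownames) by sex;
#'   non-negative counts.
#' @param base_mortality Numeric matrix, ages 45-110 by sex; annual death
#'   probabilities in `[0, 1]`, with the terminal age equal to 1.
#' @return A validated list of class `demography_model`.
#' @export
demography_model <- function(pyramid_2005, entrants, base_mortality) {
  d <- structure(list(pyramid_2005 = pyramid_2005, entrants = entrants,
                      base_mortality = base_mortality),
                 class = "demography_model")
  validate_demography(d)
}

validate_demography <- function(d) {
  ages <- as.character(copd_ages())
  sexes <- copd_sexes()
  for (nm in c("pyramid_2005", "base_mortality")) {
    m <- d[[nm]]
    if (!is.matrix(m) || !identical(rownames(m), ages) ||
        !identical(colnames(m), sexes)) {
      copd_error(sprintf("%s must be an age(45..110) x sex(male,female) matrix", nm),
                 class = "copd_validation_error")
    }
    if (any(!is.finite(m))) copd_error(sprintf("%s has non-finite entries", nm),
                                       class = "copd_validation_error")
  }
  if (any(d$pyramid_2005 < 0)) {
    copd_error("pyramid_2005 has negative counts", class = "copd_validation_error")
  }
  if (any(d$base_mortality < 0 | d$base_mortality > 1)) {
    copd_error("base_mortality: probability out of range [0, 1]",
               class = "copd_validation_error")
  }
  if (any(d$base_mortality[length(copd_ages()), ] != 1)) {
    copd_error("base_mortality at the terminal age (110) must equal 1",
               class = "copd_validation_error")
  }
  if (!is.matrix(d$entrants) || !identical(colnames(d$entrants), sexes) ||
      any(!is.finite(d$entrants)) || any(d$entrants < 0)) {
    copd_error("entrants must be a year x sex(male,female) matrix of non-negative counts",
               class = "copd_validation_error")
  }
  d
}

#' @export
print.demography_model <- function(x, ...) {
  tot <- sum(x$pyramid_2005)
  fem <- sum(x$pyramid_2005[, "female"]) / tot
  old <- sum(x$pyramid_2005[as.integer(rownames(x$pyramid_2005)) >= 65, ]) / tot
  cat(sprintf("<demography_model> %s persons 45+ (%.1f%% female, %.1f%% aged 65+)\n",
              format(round(tot), big.mark = ","), 100 * fem, 100 * old))
  cat(sprintf("  entrant cohorts: %s-%s, mean %s/yr\n",
              rownames(x$entrants)[1], rownames(x$entrants)[nrow(x$entrants)],
              format(round(mean(rowSums(x$entrants))), big.mark = ",")))
  invisible(x)
}

read_demography_csv <- function(path, cols) {
  if (!file.exists(path)) copd_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    copd_error(sprintf("%s: missing column(s) %s", basename(path),
                       paste(missing, collapse = ", ")),
               class = "copd_schema_error")
  }
  bad_sex <- setdiff(unique(df$sex), copd_sexes())
  if (length(bad_sex)) {
    copd_error(sprintf("%s: unknown sex label(s) %s (allowed: %s)", basename(path),
                       paste(bad_sex, collapse = ", "),
                       paste(copd_sexes(), collapse = ", ")),
               class = "copd_schema_error")
  }
  df
}

# long data frame -> age x sex matrix covering ages lo..hi contiguously;
# missing cells are an error, never a silent zero-fill.
cells_to_matrix <- function(df, value_col, what, rows, row_col) {
  m <- matrix(NA_real_, nrow = length(rows), ncol = 2,
              dimnames = list(as.character(rows), copd_sexes()))
  key_ok <- df[[row_col]] %in% rows
  if (any(!key_ok)) {
    copd_error(sprintf("%s: %s value(s) outside the expected range: %s", what,
                       row_col, paste(unique(df[[row_col]][!key_ok]), collapse = ", ")),
               class = "copd_schema_error")
  }
  m[cbind(as.character(df[[row_col]]), df$sex)] <- df[[value_col]]
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    gap1 <- paste0(row_col, " ", rownames(m)[gaps[1, 1]], ", sex ",
                   colnames(m)[gaps[1, 2]])
    copd_error(sprintf("%s: missing cell(s), first gap at (%s); %d cell(s) absent",
                       what, gap1, nrow(gaps)),
               class = "copd_schema_error")
  }
  m
}

#' Load a demography model from delimited text files
#'
#' Reads the three demographic inputs from comma-delimited files with a
#' mandatory header row: the pyramid (`age,sex,count`), the entrant cohorts
#' (`year,sex,count`) and background mortality (`age,sex,qx`). Ages must
#' cover 45-110 contiguously for both sexes; any missing cell is an error.
#'
#' @param pyramid_path,entrants_path,mortality_path Paths to the CSV files.
#' @return A validated `demography_model`.
#' @seealso [write_demography()] for the inverse; the round trip is exact.
#' @export
load_demography <- function(pyramid_path, entrants_path, mortality_path) {
  pyr <- read_demography_csv(pyramid_path, c("age", "sex", "count"))
  ent <- read_demography_csv(entrants_path, c("year", "sex", "count"))
  mor <- read_demography_csv(mortality_path, c("age", "sex", "qx"))

  pyramid <- cells_to_matrix(pyr, "count", "pyramid", copd_ages(), "age")
  qx <- cells_to_matrix(mor, "qx", "mortality", copd_ages(), "age")
  if (any(qx < 0 | qx > 1)) {
    copd_error("mortality: probability out of range [0, 1]",
               class = "copd_schema_error")
  }
  years <- sort(unique(ent$year))
  entrants <- cells_to_matrix(ent, "count", "entrants", years, "year")
  demography_model(pyramid, entrants, qx)
}

#' Write a demography model to delimited text files
#'
#' @param demog A `demography_model`.
#' @param pyramid_path,entrants_path,mortality_path Output CSV paths.
#' @return Invisibly, the input model.
#' @export
write_demography <- function(demog, pyramid_path, entrants_path, mortality_path) {
  mat_to_long <- function(m, row_col, value_col) {
    df <- expand.grid(row = rownames(m), sex = colnames(m),
                      stringsAsFactors = FALSE)
    df[[value_col]] <- as.vector(m)
    names(df)[1] <- row_col
    df
  }
  utils::write.csv(mat_to_long(demog$pyramid_2005, "age", "count"),
                   pyramid_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(mat_to_long(demog$entrants, "year", "count"),
                   entrants_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(mat_to_long(demog$base_mortality, "age", "qx"),
                   mortality_path, row.names = FALSE, quote = FALSE)
  invisible(demog)
}
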