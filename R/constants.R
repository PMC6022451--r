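# Dimension labels shared by every module. The population is tracked on a
# single-year age grid 45..110 (the terminal age is a closed ladder: everyone
# alive at 110 dies within the year), two sexes, three smoking statuses and
# four health states (no COPD plus the GOLD grades, 3 and 4 merged).

AGE_MIN <- 45L
AGE_MAX <- 110L

copd_ages <- function() AGE_MIN:AGE_MAX

copd_sexes <- function() c("male", "female")

copd_smoking <- function() c("never", "ex", "current")

copd_states <- function() c("noCOPD", "G1", "G2", "G34")

copd_grades <- function() c("G1", "G2", "G34")

copd_age_bands <- function() c("45-54", "55-64", "65-74", "75+")

#' Map single-year ages to reporting age bands
#'
#' @param age Integer vector of ages (45 or older).
#' @return Factor with levels `"45-54"`, `"55-64"`, `"65-74"`, `"75+"`.
#' @export
age_band <- function(age) {
  stopifnot(all(age >= AGE_MIN))
  cut(age, breaks = c(44, 54, 64, 74, Inf), labels = copd_age_bands())
}

# internal: stop() with a classed condition so tests can assert on class
copd_error <- function(msg, class = "copd_error", call. = FALSE) {
  stop(structure(
    class = c(class, "copd_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
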