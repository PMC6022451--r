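#' Iterative proportional fitting of an N-dimensional table
#'
#' Alternating (raking) scaling of a non-negative seed table until every
#' stated one-dimensional marginal is matched. Used by the baseline
#' prevalence calibrator, but exposed because it is generally useful for
#' reconstructing joint tables from printed marginals.
#'
#' Convergence is measured as the maximum relative discrepancy between the
#' table's implied marginals and the targets, `max |implied - target| /
#' max(target, eps)`. The per-sweep discrepancy history is returned so
#' callers can verify the monotone decrease that IPF guarantees for
#' compatible marginals.
#'
#' @param seed Non-negative numeric array (any number of dimensions).
#' @param margins List of target marginal vectors, one per dimension of
#'   `seed`, in dimension order. All margins must share the same total
#'   (within `tol`), since they are sums of the same table.
#' @param tol Relative tolerance for convergence. Default `1e-8`.
#' @param max_iter Maximum number of full sweeps. Default 1000.
#' @return List with `table` (fitted array), `iterations`, `max_discrepancy`
#'   and `history` (max discrepancy after each sweep).
#' @examples
#' fit <- ipf_fit(matrix(1, 2, 2), list(c(6, 4), c(7, 3)))
#' fit$table
#' @export
ipf_fit <- function(seed, margins, tol = 1e-8, max_iter = 1000) {
  if (any(seed < 0) || any(!is.finite(seed))) {
    copd_error("ipf_fit: seed must be non-negative and finite")
  }
  d <- dim(seed) %||% length(seed)
  if (length(margins) != length(d)) {
    copd_error(sprintf("ipf_fit: %d margins supplied for a %d-dimensional table",
                       length(margins), length(d)))
  }
  for (k in seq_along(margins)) {
    if (length(margins[[k]]) != d[k] || any(margins[[k]] < 0)) {
      copd_error(sprintf("ipf_fit: margin %d must be a non-negative vector of length %d",
                         k, d[k]))
    }
  }
  totals <- vapply(margins, sum, 0)
  if (max(totals) > 0 &&
      (max(totals) - min(totals)) / max(totals) > 1e-6) {
    copd_error("ipf_fit: margins disagree on the table total")
  }

  x <- if (is.array(seed)) seed else array(seed, dim = d)
  eps <- max(totals, 1) * 1e-15
  discrepancy <- function(x) {
    worst <- 0
    for (k in seq_along(margins)) {
      got <- apply(x, k, sum)
      worst <- max(worst, abs(got - margins[[k]]) / pmax(margins[[k]], eps))
    }
    worst
  }

  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (k in seq_along(margins)) {
      got <- apply(x, k, sum)
      ratio <- ifelse(got > 0, margins[[k]] / got, 0)
      x <- sweep(x, k, ratio, `*`)
    }
    history[it] <- discrepancy(x)
    if (history[it] <= tol) {
      return(list(table = x, iterations = it, max_discrepancy = history[it],
                  history = history))
    }
  }
  copd_error(sprintf(
    "ipf_fit: not converged in %d sweeps; worst marginal discrepancy %.3g (tol %.3g) — margins may be incompatible",
    max_iter, history[max_iter], tol), class = "copd_ipf_error")
}
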