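# Post-run statistics: blocking error bars for autocorrelated series,
# variance-per-time efficiency, wavefunction deviation diagnostics and spin
# reporting.

#' Blocking analysis of a correlated time series
#'
#' Successive pairwise block averaging: at each level the series is halved by
#' averaging neighbors and the naive standard error of the mean,
#' `sqrt(var(blocks) / n_blocks)`, is recorded. For correlated data the
#' estimate grows with block size until blocks decorrelate; the plateau is the
#' first level whose estimate lies within one estimated error
#' (`sigma / sqrt(2 (n_blocks - 1))`) of the next level's.
#'
#' @param series Numeric vector, length >= 32.
#' @param plateau_block Optional manual override of the plateau level
#'   (1 = unblocked).
#' @return A `blocking_result`: per-level `block_sizes`, `error_estimates`,
#'   `error_of_error`, the `plateau_block` and `plateau_estimate` (standard
#'   error of the mean).
#' @export
blocking_analysis <- function(series, plateau_block = NULL) {
  series <- as.numeric(series)
  if (length(series) < 32) stop("blocking_analysis: series too short (< 32)")
  x <- series
  sizes <- integer(0); est <- numeric(0); eoe <- numeric(0)
  bs <- 1L
  while (length(x) >= 4L) {
    nb <- length(x)
    s <- sqrt(stats::var(x) / nb)
    sizes <- c(sizes, bs); est <- c(est, s)
    eoe <- c(eoe, s / sqrt(2 * (nb - 1)))
    if (length(x) %% 2L == 1L) x <- x[-length(x)]
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
    bs <- bs * 2L
  }
  if (is.null(plateau_block)) {
    plateau <- length(est)
    for (k in seq_len(length(est) - 1L)) {
      if (abs(est[k + 1L] - est[k]) <= eoe[k]) { plateau <- k; break }
    }
  } else {
    plateau <- match(plateau_block, sizes)
    if (is.na(plateau)) stop("blocking_analysis: no level with block size ",
                             plateau_block)
  }
  structure(list(block_sizes = sizes, error_estimates = est,
                 error_of_error = eoe, plateau_block = sizes[plateau],
                 plateau_estimate = est[plateau],
                 mean = mean(series), n = length(series)),
            class = "blocking_result")
}

#' @export
print.blocking_result <- function(x, ...) {
  cat(sprintf("<blocking_result> mean %.8f +/- %.2e (plateau block %d, n = %d)\n",
              x$mean, x$plateau_estimate, x$plateau_block, x$n))
  invisible(x)
}

#' Stochastic efficiency of an estimator series
#'
#' `eta = 1 / (Var(E_proj) * t)`: the reciprocal of the blocking-corrected
#' variance of the mean times the wall-clock time. Doubling either the
#' variance or the time halves the efficiency.
#'
#' @param series Estimator time series (e.g. per-step projected energy).
#' @param wallclock Wall-clock seconds spent producing it.
#' @return List: `eta`, `variance` (of the mean), `wallclock`; `eta` is `Inf`
#'   (flagged) for a constant series.
#' @export
efficiency <- function(series, wallclock) {
  stopifnot(wallclock > 0)
  b <- blocking_analysis(series)
  v <- b$plateau_estimate^2
  list(eta = if (v == 0) Inf else 1 / (v * wallclock),
       variance = v, wallclock = wallclock, zero_variance = v == 0)
}

#' Root-mean-square deviation between two CI coefficient vectors
#'
#' Both vectors are L2-normalized and globally sign-aligned (by the sign of
#' their overlap), then `sqrt(mean((c - c_ref)^2))` is taken. Deviations are
#' also reported split by P/Q membership when given.
#'
#' @param coeffs,ref_coeffs Coefficient vectors over the same ordered space.
#' @param in_p Optional logical vector marking P members.
#' @return List: `rmse`, `deviations` (per configuration), and `rmse_p` /
#'   `rmse_q` when `in_p` is given.
#' @export
wavefunction_rmse <- function(coeffs, ref_coeffs, in_p = NULL) {
  if (length(coeffs) != length(ref_coeffs))
    stop("wavefunction_rmse: dimension mismatch")
  c1 <- coeffs / sqrt(sum(coeffs^2))
  c2 <- ref_coeffs / sqrt(sum(ref_coeffs^2))
  if (sum(c1 * c2) < 0) c1 <- -c1
  dev <- c1 - c2
  out <- list(rmse = sqrt(mean(dev^2)), deviations = dev)
  if (!is.null(in_p)) {
    out$rmse_p <- sqrt(mean(dev[in_p]^2))
    out$rmse_q <- if (any(!in_p)) sqrt(mean(dev[!in_p]^2)) else 0
  }
  out
}

#' Spin purity report for a determinant-basis state
#'
#' Evaluates `<S^2>` and its deviation from the pure value `S(S+1)` of the
#' nearest half-integer-compatible total spin (the smallest S consistent with
#' the space's Ms).
#'
#' @param coeffs Coefficient vector over `space`.
#' @param space A `ci_space`.
#' @param s_target Total spin to compare against (default: `|Ms|`).
#' @return List: `s_squared`, `s_target`, `deviation`.
#' @export
spin_report <- function(coeffs, space, s_target = NULL) {
  ms <- (space$n_alpha - space$n_beta) / 2
  if (is.null(s_target)) s_target <- abs(ms)
  s2 <- s_squared_expectation(coeffs, space)
  list(s_squared = s2, s_target = s_target,
       deviation = s2 - s_target * (s_target + 1))
}
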