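#' Decision statistics of the linear summation decoder
#'
#' The decoder sums the responses of all units tuned to each of the two
#' possible target locations and reports the location with the larger sum.
#' The blank location is evaluated at contrast 0 under the same condition's
#' response equation: in the AM condition the blank side still receives the
#' AM effects, because inducers flank both sides of the display. The summed
#' response variances are `zeta` times the summed means, and the decision
#' noise is inflated by the efficiency `epsilon`:
#' `sigma = sqrt(var(S_tgt) + var(S_blank)) / epsilon`.
#'
#' @param contrast Target contrast in % Michelson.
#' @param orientation Target orientation in degrees.
#' @param pop A [population_params()] object.
#' @param am An [am_params()] object, or `NULL` for the Flicker condition.
#' @param epsilon Efficiency, a fraction in (0, 1]. Absorbs unmodelled
#'   losses (interneural correlations, attention, lapses) that scale overall
#'   performance without being condition-specific.
#' @return An object of class `decision_stats` with fields `S_tgt_mean`,
#'   `S_blank_mean`, `mu`, `sigma`, `epsilon`.
#' @export
summed_stats <- function(contrast, orientation, pop, am = NULL, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    stop("`epsilon` must be a fraction in (0, 1]", call. = FALSE)
  }
  stopifnot(length(contrast) == 1L)
  m <- .mean_response(c(contrast, 0), orientation, pop, am)
  s_tgt <- sum(m[, 1L])
  s_blk <- sum(m[, 2L])
  structure(list(S_tgt_mean = s_tgt, S_blank_mean = s_blk,
                 mu = s_tgt - s_blk,
                 sigma = sqrt(pop$zeta * (s_tgt + s_blk)) / epsilon,
                 epsilon = epsilon),
            class = "decision_stats")
}

#' @export
print.decision_stats <- function(x, ...) {
  cat(sprintf(
    "2AFC decision stats: S_tgt=%.4g  S_blank=%.4g  mu=%.4g  sigma=%.4g (eps=%.3g)\n",
    x$S_tgt_mean, x$S_blank_mean, x$mu, x$sigma, x$epsilon))
  invisible(x)
}

#' Analytic proportion correct of the 2AFC decoder
#'
#' Under independent Gaussian response noise the decision variable
#' `S_tgt - S_blank` is Gaussian, so proportion correct is
#' `pnorm(mu / sigma)`.
#'
#' @param stats A `decision_stats` object from [summed_stats()].
#' @return Probability correct in (0, 1); 0.5 when `mu = 0`.
#' @export
proportion_correct <- function(stats) {
  stopifnot(inherits(stats, "decision_stats"))
  if (!is.finite(stats$sigma) || stats$sigma <= 0) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  stats::pnorm(stats$mu / stats$sigma)
}

# Monte-Carlo twin of the analytic decoder: n trials at one design cell.
# Each unit's response is drawn from Normal(mean, zeta * mean / epsilon^2),
# so the simulated decision statistic has exactly the analytic mean and
# variance. Draws are not truncated at zero, matching the model's normality
# assumption. Returns a logical vector of trial outcomes.
.simulate_2afc <- function(n, contrast, orientation, pop, am, epsilon) {
  m <- .mean_response(c(contrast, 0), orientation, pop, am)
  nn <- nrow(m)
  sd_t <- sqrt(pop$zeta * m[, 1L]) / epsilon
  sd_b <- sqrt(pop$zeta * m[, 2L]) / epsilon
  s_t <- colSums(matrix(stats::rnorm(nn * n, mean = m[, 1L], sd = sd_t),
                        nn, n))
  s_b <- colSums(matrix(stats::rnorm(nn * n, mean = m[, 2L], sd = sd_b),
                        nn, n))
  correct <- s_t > s_b
  tie <- s_t == s_b
  if (any(tie)) correct[tie] <- stats::runif(sum(tie)) < 0.5
  correct
}

#' Simulate a single 2AFC trial
#'
#' Draws each unit's response at the target and blank locations from its
#' Gaussian response distribution (variance scaled by `1/epsilon^2` so the
#' simulated decision statistic matches the analytic one exactly), sums per
#' location, and reports whether the target location won. Exact ties are
#' broken by a fair coin. Uses R's global random number stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams summed_stats
#' @return Logical: was the simulated response correct?
#' @export
simulate_2afc_trial <- function(contrast, orientation, pop, am = NULL,
                                epsilon) {
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon > 1) {
    stop("`epsilon` must be a fraction in (0, 1]", call. = FALSE)
  }
  .simulate_2afc(1L, contrast, orientation, pop, am, epsilon)[1L]
}
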