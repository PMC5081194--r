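#' Logistic psychometric function with a free performance ceiling
#'
#' `psi(c) = 0.5 + (0.5 - lam) / (1 + exp((c_m - c) / s))`: proportion
#' correct in a 2AFC task as a function of target contrast. Chance is fixed
#' at 0.5 by the task design; the upper asymptote `1 - lam` is free because
#' the ceiling deficit `lam` is condition-dependent here (apparent motion
#' caps maximum performance), not a stimulus-independent lapse rate.
#'
#' @param contrast Contrast(s) in % Michelson, >= 0.
#' @param c_m Midpoint contrast (% Michelson).
#' @param s Steepness scale (% Michelson, > 0); smaller is steeper.
#' @param lam Ceiling deficit in [0, 0.5].
#' @return Probability correct in [0.5, 1 - lam].
#' @export
psi <- function(contrast, c_m, s, lam = 0) {
  if (any(!is.finite(s) | s <= 0)) stop("`s` must be > 0", call. = FALSE)
  if (any(!is.finite(lam) | lam < 0 | lam > 0.5)) {
    stop("`lam` must lie in [0, 0.5]", call. = FALSE)
  }
  0.5 + (0.5 - lam) * stats::plogis((contrast - c_m) / s)
}

# ---- internal fitting machinery ------------------------------------------
# Unconstrained parameterization: u = (c_m, log s, logit(2 * lam)).
.pf_nat <- function(u) {
  c(c_m = u[[1L]], s = exp(u[[2L]]), lam = 0.5 * stats::plogis(u[[3L]]))
}

.pf_trans <- function(est) {
  lam <- min(max(est[[3L]], 1e-8), 0.5 - 1e-8)
  c(est[[1L]], log(max(est[[2L]], 1e-8)), stats::qlogis(2 * lam))
}

# Binomial negative log-likelihood; 1 - psi guarded away from 0.
.pf_negll <- function(u, contrast, n_trials, n_correct) {
  lam <- 0.5 * stats::plogis(u[[3L]])
  pr <- 0.5 + (0.5 - lam) * stats::plogis((contrast - u[[1L]]) / exp(u[[2L]]))
  -sum(n_correct * log(pr) +
       (n_trials - n_correct) * log(pmax(1 - pr, 1e-9)))
}

.pf_optim <- function(contrast, n_trials, n_correct, starts, maxit = 400L) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], .pf_negll, contrast = contrast,
                      n_trials = n_trials, n_correct = n_correct,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best
}

.pf_starts <- function(contrast, n_restarts) {
  rng <- range(contrast)
  det <- c(stats::median(contrast), log(max(diff(rng) / 5, 1e-3)),
           stats::qlogis(2 * 0.02))
  n_rand <- max(n_restarts - 1L, 0L)
  rand <- cbind(stats::runif(n_rand, rng[1L], rng[2L]),
                log(max(diff(rng) / 4, 1e-3)) + stats::runif(n_rand, -1.5, 1.5),
                stats::qlogis(2 * stats::runif(n_rand, 0.005, 0.35)))
  rbind(det, rand, deparse.level = 0L)
}

.pf_check_cells <- function(cells) {
  need <- c("contrast_pct", "n_trials", "n_correct")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$n_trials <= 0) || any(cells$n_correct < 0) ||
      any(cells$n_correct > cells$n_trials)) {
    stop("cell counts must satisfy 0 <= n_correct <= n_trials, n_trials > 0",
         call. = FALSE)
  }
  if (length(unique(cells$contrast_pct)) < 3L) {
    stop("need at least 3 distinct contrast levels", call. = FALSE)
  }
  for (col in c("condition", "orientation_deg")) {
    if (col %in% names(cells) && length(unique(cells[[col]])) > 1L) {
      stop("fit one condition x orientation at a time (found several `",
           col, "` values)", call. = FALSE)
    }
  }
  invisible(cells)
}

# Saturated-vs-fitted deviance for binomial cells.
.pf_deviance <- function(est, cells) {
  pr <- psi(cells$contrast_pct, est[["c_m"]], est[["s"]], est[["lam"]])
  pr <- pmin(pr, 1 - 1e-9)
  ph <- pmin(pmax(cells$n_correct / cells$n_trials, 1e-9), 1 - 1e-9)
  ll_fit <- sum(cells$n_correct * log(pr) +
                (cells$n_trials - cells$n_correct) * log(1 - pr))
  ll_sat <- sum(cells$n_correct * log(ph) +
                (cells$n_trials - cells$n_correct) * log(1 - ph))
  2 * (ll_sat - ll_fit)
}

#' Fit the psychometric function by maximum likelihood
#'
#' Fits `(c_m, s, lam)` of [psi()] to aggregated 2AFC cell counts for a
#' single condition x orientation by maximizing the binomial log-likelihood,
#' using a derivative-free simplex from multiple randomized starting values.
#' Bounds (`s > 0`, `0 <= lam <= 0.5`) are enforced by log/logit
#' transforms. Degenerate data (all chance, all correct) produce a fit with
#' the `boundary` flag set rather than an error.
#'
#' @param cells Data frame with columns `contrast_pct`, `n_trials`,
#'   `n_correct` (optionally `condition` and `orientation_deg`, which must
#'   then be constant); at least 3 distinct contrasts.
#' @param n_restarts Number of simplex starts (first is deterministic).
#' @param seed Optional integer seed making the randomized starts
#'   reproducible.
#' @param start Optional named vector `c(c_m, s, lam)` used as an
#'   additional starting point.
#' @return An object of class `pf_fit` with elements `estimates`
#'   (`c_m`, `s`, `lam`), `loglik`, `deviance`, `converged`, `boundary`,
#'   `n_restarts`, `cells`, `condition`, `orientation`, `seed`.
#' @export
fit_psychometric <- function(cells, n_restarts = 10L, seed = NULL,
                             start = NULL) {
  cells <- as.data.frame(cells)
  .pf_check_cells(cells)
  if (!is.null(seed)) set.seed(seed)
  starts <- .pf_starts(cells$contrast_pct, n_restarts)
  if (!is.null(start)) starts <- rbind(.pf_trans(start), starts)
  best <- .pf_optim(cells$contrast_pct, cells$n_trials, cells$n_correct,
                    starts)
  est <- .pf_nat(best$par)
  psi_hat <- psi(cells$contrast_pct, est[["c_m"]], est[["s"]], est[["lam"]])
  boundary <- est[["lam"]] > 0.5 - 1e-3 || est[["lam"]] < 1e-4 ||
    est[["c_m"]] < min(cells$contrast_pct) ||
    est[["c_m"]] > max(cells$contrast_pct) ||
    max(psi_hat) < 0.52 ||   # effectively flat at chance
    min(psi_hat) > 0.98      # effectively perfect everywhere
  structure(list(
    estimates = est,
    loglik = -best$value,
    deviance = .pf_deviance(est, cells),
    converged = best$convergence == 0L,
    boundary = boundary,
    n_restarts = nrow(starts),
    cells = cells,
    condition = if ("condition" %in% names(cells))
      as.character(cells$condition[1L]) else NA_character_,
    orientation = if ("orientation_deg" %in% names(cells))
      cells$orientation_deg[1L] else NA_real_,
    seed = seed
  ), class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat("Psychometric fit")
  if (!is.na(x$condition) || !is.na(x$orientation)) {
    cat(" [", x$condition, ", ", x$orientation, " deg]", sep = "")
  }
  cat(sprintf("\n  c_m=%.3f%%  s=%.3f%%  lam=%.4f  (ceiling %.1f%%)\n",
              x$estimates[["c_m"]], x$estimates[["s"]],
              x$estimates[["lam"]], 100 * (1 - x$estimates[["lam"]])))
  cat(sprintf("  logLik %.3f, deviance %.3f%s%s\n", x$loglik, x$deviance,
              if (x$converged) "" else " (not converged)",
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' @export
coef.pf_fit <- function(object, ...) object$estimates

#' @export
logLik.pf_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = sum(object$cells$n_trials),
            class = "logLik")
}

#' @export
predict.pf_fit <- function(object, contrast = NULL, ...) {
  if (is.null(contrast)) contrast <- object$cells$contrast_pct
  psi(contrast, object$estimates[["c_m"]], object$estimates[["s"]],
      object$estimates[["lam"]])
}

# Simulate binomial cell counts from a psychometric parameter vector at the
# design of `cells`.
.pf_simulate_cells <- function(est, cells) {
  pr <- psi(cells$contrast_pct, est[["c_m"]], est[["s"]], est[["lam"]])
  cells$n_correct <- stats::rbinom(nrow(cells), cells$n_trials, pr)
  cells
}

# Quick refit used inside bootstrap loops: parent estimates plus
# (n_restarts - 1) random starts.
.pf_refit <- function(cells, parent_est, n_restarts = 2L) {
  starts <- rbind(.pf_trans(parent_est), deparse.level = 0L)
  if (n_restarts > 1L) {
    starts <- rbind(starts,
                    .pf_starts(cells$contrast_pct, n_restarts - 1L))
  }
  best <- .pf_optim(cells$contrast_pct, cells$n_trials, cells$n_correct,
                    starts)
  .pf_nat(best$par)
}

#' Parametric-bootstrap goodness of fit via the deviance
#'
#' Simulates `n_boot` binomial data sets from the fitted psychometric
#' function at the observed design, refits each, and compares the observed
#' deviance (twice the log-likelihood ratio of the saturated model to the
#' fit) with the bootstrap distribution.
#'
#' @param fit A `pf_fit` object.
#' @param n_boot Number of bootstrap samples (>= 1; 10000 for final
#'   inference, fewer for exploration).
#' @param seed Integer seed.
#' @param n_restarts_boot Simplex starts per bootstrap refit (the first is
#'   the parent fit).
#' @return List with `p_value` (proportion of bootstrap deviances >= the
#'   observed one), `observed_deviance`, `boot_deviance`, `n_boot`.
#' @export
deviance_gof <- function(fit, n_boot = 10000L, seed = NULL,
                         n_restarts_boot = 2L) {
  stopifnot(inherits(fit, "pf_fit"))
  if (!is.numeric(n_boot) || n_boot < 1L) {
    stop("`n_boot` must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dev <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim <- .pf_simulate_cells(fit$estimates, fit$cells)
    est_b <- .pf_refit(sim, fit$estimates, n_restarts_boot)
    dev[b] <- .pf_deviance(est_b, sim)
  }
  list(p_value = mean(dev >= fit$deviance),
       observed_deviance = fit$deviance,
       boot_deviance = dev, n_boot = n_boot)
}

#' Parametric-bootstrap confidence intervals for psychometric parameters
#'
#' Percentile intervals from refits of data simulated under the fitted
#' function.
#'
#' @inheritParams deviance_gof
#' @param level Confidence level (default 0.95).
#' @return A 3 x 2 matrix of lower/upper limits for `c_m`, `s`, `lam`, with
#'   the bootstrap draws attached as attribute `"boot"`.
#' @export
bootstrap_pf_ci <- function(fit, n_boot = 10000L, seed = NULL,
                            level = 0.95, n_restarts_boot = 2L) {
  stopifnot(inherits(fit, "pf_fit"), n_boot >= 1L)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 3L,
                  dimnames = list(NULL, c("c_m", "s", "lam")))
  for (b in seq_len(n_boot)) {
    sim <- .pf_simulate_cells(fit$estimates, fit$cells)
    draws[b, ] <- .pf_refit(sim, fit$estimates, n_restarts_boot)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha)))
  attr(ci, "boot") <- draws
  ci
}

# ---- shared-ceiling null model for the lambda tests ----------------------
# Plug-in construction: each group keeps its unconstrained midpoint and
# slope, and the single shared ceiling deficit is estimated by 1-D ML with
# those shapes held fixed. (Refitting all shapes jointly under the
# constraint can degenerate when the groups' ceilings genuinely differ —
# the constrained optimum then pushes a midpoint far beyond the tested
# range, and data simulated from it no longer identify lambda at all.)
.pf_fit_shared <- function(groups, fits) {
  shapes <- lapply(fits, function(f) f$estimates)
  nll_lam <- function(lam) {
    tot <- 0
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      pr <- psi(g$contrast_pct, shapes[[k]][["c_m"]], shapes[[k]][["s"]],
                lam)
      pr <- pmin(pr, 1 - 1e-9)
      tot <- tot - sum(g$n_correct * log(pr) +
                       (g$n_trials - g$n_correct) * log(1 - pr))
    }
    tot
  }
  o <- stats::optimize(nll_lam, c(1e-6, 0.5 - 1e-6), tol = 1e-8)
  lam <- o$minimum
  per_group <- lapply(shapes, function(s) {
    c(c_m = s[["c_m"]], s = s[["s"]], lam = lam)
  })
  list(par = per_group, lam = lam, value = o$objective, converged = TRUE)
}

#' Test a ceiling difference between two conditions
#'
#' Two-sided parametric-bootstrap test of `lam_1 - lam_2` between two
#' psychometric fits on the same orientation (typically AM vs Flicker). The
#' null model constrains the two conditions to share one ceiling deficit
#' while keeping separate midpoints and slopes; data simulated under this
#' shared-ceiling model are refit without the constraint to build the null
#' distribution of the ceiling difference.
#'
#' @param fit_am,fit_flicker `pf_fit` objects for the two conditions.
#' @param n_boot Number of bootstrap samples.
#' @param seed Integer seed.
#' @param n_restarts_boot Simplex starts per bootstrap refit.
#' @return List with `delta_lambda` (`fit_am` minus `fit_flicker`),
#'   `p_value` (two-sided, `(1 + #{|null| >= |obs|}) / (1 + n_boot)`),
#'   `lambda_shared`, `null_deltas`, `n_boot`.
#' @export
compare_lambda <- function(fit_am, fit_flicker, n_boot = 1000L, seed = NULL,
                           n_restarts_boot = 2L) {
  stopifnot(inherits(fit_am, "pf_fit"), inherits(fit_flicker, "pf_fit"))
  o1 <- fit_am$orientation; o2 <- fit_flicker$orientation
  if (!is.na(o1) && !is.na(o2) && o1 != o2) {
    stop("fits are for different orientations (", o1, " vs ", o2, ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  delta <- fit_am$estimates[["lam"]] - fit_flicker$estimates[["lam"]]
  groups <- list(fit_am$cells, fit_flicker$cells)
  null_fit <- .pf_fit_shared(groups, list(fit_am, fit_flicker))
  null_deltas <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    e1 <- .pf_refit(.pf_simulate_cells(null_fit$par[[1L]], groups[[1L]]),
                    null_fit$par[[1L]], n_restarts_boot)
    e2 <- .pf_refit(.pf_simulate_cells(null_fit$par[[2L]], groups[[2L]]),
                    null_fit$par[[2L]], n_restarts_boot)
    null_deltas[b] <- e1[["lam"]] - e2[["lam"]]
  }
  p <- (1 + sum(abs(null_deltas) >= abs(delta))) / (1 + n_boot)
  list(delta_lambda = delta, p_value = p, lambda_shared = null_fit$lam,
       null_deltas = null_deltas, n_boot = n_boot)
}

#' Regression of maximum performance on target orientation
#'
#' Ordinary least squares of the fitted maximum performance `1 - lam` on
#' orientation (degrees), with a parametric-bootstrap p-value: the null
#' model shares one ceiling deficit across orientations (separate midpoints
#' and slopes), simulated data are refit per orientation, and the two-sided
#' p-value compares the observed slope against the null slope distribution.
#'
#' @param fits List of `pf_fit` objects, one per orientation (>= 3 levels);
#'   each must carry its orientation (fit on cells with an
#'   `orientation_deg` column).
#' @inheritParams compare_lambda
#' @return List with `slope` (proportion per degree), `p_value`,
#'   `orientations`, `lambdas`, `null_slopes`, `n_boot`.
#' @export
lambda_orientation_regression <- function(fits, n_boot = 1000L, seed = NULL,
                                          n_restarts_boot = 2L) {
  if (length(fits) < 3L) {
    stop("need fits at >= 3 orientation levels", call. = FALSE)
  }
  ori <- vapply(fits, function(f) f$orientation, 0)
  if (any(is.na(ori)) || anyDuplicated(ori) > 0L) {
    stop("each fit must carry a distinct orientation", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  slope_of <- function(lams) {
    y <- 1 - lams
    sum((ori - mean(ori)) * (y - mean(y))) / sum((ori - mean(ori))^2)
  }
  lams <- vapply(fits, function(f) f$estimates[["lam"]], 0)
  slope <- slope_of(lams)
  groups <- lapply(fits, function(f) f$cells)
  null_fit <- .pf_fit_shared(groups, fits)
  null_slopes <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    lam_b <- vapply(seq_along(groups), function(k) {
      est <- .pf_refit(.pf_simulate_cells(null_fit$par[[k]], groups[[k]]),
                       null_fit$par[[k]], n_restarts_boot)
      est[["lam"]]
    }, 0)
    null_slopes[b] <- slope_of(lam_b)
  }
  p <- (1 + sum(abs(null_slopes) >= abs(slope))) / (1 + n_boot)
  list(slope = slope, p_value = p, orientations = ori, lambdas = lams,
       null_slopes = null_slopes, n_boot = n_boot)
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the number of comparisons and caps at 1.
#'
#' @param p Numeric vector of p-values.
#' @param n_comparisons Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, n_comparisons = length(p)) {
  pmin(1, p * n_comparisons)
}
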