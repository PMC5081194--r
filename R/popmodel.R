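# Canonical ordering of the potentially-free parameters; AM tuning
# concentrations come after k_exc because their transform is relative to it.
.pop_free_syms <- c("c50", "r0", "p", "k_exc", "epsilon",
                    "alpha", "beta", "gamma", "k_exc_AM", "k_inh_AM")
.pop_all_syms <- c(.pop_free_syms,
                   "k_inh", "r_max", "zeta", "t", "inducer_orientation")

#' Specification of the population model to fit
#'
#' Declares which parameters are estimated and which are frozen. The full
#' model frees all ten of `c50, r0, p, k_exc, epsilon, alpha, beta, gamma,
#' k_exc_AM, k_inh_AM`; `k_inh`, `r_max`, `zeta`, the stimulus duration and
#' the inducer orientation are always fixed (they are poorly constrained by
#' 2AFC data and are set to physiologically plausible values). Nested
#' reductions are expressed by removing parameters from `free` and
#' supplying their frozen values in `fixed` (e.g. `gamma = 0` for the
#' no-suppression model, or `k_exc_AM = k_inh_AM = 0.001` for the untuned
#' AM-effects model).
#'
#' Constraints enforced during fitting: `r0 <= 0.05 * r_max`, `p >= 2`,
#' `0 < epsilon <= 1`, `0 <= gamma <= 1`, `alpha, beta >= 0`, and the AM
#' effect tuning may not be narrower than the excitatory tuning
#' (`k_exc_AM <= k_exc`, `k_inh_AM <= k_exc`).
#'
#' @param free Character vector of parameters to estimate (subset of the
#'   ten above; order is irrelevant).
#' @param fixed Named list of frozen values; merged over the defaults
#'   `k_inh = 0.001`, `r_max = 100`, `zeta = 1.9`, `t = 0.0308`,
#'   `inducer_orientation = 0`. Every non-free parameter must end up with a
#'   fixed value.
#' @param n_neurons Number of units on the uniform preferred-orientation
#'   grid over [0, 180).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(free = .pop_free_syms, fixed = list(),
                       n_neurons = 36L) {
  if (!all(free %in% .pop_free_syms)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, .pop_free_syms), collapse = ", "),
         call. = FALSE)
  }
  free <- .pop_free_syms[.pop_free_syms %in% free]
  default_fixed <- list(k_inh = 0.001, r_max = 100, zeta = 1.9, t = 0.0308,
                        inducer_orientation = 0)
  fixed <- utils::modifyList(default_fixed, as.list(fixed))
  clash <- intersect(free, names(fixed))
  if (length(clash) > 0L) {
    stop("parameter(s) both free and fixed: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.pop_all_syms, c(free, names(fixed)))
  if (length(missing) > 0L) {
    stop("no value for non-free parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1L)
  structure(list(free = free, fixed = fixed, n_neurons = n_neurons),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Population model spec: ", length(x$free), " free parameter(s) [",
      paste(x$free, collapse = ", "), "], ", x$n_neurons, " units\n",
      sep = "")
  invisible(x)
}

.spec_grid <- function(spec) {
  seq(0, by = 180 / spec$n_neurons, length.out = spec$n_neurons)
}

# Map the unconstrained optimizer vector to the natural parameter list.
# Transforms: log for scales and concentrations, scaled logistic for
# bounded fractions, 2 + exp for the exponent, and k_AM = k_exc * logistic
# so the AM tuning can never be narrower than the excitatory tuning.
.pop_natural <- function(u, spec) {
  pars <- spec$fixed
  i <- 0L
  for (nm in spec$free) {
    i <- i + 1L
    v <- u[[i]]
    pars[[nm]] <- switch(nm,
      c50 = exp(v),
      r0 = 0.05 * pars$r_max * stats::plogis(v),
      p = 2 + exp(v),
      k_exc = exp(v),
      epsilon = stats::plogis(v),
      alpha = exp(v),
      beta = exp(v),
      gamma = stats::plogis(v),
      k_exc_AM = pars$k_exc * stats::plogis(v),
      k_inh_AM = pars$k_exc * stats::plogis(v))
  }
  pars
}

.clamp01 <- function(x, eps = 1e-8) min(max(x, eps), 1 - eps)

# Inverse of .pop_natural for a full natural parameter list (free entries
# only). Values outside bounds are projected inside first.
.pop_transformed <- function(pars, spec) {
  pars <- .pop_project(pars, spec)
  u <- numeric(length(spec$free))
  i <- 0L
  for (nm in spec$free) {
    i <- i + 1L
    x <- pars[[nm]]
    u[[i]] <- switch(nm,
      c50 = log(x),
      r0 = stats::qlogis(.clamp01(x / (0.05 * pars$r_max))),
      p = log(x - 2),
      k_exc = log(x),
      epsilon = stats::qlogis(.clamp01(x)),
      alpha = log(x),
      beta = log(x),
      gamma = stats::qlogis(.clamp01(x)),
      k_exc_AM = stats::qlogis(.clamp01(x / pars$k_exc)),
      k_inh_AM = stats::qlogis(.clamp01(x / pars$k_exc)))
  }
  u
}

# Project a (possibly out-of-bounds) natural parameter list into the
# constraint region.
.pop_project <- function(pars, spec) {
  r_max <- pars$r_max
  pars$c50 <- max(pars$c50, 1e-8)
  pars$r0 <- min(max(pars$r0, 1e-8), 0.05 * r_max * (1 - 1e-8))
  pars$p <- max(pars$p, 2 + 1e-8)
  pars$k_exc <- max(pars$k_exc, 1e-8)
  pars$epsilon <- .clamp01(pars$epsilon)
  pars$alpha <- max(pars$alpha, 1e-9)
  pars$beta <- max(pars$beta, 1e-9)
  pars$gamma <- .clamp01(pars$gamma, 1e-9)
  pars$k_exc_AM <- min(max(pars$k_exc_AM, 1e-9),
                       pars$k_exc * (1 - 1e-9))
  pars$k_inh_AM <- min(max(pars$k_inh_AM, 1e-9),
                       pars$k_exc * (1 - 1e-9))
  pars
}

# Proportion correct for a vector of contrasts at one (condition,
# orientation) cell group. `pars` is a flat natural parameter list; th the
# preferred-orientation grid. Flicker groups zero the AM effects exactly.
.pop_pc_group <- function(contrasts, orientation, am_on, pars, th) {
  f <- vm_tuning(orientation - th, pars$k_exc)
  g <- vm_tuning(orientation - th, pars$k_inh)
  if (am_on) {
    h <- vm_tuning(pars$inducer_orientation - th, pars$k_exc_AM)
    j <- vm_tuning(pars$inducer_orientation - th, pars$k_inh_AM)
    a <- pars$alpha; b <- pars$beta; gm <- pars$gamma
  } else {
    h <- 0; j <- 0; a <- 0; b <- 0; gm <- 0
  }
  cc <- c(contrasts, 0)
  L <- outer(f, cc) + a * h
  G <- outer(g, cc) + b * j
  frac <- .norm_frac(L, G, pars$c50, pars$p)
  resp <- pars$t * (pars$r0 + (1 - gm * h) * pars$r_max * frac)
  S <- colSums(resp)
  m <- length(contrasts)
  s_blk <- S[[m + 1L]]
  mu <- S[seq_len(m)] - s_blk
  sig <- sqrt(pars$zeta * (S[seq_len(m)] + s_blk)) / pars$epsilon
  stats::pnorm(mu / sig)
}

# Precompute everything the likelihood needs that does not depend on the
# free parameters: the tuning-curve exponent arguments on the orientation
# grid, the (fixed-k_inh) gain-pool weights, and an index layout that
# appends one blank (contrast 0) pseudo-cell per (condition, orientation)
# group so a single vectorized pass yields all summed responses.
.pop_prep <- function(cells, spec) {
  th <- .spec_grid(spec)
  uo <- sort(unique(cells$orientation_deg))
  A <- 2 * (cos(outer(th, uo, "-") * (pi / 90)) - 1)      # N x n_ori
  a_ind <- 2 * (cos((spec$fixed$inducer_orientation - th) * (pi / 90)) - 1)
  Ginh <- exp(spec$fixed$k_inh * A)
  key <- paste(cells$condition, cells$orientation_deg)
  ukey <- unique(key)
  grp <- match(key, ukey)
  nc <- nrow(cells)
  ng <- length(ukey)
  blank_cond <- cells$condition[match(ukey, key)]
  blank_ori <- cells$orientation_deg[match(ukey, key)]
  gidx <- c(match(cells$orientation_deg, uo), match(blank_ori, uo))
  amflag <- as.numeric(c(cells$condition, blank_cond) == "AM")
  cvec <- c(cells$contrast_pct, rep(0, ng))
  list(A = A, a_ind = a_ind, Ginh_cells = Ginh[, gidx, drop = FALSE],
       gidx = gidx, amflag = amflag,
       cE = matrix(rep(cvec, each = length(th)), nrow = length(th)),
       obs_idx = seq_len(nc), blank_of = nc + grp,
       n = cells$n_trials, x = cells$n_correct)
}

.pop_negll <- function(u, spec, prep) {
  pars <- .pop_natural(u, spec)
  FF <- exp(pars$k_exc * prep$A)[, prep$gidx, drop = FALSE]
  h <- exp(pars$k_exc_AM * prep$a_ind)
  j <- exp(pars$k_inh_AM * prep$a_ind)
  L <- FF * prep$cE + outer(h, pars$alpha * prep$amflag)
  G <- prep$Ginh_cells * prep$cE + outer(j, pars$beta * prep$amflag)
  la <- pars$p * log(L)
  lb <- pars$p * log(pars$c50)
  ld <- pars$p * log(G)
  hi <- pmax(ld, lb)
  frac <- exp(la - (hi + log1p(exp(pmin(ld, lb) - hi))))
  gain <- 1 - pars$gamma * outer(h, prep$amflag)
  S <- colSums(pars$t * (pars$r0 + gain * pars$r_max * frac))
  s_obs <- S[prep$obs_idx]
  s_blk <- S[prep$blank_of]
  pc <- stats::pnorm((s_obs - s_blk) /
                       (sqrt(pars$zeta * (s_obs + s_blk)) / pars$epsilon))
  pc <- pmin(pmax(pc, 1e-9), 1 - 1e-9)
  nll <- -sum(prep$x * log(pc) + (prep$n - prep$x) * log(1 - pc))
  if (!is.finite(nll)) 1e10 else nll
}

.pop_check_cells <- function(cells) {
  need <- c("condition", "orientation_deg", "contrast_pct", "n_trials",
            "n_correct")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) == 0L) stop("no cells to fit", call. = FALSE)
  if (any(cells$n_trials <= 0) || any(cells$n_correct < 0) ||
      any(cells$n_correct > cells$n_trials)) {
    stop("cell counts must satisfy 0 <= n_correct <= n_trials, n_trials > 0",
         call. = FALSE)
  }
  if (!all(cells$condition %in% c("AM", "Flicker"))) {
    stop("condition must be 'AM' or 'Flicker'", call. = FALSE)
  }
  invisible(cells)
}

# Random starting values, drawn log-uniform (or uniform for bounded
# fractions) over generous physiological ranges.
.pop_random_start <- function(spec) {
  pars <- spec$fixed
  runif1 <- function(lo, hi) stats::runif(1L, lo, hi)
  for (nm in spec$free) {
    pars[[nm]] <- switch(nm,
      c50 = exp(runif1(log(3), log(25))),
      r0 = runif1(0.2, 0.95) * 0.05 * pars$r_max,
      p = 2 + exp(runif1(log(0.5), log(6))),
      k_exc = exp(runif1(log(0.4), log(4))),
      epsilon = runif1(0.25, 0.95),
      alpha = exp(runif1(log(0.05), log(4))),
      beta = exp(runif1(log(0.05), log(4))),
      gamma = runif1(0.05, 0.9),
      k_exc_AM = pars$k_exc * exp(runif1(log(1e-3), log(0.95))),
      k_inh_AM = pars$k_exc * exp(runif1(log(1e-3), log(0.95))))
  }
  pars
}

.pop_det_start <- function(spec) {
  utils::modifyList(
    list(c50 = 10, r0 = 2, p = 3.5, k_exc = 1.5, epsilon = 0.6,
         alpha = 0.5, beta = 0.5, gamma = 0.3, k_exc_AM = 0.75,
         k_inh_AM = 0.01)[.pop_free_syms %in% spec$free],
    spec$fixed)[c(spec$free, names(spec$fixed))]
}

#' Fit the population-code model to 2AFC cell counts
#'
#' Joint maximum-likelihood fit of the AM-extended contrast-normalization
#' population model to aggregated 2AFC data from both conditions. The
#' binomial log-likelihood of the analytic decoder predictions is maximized
#' by a derivative-free simplex from multiple randomized starting values;
#' all constraints (see [model_spec()]) are enforced by smooth transforms,
#' so out-of-bounds starting values are projected into the feasible region
#' rather than rejected.
#'
#' @param cells Data frame with columns `condition` (`"AM"`/`"Flicker"`),
#'   `orientation_deg`, `contrast_pct`, `n_trials`, `n_correct`.
#' @param spec A [model_spec()].
#' @param n_restarts Total number of simplex starts: a provided `start`
#'   first, then a deterministic start, then randomized draws. The best
#'   final likelihood wins; ties go to the first found.
#' @param seed Integer seed for the randomized starts.
#' @param start Optional named list of natural-scale starting values
#'   (free parameters; out-of-bounds values are projected inside).
#' @param maxit Iteration cap per simplex run.
#' @param n_polish Maximum number of quasi-Newton/simplex polish rounds
#'   applied to the winning start (1 is enough for warm-started bootstrap
#'   refits).
#' @return An object of class `popcode_fit` with elements `estimates`
#'   (named list, natural scale), `fixed`, `spec`, `loglik`, `aic`,
#'   `n_params`, `converged`, `restarts`, `seed`, `data`, `fitted` (the
#'   predicted proportion-correct table at the observed design).
#' @export
fit_population_model <- function(cells, spec = model_spec(),
                                 n_restarts = 20L, seed = NULL,
                                 start = NULL, maxit = 3000L,
                                 n_polish = 6L) {
  cells <- as.data.frame(cells)
  .pop_check_cells(cells)
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_restarts <- max(as.integer(n_restarts), 1L)
  prep <- .pop_prep(cells, spec)

  starts <- list()
  if (!is.null(start)) {
    st <- utils::modifyList(.pop_det_start(spec), as.list(start))
    starts <- c(starts, list(.pop_transformed(st, spec)))
  }
  if (length(starts) < n_restarts) {
    starts <- c(starts, list(.pop_transformed(.pop_det_start(spec), spec)))
  }
  while (length(starts) < n_restarts) {
    starts <- c(starts,
                list(.pop_transformed(.pop_random_start(spec), spec)))
  }

  best <- NULL
  n_ok <- 0L
  for (u0 in starts) {
    o <- tryCatch(
      stats::optim(u0, .pop_negll, spec = spec, prep = prep,
                   method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e10) next
    n_ok <- n_ok + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("model fit failed: non-finite likelihood at all ",
         length(starts), " starting points", call. = FALSE)
  }
  # The likelihood surface has long curved ridges (k_exc trades off against
  # epsilon and the nonlinearity), which a simplex alone crawls along.
  # Alternate quasi-Newton and simplex polish runs on the winner until the
  # objective stops improving.
  for (round in seq_len(n_polish)) {
    ob <- tryCatch(
      stats::optim(best$par, .pop_negll, spec = spec, prep = prep,
                   method = "BFGS",
                   control = list(maxit = 200L, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(ob) && is.finite(ob$value) && ob$value < best$value) {
      best <- ob
    }
    o2 <- stats::optim(best$par, .pop_negll, spec = spec, prep = prep,
                       method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
    improved <- best$value - o2$value
    if (o2$value < best$value) best <- o2
    if (improved < 1e-6) break
  }

  pars <- .pop_natural(best$par, spec)
  k <- length(spec$free)
  ll <- -best$value
  fit <- structure(list(
    estimates = pars[spec$free],
    fixed = spec$fixed,
    spec = spec,
    loglik = ll,
    aic = 2 * k - 2 * ll,
    n_params = k,
    n_neurons = spec$n_neurons,
    converged = best$convergence == 0L,
    restarts = length(starts),
    n_restarts_ok = n_ok,
    seed = seed,
    data = cells,
    fitted = NULL
  ), class = "popcode_fit")
  fit$fitted <- stats::predict(fit)
  fit
}

# Full natural parameter list (free + fixed) of a fit.
.pop_fit_pars <- function(fit) {
  c(fit$estimates, fit$fixed)
}

#' @export
print.popcode_fit <- function(x, ...) {
  cat("Population-code model fit (", x$n_params, " free parameters, ",
      x$n_neurons, " units)\n", sep = "")
  est <- unlist(x$estimates)
  cat("  ", paste(sprintf("%s=%.4g", names(est), est), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  logLik %.3f  AIC %.3f%s\n", x$loglik, x$aic,
              if (x$converged) "" else "  (not converged)"))
  invisible(x)
}

#' @export
summary.popcode_fit <- function(object, ...) {
  cat("Population-code model of AM masking\n")
  print(object$spec)
  cat("Free estimates:\n")
  print(unlist(object$estimates))
  cat("Fixed:\n")
  print(unlist(object$fixed))
  cat(sprintf("logLik %.3f  AIC %.3f  trials %d\n", object$loglik,
              object$aic, sum(object$data$n_trials)))
  invisible(object)
}

#' @export
coef.popcode_fit <- function(object, ...) unlist(object$estimates)

#' @export
logLik.popcode_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = sum(object$data$n_trials), class = "logLik")
}

#' @export
predict.popcode_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  .pop_predict_table(.pop_fit_pars(object), newdata,
                     .spec_grid(object$spec))
}

#' @export
simulate.popcode_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- object$fitted
  lapply(seq_len(nsim), function(b) {
    out <- object$data
    out$n_correct <- stats::rbinom(nrow(out), out$n_trials, tab$pc)
    out
  })
}

#' @export
residuals.popcode_fit <- function(object, ...) {
  obs <- object$data$n_correct / object$data$n_trials
  pc <- object$fitted$pc
  sgn <- sign(obs - pc)
  x <- object$data$n_correct; n <- object$data$n_trials
  ph <- pmin(pmax(obs, 1e-9), 1 - 1e-9)
  pcl <- pmin(pmax(pc, 1e-9), 1 - 1e-9)
  dev <- 2 * (x * log(ph / pcl) + (n - x) * log((1 - ph) / (1 - pcl)))
  sgn * sqrt(pmax(dev, 0))
}

# Predicted proportion correct for each row of a design data frame.
.pop_predict_table <- function(pars, design, th) {
  design <- as.data.frame(design)
  need <- c("condition", "orientation_deg", "contrast_pct")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pc <- numeric(nrow(design))
  key <- interaction(design$condition, design$orientation_deg, drop = TRUE)
  for (idx in split(seq_len(nrow(design)), key)) {
    pc[idx] <- .pop_pc_group(design$contrast_pct[idx],
                             design$orientation_deg[idx[1L]],
                             design$condition[idx[1L]] == "AM", pars, th)
  }
  out <- design[c("condition", "orientation_deg", "contrast_pct")]
  out$pc <- pc
  out
}

#' Predicted proportion-correct table of the population model
#'
#' Analytic decoder predictions for every row of a design (condition,
#' orientation, contrast). Flicker rows use the standard normalization
#' model; AM rows apply the AM effect terms at the inducer orientation.
#'
#' @param design A data frame with columns `condition`, `orientation_deg`,
#'   `contrast_pct`, or an [experiment_design()] object.
#' @param pop A [population_params()] object.
#' @param am An [am_params()] object (applied to AM rows only).
#' @param epsilon Decoder efficiency in (0, 1].
#' @return The design with a `pc` column appended.
#' @export
predict_pc_table <- function(design, pop, am, epsilon) {
  stopifnot(inherits(pop, "population_params"), inherits(am, "am_params"))
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon > 1) {
    stop("`epsilon` must be a fraction in (0, 1]", call. = FALSE)
  }
  if (inherits(design, "experiment_design")) design <- design_cells(design)
  pop_l <- unclass(pop)
  am_l <- unclass(am)
  pars <- c(pop_l[setdiff(names(pop_l), "preferred_orientations")],
            am_l, list(epsilon = epsilon))
  .pop_predict_table(pars, design, pop$preferred_orientations)
}

#' Post-fit ablation of AM effect parameters
#'
#' Recomputes the predicted proportion-correct table with a subset of the
#' AM effect magnitudes (`alpha`, `beta`, `gamma`) forced to zero while all
#' other parameters keep their fitted values. Used to attribute masking to
#' individual mechanisms: zeroing `gamma` removes response-gain
#' suppression (revealing pedestal facilitation at low contrast), zeroing
#' `alpha` and `beta` removes the filling-in excitation and inhibition.
#'
#' @param fit A `popcode_fit` object.
#' @param zero Character vector, subset of `c("alpha", "beta", "gamma")`.
#' @param design Optional design data frame (defaults to the fitted data).
#' @return Predicted proportion-correct table.
#' @export
ablate_post_fit <- function(fit, zero = character(), design = NULL) {
  stopifnot(inherits(fit, "popcode_fit"))
  if (!all(zero %in% c("alpha", "beta", "gamma"))) {
    stop("`zero` must be a subset of alpha, beta, gamma", call. = FALSE)
  }
  pars <- .pop_fit_pars(fit)
  for (nm in zero) pars[[nm]] <- 0
  if (is.null(design)) design <- fit$data
  .pop_predict_table(pars, design, .spec_grid(fit$spec))
}

#' Parametric-bootstrap comparison of nested population models
#'
#' Compares a full and a reduced model by their AIC difference. The
#' observed statistic is `AIC(reduced) - AIC(full)`; its null distribution
#' is built by simulating data sets from the *reduced* fit at the observed
#' design and refitting both models to each. The p-value is the upper-tail
#' bootstrap probability `(1 + #{null >= observed}) / (1 + n_boot)`.
#'
#' @param fit_full,fit_reduced `popcode_fit` objects on the same data; the
#'   reduced spec should free a subset of the full spec's parameters (a
#'   non-nested pair is flagged with a warning but still compared).
#' @param n_boot Number of bootstrap samples.
#' @param seed Integer seed.
#' @param n_restarts_boot Simplex starts per bootstrap refit (first start
#'   is the parent estimate).
#' @param maxit_boot Iteration cap per bootstrap refit.
#' @return List with `aic_difference`, `p_value`, `nested`, `null_diffs`,
#'   `n_boot`.
#' @export
compare_models_aic <- function(fit_full, fit_reduced, n_boot = 100L,
                               seed = NULL, n_restarts_boot = 2L,
                               maxit_boot = 1000L) {
  stopifnot(inherits(fit_full, "popcode_fit"),
            inherits(fit_reduced, "popcode_fit"))
  nested <- all(fit_reduced$spec$free %in% fit_full$spec$free)
  if (!nested) {
    warning("model specs are not nested; comparison computed anyway")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- fit_reduced$aic - fit_full$aic
  null_diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim <- simulate(fit_reduced)[[1L]]
    rf_full <- fit_population_model(sim, fit_full$spec,
                                    n_restarts = n_restarts_boot,
                                    start = fit_full$estimates,
                                    maxit = maxit_boot, n_polish = 1L)
    rf_red <- fit_population_model(sim, fit_reduced$spec,
                                   n_restarts = n_restarts_boot,
                                   start = fit_reduced$estimates,
                                   maxit = maxit_boot, n_polish = 1L)
    null_diffs[b] <- rf_red$aic - rf_full$aic
  }
  p <- (1 + sum(null_diffs >= obs)) / (1 + n_boot)
  list(aic_difference = obs, p_value = p, nested = nested,
       null_diffs = null_diffs, n_boot = n_boot)
}

#' Parametric-bootstrap confidence intervals for the population model
#'
#' Simulates data sets from the fitted model at the observed design, refits
#' each, and returns percentile intervals per free parameter.
#'
#' @param fit A `popcode_fit`.
#' @param n_boot Number of bootstrap samples (1000 for final inference).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param n_restarts_boot Simplex starts per refit.
#' @param maxit_boot Iteration cap per refit.
#' @return Matrix (free parameters x 2) of interval limits, with the
#'   bootstrap draws as attribute `"boot"`. Errors if more than 20% of the
#'   refits fail.
#' @export
bootstrap_model_ci <- function(fit, n_boot = 1000L, seed = NULL,
                               level = 0.95, n_restarts_boot = 2L,
                               maxit_boot = 1000L) {
  stopifnot(inherits(fit, "popcode_fit"), n_boot >= 1L)
  if (!is.null(seed)) set.seed(seed)
  free <- fit$spec$free
  draws <- matrix(NA_real_, n_boot, length(free),
                  dimnames = list(NULL, free))
  failures <- character(0)
  for (b in seq_len(n_boot)) {
    sim <- simulate(fit)[[1L]]
    rf <- tryCatch(
      fit_population_model(sim, fit$spec, n_restarts = n_restarts_boot,
                           start = fit$estimates, maxit = maxit_boot,
                           n_polish = 1L),
      error = function(e) e)
    if (inherits(rf, "error")) {
      failures <- c(failures, sprintf("sample %d: %s", b,
                                      conditionMessage(rf)))
    } else {
      draws[b, ] <- unlist(rf$estimates)
    }
  }
  if (length(failures) > 0.2 * n_boot) {
    stop("more than 20% of bootstrap refits failed:\n",
         paste(utils::head(failures, 10L), collapse = "\n"), call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  attr(ci, "boot") <- draws
  attr(ci, "failures") <- failures
  ci
}
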