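#' Parameters of the V1-like encoding population
#'
#' Bundles the parameters of the contrast-normalization encoding front-end:
#' a bank of orientation-tuned units with Naka-Rushton contrast responses
#' and Poisson-like (variance proportional to mean) response noise.
#'
#' @param k_exc Concentration of the excitatory orientation tuning
#'   (dimensionless, > 0).
#' @param k_inh Concentration of the gain-pool tuning (> 0). A very small
#'   value (default 0.001) makes divisive normalization effectively untuned.
#' @param p Response exponent of the accelerating nonlinearity (>= 2).
#' @param c50 Semi-saturation contrast in % Michelson (> 0).
#' @param r0 Spontaneous discharge rate in Hz; constrained to at most 5% of
#'   `r_max`.
#' @param r_max Maximum response rate in Hz (> 0).
#' @param t Stimulus duration in seconds (> 0).
#' @param zeta Proportionality constant linking response variance to mean
#'   spike count (> 0).
#' @param preferred_orientations Preferred orientations of the population in
#'   degrees, unique modulo 180. Default: 36 units evenly spaced at 5
#'   degrees over [0, 180).
#' @return An object of class `population_params`.
#' @export
population_params <- function(k_exc = 1.35, k_inh = 0.001, p = 5.52,
                              c50 = 9.65, r0 = 4.55, r_max = 100,
                              t = 0.0308, zeta = 1.9,
                              preferred_orientations = seq(0, 175, by = 5)) {
  pos <- c(k_exc = k_exc, k_inh = k_inh, c50 = c50, r_max = r_max,
           t = t, zeta = zeta)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("k_exc, k_inh, c50, r_max, t and zeta must all be finite and > 0",
         call. = FALSE)
  }
  if (!is.finite(p) || p < 2) {
    stop("response exponent `p` must be >= 2", call. = FALSE)
  }
  if (!is.finite(r0) || r0 < 0 || r0 > 0.05 * r_max) {
    stop("`r0` must lie in [0, 0.05 * r_max]", call. = FALSE)
  }
  th <- preferred_orientations
  if (length(th) < 1L || any(!is.finite(th)) ||
      anyDuplicated(round(th %% 180, 9)) > 0L) {
    stop("`preferred_orientations` must be unique modulo 180 degrees",
         call. = FALSE)
  }
  structure(list(k_exc = k_exc, k_inh = k_inh, p = p, c50 = c50, r0 = r0,
                 r_max = r_max, t = t, zeta = zeta,
                 preferred_orientations = as.numeric(th)),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("V1-like population (", length(x$preferred_orientations),
      " units)\n", sep = "")
  cat(sprintf("  k_exc=%.4g  k_inh=%.4g  p=%.4g  c50=%.4g%%\n",
              x$k_exc, x$k_inh, x$p, x$c50))
  cat(sprintf("  r0=%.4g Hz  r_max=%.4g Hz  t=%.4g s  zeta=%.4g\n",
              x$r0, x$r_max, x$t, x$zeta))
  invisible(x)
}

#' Apparent-motion effect parameters
#'
#' The three ways apparent motion (AM) can modify the encoding of a target
#' grating: `alpha` adds excitatory drive (filling-in of activation along
#' the AM path), `beta` adds drive to the divisive gain pool (a contrast-gain
#' shift), and `gamma` multiplicatively scales down the maximum response
#' (response-gain suppression). Each effect is weighted by a von Mises
#' tuning function of the unit's preferred orientation relative to the
#' inducer orientation. The all-zero setting (`alpha = beta = gamma = 0`)
#' represents the Flicker control condition, in which the AM-extended
#' response reduces exactly to the standard normalization model.
#'
#' @param alpha AM-induced excitation, in % Michelson contrast units (>= 0).
#' @param beta AM-induced normalization drive, in % contrast units (>= 0).
#' @param gamma Response-gain suppression, a fraction in [0, 1].
#' @param k_exc_AM Concentration of the tuning of the excitation and
#'   suppression effects (> 0).
#' @param k_inh_AM Concentration of the tuning of the inhibition effect
#'   (> 0).
#' @param inducer_orientation Orientation of the AM inducers in degrees.
#' @return An object of class `am_params`.
#' @export
am_params <- function(alpha = 0, beta = 0, gamma = 0,
                      k_exc_AM = 1.35, k_inh_AM = 0.001,
                      inducer_orientation = 0) {
  if (!is.finite(alpha) || alpha < 0 || !is.finite(beta) || beta < 0) {
    stop("`alpha` and `beta` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(k_exc_AM) || k_exc_AM <= 0 ||
      !is.finite(k_inh_AM) || k_inh_AM <= 0) {
    stop("`k_exc_AM` and `k_inh_AM` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(inducer_orientation)) {
    stop("`inducer_orientation` must be finite", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 k_exc_AM = k_exc_AM, k_inh_AM = k_inh_AM,
                 inducer_orientation = inducer_orientation),
            class = "am_params")
}

#' @export
print.am_params <- function(x, ...) {
  cat(sprintf(
    "AM effects: alpha=%.4g%%  beta=%.4g%%  gamma=%.4g  (k_exc_AM=%.4g, k_inh_AM=%.4g, inducer %g deg)\n",
    x$alpha, x$beta, x$gamma, x$k_exc_AM, x$k_inh_AM,
    x$inducer_orientation))
  invisible(x)
}

#' Reference parameterization of the population model
#'
#' Loads the bundled reference parameter set: maximum-likelihood estimates
#' obtained by fitting the full AM-extended population model to a pooled
#' human 2AFC contrast-detection data set (five observers, AM and Flicker
#' conditions, five contrasts and five target orientations). Used as the
#' default generator settings of the synthetic observer and throughout the
#' examples.
#'
#' @return A list with components `pop` ([population_params()]), `am`
#'   ([am_params()]) and `epsilon` (decoder efficiency).
#' @export
reference_estimates <- function() {
  path <- system.file("extdata", "reference-estimates.json",
                      package = "ampop", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(j$n_neurons)
  list(
    pop = population_params(
      k_exc = j$k_exc, k_inh = j$k_inh, p = j$p, c50 = j$c50, r0 = j$r0,
      r_max = j$r_max, t = j$t, zeta = j$zeta,
      preferred_orientations = seq(0, by = 180 / n, length.out = n)),
    am = am_params(alpha = j$alpha, beta = j$beta, gamma = j$gamma,
                   k_exc_AM = j$k_exc_AM, k_inh_AM = j$k_inh_AM,
                   inducer_orientation = j$inducer_orientation),
    epsilon = j$epsilon
  )
}
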