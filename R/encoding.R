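# Naka-Rushton fraction L^p / (c50^p + G^p), computed in log space so that
# large response exponents cannot overflow. L and G are matrices of linear
# drives (units x contrasts); zero drive maps to a zero (L) or absent (G)
# term exactly.
.norm_frac <- function(L, G, c50, p) {
  la <- p * log(L)                       # -Inf where L == 0
  lb <- p * log(c50)
  ld <- p * log(G)                       # -Inf where G == 0
  hi <- pmax(lb, ld)
  logden <- hi + log1p(exp(pmin(lb, ld) - hi))
  exp(la - logden)
}

# Mean spike counts of every unit, for a vector of contrasts. Returns an
# N x length(contrast) matrix. `am = NULL` gives the standard (Flicker)
# normalization model; passing am_params with all effects zero is
# bit-for-bit identical to that.
.mean_response <- function(contrast, orientation, pop, am = NULL) {
  if (any(!is.finite(contrast)) || any(contrast < 0)) {
    stop("`contrast` must be finite and >= 0", call. = FALSE)
  }
  th <- pop$preferred_orientations
  f <- vm_tuning(orientation - th, pop$k_exc)
  g <- vm_tuning(orientation - th, pop$k_inh)
  if (is.null(am)) {
    a <- 0; b <- 0; gm <- 0; h <- 0; j <- 0
  } else {
    h <- vm_tuning(am$inducer_orientation - th, am$k_exc_AM)
    j <- vm_tuning(am$inducer_orientation - th, am$k_inh_AM)
    a <- am$alpha; b <- am$beta; gm <- am$gamma
  }
  L <- outer(f, contrast) + a * h        # column recycling over units
  G <- outer(g, contrast) + b * j
  frac <- .norm_frac(L, G, pop$c50, pop$p)
  pop$t * (pop$r0 + (1 - gm * h) * pop$r_max * frac)
}

#' Mean population response to a target grating
#'
#' Expected spike count of each unit in the population over the stimulus
#' duration. `mean_response_flicker()` evaluates the standard contrast
#' normalization model `t * (r0 + r_max * L^p / (c50^p + G^p))` with linear
#' drives `L = c * f(theta)` (excitatory receptive field) and
#' `G = c * g(theta)` (gain pool). `mean_response_am()` evaluates the
#' AM-extended response
#' `t * (r0 + (1 - gamma*h) * r_max * (L + alpha*h)^p / (c50^p + (G + beta*j)^p))`
#' in which `h` and `j` are von Mises weights of the unit's preferred
#' orientation relative to the inducer orientation. With
#' `alpha = beta = gamma = 0` the two are identical.
#'
#' @param contrast Target contrast(s) in % Michelson (>= 0).
#' @param orientation Target orientation in degrees.
#' @param pop A [population_params()] object.
#' @param am An [am_params()] object.
#' @return For a single contrast, a vector of mean spike counts (one per
#'   unit); for several contrasts, a units x contrasts matrix.
#' @export
mean_response_flicker <- function(contrast, orientation, pop) {
  m <- .mean_response(contrast, orientation, pop, am = NULL)
  if (length(contrast) == 1L) m[, 1L] else m
}

#' @rdname mean_response_flicker
#' @export
mean_response_am <- function(contrast, orientation, pop, am) {
  stopifnot(inherits(am, "am_params"))
  m <- .mean_response(contrast, orientation, pop, am = am)
  if (length(contrast) == 1L) m[, 1L] else m
}

#' Response variance of a unit
#'
#' Variance of the spike count, proportional to its mean:
#' `var(r) = zeta * mean`.
#'
#' @param mean_count Mean spike count(s), >= 0.
#' @param pop A [population_params()] object (supplies `zeta`).
#' @return Variance(s) in spikes^2.
#' @export
response_variance <- function(mean_count, pop) {
  if (any(!is.finite(mean_count)) || any(mean_count < 0)) {
    stop("`mean_count` must be finite and >= 0", call. = FALSE)
  }
  pop$zeta * mean_count
}
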