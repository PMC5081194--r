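#' Rescaled von Mises orientation tuning
#'
#' Orientation tuning weight of a V1-like unit as a function of the angular
#' distance between stimulus and preferred orientation. The von Mises curve
#' `exp(k * (2 * cos(2 * delta) - 1)) / exp(k)` is rescaled so that it peaks
#' at exactly 1 for `delta_theta = 0` irrespective of the concentration `k`.
#' Because the argument is `cos(2 * delta)`, the function has the 180-degree
#' period appropriate for orientation (not direction).
#'
#' @param delta_theta Angular distance in degrees between stimulus and
#'   preferred orientation. Any real value; interpreted modulo 180 degrees.
#' @param k Concentration (dimensionless, > 0). Larger values give narrower
#'   tuning; `k = 0.001` is effectively untuned (weight within 0.4% of 1 at
#'   all angles).
#' @return Tuning weight(s) in (0, 1].
#' @seealso [bandwidth_from_k()] for the width of this curve at half height.
#' @examples
#' vm_tuning(0, 1.35)    # 1 at the preferred orientation
#' vm_tuning(90, 1.35)   # exp(-4 * 1.35), the orthogonal floor
#' @export
vm_tuning <- function(delta_theta, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("concentration `k` must be a single finite value > 0", call. = FALSE)
  }
  exp(2 * k * (cos(delta_theta * (pi / 90)) - 1))
}

#' Orientation bandwidth at half height of the von Mises tuning curve
#'
#' Full width (in degrees) at which [vm_tuning()] has fallen to one half.
#' Solving `exp(2k (cos(B) - 1)) = 1/2` gives `B = acos(1 - ln(2) / (2k))`,
#' where `B` is the full width because the half-width enters through
#' `cos(2 * delta)`. For `k <= ln(2)/4` the curve never reaches one half on
#' the orientation domain and the bandwidth is undefined.
#'
#' @param k Concentration (> `log(2)/4`). Vectorised.
#' @return Full width at half height in degrees, in (0, 180).
#' @examples
#' bandwidth_from_k(1.35) # about 42 degrees, a typical V1 bandwidth
#' @export
bandwidth_from_k <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k))) {
    stop("`k` must be finite", call. = FALSE)
  }
  if (any(k <= log(2) / 4)) {
    stop("bandwidth undefined: tuning never falls to one half for ",
         "k <= ln(2)/4 (", format(log(2) / 4, digits = 6), ")", call. = FALSE)
  }
  acos(1 - log(2) / (2 * k)) * (180 / pi)
}

#' @rdname bandwidth_from_k
#' @param bandwidth Full width at half height in degrees, in (0, 180).
#' @export
k_from_bandwidth <- function(bandwidth) {
  if (!is.numeric(bandwidth) || any(!is.finite(bandwidth)) ||
      any(bandwidth <= 0) || any(bandwidth >= 180)) {
    stop("`bandwidth` must lie in (0, 180) degrees", call. = FALSE)
  }
  log(2) / (2 * (1 - cos(bandwidth * (pi / 180))))
}
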