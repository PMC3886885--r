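#' Direction-tuned input population
#'
#' Constructs the ring of `N` direction-tuned input neurons with evenly spaced
#' preferred directions and Von Mises tuning
#' \deqn{u_i(\theta) = \Lambda \exp\{\rho(\cos(\theta - \theta_i) - 1)\},}
#' where `rho` is the tuning concentration (large `rho` = narrow tuning; the
#' half bandwidth is given by [half_bandwidth()]) and the peak response
#' \eqn{\Lambda} is set so the squared population norm
#' \eqn{\|u(\theta)\|^2} equals `U_target` for every direction. Holding the
#' norm fixed while varying `rho` keeps the normalized learning rate --- and
#' hence the time to learn a single target --- independent of the tuning width.
#'
#' @param N number of input neurons (evenly spaced preferred directions).
#' @param rho tuning concentration, `rho >= 0`; `rho = 0` gives flat tuning.
#' @param U_target required squared population norm after normalization.
#' @return An object of class `tuning_field` with fields `N`, `rho`, `Lambda`,
#'   `preferred_dirs`, `U_target`.
#' @examples
#' f <- tuning_field(60, rho = 1)
#' u <- input_activity(pi / 3, f)
#' sum(u^2)  # ~ 1
#' @export
tuning_field <- function(N, rho, U_target = 1) {
  stopifnot(N >= 1, rho >= 0, U_target > 0)
  theta_i <- 2 * pi * (seq_len(N) - 1) / N
  # squared-norm sum at theta = 0; theta-dependence is O(exp(-N)) on the grid
  S <- sum(exp(2 * rho * (cos(theta_i) - 1)))
  structure(list(
    N = as.integer(N), rho = rho, Lambda = sqrt(U_target / S),
    preferred_dirs = theta_i, U_target = U_target
  ), class = "tuning_field")
}

#' @export
print.tuning_field <- function(x, ...) {
  cat(sprintf(
    "<tuning_field> N = %d, rho = %g, Lambda = %.6g, ||u||^2 = %g (half bandwidth %.1f deg)\n",
    x$N, x$rho, x$Lambda, x$U_target, 180 / pi * half_bandwidth(x$rho)))
  invisible(x)
}

#' Input-layer population activity
#'
#' Activity of every input neuron upon presentation of a target in direction
#' `theta` (radians). The profile peaks at `Lambda` for the neuron whose
#' preferred direction equals `theta` and decays to baseline
#' `Lambda * exp(-2 rho)` on the opposite side of the ring.
#'
#' @param theta target direction, radians.
#' @param field a [tuning_field()].
#' @return Numeric vector of length `field$N`.
#' @export
input_activity <- function(theta, field) {
  field$Lambda * exp(field$rho * (cos(theta - field$preferred_dirs) - 1))
}

# Activity matrix for several directions, one column per direction.
activity_matrix <- function(thetas, field) {
  vapply(thetas, input_activity, numeric(field$N), field = field)
}

#' Tuning-curve half bandwidth
#'
#' Half width of the tuning curve at half of its peak-to-baseline range,
#' i.e. the angle solving
#' \eqn{\exp\{\rho(\cos\theta - 1)\} = (1 + e^{-2\rho})/2}.
#' Strictly decreasing in `rho`; for flat tuning (`rho = 0`) the convention is
#' to return `pi`.
#'
#' @param rho tuning concentration, `rho >= 0`.
#' @return Half bandwidth in radians.
#' @export
half_bandwidth <- function(rho) {
  if (length(rho) > 1L) return(vapply(rho, half_bandwidth, numeric(1)))
  stopifnot(rho >= 0)
  if (rho == 0) return(pi)
  half <- (1 + exp(-2 * rho)) / 2
  f <- function(th) rho * (cos(th) - 1) - log(half)
  uniroot(f, c(.Machine$double.eps, pi), tol = 1e-12)$root
}

#' Activity-profile overlap between two target directions
#'
#' Normalized inner product
#' \eqn{\Gamma(\Delta\theta) = u(\theta)\cdot u(\theta + \Delta\theta) / \|u\|^2}
#' of the input activity profiles for two targets separated by `delta_theta`.
#' The overlap controls both generalization and cross-target interference.
#' With a `tuning_field` the discrete sum is used (independent of `theta` up to
#' grid effects); see [overlap_closed_form()] for the large-`N` Bessel form.
#'
#' @param delta_theta angular separation, radians (vectorized).
#' @param field a [tuning_field()].
#' @param theta reference direction (default 0).
#' @return Overlap value(s) in `[-1, 1]`; `overlap(0, field) = 1`.
#' @export
overlap <- function(delta_theta, field, theta = 0) {
  u0 <- input_activity(theta, field)
  U <- sum(u0^2)
  vapply(delta_theta,
         function(d) sum(u0 * input_activity(theta + d, field)) / U,
         numeric(1))
}

#' Large-N closed form of the overlap
#'
#' \deqn{\Gamma(\Delta\theta) = I_0(2\rho\cos(\Delta\theta/2)) / I_0(2\rho)}
#' with \eqn{I_0} the modified Bessel function of the first kind. Evaluated
#' with exponentially scaled Bessel functions so large `rho` does not
#' overflow.
#'
#' @param delta_theta angular separation, radians (vectorized).
#' @param rho tuning concentration.
#' @return Overlap value(s).
#' @export
overlap_closed_form <- function(delta_theta, rho) {
  if (rho == 0) return(rep(1, length(delta_theta)))
  a <- 2 * rho * abs(cos(delta_theta / 2))
  b <- 2 * rho
  exp(a - b) * besselI(a, 0, expon.scaled = TRUE) /
    besselI(b, 0, expon.scaled = TRUE)
}
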