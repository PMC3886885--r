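#' Probability of a rewarded trial
#'
#' Probability that the next trial is rewarded given the current noiseless
#' error. The cursor endpoint is the noiseless displacement plus isotropic 2-D
#' Gaussian noise, so the cursor-target distance is Rice distributed and
#' \deqn{P = \int_0^{n_0} \frac{r}{\sigma^2}
#'       e^{-(r^2+\tilde E)/(2\sigma^2)} I_0\!\left(\frac{r\sqrt{\tilde E}}
#'       {\sigma^2}\right) dr,}
#' evaluated exactly through the noncentral chi-square CDF with 2 degrees of
#' freedom (the Marcum-Q identity). Decreasing in `E_noiseless`; for fixed
#' `E_noiseless > n0^2` it is non-monotonic in `sigma`, with an interior
#' maximum: too little noise never reaches the target, too much misses it.
#'
#' @param E_noiseless noiseless squared error(s) \eqn{\tilde E \ge 0}.
#' @param sigma noise SD per component; `sigma = 0` degenerates to the
#'   indicator `E_noiseless <= n0^2`.
#' @param n0 target radius.
#' @return Probability in `[0, 1]` (vectorized over `E_noiseless`).
#' @export
reward_probability <- function(E_noiseless, sigma, n0) {
  stopifnot(all(E_noiseless >= 0), sigma >= 0, n0 > 0)
  if (sigma == 0) return(as.numeric(E_noiseless <= n0^2))
  pchisq(n0^2 / sigma^2, df = 2, ncp = E_noiseless / sigma^2)
}

# Adaptive-quadrature evaluation of the Rice integral; kept as an independent
# route to cross-check the noncentral chi-square identity. The integrand is
# rewritten with a scaled Bessel so the exponent is -(r - sqrt(Et))^2/(2 s^2).
reward_probability_quad <- function(E_noiseless, sigma, n0, rel.tol = 1e-10) {
  vapply(E_noiseless, function(Et) {
    a <- sqrt(Et)
    f <- function(r) {
      x <- r * a / sigma^2
      r / sigma^2 * exp(-(r - a)^2 / (2 * sigma^2)) *
        besselI(x, 0, expon.scaled = TRUE)
    }
    integrate(f, 0, n0, rel.tol = rel.tol)$value
  }, numeric(1))
}

#' Waiting time to the first reward
#'
#' The number of trials until the first reward is geometric with success
#' probability `P1` (the reward probability at the initial noiseless error).
#'
#' @param P1 probability of reward on a single pre-learning trial.
#' @return List with `mean` (`1/P1`, `Inf` flagged when `P1 = 0`) and
#'   `quantile(p)`, the closed-form geometric quantile function (in trials,
#'   starting at 1).
#' @export
first_reward_stats <- function(P1) {
  stopifnot(P1 >= 0, P1 <= 1)
  if (P1 == 0) {
    warning("P1 = 0: the first reward never arrives (mean waiting time Inf)")
    return(list(mean = Inf, quantile = function(p) rep(Inf, length(p))))
  }
  list(mean = 1 / P1,
       quantile = function(p) qgeom(p, prob = P1) + 1)
}

#' Noiseless error across rewarded trials (small-target limit)
#'
#' In the limit of a vanishing target radius the noise on a rewarded trial is
#' fully determined, and the noiseless error after `k` rewarded trials is
#' \deqn{\tilde E_k = (1 - \tilde\eta)^{2k} \tilde E_0.}
#' Converges to zero iff `0 < eta_tilde < 2` and grows without bound for
#' `eta_tilde > 2`.
#'
#' @param E0 initial noiseless squared error (e.g. `2 * (1 - cos(gamma))`).
#' @param eta_tilde normalized learning rate.
#' @param k rewarded-trial index (vectorized).
#' @return \eqn{\tilde E_k}.
#' @export
smalltarget_trajectory <- function(E0, eta_tilde, k) {
  stopifnot(E0 >= 0, eta_tilde >= 0, all(k >= 0))
  (1 - eta_tilde)^(2 * k) * E0
}

#' Worst-case long-run noiseless error
#'
#' For a finite target radius the rewarded noise is only determined up to an
#' offset within the target disc. The adversarial recursion on the noiseless
#' displacement magnitude,
#' \eqn{|d_{k+1}| = |1-\tilde\eta||d_k| + \tilde\eta n_0,}
#' is iterated to its fixed point, giving the supremum of \eqn{\sqrt{\tilde E}}
#' over all rewarded-noise sequences at long times:
#' `n0` for `eta_tilde <= 1`; `eta_tilde * n0 / (2 - eta_tilde)` for
#' `1 < eta_tilde < 2`; `Inf` for `eta_tilde >= 2`. Noiseless performance is
#' therefore perfect exactly when `eta_tilde <= 1`.
#'
#' @param eta_tilde normalized learning rate (vectorized).
#' @param n0 target radius.
#' @param d0 starting displacement magnitude for the iteration.
#' @param max_iter,tol iteration controls.
#' @return Supremum of the long-run noiseless displacement magnitude
#'   (`sqrt(E_noiseless)` scale).
#' @export
worstcase_error_bound <- function(eta_tilde, n0, d0 = 1,
                                  max_iter = 100000L, tol = 1e-14) {
  stopifnot(all(eta_tilde >= 0), n0 > 0)
  one <- function(h) {
    a <- abs(1 - h)
    if (a >= 1 && h > 0) return(Inf)  # no fixed point: the recursion diverges
    d <- d0
    for (i in seq_len(max_iter)) {
      d_new <- a * d + h * n0
      if (!is.finite(d_new) || d_new > 1e12) return(Inf)
      if (abs(d_new - d) <= tol * max(1, d)) return(d_new)
      d <- d_new
    }
    d
  }
  vapply(eta_tilde, one, numeric(1))
}

#' Generalization error after single-target adaptation
#'
#' After full adaptation to one target in the small-target limit, the relative
#' reduction of the noiseless error on a test target `delta_theta` away is
#' \deqn{G(\Delta\theta) = \Gamma\,(2\cos\Delta\theta - \Gamma),}
#' which depends on the tuning width and the separation only through the
#' overlap \eqn{\Gamma}. `G(0) = 1` (perfect generalization at the trained
#' direction) and `G < 0` (worse than baseline) wherever
#' \eqn{\cos\Delta\theta < \Gamma/2}, e.g. opposite targets under wide tuning.
#'
#' @param delta_theta angular distance from the trained target, radians
#'   (vectorized).
#' @param field a [tuning_field()]; alternatively give `rho` to use the
#'   large-N closed form of the overlap.
#' @param rho tuning concentration (used when `field` is missing).
#' @return Generalization error value(s), at most 1.
#' @export
generalization_curve <- function(delta_theta, field = NULL, rho = NULL) {
  G <- if (!is.null(field)) overlap(delta_theta, field)
       else overlap_closed_form(delta_theta, rho)
  G * (2 * cos(delta_theta) - G)
}

#' One-step interference between two targets
#'
#' Relative reduction of the *other* target's noiseless error caused by the
#' first rewarded trial, when both targets start from pre-adaptation
#' displacements of equal magnitude subtending `delta_theta`:
#' \deqn{I_1(\Delta\theta) = \tilde\eta\Gamma\,
#'       (2\cos\Delta\theta - \tilde\eta\Gamma).}
#' Positive values are constructive interference (the other target improves),
#' negative values destructive (its error grows); the transition sits at
#' \eqn{\cos\Delta\theta = \tilde\eta\Gamma/2}. At `eta_tilde = 1` the
#' interference function coincides with [generalization_curve()].
#'
#' @inheritParams generalization_curve
#' @param eta_tilde normalized learning rate.
#' @return Interference value(s).
#' @export
interference_function <- function(delta_theta, eta_tilde, field = NULL,
                                  rho = NULL) {
  G <- if (!is.null(field)) overlap(delta_theta, field)
       else overlap_closed_form(delta_theta, rho)
  eta_tilde * G * (2 * cos(delta_theta) - eta_tilde * G)
}

#' Angle where the interference stops being monotonic
#'
#' Locates a sign change of \eqn{dI_1/d\Delta\theta} on `(0, pi)` by bracketed
#' root finding on a central-difference derivative of
#' [interference_function()]. For sufficiently narrow tuning the interference
#' varies non-monotonically with the separation; when the derivative does not
#' change sign the function is monotone on the interval and the result is
#' flagged accordingly.
#'
#' @param eta_tilde normalized learning rate.
#' @param rho tuning concentration (large-N overlap is used).
#' @param grid number of bracketing grid points.
#' @return List with `angle` (radians, `NA` if none) and `monotone` (logical).
#' @export
critical_angle <- function(eta_tilde, rho, grid = 720) {
  h <- 1e-6
  dI <- function(x) {
    (interference_function(x + h, eta_tilde, rho = rho) -
     interference_function(x - h, eta_tilde, rho = rho)) / (2 * h)
  }
  xs <- seq(1e-3, pi - 1e-3, length.out = grid)
  ds <- dI(xs)
  flip <- which(ds[-length(ds)] * ds[-1] < 0)
  if (length(flip) == 0) return(list(angle = NA_real_, monotone = TRUE))
  root <- uniroot(dI, c(xs[flip[1]], xs[flip[1] + 1]), tol = 1e-10)$root
  list(angle = root, monotone = FALSE)
}

#' Small-target update of a displacement pair
#'
#' A rewarded trial for the target carrying noiseless displacement `d`
#' contracts it by `(1 - eta_tilde)` and moves the other target's displacement
#' by the overlap-weighted image of the update:
#' `d' <- (1 - eta_tilde) d`, `d_other' <- d_other - eta_tilde * Gamma * d`.
#'
#' @param d 2-vector, noiseless displacement of the rewarded target.
#' @param d_other 2-vector, noiseless displacement of the other target.
#' @param Gamma overlap between the two targets' activity profiles.
#' @param eta_tilde normalized learning rate.
#' @return List with updated `d` and `d_other`.
#' @export
pair_update <- function(d, d_other, Gamma, eta_tilde) {
  list(d = (1 - eta_tilde) * d,
       d_other = d_other - eta_tilde * Gamma * d)
}
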