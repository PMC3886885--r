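#' 2-D rotation matrix
#'
#' Counter-clockwise rotation by `gamma` radians.
#' @param gamma rotation angle, radians.
#' @return 2 x 2 matrix.
#' @export
rotation_matrix <- function(gamma) {
  matrix(c(cos(gamma), sin(gamma), -sin(gamma), cos(gamma)), 2, 2)
}

#' Initial sensorimotor connectivity
#'
#' Builds the 2 x N map `W0` such that, with no rotation and no noise, the
#' network reaches every target exactly: `W0 u(theta) = (cos theta, sin theta)`
#' for all directions. By default `W0` is the minimum-norm least-squares
#' solution of that constraint on a fine direction grid; the analytic Fourier
#' form `W0[ , i] = (cos theta_i, sin theta_i) / (N f1)` (with `f1` the first
#' Fourier coefficient of the tuning curve) is available as a cross-check and
#' agrees with the least-squares construction whenever `f1` is well away from
#' zero.
#'
#' @param field a [tuning_field()]; requires `rho > 0` (flat tuning has a
#'   vanishing first Fourier coefficient, making the constraint unsolvable).
#' @param method `"least_squares"` (pseudo-inverse on a direction grid) or
#'   `"fourier"` (analytic form).
#' @param grid number of grid directions for the least-squares construction.
#' @param rcond relative singular-value cutoff of the pseudo-inverse;
#'   directions of the activity matrix below `rcond` times the leading
#'   singular value are unconstrained high harmonics and are set to zero
#'   (minimum-norm convention).
#' @return 2 x N connectivity matrix.
#' @export
init_connectivity <- function(field, method = c("least_squares", "fourier"),
                              grid = 720, rcond = 1e-8) {
  method <- match.arg(method)
  f1 <- field$Lambda * besselI(field$rho, 1, expon.scaled = TRUE)
  if (f1 < 1e-12) {
    stop("init_connectivity(): the first Fourier coefficient of the tuning ",
         "curve vanishes (rho = ", field$rho, "); the zero-error constraint ",
         "does not determine W0. Use rho > 0.")
  }
  if (method == "fourier") {
    return(rbind(cos(field$preferred_dirs),
                 sin(field$preferred_dirs)) / (field$N * f1))
  }
  thetas <- 2 * pi * (seq_len(grid) - 1) / grid
  A <- activity_matrix(thetas, field)        # N x grid
  B <- rbind(cos(thetas), sin(thetas))       # 2 x grid
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  # min-norm solution of W A = B: W = B V D^-1 U'
  B %*% sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Single-trial outcome
#'
#' Executes one reach: the noisy output is `y = W u(theta) + xi`, the cursor
#' is the rotated output `c = R(gamma) y`, and the squared cursor-target
#' distance is the error. The noiseless error uses the same expression with
#' the noise suppressed and is independent of `xi`.
#'
#' @param W 2 x N connectivity matrix.
#' @param theta target direction, radians; the target sits at unit distance.
#' @param gamma imposed rotation, radians.
#' @param xi 2-vector of output noise (e.g. `rnorm(2, 0, sigma)`).
#' @param field a [tuning_field()].
#' @return List with `E` (squared error), `E_noiseless`, and `endpoint` (the
#'   cursor position).
#' @export
trial_outcome <- function(W, theta, gamma, xi, field) {
  u <- input_activity(theta, field)
  v <- c(cos(theta), sin(theta))
  Rg <- rotation_matrix(gamma)
  y0 <- drop(W %*% u)
  cursor <- drop(Rg %*% (y0 + xi))
  d  <- cursor - v
  d0 <- drop(Rg %*% y0) - v
  list(E = sum(d^2), E_noiseless = sum(d0^2), endpoint = cursor)
}

#' Binary reward
#'
#' Reward 1 iff the squared error is within the squared target radius
#' (`E <= n0^2`, non-strict at the boundary), else 0.
#'
#' @param E squared error(s).
#' @param n0 target radius.
#' @return 0/1 vector.
#' @export
binary_reward <- function(E, n0) as.numeric(E <= n0^2)

#' Reward-modulated weight update
#'
#' The REINFORCE-style rule \eqn{W' = W + \eta R \, \xi u^\top}: the noise
#' that produced the movement is consolidated into the map, scaled by the
#' delivered reward. With `R = 0` the map is unchanged.
#'
#' @param W 2 x N connectivity matrix.
#' @param R delivered reward in `[0, 1]`.
#' @param xi 2-vector of output noise used on the trial.
#' @param u input activity vector of the presented target.
#' @param eta learning rate.
#' @return Updated 2 x N matrix.
#' @export
update_weights <- function(W, R, xi, u, eta) {
  if (R == 0) return(W)
  W + (eta * R) * tcrossprod(xi, u)
}

#' Normalized learning rate
#'
#' The dimensionless rate \eqn{\tilde\eta = \eta \|u\|^2}. On a rewarded trial
#' in the small-target limit the noiseless displacement contracts by exactly
#' `(1 - eta_tilde)`, which makes `eta_tilde` the natural control parameter of
#' the learning dynamics.
#'
#' @param eta learning rate.
#' @param field a [tuning_field()].
#' @return `eta * U_target`.
#' @export
normalized_rate <- function(eta, field) eta * field$U_target

#' @rdname normalized_rate
#' @param eta_tilde normalized learning rate.
#' @export
rate_from_normalized <- function(eta_tilde, field) eta_tilde / field$U_target
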