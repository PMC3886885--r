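#' Reward-function family
#'
#' Three reward families: `"binary"` (1 iff the squared error is within the
#' squared target radius), `"smooth"` (deterministic logistic in the squared
#' error, \eqn{R = 1/(1 + e^{(E - n_0^2)/T})}, which recovers the binary
#' reward as the smoothing parameter `T -> 0`), and `"bernoulli"` (a binary
#' draw with the logistic value as success probability). Smoothing the reward
#' is the reward-shaping strategy: it conveys graded information about the
#' miss distance while still paying at most 1.
#'
#' @param family one of `"binary"`, `"smooth"` (alias
#'   `"smooth_deterministic"`), `"bernoulli"` (alias `"stochastic_bernoulli"`).
#' @param T smoothing parameter, required positive for the non-binary
#'   families.
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(family = c("binary", "smooth", "bernoulli",
                                   "smooth_deterministic",
                                   "stochastic_bernoulli"),
                        T = NULL) {
  family <- match.arg(family)
  family <- switch(family, smooth_deterministic = "smooth",
                   stochastic_bernoulli = "bernoulli", family)
  if (family != "binary") {
    if (is.null(T) || !is.numeric(T) || T <= 0)
      stop("reward_spec(): family '", family,
           "' requires a smoothing parameter T > 0", call. = FALSE)
  } else T <- 0
  structure(list(family = family, T = T), class = "reward_spec")
}

#' Evaluate a reward function
#'
#' @param E squared error(s).
#' @param spec a [reward_spec()].
#' @param n0 target radius.
#' @return Reward value(s) in `[0, 1]`. The `"bernoulli"` family draws from
#'   R's RNG (seed upstream for reproducibility).
#' @export
reward_value <- function(E, spec, n0) {
  switch(spec$family,
    binary    = binary_reward(E, n0),
    smooth    = plogis((n0^2 - E) / spec$T),
    bernoulli = as.numeric(runif(length(E)) < plogis((n0^2 - E) / spec$T)))
}

#' Shaping schedule
#'
#' Curriculum controllers that make a hard adaptation problem reachable:
#' * `"target_size"` starts with a large target radius `n0_init` and shrinks
#'   it by `n0_step` (down to the task's radius) each time the per-target
#'   running averages (EMAs) of the reward have all reached a steady state ---
#'   changed by less than `steady_tol` over one `ema_timescale` while sitting
#'   above `ema_floor` --- after which the EMAs are reset to zero.
#' * `"rotation"` starts from a small rotation `gamma_init` and grows it by
#'   `gamma_step`, either every `block_len` trials (`variant = "block"`) or
#'   adaptively on the same EMA steady-state rule (`variant = "adaptive"`),
#'   up to the task's rotation angle.
#'
#' Reward EMAs are monitored per target, which is what keeps two-target
#' shaping from advancing while one target still fails.
#'
#' @param kind `"none"`, `"target_size"` or `"rotation"`.
#' @param n0_init,n0_step initial radius and decrement (target-size shaping).
#' @param gamma_init,gamma_step initial angle and increment, radians
#'   (rotation shaping).
#' @param variant `"block"` or `"adaptive"` (rotation shaping only).
#' @param block_len trials per block for the `"block"` variant.
#' @param ema_timescale EMA timescale in trials.
#' @param steady_tol maximal EMA change over one timescale to declare steady
#'   state.
#' @param ema_floor minimal EMA value to declare steady state (prevents
#'   declaring "steady" on an all-failure plateau).
#' @return An object of class `shaping_spec`.
#' @export
shaping_spec <- function(kind = c("none", "target_size", "rotation"),
                         n0_init = NULL, n0_step = NULL,
                         gamma_init = NULL, gamma_step = NULL,
                         variant = c("block", "adaptive"),
                         block_len = 25L, ema_timescale = 100L,
                         steady_tol = 0.02, ema_floor = 0.3) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (kind == "target_size") {
    if (is.null(n0_init) || is.null(n0_step) || n0_init <= 0 || n0_step <= 0)
      stop("target_size shaping requires n0_init > 0 and n0_step > 0",
           call. = FALSE)
  }
  if (kind == "rotation") {
    if (is.null(gamma_step) || gamma_step <= 0)
      stop("rotation shaping requires gamma_step > 0", call. = FALSE)
    if (is.null(gamma_init)) gamma_init <- gamma_step
  }
  structure(list(kind = kind, n0_init = n0_init, n0_step = n0_step,
                 gamma_init = gamma_init, gamma_step = gamma_step,
                 variant = variant, block_len = as.integer(block_len),
                 ema_timescale = as.integer(ema_timescale),
                 steady_tol = steady_tol, ema_floor = ema_floor),
            class = "shaping_spec")
}

shaping_code <- function(shaping) {
  switch(shaping$kind,
         none = 0L, target_size = 1L,
         rotation = if (shaping$variant == "block") 2L else 3L)
}

#' Run a reward-gated adaptation experiment
#'
#' Executes the full per-trial loop: select target, compute the input
#' activity, draw the 2-D output noise, form the rotated cursor endpoint and
#' error, deliver the reward, apply the reward-modulated weight update, and
#' step the shaping controller. The initial map is the zero-error
#' connectivity, so the recorded error at the first trial already reflects the
#' imposed rotation (`E_noiseless = 2(1 - cos gamma)` at `t = 1`).
#'
#' @param n_trials maximal number of trials.
#' @param seed integer seed; identical seeds reproduce the run bit for bit.
#' @param field a [tuning_field()].
#' @param gamma imposed rotation, radians.
#' @param n0 target radius (the final radius when shaping the target size).
#' @param sigma output noise SD per component.
#' @param eta_tilde normalized learning rate (ignored if `eta` given).
#' @param eta raw learning rate; default derived from `eta_tilde`.
#' @param targets target directions, radians.
#' @param schedule `"cyclic"` (in alternation, fixed starting target) or
#'   `"random"` (uniform each trial).
#' @param reward a [reward_spec()].
#' @param shaping a [shaping_spec()].
#' @param W0 optional starting connectivity (default [init_connectivity()]).
#' @param early_stop stop once the noiseless errors of all targets have been
#'   within the squared target radius for `early_window` consecutive trials
#'   (and any shaping schedule has completed).
#' @param early_window consecutive-trial window for `early_stop`.
#' @param diverge_guard terminate (flagged, records preserved) when the
#'   noiseless error exceeds this guard.
#' @return An object of class `run_result`: `records` (data frame with one
#'   row per trial: `t`, `target`, `E`, `E_noiseless`, `R`, `n0_t`,
#'   `gamma_t`), `W_final`, `W0`, `divergent`, `seed`, `field`, and `config`
#'   (the full configuration snapshot).
#' @examples
#' run <- run_adaptation(500, seed = 1, sigma = 0.3, n0 = 0.3)
#' tail(run$records$E_noiseless, 1)  # far below the initial 2(1 - cos 30 deg)
#' @export
run_adaptation <- function(n_trials, seed,
                           field = tuning_field(60, 1),
                           gamma = pi / 6, n0 = 0.1, sigma = 0.3,
                           eta_tilde = 0.3, eta = NULL,
                           targets = 0,
                           schedule = c("cyclic", "random"),
                           reward = reward_spec("binary"),
                           shaping = shaping_spec("none"),
                           W0 = NULL,
                           early_stop = FALSE, early_window = 500L,
                           diverge_guard = 1e6) {
  schedule <- match.arg(schedule)
  stopifnot(n_trials >= 1, n0 > 0, n0 < 1, sigma >= 0, length(targets) >= 1)
  if (is.null(eta)) eta <- rate_from_normalized(eta_tilde, field)
  else eta_tilde <- normalized_rate(eta, field)
  if (is.null(W0)) W0 <- init_connectivity(field)

  U <- activity_matrix(targets, field)
  V <- rbind(cos(targets), sin(targets))
  sc <- shaping_code(shaping)

  set.seed(as.integer(seed))
  out <- .adapt_loop(
    W0, U, V,
    gamma_final = gamma, sigma = sigma, eta = eta,
    schedule_mode = if (schedule == "cyclic") 0L else 1L,
    reward_family = switch(reward$family, binary = 0L, smooth = 1L,
                           bernoulli = 2L),
    T_smooth = reward$T, n0_final = n0,
    shaping_kind = sc,
    n0_init = if (sc == 1L) shaping$n0_init else n0,
    n0_step = if (sc == 1L) shaping$n0_step else 0,
    gamma_init = if (sc %in% c(2L, 3L)) shaping$gamma_init else gamma,
    gamma_step = if (sc %in% c(2L, 3L)) shaping$gamma_step else 0,
    block_len = shaping$block_len,
    ema_timescale = shaping$ema_timescale,
    steady_tol = shaping$steady_tol, ema_floor = shaping$ema_floor,
    n_trials = as.integer(n_trials), diverge_guard = diverge_guard,
    early_stop = early_stop, early_window = as.integer(early_window))

  records <- data.frame(
    t = seq_len(out$n_done), target = out$target + 1L,
    E = out$E, E_noiseless = out$E_noiseless, R = out$R,
    n0_t = out$n0_t, gamma_t = out$gamma_t)

  structure(list(
    records = records, W_final = out$W, W0 = W0,
    divergent = out$divergent, seed = as.integer(seed), field = field,
    config = list(n_trials = n_trials, gamma = gamma, n0 = n0, sigma = sigma,
                  eta = eta, eta_tilde = eta_tilde, targets = targets,
                  schedule = schedule, reward = reward, shaping = shaping,
                  early_stop = early_stop, early_window = early_window,
                  N = field$N, rho = field$rho, U_target = field$U_target)
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<run_result> %d trials, %d target(s), seed %d%s\n  reward rate %.3f, last E_noiseless %.4g\n",
    nrow(r), length(x$config$targets), x$seed,
    if (x$divergent) " [DIVERGENT]" else "",
    mean(r$R), r$E_noiseless[nrow(r)]))
  invisible(x)
}

#' Generalization profile of a frozen map
#'
#' Evaluates, without any learning, the noiseless error of connectivity `W`
#' under rotation `gamma` on a grid of test directions and expresses it as the
#' generalization error \eqn{G = 1 - \tilde E_{after}/\tilde E_{before}} with
#' \eqn{\tilde E_{before} = 2(1 - \cos\gamma)}, the pre-adaptation noiseless
#' error common to all directions.
#'
#' @param W 2 x N connectivity (e.g. `run$W_final`).
#' @param gamma imposed rotation, radians; `gamma = 0` makes `G` undefined
#'   (flagged with `NA` and attribute `undefined_G`).
#' @param test_dirs test directions, radians.
#' @param field a [tuning_field()].
#' @param n0 optional target radius; when given, the attribute
#'   `noiseless_performance` holds the share of test directions whose
#'   noiseless error is within `n0^2`.
#' @return Data frame with `theta`, `E_noiseless`, `G`.
#' @export
evaluate_generalization <- function(W, gamma, test_dirs, field, n0 = NULL) {
  U <- activity_matrix(test_dirs, field)
  V <- rbind(cos(test_dirs), sin(test_dirs))
  D <- rotation_matrix(gamma) %*% (W %*% U) - V
  after <- colSums(D^2)
  before <- 2 * (1 - cos(gamma))
  if (before < .Machine$double.eps) {
    G <- rep(NA_real_, length(test_dirs))
    out <- data.frame(theta = test_dirs, E_noiseless = after, G = G)
    attr(out, "undefined_G") <- TRUE
  } else {
    out <- data.frame(theta = test_dirs, E_noiseless = after,
                      G = 1 - after / before)
    attr(out, "undefined_G") <- FALSE
  }
  if (!is.null(n0)) attr(out, "noiseless_performance") <- mean(after <= n0^2)
  out
}
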