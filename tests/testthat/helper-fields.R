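# Shared fixtures: small tuning fields and convenience wrappers.

field60 <- function(rho = 1) tuning_field(60, rho)

deg <- pi / 180

# initial noiseless error under rotation gamma (pre-adaptation)
initial_error <- function(gamma) 2 * (1 - cos(gamma))

# learning duration of a run's (noisy) single-target error curve
run_tau <- function(run) {
  e <- run$records$E
  as.integer(learning_duration(e, suppressWarnings(final_error(e))))
}

# noise vector that makes the rotated endpoint land exactly on the target;
# consolidating it at eta_tilde = 1 cancels the displacement in one step
cancelling_noise <- function(W, theta, gamma, field) {
  v <- c(cos(theta), sin(theta))
  drop(solve(rotation_matrix(gamma)) %*% v) -
    drop(W %*% input_activity(theta, field))
}
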