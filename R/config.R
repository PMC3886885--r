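#' Experiment configuration
#'
#' Nested configuration mirroring the network, task, noise, learning, reward,
#' schedule, shaping and run settings. Angles are stored in degrees on disk
#' and in the configuration object; they are converted to radians when a run
#' is launched. Configurations round-trip losslessly through YAML
#' ([write_config()] / [read_config()]) and every run embeds its snapshot.
#'
#' @param N,rho,U_target input-layer settings, see [tuning_field()].
#' @param gamma_deg imposed rotation, degrees.
#' @param n0 target radius.
#' @param targets_deg target directions, degrees.
#' @param sigma output noise SD.
#' @param eta_tilde normalized learning rate.
#' @param reward_family,reward_T reward settings, see [reward_spec()].
#' @param schedule `"cyclic"` or `"random"`.
#' @param shaping_kind,n0_init,n0_step,gamma_init_deg,gamma_step_deg,variant,block_len,ema_timescale,steady_tol,ema_floor
#'   shaping settings, see [shaping_spec()].
#' @param n_trials,n_realizations,seed run settings.
#' @param early_stop,early_window early stopping, see [run_adaptation()].
#' @return A nested list of class `experiment_config`.
#' @export
experiment_config <- function(N = 60L, rho = 1, U_target = 1,
                              gamma_deg = 30, n0 = 0.1, targets_deg = 0,
                              sigma = 0.3, eta_tilde = 0.3,
                              reward_family = "binary", reward_T = NULL,
                              schedule = "cyclic",
                              shaping_kind = "none",
                              n0_init = NULL, n0_step = NULL,
                              gamma_init_deg = NULL, gamma_step_deg = NULL,
                              variant = "block", block_len = 25L,
                              ema_timescale = 100L, steady_tol = 0.02,
                              ema_floor = 0.3,
                              n_trials = 2000L, n_realizations = 1L,
                              seed = 1L, early_stop = FALSE,
                              early_window = 500L) {
  cfg <- list(
    network  = list(N = as.integer(N), rho = rho, U_target = U_target),
    task     = list(gamma_deg = gamma_deg, n0 = n0,
                    targets_deg = targets_deg),
    noise    = list(sigma = sigma),
    learning = list(eta_tilde = eta_tilde),
    reward   = list(family = reward_family, T = reward_T),
    schedule = list(mode = schedule),
    shaping  = list(kind = shaping_kind, n0_init = n0_init,
                    n0_step = n0_step, gamma_init_deg = gamma_init_deg,
                    gamma_step_deg = gamma_step_deg, variant = variant,
                    block_len = as.integer(block_len),
                    ema_timescale = as.integer(ema_timescale),
                    steady_tol = steady_tol, ema_floor = ema_floor),
    run      = list(n_trials = as.integer(n_trials),
                    n_realizations = as.integer(n_realizations),
                    seed = as.integer(seed), early_stop = early_stop,
                    early_window = as.integer(early_window)))
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Checks every field; on failure raises a condition of class
#' `config_error` listing the offending fields.
#'
#' @param cfg a configuration list.
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(is.numeric(cfg$network$N) && cfg$network$N >= 1, "network.N")
  chk(is.numeric(cfg$network$rho) && cfg$network$rho >= 0, "network.rho")
  chk(is.numeric(cfg$network$U_target) && cfg$network$U_target > 0,
      "network.U_target")
  chk(is.numeric(cfg$task$gamma_deg), "task.gamma_deg")
  chk(is.numeric(cfg$task$n0) && cfg$task$n0 > 0 && cfg$task$n0 < 1,
      "task.n0")
  chk(is.numeric(cfg$task$targets_deg) && length(cfg$task$targets_deg) >= 1,
      "task.targets_deg")
  chk(is.numeric(cfg$noise$sigma) && cfg$noise$sigma >= 0, "noise.sigma")
  chk(is.numeric(cfg$learning$eta_tilde) && cfg$learning$eta_tilde >= 0,
      "learning.eta_tilde")
  chk(cfg$reward$family %in% c("binary", "smooth", "bernoulli",
                               "smooth_deterministic",
                               "stochastic_bernoulli"), "reward.family")
  if (!identical(cfg$reward$family, "binary"))
    chk(is.numeric(cfg$reward$T) && cfg$reward$T > 0, "reward.T")
  chk(cfg$schedule$mode %in% c("cyclic", "random"), "schedule.mode")
  chk(cfg$shaping$kind %in% c("none", "target_size", "rotation"),
      "shaping.kind")
  chk(is.numeric(cfg$run$n_trials) && cfg$run$n_trials >= 1,
      "run.n_trials")
  chk(is.numeric(cfg$run$n_realizations) && cfg$run$n_realizations >= 1,
      "run.n_realizations")
  chk(is.numeric(cfg$run$seed), "run.seed")
  if (length(bad)) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0("invalid configuration field(s): ",
                                         paste(bad, collapse = ", ")),
                        call = sys.call(-1), fields = bad)))
  }
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a validated `experiment_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' @rdname read_config
#' @param cfg an `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Apply dotted-path overrides to a configuration
#'
#' Overrides written as `"section.field=value"` (e.g. `"noise.sigma=0.2"`)
#' are parsed and substituted into the configuration, which is re-validated.
#'
#' @param cfg an `experiment_config`.
#' @param overrides character vector of `path=value` strings, or a named list
#'   with dotted names.
#' @return The updated configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  if (is.null(overrides) || length(overrides) == 0) return(cfg)
  if (is.character(overrides)) {
    sp <- strsplit(overrides, "=", fixed = TRUE)
    vals <- lapply(sp, function(x) paste(x[-1], collapse = "="))
    names(vals) <- vapply(sp, `[[`, character(1), 1L)
    overrides <- vals
  }
  for (key in names(overrides)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(path) != 2)
      stop("override key must be section.field: ", key, call. = FALSE)
    val <- overrides[[key]]
    if (is.character(val)) {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (!anyNA(num)) val <- num
      else if (val %in% c("TRUE", "FALSE", "true", "false"))
        val <- as.logical(toupper(val))
    }
    cfg[[path[1]]][[path[2]]] <- val
  }
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Per-realization seed streams
#'
#' Derives one seed per realization from a base seed by a fixed
#' counter-based affine scheme (streams do not depend on execution order and
#' stay below 2^31).
#'
#' @param base_seed integer base seed.
#' @param n number of realizations.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(base_seed, n) {
  as.integer((as.numeric(base_seed) + 1000003 * seq_len(n) - 1) %% 2147483647)
}

# Launch run_adaptation from a configuration (one realization).
run_from_config <- function(cfg, seed) {
  field <- tuning_field(cfg$network$N, cfg$network$rho, cfg$network$U_target)
  deg <- pi / 180
  shp <- cfg$shaping
  shaping <- switch(shp$kind,
    none = shaping_spec("none"),
    target_size = shaping_spec("target_size", n0_init = shp$n0_init,
                               n0_step = shp$n0_step,
                               ema_timescale = shp$ema_timescale,
                               steady_tol = shp$steady_tol,
                               ema_floor = shp$ema_floor),
    rotation = shaping_spec("rotation",
                            gamma_init = if (is.null(shp$gamma_init_deg))
                              NULL else shp$gamma_init_deg * deg,
                            gamma_step = shp$gamma_step_deg * deg,
                            variant = shp$variant, block_len = shp$block_len,
                            ema_timescale = shp$ema_timescale,
                            steady_tol = shp$steady_tol,
                            ema_floor = shp$ema_floor))
  reward <- if (identical(cfg$reward$family, "binary")) reward_spec("binary")
            else reward_spec(cfg$reward$family, T = cfg$reward$T)
  run_adaptation(
    n_trials = cfg$run$n_trials, seed = seed, field = field,
    gamma = cfg$task$gamma_deg * deg, n0 = cfg$task$n0,
    sigma = cfg$noise$sigma, eta_tilde = cfg$learning$eta_tilde,
    targets = cfg$task$targets_deg * deg, schedule = cfg$schedule$mode,
    reward = reward, shaping = shaping,
    early_stop = isTRUE(cfg$run$early_stop),
    early_window = cfg$run$early_window)
}
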