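#' Final error of a learning curve
#'
#' Median of the error over the terminal window of the run (default the last
#' 10% of trials, widened to at least 10 trials with a warning).
#'
#' @param errors error series.
#' @param tail_fraction fraction of the series forming the terminal window.
#' @return Nonnegative scalar.
#' @export
final_error <- function(errors, tail_fraction = 0.1) {
  n <- length(errors)
  stopifnot(n >= 1)
  w <- ceiling(tail_fraction * n)
  if (w < 10) {
    if (n >= 10) {
      warning("final_error(): terminal window widened to 10 trials")
      w <- 10L
    } else w <- n
  }
  median(errors[(n - w + 1):n])
}

#' Learning duration
#'
#' Number of trials until the task is learned: the first trial at which the
#' median-filtered learning curve (window `window`, default 50 trials) falls
#' below `threshold_factor` times the final error and stays below for one
#' filter window. The error series is assumed to start with the rotation in
#' force (the trial-0 error is computed as if the cursor were already
#' rotated), so the curve starts high and decays. If the threshold is never
#' crossed the run length is returned with attribute `censored = TRUE`.
#'
#' @param errors error series.
#' @param final_err final error (see [final_error()]).
#' @param window median-filter window, trials (forced odd).
#' @param threshold_factor threshold relative to the final error.
#' @return Integer duration with attribute `censored`.
#' @export
learning_duration <- function(errors, final_err, window = 50L,
                              threshold_factor = 1.05) {
  n <- length(errors)
  k <- min(as.integer(window), n)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- if (n %% 2L == 0L) n - 1L else n
  filt <- if (k >= 3) runmed(errors, k, endrule = "median") else errors
  thr <- threshold_factor * final_err
  below <- filt <= thr
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  need <- min(k, n)
  ok <- which(runs$values & (runs$lengths >= need | ends == n))
  if (length(ok) == 0) {
    tau <- n
    censored <- TRUE
  } else {
    tau <- starts[ok[1]]
    censored <- FALSE
  }
  structure(as.integer(tau), censored = censored)
}

#' Performance and noiseless performance
#'
#' Long-run probabilities that the (noisy or noiseless) squared error falls
#' within the squared target radius, estimated as time averages after
#' excluding the transient learning phase.
#'
#' @param run a [run_adaptation()] result.
#' @param transient number of initial trials to exclude.
#' @return List with `performance` and `noiseless_performance`.
#' @export
performance_metrics <- function(run, transient = 0L) {
  r <- run$records
  stopifnot(nrow(r) > transient)
  keep <- r$t > transient
  lim <- r$n0_t[keep]^2
  list(performance = mean(r$E[keep] <= lim),
       noiseless_performance = mean(r$E_noiseless[keep] <= lim))
}

#' Per-target learning summaries of a multi-target run
#'
#' Splits the trial records by presented target and computes, per target, the
#' final error and learning duration on that target's own presentation
#' series, plus the global trial index at which the criterion is met.
#'
#' @param run a [run_adaptation()] result.
#' @param tail_fraction,window,threshold_factor passed to [final_error()] and
#'   [learning_duration()].
#' @return Data frame with one row per target: `target`, `n_presentations`,
#'   `tau` (in presentations of that target), `censored`, `completion_trial`
#'   (in total trial count), `final_error`.
#' @export
per_target_durations <- function(run, tail_fraction = 0.1, window = 50L,
                                 threshold_factor = 1.05) {
  r <- run$records
  targets <- sort(unique(r$target))
  out <- lapply(targets, function(k) {
    idx <- which(r$target == k)
    e <- r$E[idx]
    fe <- suppressWarnings(final_error(e, tail_fraction))
    tau <- learning_duration(e, fe, window, threshold_factor)
    data.frame(target = k, n_presentations = length(idx),
               tau = as.integer(tau),
               censored = attr(tau, "censored"),
               completion_trial = idx[as.integer(tau)],
               final_error = fe)
  })
  do.call(rbind, out)
}

#' Cross-target error correlation over learning
#'
#' For an ensemble of two-target runs with identical cyclic schedules,
#' computes at every trial `t` the Pearson correlation, across realizations,
#' between the error at trial `t` (one target) and trial `t + 1` (the other
#' target). Negative correlations diagnose destructive interference, positive
#' correlations constructive interference; before any reward the map never
#' changes, so `CC(t)` is statistically zero. A centered moving average
#' (window `smooth_window`) is applied for reporting, and the signed extremum
#' is taken on the smoothed curve; the smoothing introduces a boundary
#' artifact at the very start of the curve, which is reported rather than
#' masked.
#'
#' @param runs list of [run_adaptation()] results (same length, two targets,
#'   cyclic schedule).
#' @param smooth_window centered moving-average window, in trials.
#' @return Data frame with `t`, `cc`, `cc_smooth`; attributes `cc_ext`
#'   (signed extremum of the smoothed curve) and `n_realizations`. Slices
#'   with zero variance give `NA`.
#' @export
cc_curve <- function(runs, smooth_window = 51L) {
  stopifnot(length(runs) >= 2)
  n <- vapply(runs, function(r) nrow(r$records), integer(1))
  Tn <- min(n)
  E <- vapply(runs, function(r) r$records$E[seq_len(Tn)], numeric(Tn))
  cc <- vapply(seq_len(Tn - 1L), function(t) {
    x <- E[t, ]; y <- E[t + 1L, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  k <- min(as.integer(smooth_window), length(cc))
  sm <- as.numeric(stats::filter(cc, rep(1 / k, k), sides = 2))
  ext <- if (all(is.na(sm))) NA_real_ else sm[which.max(abs(sm))]
  out <- data.frame(t = seq_len(Tn - 1L), cc = cc, cc_smooth = sm)
  attr(out, "cc_ext") <- ext
  attr(out, "n_realizations") <- length(runs)
  out
}

#' Delayed-learning statistics for two targets
#'
#' Per realization, the two per-target learning durations are sorted into
#' `tau1 <= tau2` (in presentations of each target) and the ratio
#' `tau2 / tau1` is formed. The independence null is the distribution of
#' `(min, max)` over pairs drawn independently from a single-target duration
#' distribution at matched parameters; delayed learning shows up as a
#' right-shift of the observed `tau2` beyond that null. Censored durations
#' (threshold never crossed) are excluded from ratio statistics but counted.
#'
#' @param runs list of two-target [run_adaptation()] results.
#' @param single_tau vector of single-target learning durations at matched
#'   parameters (the independence null); optional.
#' @return List with `tau1`, `tau2`, `ratio`, `median_ratio`, `n_censored`,
#'   and, when `single_tau` is given, `null_tau1`, `null_tau2` (all ordered
#'   pairs) and `median_null_tau2`.
#' @export
delayed_learning_summary <- function(runs, single_tau = NULL) {
  per <- lapply(runs, per_target_durations)
  cens <- vapply(per, function(d) any(d$censored), logical(1))
  taus <- t(vapply(per, function(d) sort(d$tau), numeric(2)))
  out <- list(tau1 = taus[!cens, 1], tau2 = taus[!cens, 2],
              ratio = taus[!cens, 2] / taus[!cens, 1],
              n_censored = sum(cens))
  out$median_ratio <- median(out$ratio)
  if (!is.null(single_tau)) {
    pairs_min <- outer(single_tau, single_tau, pmin)
    pairs_max <- outer(single_tau, single_tau, pmax)
    keep <- upper.tri(pairs_min)  # unordered distinct pairs
    out$null_tau1 <- pairs_min[keep]
    out$null_tau2 <- pairs_max[keep]
    out$median_null_tau2 <- median(out$null_tau2)
  }
  out
}

#' Chance level of close-to-far ordered learning
#'
#' Exact chance probability that a uniformly random completion order of the
#' remaining `m - 1` targets is non-decreasing in angular distance from the
#' first-completed target, counting symmetric-distance ties as exchangeable:
#' the product of factorials of the tie multiplicities over `(m - 1)!`. For
#' `m = 6` evenly spaced targets this is `2! 2! 1! / 5! = 1/30`.
#'
#' @param m number of evenly spaced targets.
#' @return Probability.
#' @export
ordered_chance_level <- function(m) {
  stopifnot(m >= 2)
  dirs <- 2 * pi * (seq_len(m) - 1) / m
  d <- angular_distance(dirs[-1], dirs[1])
  counts <- table(round(d, 12))
  prod(factorial(as.numeric(counts))) / factorial(m - 1)
}

angular_distance <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Per-target completion times from the noiseless error
#'
#' The trial at which a target counts as learned in the noiseless sense: the
#' first presentation at which that target's noiseless error is within the
#' squared target radius and stays within for `window` consecutive
#' presentations (brief later excursions caused by updates for other targets
#' do not revoke completion). The noiseless error changes only on rewarded
#' trials, so this criterion is free of the output noise and resolves
#' completion order crisply even when the noise SD exceeds the target
#' radius.
#'
#' @param run a [run_adaptation()] result.
#' @param n0 target radius defining completion (default the task radius).
#' @param window persistence window, in presentations of the target.
#' @return Data frame with `target`, `completion_trial`, `censored` (`TRUE`
#'   when the noiseless error never settles below `n0^2`).
#' @export
noiseless_completion <- function(run, n0 = run$config$n0, window = 25L) {
  r <- run$records
  lim <- n0^2
  out <- lapply(sort(unique(r$target)), function(k) {
    idx <- which(r$target == k)
    below <- r$E_noiseless[idx] <= lim
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- which(runs$values &
                  (runs$lengths >= window | ends == length(below)))
    if (length(ok) == 0) {
      data.frame(target = k, completion_trial = idx[length(idx)],
                 censored = TRUE)
    } else {
      data.frame(target = k, completion_trial = idx[starts[ok[1]]],
                 censored = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Multi-target ensemble summary
#'
#' For an ensemble of `m`-target runs: the entire-task duration (total trial
#' index at which the last per-target learning criterion is met) and the
#' fraction of realizations learned in close-to-far order --- completion
#' order non-decreasing in angular distance from the first-completed target,
#' symmetric ties exchangeable. Completion is judged on the noiseless error
#' by default ([noiseless_completion()]); `criterion = "curve"` uses the
#' median-filtered learning-curve estimator ([per_target_durations()])
#' instead. Realizations with any censored target are excluded and counted.
#'
#' @param runs list of [run_adaptation()] results sharing the same target
#'   set.
#' @param target_dirs target directions, radians (default taken from the
#'   first run's configuration).
#' @param criterion `"noiseless"` or `"curve"`.
#' @return List with `entire_task_duration` (vector over realizations),
#'   `ordered` (logical vector), `ordered_fraction`, `chance_level`,
#'   `n_censored`.
#' @export
multitarget_summary <- function(runs, target_dirs = NULL,
                                criterion = c("noiseless", "curve")) {
  criterion <- match.arg(criterion)
  if (is.null(target_dirs)) target_dirs <- runs[[1]]$config$targets
  m <- length(target_dirs)
  per <- lapply(runs, if (criterion == "noiseless") noiseless_completion
                      else per_target_durations)
  cens <- vapply(per, function(d) any(d$censored), logical(1))
  per_ok <- per[!cens]
  entire <- vapply(per_ok, function(d) max(d$completion_trial), numeric(1))
  ordered <- vapply(per_ok, function(d) {
    first <- d$target[which.min(d$completion_trial)]
    rest <- d[d$target != first, ]
    dist <- angular_distance(target_dirs[rest$target], target_dirs[first])
    all(diff(dist[order(rest$completion_trial)]) >= -1e-9)
  }, logical(1))
  list(entire_task_duration = entire, ordered = ordered,
       ordered_fraction = if (m >= 2) mean(ordered) else NA_real_,
       chance_level = if (m >= 2) ordered_chance_level(m) else NA_real_,
       n_censored = sum(cens))
}
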