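test_that("reward families behave as declared", {
  sm <- reward_spec("smooth", T = 0.01)
  expect_equal(reward_value(0.1^2, sm, 0.1), 0.5)  # logistic midpoint
  # T -> 0 limit recovers the binary reward away from the boundary
  sharp <- reward_spec("smooth", T = 1e-9)
  E <- c(0.001, 0.005, 0.009, 0.011, 0.05, 0.4)
  expect_equal(reward_value(E, sharp, 0.1), binary_reward(E, 0.1),
               tolerance = 1e-6)
  # bernoulli frequency matches the logistic success probability
  set.seed(3)
  bern <- reward_spec("bernoulli", T = 0.02)
  E0 <- 0.015; n <- 1e5
  p <- plogis((0.1^2 - E0) / 0.02)
  p_hat <- mean(reward_value(rep(E0, n), bern, 0.1))
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  # configuration errors
  expect_error(reward_spec("smooth"), "T > 0")
  expect_error(reward_spec("bernoulli", T = -1), "T > 0")
  # long spec names accepted
  expect_equal(reward_spec("smooth_deterministic", T = 1)$family, "smooth")
})

test_that("runs are deterministic under the seed and frozen without rewards", {
  a <- run_adaptation(800, seed = 9, sigma = 0.25, n0 = 0.1)
  b <- run_adaptation(800, seed = 9, sigma = 0.25, n0 = 0.1)
  expect_identical(a$records, b$records)
  expect_identical(a$W_final, b$W_final)
  d <- run_adaptation(800, seed = 10, sigma = 0.25, n0 = 0.1)
  expect_false(identical(a$records$E, d$records$E))
  # before the first reward the map (hence the noiseless error) is constant
  first_R <- which(a$records$R > 0)[1]
  expect_gt(first_R, 1)
  expect_equal(a$records$E_noiseless[seq_len(first_R)],
               rep(initial_error(pi / 6), first_R))
  # perfect, unperturbed task: zero error forever
  z <- run_adaptation(200, seed = 1, gamma = 0, sigma = 0)
  expect_lt(max(z$records$E), 1e-20)
})

test_that("more noise brings earlier rewards; less noise a lower final error", {
  onset <- function(run) {
    w <- which(run$records$R > 0)[1]
    if (is.na(w)) nrow(run$records) + 1L else w
  }
  res <- vapply(1:15, function(i) {
    lo <- run_adaptation(4000, seed = i, sigma = 0.08, n0 = 0.3)
    hi <- run_adaptation(4000, seed = i, sigma = 0.15, n0 = 0.3)
    c(onset_lo = onset(lo), onset_hi = onset(hi),
      fin_lo = final_error(lo$records$E), fin_hi = final_error(hi$records$E))
  }, numeric(4))
  expect_gt(mean(res["onset_lo", ] > res["onset_hi", ]), 0.6)
  expect_lt(median(res["fin_hi", ]), 0.3^2)          # learned at high noise
  expect_lt(median(res["fin_lo", ]), median(res["fin_hi", ]))
})

test_that("opposite targets show a transient rise of the lagging target's error", {
  E0 <- initial_error(30 * deg)
  rises <- vapply(1:12, function(i) {
    run <- run_adaptation(30000, seed = i, sigma = 0.2, n0 = 0.1,
                          targets = c(0, pi), early_stop = TRUE)
    max(run$records$E_noiseless) > E0 * 1.1
  }, logical(1))
  expect_gt(mean(rises), 0.8)
})

test_that("divergent learning is flagged and terminates with records intact", {
  # far beyond the critical rate a single rewarded trial blows the map past
  # any recoverable error; the guard stops the run and keeps the records
  run <- run_adaptation(20000, seed = 2, sigma = 0.3, n0 = 0.9,
                        eta_tilde = 20, diverge_guard = 25)
  expect_true(run$divergent)
  expect_lt(nrow(run$records), 20000)
  expect_gt(nrow(run$records), 0)
})

test_that("target-size shaping reaches a radius unreachable without shaping", {
  sh <- shaping_spec("target_size", n0_init = 0.4, n0_step = 0.1,
                     ema_timescale = 50)
  shaped <- vapply(1:10, function(i) {
    run <- run_adaptation(4000, seed = i, sigma = 0.05, n0 = 0.1,
                          eta_tilde = 0.3, shaping = sh)
    tl <- tail(run$records, 200)
    c(n0 = tl$n0_t[200], rew = mean(tl$R))
  }, numeric(2))
  expect_true(all(shaped["n0", ] == 0.1))        # schedule completed
  expect_gt(mean(shaped["rew", ]), 0.5)          # and still rewarded
  unshaped <- vapply(1:10, function(i) {
    sum(run_adaptation(4000, seed = i, sigma = 0.05, n0 = 0.1,
                       eta_tilde = 0.3)$records$R)
  }, numeric(1))
  expect_equal(sum(unshaped), 0)                 # same budget, zero rewards
  # no-op when the radius already equals the final value
  flat <- run_adaptation(500, seed = 1, sigma = 0.3, n0 = 0.1,
                         shaping = shaping_spec("target_size", n0_init = 0.1,
                                                n0_step = 0.05))
  expect_true(all(flat$records$n0_t == 0.1))
})

test_that("gradual rotation shaping tracks a large angle in a small multiple of the schedule", {
  sh <- shaping_spec("rotation", gamma_init = 10 * deg, gamma_step = 10 * deg,
                     block_len = 25)
  schedule_len <- (90 / 10) * 25
  done <- vapply(1:15, function(i) {
    run <- run_adaptation(4 * schedule_len, seed = i, gamma = 90 * deg,
                          n0 = 0.15, sigma = 0.15, eta_tilde = 0.5,
                          shaping = sh)
    mean(tail(run$records$E_noiseless, 100) <= 0.15^2) > 0.9
  }, logical(1))
  expect_gt(mean(done), 0.7)   # most seeds adapt; occasional failures allowed
})

test_that("generalization evaluation matches the closed form after training", {
  f <- tuning_field(60, 2)
  test_dirs <- seq(0, 345, by = 15) * deg
  Gm <- rowMeans(vapply(1:50, function(i) {
    run <- run_adaptation(60000, seed = i, field = f, gamma = 10 * deg,
                          n0 = 0.02, sigma = 0.05, eta_tilde = 0.1,
                          early_stop = TRUE, early_window = 200)
    evaluate_generalization(run$W_final, 10 * deg, test_dirs, f)$G
  }, numeric(length(test_dirs))))
  expect_equal(Gm[1], 1, tolerance = 0.05)   # trained direction
  expect_lt(mean(abs(Gm - generalization_curve(test_dirs, rho = 2))), 0.05)
  # gamma = 0 leaves G undefined
  g0 <- evaluate_generalization(init_connectivity(f), 0, test_dirs, f)
  expect_true(attr(g0, "undefined_G"))
  expect_true(all(is.na(g0$G)))
})

test_that("three trained targets suffice for near-perfect broad-tuning performance", {
  f <- tuning_field(60, 0.5)
  test_dirs <- seq(0, 350, by = 10) * deg
  perf <- vapply(1:10, function(i) {
    run <- run_adaptation(1e5, seed = i, field = f, sigma = 0.3, n0 = 0.1,
                          targets = 2 * pi * (0:2) / 3,
                          early_stop = TRUE)
    attr(evaluate_generalization(run$W_final, pi / 6, test_dirs, f,
                                 n0 = 0.1), "noiseless_performance")
  }, numeric(1))
  expect_gt(mean(perf), 0.9)
})
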