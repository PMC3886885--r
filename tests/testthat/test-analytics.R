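test_that("reward probability matches quadrature, Monte Carlo and limits", {
  # Rayleigh case at zero noiseless error
  expect_equal(reward_probability(0, 0.2, 0.1),
               1 - exp(-0.01 / (2 * 0.04)), tolerance = 1e-12)
  # noncentral chi-square route vs adaptive quadrature of the Rice density
  grid <- expand.grid(Et = c(0.05, 0.3, 1), s = c(0.1, 0.3), n0 = c(0.05, 0.2))
  for (i in seq_len(nrow(grid))) {
    expect_equal(
      reward_probability(grid$Et[i], grid$s[i], grid$n0[i]),
      rewardadapt:::reward_probability_quad(grid$Et[i], grid$s[i], grid$n0[i]),
      tolerance = 1e-8)
  }
  # Monte-Carlo oracle at the fixture point
  set.seed(11)
  Et <- 0.5; s <- 0.2; n0 <- 0.1; n <- 1e6
  x <- sqrt(Et) + rnorm(n, 0, s); y <- rnorm(n, 0, s)
  p_hat <- mean(x^2 + y^2 <= n0^2)
  p <- reward_probability(Et, s, n0)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  # decreasing in the noiseless error; total mass as the target grows
  Ets <- seq(0, 2, length.out = 50)
  expect_true(all(diff(reward_probability(Ets, 0.3, 0.1)) < 0))
  expect_equal(reward_probability(0.5, 0.3, 50), 1, tolerance = 1e-10)
  # degenerate noiseless convention
  expect_equal(reward_probability(c(0.005, 0.02), 0, 0.1), c(1, 0))
})

test_that("reward probability is non-monotonic in noise when the error exceeds the target", {
  E0 <- initial_error(30 * deg)
  sg <- seq(0.02, 1.5, by = 0.01)
  P <- vapply(sg, function(s) reward_probability(E0, s, 0.1), numeric(1))
  k <- which.max(P)
  expect_gt(k, 1)
  expect_lt(k, length(sg))
  expect_gt(P[k], P[1])
  expect_gt(P[k], P[length(sg)])
})

test_that("first-reward waiting time is geometric", {
  expect_equal(first_reward_stats(1)$mean, 1)
  expect_equal(first_reward_stats(0.1)$mean, 10)
  expect_warning(fr <- first_reward_stats(0), "Inf")
  expect_identical(fr$mean, Inf)
  # simulation oracle: repeated model trials at fixed noiseless displacement
  set.seed(21)
  Et <- 0.1; s <- 0.25; n0 <- 0.15
  P1 <- reward_probability(Et, s, n0)
  n_rep <- 1e5
  waits <- integer(n_rep); left <- seq_len(n_rep); t <- 0L
  while (length(left) && t < 1000L) {
    t <- t + 1L
    hit <- (sqrt(Et) + rnorm(length(left), 0, s))^2 +
      rnorm(length(left), 0, s)^2 <= n0^2
    waits[left[hit]] <- t
    left <- left[!hit]
  }
  expect_lt(length(left) / n_rep, 0.001)
  expect_equal(mean(waits[waits > 0]), 1 / P1, tolerance = 0.02)
})

test_that("small-target trajectory converges below eta_tilde = 2 and diverges above", {
  E0 <- initial_error(30 * deg)
  expect_equal(smalltarget_trajectory(E0, 1, 1), 0)
  expect_lt(smalltarget_trajectory(E0, 0.5, 200), 1e-10)
  traj <- smalltarget_trajectory(E0, 2.5, c(10, 50, 200))
  expect_true(all(diff(traj) > 0))
  expect_gt(traj[3], 1e69)
})

test_that("worst-case error bound has the three-regime form", {
  n0 <- 0.1
  expect_equal(worstcase_error_bound(1, n0), n0, tolerance = 1e-10)
  expect_equal(worstcase_error_bound(0.4, n0), n0, tolerance = 1e-10)
  expect_equal(worstcase_error_bound(1.5, n0), 3 * n0, tolerance = 1e-10)
  expect_equal(worstcase_error_bound(1.9, n0), 1.9 * n0 / 0.1,
               tolerance = 1e-8)
  expect_identical(worstcase_error_bound(c(2, 2.5), n0), c(Inf, Inf))
  # adversarial cross-check: no random rewarded-noise sequence exceeds the
  # bound, and greedy adversarial offsets approach it
  set.seed(5)
  for (et in c(0.7, 1.5)) {
    bound <- worstcase_error_bound(et, n0)
    worst <- 0
    for (r in 1:200) {
      d <- c(0.5, 0)
      for (k in 1:300) {
        eps <- rnorm(2); eps <- eps / sqrt(sum(eps^2)) * runif(1, 0, n0)
        d <- (1 - et) * d + et * eps
      }
      worst <- max(worst, sqrt(sum(d^2)))
    }
    expect_lte(worst, bound + 1e-9)
    # greedy adversary: full-n0 offset aligned with the contracted term
    d <- c(0.5, 0)
    s <- sign(1 - et)
    for (k in 1:2000) d <- (1 - et) * d + et * (n0 * s * d / sqrt(sum(d^2)))
    expect_equal(sqrt(sum(d^2)), bound, tolerance = 1e-6)
  }
  # n0 -> 0 limit recovers the small-target convergence region
  expect_lt(worstcase_error_bound(1.5, 1e-12), 1e-10)
})

test_that("generalization curve follows the overlap and goes negative for far targets", {
  expect_equal(generalization_curve(0, field60()), 1)
  dth <- seq(0, pi, length.out = 91)
  for (rho in c(0.5, 1, 2, 6)) {
    G <- generalization_curve(dth, rho = rho)
    expect_true(all(G <= 1 + 1e-12))
    expect_equal(max(G), 1, tolerance = 1e-12)
  }
  # wide tuning, opposite target: worse than baseline
  expect_lt(generalization_curve(pi, rho = 0.5), 0)
  # G depends on (rho, dtheta) only through the overlap
  g <- overlap_closed_form(2, 1.3)
  expect_equal(generalization_curve(2, rho = 1.3), g * (2 * cos(2) - g))
})

test_that("interference equals generalization at eta_tilde = 1 and flips sign", {
  dth <- seq(0, pi, by = pi / 180)
  for (rho in c(0.5, 2, 6)) {
    expect_equal(interference_function(dth, 1, rho = rho),
                 generalization_curve(dth, rho = rho), tolerance = 1e-15)
  }
  expect_lt(interference_function(pi, 0.3, rho = 0.5), 0)  # destructive
  expect_gt(interference_function(pi / 12, 0.3, rho = 0.5), 0)
  ca_narrow <- critical_angle(1, 6)
  expect_false(ca_narrow$monotone)
  expect_true(ca_narrow$angle > 0 && ca_narrow$angle < pi)
  expect_true(critical_angle(1, 0.2)$monotone)
})

test_that("pair update matches one full-network rewarded trial", {
  f <- field60()
  W0 <- init_connectivity(f)
  gam <- 30 * deg
  th1 <- 0; th2 <- pi
  et <- 0.6
  # displacement vectors before: d = R_gamma W u - v
  dvec <- function(W, th) {
    drop(rotation_matrix(gam) %*% (W %*% input_activity(th, f))) -
      c(cos(th), sin(th))
  }
  d1 <- dvec(W0, th1); d2 <- dvec(W0, th2)
  G <- overlap(th2 - th1, f)
  pred <- pair_update(d1, d2, G, et)
  # network route: rewarded trial for target 1 with the cancelling noise
  xi <- cancelling_noise(W0, th1, gam, f)
  W1 <- update_weights(W0, 1, xi, input_activity(th1, f),
                       rate_from_normalized(et, f))
  expect_equal(dvec(W1, th1), pred$d, tolerance = 1e-10)
  expect_equal(dvec(W1, th2), pred$d_other, tolerance = 1e-10)
  # Gamma = 0: independent learning, the other target is untouched
  expect_equal(pair_update(d1, d2, 0, et)$d_other, d2)
  # contraction for the rewarded target whenever eta_tilde <= 1
  expect_lte(sqrt(sum(pair_update(d1, d2, G, 0.9)$d^2)), sqrt(sum(d1^2)))
  # I1 is the relative error reduction implied by that same update
  I1_net <- 1 - sum(dvec(W1, th2)^2) / sum(d2^2)
  expect_equal(I1_net, interference_function(pi, et, field = f),
               tolerance = 1e-10)
})
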