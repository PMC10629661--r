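cfg <- default_config()

test_that("analytic signal reproduces the closed form for a cosine", {
  n <- 1024; f <- 10
  tt <- (0:(n - 1)) / n
  x <- 3 * cos(2 * pi * f * tt)
  a <- analytic_signal(x)
  expect_equal(Mod(a), rep(3, n), tolerance = 1e-9)
  expect_equal(Re(a), x, tolerance = 1e-9)
})

test_that("theta modulation score separates 8 Hz, homogeneous and 30 Hz trains", {
  t8 <- modulated_train(8, 0.8, seed = 1)
  t0 <- modulated_train(8, 0, seed = 2)
  t30 <- modulated_train(30, 0.8, seed = 3)
  s8 <- theta_modulation_score(t8, cfg)
  s0 <- theta_modulation_score(t0, cfg)
  s30 <- theta_modulation_score(t30, cfg)
  expect_gt(s8, s0)
  expect_gt(s8, s30)
  # invariant to global time translation
  expect_equal(theta_modulation_score(t8 + 500.123, cfg), s8)
  # too few spikes -> untested
  expect_true(is.na(theta_modulation_score(t8[1:20], cfg)))
  r <- theta_modulation_test(t8[1:20], c(0, 600), seed = 1, config = cfg)
  expect_equal(r$is_theta_modulated, "untested")
})

test_that("permutation test flags the modulated train and is deterministic", {
  t8 <- modulated_train(8, 0.8, seed = 4)
  r1 <- theta_modulation_test(t8, c(0, 600), seed = 9, config = cfg)
  r2 <- theta_modulation_test(t8, c(0, 600), seed = 9, config = cfg)
  expect_equal(r1$is_theta_modulated, "yes")
  expect_identical(r1$shuffle_scores, r2$shuffle_scores)
  # 99th percentile is stricter than 97.5 on the same null sample
  expect_gte(stats::quantile(r1$shuffle_scores, 0.99),
             stats::quantile(r1$shuffle_scores, 0.975))
  t30 <- modulated_train(30, 0.8, seed = 5)
  expect_equal(theta_modulation_test(t30, c(0, 600), seed = 10,
                                     config = cfg)$is_theta_modulated, "no")
})

test_that("theta channel selection maximizes the theta/delta ratio", {
  ch8 <- synthetic_lfp(8, id = "b_theta", seed = 1)
  ch3 <- synthetic_lfp(3, id = "a_delta", seed = 2)
  expect_equal(select_theta_channel(list(ch3, ch8), cfg), "b_theta")
  expect_equal(select_theta_channel(list(ch8), cfg), "b_theta")
  # equal white-noise channels: tie goes to the lowest channel id
  w1 <- synthetic_lfp(0, amp = 0, noise = 1, id = "chB", seed = 3)
  w2 <- synthetic_lfp(0, amp = 0, noise = 1, id = "chA", seed = 3)
  expect_equal(select_theta_channel(list(w1, w2), cfg), "chA")
  expect_error(select_theta_channel(list()), "no CA1 LFP channel")
})

test_that("spike phases: perfect locking, uniform null, closed-form Rayleigh", {
  ch <- synthetic_lfp(8, dur_s = 60, amp = 30, noise = 0.5, seed = 6)
  st_peak <- seq(1, 59, by = 0.125)     # every cosine peak
  pl <- spike_phases(st_peak, ch, config = cfg)
  expect_lt(pl$rayleigh_p, 1e-6)
  expect_lt(abs(pl$mean_phase), 0.2)
  set.seed(7)
  pu <- spike_phases(runif(400, 1, 59), ch, config = cfg)
  expect_gt(pu$rayleigh_p, 1e-4)
  # von Mises kappa = 1 phases: p within 10% of exp(-n rbar^2)
  set.seed(8)
  n <- 200
  u <- runif(3 * n) * 2 * pi
  keep <- runif(3 * n) < exp(cos(u) - 1)
  ph <- u[keep][1:n]
  rt <- rayleigh_test(ph)
  expect_equal(rt$p_value, exp(-n * rt$rbar^2), tolerance = 0.1)
  # speed filter removes slow-running spikes
  speed <- data.frame(time_s = c(0, 30, 60), speed_cm_s = c(0, 0, 0))
  pl0 <- spike_phases(st_peak, ch, speed = speed, config = cfg)
  expect_equal(pl0$n, 0L)
  expect_true(pl0$low_n)
})

test_that("phase locking by learning period recovers a planted trend", {
  set.seed(9)
  mk_p <- function(kappa, n) {
    vapply(seq_len(n), function(i) {
      u <- runif(600) * 2 * pi
      ph <- u[runif(600) < exp(kappa * (cos(u) - 1))][1:40]
      rayleigh_test(ph)$p_value
    }, 0)
  }
  p_early <- mk_p(0.15, 25); p_mid <- mk_p(1.2, 25); p_late <- mk_p(1.2, 25)
  day <- rep(c(1, 3, 5), each = 25)
  res <- phase_locking_by_period(c(p_early, p_mid, p_late), day,
                                 n_boot = 2000, seed = 10)
  expect_gt(res$means[["early"]], res$means[["mid"]])
  cmp <- res$comparisons
  em <- cmp[cmp$period_a == "early" & cmp$period_b == "mid", ]
  expect_lt(em$p_value, 0.05)
  # single period: no comparisons
  r1 <- phase_locking_by_period(p_early, rep(1, 25), n_boot = 100, seed = 1)
  expect_null(r1$comparisons)
})
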