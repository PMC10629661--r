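cfg <- default_config()

test_that("normalized participation: saturation, analytic chance, null mean", {
  win <- c(0, 100)
  set.seed(1)
  ev <- data.frame(start_s = seq(5, 90, by = 10), end_s = seq(5, 90, by = 10) + 0.5)
  # a cell firing every millisecond participates in everything: normalized 1
  dense <- seq(0, 100, by = 0.001)
  pr <- normalized_participation(dense, ev, win, seed = 2)
  expect_equal(pr$normalized, 1)
  expect_false(pr$untestable)
  # cell firing only inside events covering 5% of the epoch: ~ 1/0.05
  ev5 <- data.frame(start_s = seq(0, 95, by = 20), end_s = seq(0, 95, by = 20) + 1)
  inside <- as.vector(sapply(ev5$start_s, function(s) seq(s + 0.05, s + 0.95,
                                                          by = 0.05)))
  pr5 <- normalized_participation(sort(inside), ev5, win, seed = 3)
  expect_equal(pr5$normalized, 1 / 0.05, tolerance = 0.2 * 20)
  expect_gt(pr5$normalized, 5)
  expect_true(pr5$significant)
  # Poisson cell independent of events: normalized near 1 across cells
  set.seed(4)
  vals <- vapply(1:25, function(i) {
    st <- sort(runif(300, 0, 100))
    normalized_participation(st, ev, win, seed = 10 + i)$normalized
  }, 0)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 2.5 * se + 0.02)
  # silent cell is untestable
  expect_true(normalized_participation(numeric(0), ev, win, seed = 1)$untestable)
  expect_error(normalized_participation(dense, ev[1:3, ], win), "at least 5")
})

test_that("coherence score: closed forms and self-consistency with the fit", {
  # dMEC posterior concentrated exactly on the CA1 line -> 1
  post <- delta_line_posterior(V = 4, c0 = 1.5, nt = 6)
  fit <- list(V = 4, c = 1.5, R = 1)
  expect_equal(coherence_score(fit, post, cfg), 1)
  # concentrated maximally far from the line -> 0
  far <- delta_line_posterior(V = 4, c0 = 4.5, nt = 6)
  expect_equal(coherence_score(fit, far, cfg), 0)
  # uniform posterior equals the corridor's track fraction, brute force
  un <- matrix(1 / 300, 300, 6)
  oracle <- mean(vapply(0:5, function(t) {
    x <- 4 * t * 0.01 + 1.5
    sum(abs((0:299) * 0.02 + 0.01 - x) <= 0.3 + 1e-12) / 300
  }, 0))
  expect_equal(coherence_score(fit, un, cfg), oracle, tolerance = 1e-12)
  # self-consistency: coherence of a posterior with its own fit == fit R
  p <- random_posterior(nt = 5, seed = 9, peaky = TRUE)
  f <- fit_trajectory_line(p, cfg)
  expect_identical(coherence_score(f, p, cfg), f$R)
})

test_that("coherence nulls respect their regime definitions", {
  set.seed(5)
  nb <- 300
  rate <- matrix(rexp(nb * 4), nb, 4)
  sp <- setNames(lapply(1:4, function(i) sort(runif(8, 10, 10.08))),
                 paste0("d", 1:4))
  fit <- list(V = 5, c = 1, R = 0.5)
  win <- c(10, 10.08)
  # cell-ID shuffle requires >= 2 cells
  expect_error(coherence_null(sp[1], win, rate[, 1, drop = FALSE], fit,
                              regime = "cell_id"), "at least 2")
  # with identical ratemaps the cell-ID shuffle reproduces the data score
  rate_same <- rate[, c(1, 1, 1, 1)]
  obs <- coherence_score(fit, bayesian_posterior(sp, win, rate_same, cfg), cfg)
  nul <- coherence_null(sp, win, rate_same, fit, regime = "cell_id",
                        n_shuffles = 12, seed = 6)
  expect_equal(nul, rep(obs, 12), tolerance = 1e-12)
  # field rotation changes scores but keeps them in [0, 1]
  nr <- coherence_null(sp, win, rate, fit, regime = "field_rotation",
                       n_shuffles = 12, seed = 7)
  expect_true(all(nr >= 0 & nr <= 1))
  # spike-time shuffle is reproducible under a fixed seed
  n1 <- coherence_null(sp, win, rate, fit, regime = "spike_time",
                       n_shuffles = 6, seed = 8)
  n2 <- coherence_null(sp, win, rate, fit, regime = "spike_time",
                       n_shuffles = 6, seed = 8)
  expect_identical(n1, n2)
})

test_that("AUC comparison: null gives p ~ 0.5, separation gives small p", {
  set.seed(10)
  a <- runif(120, 0.2, 0.8)
  r0 <- auc_compare(a, a, n_boot = 2000, seed = 1)
  expect_equal(r0$p_value, 0.5, tolerance = 0.1)
  expect_equal(r0$auc_diff, 0, tolerance = 1e-12)
  b <- a + 1 * sd(a)
  r1 <- auc_compare(b, a, n_boot = 2000, seed = 2)
  expect_gt(r1$auc_diff, 0)        # data more coherent -> positive
  expect_lt(r1$p_value, 0.001)
  r2 <- auc_compare(a, b, n_boot = 2000, seed = 3)
  expect_gt(r2$p_value, 0.99)      # data worse than shuffle
  expect_error(auc_compare(a[1:5], a), "at least 10")
  # fixed seed reproducibility
  expect_identical(auc_compare(b, a, n_boot = 500, seed = 4)$p_value,
                   auc_compare(b, a, n_boot = 500, seed = 4)$p_value)
})

test_that("PSTH peaks at zero lag for symmetric bursts", {
  set.seed(11)
  ev <- data.frame(start_s = seq(10, 300, by = 10),
                   end_s = seq(10, 300, by = 10) + 0.1)
  mids <- (ev$start_s + ev$end_s) / 2
  sp <- list(d1 = sort(c(runif(300, 0, 305),
                         rep(mids, each = 4) + rnorm(4 * nrow(ev), 0, 0.01))))
  ps <- psth(sp, ev)
  expect_equal(ps$peak_lag_s, 0, tolerance = 0.008)
  expect_gt(max(ps$normalized), 2)
  expect_error(psth(sp, ev[1:5, ]), "at least 10")
})

test_that("bootstrap difference and Bonferroni behave as specified", {
  set.seed(12)
  a <- rnorm(40)
  r <- bootstrap_difference(a, a, n_boot = 2000, seed = 1)
  expect_equal(r$p_one_sided, 0.5, tolerance = 0.1)
  b <- a + 10 * sd(a)
  r2 <- bootstrap_difference(b, a, n_boot = 2000, seed = 2)
  expect_lt(r2$p_one_sided, 1e-3)
  r3 <- bootstrap_difference(b, a, n_boot = 1, seed = 3)
  expect_identical(r3$diffs, bootstrap_difference(b, a, n_boot = 1,
                                                  seed = 3)$diffs)
  expect_error(bootstrap_difference(a[1:3], a), "at least 5")
  expect_identical(bonferroni_decisions(c(0.04, 0.01), m = 3),
                   c(FALSE, TRUE))
  expect_true(bonferroni_decisions(0.04, m = 1))
})

test_that("theta quartiles partition tested cells into near-equal groups", {
  ids <- sprintf("c%02d", 1:18)
  sc <- c(seq_len(16) / 10, NA, NA)
  q <- theta_quartiles(ids, sc)
  expect_equal(sort(names(q)), c("q1", "q2", "q3", "q4"))
  expect_equal(unname(lengths(q)), c(4L, 4L, 4L, 4L))
  expect_true(all(q$q1 %in% ids[1:4]))
  expect_true(all(q$q4 %in% ids[13:16]))
})
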