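cfg <- default_config()

test_that("MUA event detection honors burst, duration and participation rules", {
  set.seed(1)
  dur <- 120
  # 8 cells, 1 Hz baseline, one planted 100 ms burst at high rate
  base <- lapply(1:8, function(i) sort(runif(dur, 0, dur)))
  burst <- lapply(1:8, function(i) sort(runif(30, 60.00, 60.10)))
  spikes <- setNames(Map(function(a, b) sort(c(a, b)), base, burst),
                     paste0("c", 1:8))
  ev <- detect_candidate_events(spikes, c(0, dur), cfg)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$start_s, 60.0)
  expect_gt(ev$end_s, 60.1)
  expect_equal(ev$n_cells, 8)
  # constant-rate MUA (one pooled spike every ms, round-robin): no events
  clock <- seq(0.0005, dur, by = 0.001)
  const <- setNames(lapply(1:8, function(i)
    clock[seq(i, length(clock), by = 8)]), paste0("c", 1:8))
  ev0 <- detect_candidate_events(const, c(0, dur), cfg)
  expect_equal(nrow(ev0), 0)
  # 35 ms burst: below the 40 ms minimum.  Smoothing can stretch the
  # super-threshold period, so plant a sparser short burst.
  burst35 <- lapply(1:8, function(i) sort(runif(4, 60.000, 60.035)))
  spikes35 <- setNames(Map(function(a, b) sort(c(a, b)), base, burst35),
                       paste0("c", 1:8))
  ev35 <- detect_candidate_events(spikes35, c(0, dur), cfg)
  if (nrow(ev35)) expect_gte(min(ev35$duration_ms), 40)
  # participation filter: burst carried by only 3 of 12 cells is rejected
  base12 <- setNames(lapply(1:12, function(i) sort(runif(dur, 0, dur))),
                     paste0("c", 1:12))
  few <- base12
  for (i in 1:3) few[[i]] <- sort(c(few[[i]], runif(40, 60.00, 60.10)))
  quiet <- lapply(few[4:12], function(st) st[st < 59.9 | st > 60.2])
  few[4:12] <- quiet
  ev3 <- detect_candidate_events(few, c(0, dur), cfg)
  expect_equal(nrow(ev3), 0)
  expect_error(detect_candidate_events(list(), c(0, 1)), "empty spike set")
})

test_that("awake events require immobility", {
  set.seed(2)
  dur <- 60
  spikes <- setNames(lapply(1:8, function(i)
    sort(c(runif(dur, 0, dur), runif(30, 30.00, 30.10)))), paste0("c", 1:8))
  fast <- data.frame(time_s = c(0, dur), speed_cm_s = c(10, 10))
  slow <- data.frame(time_s = c(0, dur), speed_cm_s = c(0.2, 0.2))
  expect_equal(nrow(detect_candidate_events(spikes, c(0, dur), cfg,
                                            speed = fast)), 0)
  ev <- detect_candidate_events(spikes, c(0, dur), cfg, speed = slow)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, "awake_immobile")
})

test_that("posterior matches the Poisson likelihood brute force", {
  set.seed(3)
  nb <- 300
  rate <- matrix(rexp(nb * 5, rate = 0.5), nb, 5)
  spikes <- setNames(lapply(1:5, function(i) sort(runif(6, 0, 0.05))),
                     paste0("c", 1:5))
  post <- bayesian_posterior(spikes, c(0, 0.05), rate, cfg)
  expect_equal(dim(post$prob), c(nb, 5L))
  expect_equal(colSums(post$prob), rep(1, 5), tolerance = 1e-9)
  # brute-force oracle over all bins
  r <- pmax(rate, cfg$rate_floor_hz)
  tau <- cfg$decode_bin_s
  for (t in 1:5) {
    k <- post$counts[, t]
    L <- apply(r, 1, function(rx) prod((tau * rx)^k * exp(-tau * rx)))
    expect_equal(post$prob[, t], L / sum(L), tolerance = 1e-9)
  }
  # single cell, single-bin field, one spike -> argmax at that bin
  r1 <- matrix(cfg$rate_floor_hz, nb, 1); r1[42, 1] <- 20
  p1 <- bayesian_posterior(list(c1 = 0.005), c(0, 0.01), r1, cfg)
  expect_equal(which.max(p1$prob[, 1]), 42)
  # no spikes in a bin: posterior proportional to exp(-tau * sum rates)
  p0 <- bayesian_posterior(list(c1 = numeric(0)), c(0, 0.01), rate[, 1,
                           drop = FALSE], cfg)
  L0 <- exp(-tau * pmax(rate[, 1], cfg$rate_floor_hz))
  expect_equal(p0$prob[, 1], L0 / sum(L0), tolerance = 1e-12)
  expect_error(bayesian_posterior(spikes, c(0, 0.05), rate * 0, cfg),
               "all-zero ratemaps")
})

test_that("line fit: perfect line gives R = 1; uniform posterior matches oracle", {
  post <- delta_line_posterior(V = 5, c0 = 1, nt = 8)
  f <- fit_trajectory_line(post, cfg)
  expect_equal(f$R, 1)
  # the returned line must cover every ridge point within the corridor
  x_true <- 5 * (0:7) * 0.01 + 1
  x_line <- f$V * (0:7) * 0.01 + f$c
  expect_true(all(abs(x_true - x_line) <= 0.3 + 0.02))
  # uniform posterior: R equals the best corridor coverage fraction
  un <- matrix(1 / 300, 300, 4)
  fu <- fit_trajectory_line(un, cfg)
  # a 60 cm corridor fully on the 6 m track covers 31 bin centers at most
  expect_equal(fu$R, 31 / 300, tolerance = 1e-12)
  expect_error(fit_trajectory_line(un[, 1, drop = FALSE], cfg),
               "at least 2 time bins")
})

test_that("fast search equals the naive double-loop exactly", {
  for (s in 1:4) {
    p <- random_posterior(nt = 3, seed = s, peaky = s %% 2 == 0)
    ff <- fit_trajectory_line(p, cfg)
    fn <- fit_trajectory_line(p, cfg, method = "naive")
    expect_identical(ff$V, fn$V)
    expect_identical(ff$c, fn$c)
    expect_equal(ff$R, fn$R, tolerance = 1e-12)
  }
})

test_that("corridor mass is invariant under joint reflection with time reversal", {
  # reversing the posterior in time maps the line (V, c) to
  # (-V, c + V T (n-1)); the corridor mass along the mapped line is
  # identical.  (The mapped intercept is generally off the 0.01 m search
  # grid, so the argmax itself need not map; the score does, exactly.)
  for (s in 1:5) {
    p <- random_posterior(nt = 6, seed = 100 + s, peaky = TRUE)
    n <- ncol(p)
    p_rev <- p[, n:1]
    f <- fit_trajectory_line(p, cfg)
    lines <- list(c(f$V, f$c), c(4, 1.23), c(-8.5, 5.115), c(2, -0.5))
    for (ln in lines) {
      a <- coherence_score(list(V = ln[1], c = ln[2]), p, cfg)
      b <- coherence_score(list(V = -ln[1],
                                c = ln[2] + ln[1] * 0.01 * (n - 1)),
                           p_rev, cfg)
      expect_equal(a, b, tolerance = 1e-12)
    }
    # and the reversed fit can never beat the forward optimum's score
    f_rev <- fit_trajectory_line(p_rev, cfg)
    expect_equal(f_rev$R, f$R, tolerance = 0.02)
  }
})

test_that("event significance is reproducible and calibrated on scrambles", {
  set.seed(4)
  run <- simulate_run_epoch(sim_params(n_ca1 = 30L, n_dmec = 0L, run_s = 300),
                            seed = 55)
  lint <- linearize_position(run$position, config = cfg)
  maps <- compute_ratemaps(run$spikes, lint, config = cfg)
  ids <- names(run$spikes)
  rmats <- list(outbound = ratemap_matrix(maps, "outbound", ids),
                inbound = ratemap_matrix(maps, "inbound", ids))
  rest <- simulate_rest_epoch(sim_params(n_ca1 = 30L, n_dmec = 0L,
                                         event_rate_hz = 0.3,
                                         event_dur_range_s = c(0.1, 0.15),
                                         replay_gain = 8, rest_s = 60),
                              seed = 56, truth = run$truth)
  ev <- rest$events[1:4, ]
  sp <- rest$spikes[ids]
  for (i in 1:2) {
    win <- c(ev$start_s[i], ev$end_s[i])
    s1 <- event_significance(sp, win, rmats, n_shuffles = 40, seed = 7,
                             config = cfg)
    s2 <- event_significance(sp, win, rmats, n_shuffles = 40, seed = 7,
                             config = cfg)
    expect_identical(s1$outbound$p_value, s2$outbound$p_value)
    # planted trajectories come out significant
    expect_lt(min(s1$outbound$p_value, s1$inbound$p_value), cfg$replay_p)
  }
  # scrambled event (spike times shuffled within window): high p expected
  win <- c(ev$start_s[3], ev$end_s[3])
  set.seed(8)
  scr <- lapply(sp, function(st) {
    inw <- st[st >= win[1] & st < win[2]]
    sort(runif(length(inw), win[1], win[2]))
  })
  s3 <- event_significance(scr, win, rmats, n_shuffles = 40, seed = 9,
                           config = cfg)
  expect_gte(s3$outbound$p_value, 0)  # defined; calibration is in acceptance
})
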