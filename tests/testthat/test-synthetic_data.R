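test_that("identical (params, seed) give bit-identical sessions; seeds differ", {
  a <- tiny_session(seed = 7)
  b <- tiny_session(seed = 7)
  c_ <- tiny_session(seed = 8)
  expect_identical(a$session$spikes, b$session$spikes)
  expect_identical(a$session$position, b$session$position)
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(a$session$spikes, c_$session$spikes))
  # schema identical across seeds
  expect_identical(names(a$session), names(c_$session))
  expect_identical(dim(a$session$cells), dim(c_$session$cells))
})

test_that("spike counts match rate integrals within 3 Monte-Carlo SDs", {
  dur <- 300; base <- 2
  st <- modulated_train(8, 0.5, dur_s = dur, base_hz = base, seed = 11)
  expected <- base * dur  # modulation integrates to zero
  expect_lt(abs(length(st) - expected), 3 * sqrt(expected))
})

test_that("theta-locked generated spikes show strong phase concentration", {
  st <- modulated_train(8, 0.8, dur_s = 300, base_hz = 2, seed = 12)
  phases <- (2 * pi * 8 * st) %% (2 * pi)
  rt <- rayleigh_test(phases)
  expect_lt(rt$p_value, 1e-6)
  # null case: unmodulated train's phases are uniform
  st0 <- modulated_train(8, 0, dur_s = 300, base_hz = 2, seed = 13)
  rt0 <- rayleigh_test((2 * pi * 8 * st0) %% (2 * pi))
  expect_gt(rt0$p_value, 0.01)
})

test_that("coordinated dMEC spikes lag CA1 event spikes by the planted 10 ms", {
  p <- sim_params(event_rate_hz = 0.3, replay_gain = 8, dmec_event_gain = 8,
                  frac_dmec_theta = 1)  # all dMEC coordinated
  geom <- track_geometry()
  truth <- thetareplay:::make_cell_truth(p, geom, 42)
  rest <- simulate_rest_epoch(p, seed = 21, truth = truth)
  ev <- rest$events
  ca1 <- unlist(rest$spikes[grepl("ca1", names(rest$spikes))], use.names = FALSE)
  dmec <- unlist(rest$spikes[grepl("dmec", names(rest$spikes))], use.names = FALSE)
  # cross-correlogram restricted to event windows, 2 ms bins centered so
  # one bin spans [9, 11) ms
  lags <- seq(-0.029, 0.031, by = 0.002)
  counts <- numeric(length(lags) - 1)
  for (i in seq_len(nrow(ev))) {
    a <- ca1[ca1 >= ev$start_s[i] & ca1 < ev$end_s[i]]
    b <- dmec[dmec >= ev$start_s[i] & dmec < ev$end_s[i] + 0.02]
    if (!length(a) || !length(b)) next
    d <- outer(b, a, "-")
    counts <- counts + hist(d[d >= -0.029 & d < 0.031], breaks = lags,
                            plot = FALSE)$counts
  }
  peak <- (lags[-1] - 0.001)[which.max(counts)]
  expect_lt(abs(peak - 0.010), 0.0041)
})

test_that("zero event rate plants nothing; detection drops to chance level", {
  geom <- track_geometry()
  p0 <- sim_params(event_rate_hz = 0, n_ca1 = 20L, n_dmec = 0L, rest_s = 120)
  truth <- thetareplay:::make_cell_truth(p0, geom, 1)
  rest0 <- simulate_rest_epoch(p0, seed = 2, truth = truth)
  expect_equal(nrow(rest0$events), 0)
  # with the detection threshold referenced to a structured rest epoch (as
  # the pipeline does for the pre-task rest), the event-free epoch yields
  # nothing, while the structured epoch itself yields its planted events
  p1 <- sim_params(event_rate_hz = 0.25, n_ca1 = 20L, n_dmec = 0L,
                   rest_s = 120)
  rest1 <- simulate_rest_epoch(p1, seed = 2, truth = truth)
  expect_gt(nrow(rest1$events), 15)
  combined <- Map(function(a, b) sort(c(a, b + 120)),
                  rest0$spikes, rest1$spikes)
  n0 <- nrow(detect_candidate_events(combined, c(0, 120),
                                     ref_window = c(120, 240)))
  n1 <- nrow(detect_candidate_events(combined, c(120, 240)))
  # a few chance crossings of the (event-inflated) threshold are expected
  # in 120 s of Poisson baseline; the planted epoch must dominate
  expect_lte(n0, 0.25 * n1)
  expect_gt(n1, 15)
})

test_that("a CA1-only session is valid and survives a round trip", {
  p <- sim_params(n_ca1 = 5L, n_dmec = 0L, run_s = 30, rest_s = 30,
                  pre_rest_s = 10, of_s = 20)
  sim <- assemble_session(p, 3)
  expect_true(validate_session(sim$session))
  dir <- file.path(tempdir(), "ca1only")
  save_session(sim$session, dir)
  s2 <- load_session(dir)
  expect_identical(nrow(s2$cells), 5L)
})

test_that("planted place-field centers are recovered within 2 bins", {
  cfg <- default_config()
  run <- simulate_run_epoch(sim_params(), seed = 31)
  lint <- linearize_position(run$position, config = cfg)
  maps <- compute_ratemaps(run$spikes, lint, config = cfg)
  geom <- track_geometry()
  errs <- c()
  for (cell in run$truth) {
    if (cell$region != "CA1") next
    if (in_excluded_zone(cell$track_centers, geom)) next
    r <- pmax(maps[[cell$cell_id]]$outbound$rate,
              maps[[cell$cell_id]]$inbound$rate)
    pk_cm <- (which.max(r) - 0.5) * geom$bin_cm
    errs <- c(errs, abs(pk_cm - cell$track_centers))
  }
  expect_gt(length(errs), 20)
  expect_gte(mean(errs <= 2 * geom$bin_cm + 1), 0.85)
  expect_lte(median(errs), 2 * geom$bin_cm)
})
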