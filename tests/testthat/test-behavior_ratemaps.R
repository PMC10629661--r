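geom <- track_geometry()
cfg <- default_config()

test_that("linearization maps skeleton landmarks correctly", {
  v <- geom$vertices
  # start of arm 1 -> 0 cm; far end -> 600 cm
  expect_equal(xy_to_lin(v[1, 1], v[1, 2], geom)$lin_cm, 0)
  expect_equal(xy_to_lin(v[4, 1], v[4, 2], geom)$lin_cm, 600)
  # mid-diagonal point: 190 + 110 = 300 cm (geometric projection oracle)
  mid <- (v[2, ] + v[3, ]) / 2
  expect_equal(xy_to_lin(mid[1], mid[2], geom)$lin_cm, 300)
  # off-track sample keeps nearest projection and reports its distance
  pr <- xy_to_lin(v[1, 1], v[1, 2] + 40, geom)
  expect_equal(pr$dist_cm, 40)
  # round trip along the whole skeleton
  lin <- seq(0, 600, by = 7)
  xy <- lin_to_xy(lin, geom)
  expect_equal(xy_to_lin(xy[, 1], xy[, 2], geom)$lin_cm, lin, tolerance = 1e-9)
})

test_that("linearize_position labels directions and exclusions", {
  tt <- seq(0, 20, by = 0.02)
  lin <- pmin(pmax(30 * tt, 0), 600)           # steady outbound run
  xy <- lin_to_xy(lin, geom)
  tr <- data.frame(time_s = tt, x_cm = xy[, 1], y_cm = xy[, 2], hd_rad = 0)
  tr <- thetareplay:::add_derived_speed(tr)
  lt <- linearize_position(tr, geom, cfg)
  mid <- lt$lin_cm > 30 & lt$lin_cm < 560
  expect_true(all(lt$direction[mid] == "outbound"))
  expect_true(all(lt$in_excluded_zone[lt$lin_cm < 10]))
  expect_true(all(!lt$included[lt$in_excluded_zone]))
})

test_that("ratemap mass is conserved and single-spike maps match the kernel", {
  # uniform dwell, one spike: smoothed counts / smoothed dwell
  tt <- seq(0, 40, by = 0.02)
  lin <- pmin(20 + 14 * tt, 600)   # one slow outbound sweep at 14 cm/s
  xy <- lin_to_xy(lin, geom)
  tr <- thetareplay:::add_derived_speed(
    data.frame(time_s = tt, x_cm = xy[, 1], y_cm = xy[, 2], hd_rad = 0))
  lt <- linearize_position(tr, geom, cfg)
  spike_t <- tt[which.min(abs(lin - 301))]     # one spike at ~301 cm
  maps <- compute_ratemaps(list(c1 = spike_t), lt, geom, cfg)
  m <- maps$c1$outbound
  expect_equal(sum(m$counts), 1)
  expect_equal(sum(m$rate * m$occupancy_s), 1, tolerance = 0.05)
  # no-spike cell: all-zero map
  maps0 <- compute_ratemaps(list(c0 = numeric(0)), lt, geom, cfg)
  expect_true(all(maps0$c0$outbound$rate == 0))
  # direct convolution oracle around the spike bin
  k <- dnorm(-15:15, sd = 5); k <- k / sum(k)
  spike_bin <- floor(301 / 2) + 1
  occ <- m$occupancy_s
  sm_c <- as.numeric(stats::filter(c(rep(0, 15), tabulate(spike_bin, 300),
                                     rep(0, 15)), k, sides = 2))[16:315]
  sm_o <- as.numeric(stats::filter(c(rep(0, 15), occ, rep(0, 15)),
                                   k, sides = 2))[16:315]
  idx <- (spike_bin - 5):(spike_bin + 5)
  expect_equal(m$rate[idx], (sm_c / sm_o)[idx], tolerance = 1e-9)
})

test_that("place-cell criteria respect the 20-bin and 1 Hz boundaries", {
  mk <- function(rate) list(outbound = list(rate = rate),
                            inbound = list(rate = rep(0, 300)))
  base <- rep(0, 300)
  r20 <- base; r20[101:120] <- 2          # 20 contiguous bins at 2 Hz
  pc <- classify_place_cell(mk(r20), mean_rate_hz = 0.1, cfg)
  expect_true(pc$is_place_cell)
  expect_equal(pc$fields$length_cm[1], 40)
  r19 <- base; r19[101:119] <- 2          # 19 bins: not a place cell
  expect_false(classify_place_cell(mk(r19), 0.1, cfg)$is_place_cell)
  r_low <- base; r_low[101:125] <- 0.9    # peak below 1 Hz
  expect_false(classify_place_cell(mk(r_low), 0.1, cfg)$is_place_cell)
})

test_that("Skaggs information matches closed forms and the direct formula", {
  # flat map -> 0 bits/spike
  expect_equal(skaggs_information(rep(3, 10), rep(1, 10)), 0)
  # two equal-occupancy bins at (2, 0) Hz -> exactly 1 bit/spike
  expect_equal(skaggs_information(c(2, 0), c(1, 1)), 1.0)
  # random map vs direct-formula oracle
  set.seed(5)
  r <- rexp(50); occ <- runif(50)
  p <- occ / sum(occ); rb <- sum(p * r)
  oracle <- sum(ifelse(r > 0, p * (r / rb) * log2(r / rb), 0))
  expect_equal(skaggs_information(r, occ), oracle, tolerance = 1e-12)
  expect_gte(skaggs_information(r, occ), 0)
  expect_error(skaggs_information(rep(0, 5), rep(1, 5)), "zero mean rate")
})

test_that("ratemap overlap hits the correlation limits", {
  mk2 <- function(a, b) list(outbound = list(rate = a),
                             inbound = list(rate = b))
  x <- c(1, 2, 3, 4, 5, 0, 0)
  expect_equal(ratemap_overlap(mk2(x, x), mk2(x, x)), 1)
  y <- c(5, 4, 3, 2, 1, 0, 0)   # anti-correlated profile over joint support
  expect_equal(ratemap_overlap(mk2(x, x), mk2(y, y)), -1)
  set.seed(6)
  a <- rexp(40); b <- rexp(40)
  sel <- a > 0 & b > 0
  expect_equal(ratemap_overlap(mk2(a, rep(0, 40)), mk2(b, rep(0, 40))),
               cor(a[sel], b[sel]), tolerance = 1e-12)
  # fewer than 3 jointly positive bins -> undefined
  expect_true(is.na(ratemap_overlap(mk2(c(1, 0, 0, 0), rep(0, 4)),
                                    mk2(c(0, 0, 0, 1), rep(0, 4)))))
})

test_that("performance score and experience correlation behave", {
  expect_equal(performance_score(0, 10)$proportion_incorrect, 0)
  expect_equal(performance_score(5, 10)$proportion_incorrect, 0.5)
  ps <- performance_score(c(6, 5, 4, 3, 2, 1), rep(10, 6), day = 1:6)
  expect_lt(ps$r, 0)
  expect_lt(ps$p_value, 0.05)
  expect_error(performance_score(1, 0), "at least one lap")
})
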