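cfg <- default_config()

test_that("KL directionality matches closed forms and the direct sum", {
  expect_equal(kl_directionality(rep(1 / 36, 36)), 0)
  one_hot <- c(1, rep(0, 35))
  expect_equal(kl_directionality(one_hot), log(36), tolerance = 1e-12)
  set.seed(7)
  tau <- rexp(36); tau <- tau / sum(tau)
  oracle <- sum(tau * log(tau / (1 / 36)))
  expect_equal(kl_directionality(tau), oracle, tolerance = 1e-12)
  expect_gte(kl_directionality(tau), 0)
  expect_error(kl_directionality(numeric(0)), "empty polar map")
  expect_error(kl_directionality(rep(1, 36)), "sum to 1")
})

test_that("gridness is high for a hexagonal field and low for a square lattice", {
  n <- 50
  xy <- expand.grid(x = (1:n) - 0.5, y = (1:n) - 0.5) * 2
  hexmap <- function(spacing, orient = 0.1) {
    k <- 4 * pi / (sqrt(3) * spacing)
    g <- 0
    for (a in orient + c(0, pi / 3, 2 * pi / 3))
      g <- g + cos(k * (cos(a) * xy$x + sin(a) * xy$y))
    matrix(pmax(0, g), n, n)
  }
  sqmap <- function(spacing) {
    k <- 2 * pi / spacing
    matrix(pmax(0, cos(k * xy$x) + cos(k * xy$y)), n, n)
  }
  g_hex <- gridness_score(spatial_autocorrelogram(hexmap(40)))
  g_sq <- gridness_score(spatial_autocorrelogram(sqmap(40)))
  expect_gt(g_hex, 1)
  expect_lt(g_sq, 0)
})

test_that("spatial autocorrelogram is 180-degree symmetric with unit center", {
  set.seed(8)
  M <- matrix(rexp(900), 30, 30)
  ac <- spatial_autocorrelogram(M)
  expect_equal(ac[30, 30], 1, tolerance = 1e-9)  # zero offset
  flipped <- ac[rev(seq_len(nrow(ac))), rev(seq_len(ncol(ac)))]
  expect_equal(ac, flipped, tolerance = 1e-9)
})

test_that("border score separates wall fields from central fields", {
  n <- 50
  wall <- matrix(0, n, n); wall[1:3, ] <- 5      # full wall, 3 bins deep
  mw <- structure(list(rate = wall, occupancy_s = matrix(1, n, n)),
                  class = "open_field_map")
  bs <- border_score(mw)
  expect_gt(bs$score, 0.8)
  d <- sqrt(outer(((1:n) - 25.5)^2, ((1:n) - 25.5)^2, "+"))
  disc <- matrix(0, n, n); disc[d < 8] <- 5      # central disc field
  md <- structure(list(rate = disc, occupancy_s = matrix(1, n, n)),
                  class = "open_field_map")
  expect_lt(border_score(md)$score, 0)
  # empty map -> no field
  m0 <- structure(list(rate = matrix(0, n, n)), class = "open_field_map")
  expect_true(is.na(border_score(m0)$score))
})

test_that("classification recovers planted dMEC cell classes", {
  # one open-field trajectory, several cells per class, reduced shuffle count
  # (the full 100-shuffle battery runs in the acceptance suite)
  p <- sim_params(of_s = 600)
  geom <- track_geometry()
  classes <- c("grid", "head_direction", "border", "other_spatial")
  set.seed(9)
  tuns <- lapply(rep(classes, each = 3), thetareplay:::make_of_tuning,
                 params = p)
  of_pos <- simulate_open_field(sim_params(n_ca1 = 0L, n_dmec = 0L,
                                           of_s = 600), seed = 10)$position
  set.seed(11)
  got <- vapply(seq_along(tuns), function(i) {
    r <- thetareplay:::of_rate(tuns[[i]], of_pos$x_cm, of_pos$y_cm,
                               of_pos$hd_rad)
    st <- sim_inhom_poisson(r, 0.02, t0 = of_pos$time_s[1])
    classify_dmec(st, of_pos, cfg, n_shuffles = 30, seed = 100 + i)$class
  }, "")
  truth <- rep(classes, each = 3)
  expect_gte(mean(got == truth), 0.75)
  # the flat-rate cell stays unclassified
  set.seed(12)
  st_flat <- sim_inhom_poisson(rep(1.5, nrow(of_pos)), 0.02,
                               t0 = of_pos$time_s[1])
  expect_true(classify_dmec(st_flat, of_pos, cfg, n_shuffles = 30,
                            seed = 13)$class %in%
                c("unclassified", "other_spatial"))
})
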