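#' Simulation parameters for a synthetic session
#'
#' Defaults emulate one recording day of the study system: ~40 CA1 place
#' cells and ~16 dMEC cells recorded while a rat runs laps on the Z-track,
#' rests (with time-compressed replay bursts), and forages in a 1 m open
#' field.  Replay event rates and speeds are free parameters (not reported
#' for the source dataset); defaults are standard values for rodent rest
#' replay and are discussed in the methods vignette.
#'
#' @param ... named overrides of any default.
#' @return A list of class \code{"sim_params"}.  Key fields:
#' \describe{
#'   \item{n_ca1, n_dmec}{cell counts (40 CA1, 16 dMEC).}
#'   \item{dmec_mix}{class mix for dMEC cells (grid, conjunctive,
#'     head_direction, border, other_spatial).}
#'   \item{place_sigma_cm, ca1_peak_hz}{CA1 place-field width (15 cm) and
#'     peak rate (15 Hz).}
#'   \item{theta_hz}{theta frequency (8 Hz).}
#'   \item{theta_depth_ca1, theta_depth_dmec}{rate-modulation depth m in
#'     rate * (1 + m cos(theta_phase - phase_pref)) for theta-locked cells.}
#'   \item{frac_dmec_theta}{fraction of dMEC cells that are theta-locked.}
#'   \item{run_s, rest_s, pre_rest_s, of_s}{epoch durations (600, 600, 600,
#'     1200 s).}
#'   \item{event_rate_hz, event_dur_range_s}{planted replay event rate
#'     (0.25/s) and duration range (40--200 ms).}
#'   \item{event_speeds_m_s}{planted trajectory speeds V* (+/-3, 5, 8 m/s;
#'     all outside the fit's excluded (-2, 2) zone and on the 0.5 m/s grid).}
#'   \item{replay_gain, dmec_event_gain}{time-compression rate gain applied
#'     to the tuning curve during events.}
#'   \item{dmec_coordination}{"coordinated" (theta-locked dMEC cells replay
#'     the planted trajectory at \code{dmec_lag_ms}; non-locked cells fire at
#'     an elevated trajectory-agnostic rate) or "independent" (all dMEC cells
#'     trajectory-agnostic).}
#'   \item{dmec_lag_ms}{lag of coordinated dMEC spikes after CA1 (10 ms).}
#'   \item{dmec_indep_frac}{event-rate elevation of trajectory-agnostic dMEC
#'     cells relative to the coordinated drive (0.5), placing their
#'     participation above chance but below the coordinated group.}
#'   \item{ca1_rest_hz, dmec_rest_hz}{baseline rest rates (0.5, 0.9 Hz).}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    n_ca1 = 40L,
    n_dmec = 16L,
    dmec_mix = c(grid = 3, conjunctive = 1, head_direction = 6,
                 border = 1, other_spatial = 5),
    place_sigma_cm = 15,
    ca1_peak_hz = 15,
    dmec_peak_hz = 7,
    theta_hz = 8,
    theta_depth_ca1 = 0.6,
    theta_depth_dmec = 0.8,
    frac_dmec_theta = 0.5,
    hd_kappa = 4,
    run_s = 600,
    rest_s = 600,
    pre_rest_s = 600,
    of_s = 1200,
    arena_cm = 100,
    run_speed_range = c(15, 35),
    pause_range_s = c(0.5, 2),
    event_rate_hz = 0.25,
    event_dur_range_s = c(0.04, 0.20),
    event_speeds_m_s = c(-8, -5, -3, 3, 5, 8),
    replay_gain = 4,
    dmec_event_gain = 4,
    dmec_indep_frac = 0.5,
    dmec_coordination = "coordinated",
    dmec_lag_ms = 10,
    ca1_rest_hz = 0.5,
    dmec_rest_hz = 0.9,
    ca1_track_base_hz = 0.1,
    session_day = 1L,
    animal_id = "S1"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$n_ca1 >= 0, p$n_dmec >= 0,
            all(abs(p$event_speeds_m_s) >= 2),
            p$frac_dmec_theta >= 0, p$frac_dmec_theta <= 1)
  structure(p, class = "sim_params")
}

#' Inhomogeneous Poisson spike times from a piecewise-constant rate
#'
#' The rate is taken as constant within each grid interval of width
#' \code{dt}; counts per interval are Poisson(rate * dt) and spikes are
#' placed uniformly within the interval.  For a piecewise-constant intensity
#' this is an exact sampler (equivalent to thinning, without rejections).
#'
#' @param rate_hz numeric vector of rates (Hz) on a uniform grid.
#' @param dt grid step (s).
#' @param t0 time of the start of the first interval (s).
#' @return Sorted numeric vector of spike times.
#' @export
sim_inhom_poisson <- function(rate_hz, dt, t0 = 0) {
  counts <- stats::rpois(length(rate_hz), pmax(rate_hz, 0) * dt)
  idx <- rep.int(seq_along(rate_hz), counts)
  if (!length(idx)) return(numeric(0))
  sort(t0 + (idx - 1) * dt + stats::runif(length(idx)) * dt)
}

## ---- ground-truth tuning construction -------------------------------------

# Build per-cell tuning descriptors.  Everything downstream (RUN, REST and
# open-field simulation) evaluates these same descriptors, so planted events
# are recoverable up to spike noise.
make_cell_truth <- function(params, geom, seed) {
  set.seed(seed)
  total <- geom$total_cm
  cells <- list()
  n_ca1 <- params$n_ca1
  if (n_ca1 > 0) {
    # jittered tiling: population-level field coverage is near-uniform, as
    # for CA1 place fields on a long track
    centers <- ((seq_len(n_ca1) - 0.5) / n_ca1) * total +
      stats::runif(n_ca1, -0.4, 0.4) * total / n_ca1
    centers <- pmin(pmax(centers, 0), total)
    ord <- sample.int(n_ca1)  # decouple id order from position
    for (i in seq_len(n_ca1)) {
      cells[[length(cells) + 1]] <- list(
        cell_id = sprintf("ca1_%02d", i), region = "CA1",
        class = "place", theta_locked = TRUE,
        theta_depth = params$theta_depth_ca1,
        phase_pref = stats::runif(1, 0, 2 * pi),
        track_centers = centers[ord[i]],
        track_sigmas = params$place_sigma_cm,
        track_peaks = params$ca1_peak_hz)
    }
  }
  n_dmec <- params$n_dmec
  if (n_dmec > 0) {
    mix <- params$dmec_mix
    classes <- rep(names(mix), times = round(mix / sum(mix) * n_dmec))
    classes <- c(classes, rep("other_spatial", max(0, n_dmec - length(classes))))
    classes <- classes[seq_len(n_dmec)]
    n_theta <- round(params$frac_dmec_theta * n_dmec)
    locked <- sample(rep(c(TRUE, FALSE), c(n_theta, n_dmec - n_theta)))
    for (i in seq_len(n_dmec)) {
      cl <- classes[i]
      if (cl %in% c("grid", "conjunctive")) {
        spacing <- stats::runif(1, 40, 100)
        phase <- stats::runif(1, 0, spacing)
        ctr <- seq(phase, total, by = spacing)
        sig <- rep(stats::runif(1, 10, 18), length(ctr))
        pk <- rep(stats::runif(1, 4, params$dmec_peak_hz), length(ctr))
      } else {
        nf <- sample(1:3, 1)
        ctr <- stats::runif(nf, 0, total)
        sig <- stats::runif(nf, 12, 25)
        pk <- stats::runif(nf, 3, params$dmec_peak_hz)
      }
      # normalize tuning so the cell's mean track rate matches the observed
      # dMEC range (~1.25 Hz, well under the 7 Hz inclusion cap)
      target <- min(max(stats::rnorm(1, 1.25, 0.4), 0.5), 3)
      cell0 <- list(track_centers = ctr, track_sigmas = sig, track_peaks = pk)
      m0 <- mean(track_rate(cell0, seq(0, total, by = 1)))
      pk <- pk * target / m0
      cells[[length(cells) + 1]] <- list(
        cell_id = sprintf("dmec_%02d", i), region = "dMEC",
        class = cl, theta_locked = locked[i],
        theta_depth = if (locked[i]) params$theta_depth_dmec else 0,
        phase_pref = stats::runif(1, 0, 2 * pi),
        track_centers = ctr, track_sigmas = sig, track_peaks = pk,
        of = make_of_tuning(cl, params))
    }
  }
  names(cells) <- vapply(cells, `[[`, "", "cell_id")
  cells
}

make_of_tuning <- function(class, params) {
  a <- params$arena_cm
  tun <- list(class = class, peak = stats::runif(1, 5, 12), base = 0.1,
              arena = a)
  if (class %in% c("grid", "conjunctive")) {
    tun$spacing <- stats::runif(1, 35, 60)
    tun$orient <- stats::runif(1, 0, pi / 3)
    tun$offset <- stats::runif(2, 0, tun$spacing)
  }
  if (class %in% c("conjunctive", "head_direction")) {
    tun$hd_mu <- stats::runif(1, 0, 2 * pi)
    tun$hd_kappa <- params$hd_kappa
  }
  if (class == "border") {
    tun$wall <- sample(c("W", "E", "S", "N"), 1)
    tun$depth_cm <- 8
  }
  if (class == "other_spatial") {
    nb <- sample(1:2, 1)
    tun$blob_x <- stats::runif(nb, 0.15 * a, 0.85 * a)
    tun$blob_y <- stats::runif(nb, 0.15 * a, 0.85 * a)
    tun$blob_sigma <- stats::runif(nb, 8, 14)
  }
  tun
}

# firing rate (Hz) of a cell at linearized track positions (cm)
track_rate <- function(cell, lin_cm, base_hz = 0) {
  r <- rep(base_hz, length(lin_cm))
  for (k in seq_along(cell$track_centers)) {
    r <- r + cell$track_peaks[k] *
      exp(-0.5 * ((lin_cm - cell$track_centers[k]) / cell$track_sigmas[k])^2)
  }
  r
}

# firing rate (Hz) in the open field at (x, y, hd)
of_rate <- function(tun, x, y, hd) {
  r <- rep(tun$base, length(x))
  if (tun$class %in% c("grid", "conjunctive")) {
    k <- 4 * pi / (sqrt(3) * tun$spacing)
    ang <- tun$orient + c(0, pi / 3, 2 * pi / 3)
    g <- 0
    for (a in ang) {
      g <- g + cos(k * (cos(a) * (x - tun$offset[1]) +
                        sin(a) * (y - tun$offset[2])))
    }
    spat <- pmax(0, g) / 3
    r <- r + tun$peak * spat
  } else if (tun$class == "border") {
    d <- switch(tun$wall, W = x, E = tun$arena - x, S = y, N = tun$arena - y)
    r <- r + tun$peak * exp(-pmax(d, 0) / tun$depth_cm)
  } else if (tun$class == "other_spatial") {
    for (b in seq_along(tun$blob_x)) {
      r <- r + tun$peak * exp(-0.5 * (((x - tun$blob_x[b])^2 +
                                        (y - tun$blob_y[b])^2) /
                                       tun$blob_sigma[b]^2))
    }
  }
  if (!is.null(tun$hd_mu)) {
    hdf <- exp(tun$hd_kappa * (cos(hd - tun$hd_mu) - 1))
    if (tun$class == "head_direction") r <- r + tun$peak * hdf
    else r <- tun$base + (r - tun$base) * hdf
  }
  r
}

## ---- RUN epoch -------------------------------------------------------------

#' Simulate a RUN epoch on the Z-track
#'
#' Back-and-forth laps at 10--40 cm/s with brief pauses at the ends and
#' corners; spikes are inhomogeneous Poisson with rate equal to the spatial
#' tuning times (1 + m cos(theta_phase - phase_pref)) for theta-locked cells;
#' the LFP is an 8 Hz theta sinusoid plus pink noise on two CA1 channels (the
#' first with the stronger theta-to-delta ratio) and is phase-aligned with
#' the spiking modulation.
#'
#' @param params a \code{\link{sim_params}} list.
#' @param seed integer seed.
#' @param t0 epoch start time (s).
#' @param truth cell tuning list from the internal generator; built from
#'   (params, seed) when NULL.
#' @param geom a \code{\link{track_geometry}}.
#' @return A list with \code{position} (data.frame at 50 Hz), \code{spikes}
#'   (named list), \code{lfp} (list of channels) and \code{truth}.
#' @export
simulate_run_epoch <- function(params, seed, t0 = 0, truth = NULL,
                               geom = track_geometry()) {
  if (params$run_s <= 0) stop("zero-duration RUN epoch")
  if (is.null(truth)) truth <- make_cell_truth(params, geom, child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  fs <- 50
  n <- round(params$run_s * fs)
  dt <- 1 / fs
  # scripted laps: stops at corners and ends, cruise speed per leg
  stops <- c(0, geom$corners_cm, geom$total_cm)
  lin <- numeric(n)
  pos_now <- 0; dirn <- 1; i <- 1
  while (i <= n) {
    nxt <- if (dirn > 0) stops[which(stops > pos_now + 1e-6)[1]] else
      rev(stops[stops < pos_now - 1e-6])[1]
    if (is.na(nxt)) { dirn <- -dirn; next }
    v <- stats::runif(1, params$run_speed_range[1], params$run_speed_range[2])
    n_move <- max(1L, ceiling(abs(nxt - pos_now) / (v * dt)))
    seg <- seq(pos_now, nxt, length.out = n_move + 1)[-1]
    take <- seq_len(min(length(seg), n - i + 1))
    lin[i - 1 + take] <- seg[take]
    i <- i + length(take)
    pos_now <- nxt
    if (i > n) break
    n_pause <- round(stats::runif(1, params$pause_range_s[1],
                                  params$pause_range_s[2]) * fs)
    take <- seq_len(min(n_pause, n - i + 1))
    if (length(take)) lin[i - 1 + take] <- pos_now
    i <- i + length(take)
    if (nxt %in% c(0, geom$total_cm)) dirn <- -dirn
  }
  tt <- t0 + (seq_len(n) - 1) * dt
  xy <- lin_to_xy(lin, geom)
  # heading from motion direction along the skeleton (plus jitter)
  dlin <- c(diff(lin), 0)
  seg_idx <- pmin(pmax(findInterval(lin, c(geom$seg_start, Inf)), 1L), 3L)
  v <- geom$vertices
  seg_vec <- rbind(v[2, ] - v[1, ], v[3, ] - v[2, ], v[4, ] - v[3, ])
  ang <- atan2(seg_vec[seg_idx, 2], seg_vec[seg_idx, 1])
  ang[dlin < 0] <- ang[dlin < 0] + pi
  hd <- (ang + stats::rnorm(n, 0, 0.15)) %% (2 * pi)
  position <- data.frame(time_s = tt, x_cm = xy[, 1], y_cm = xy[, 2],
                         hd_rad = hd)
  # spikes on a finer grid so 8 Hz modulation is well resolved
  dts <- 0.002
  ts <- seq(t0, t0 + params$run_s - dts, by = dts)
  lin_f <- stats::approx(tt, lin, xout = ts, rule = 2)$y
  phase <- (2 * pi * params$theta_hz * (ts - t0)) %% (2 * pi)
  spd <- c(abs(dlin) / dt, 0)[pmin(findInterval(ts, tt), n)]
  spikes <- list()
  for (cell in truth) {
    base <- if (cell$region == "CA1") params$ca1_track_base_hz else 0.05
    r <- track_rate(cell, lin_f, base)
    if (cell$theta_depth > 0)
      r <- r * (1 + cell$theta_depth * cos(phase - cell$phase_pref))
    spikes[[cell$cell_id]] <- sim_inhom_poisson(r, dts, t0)
  }
  lfp <- make_theta_lfp(params, t0, params$run_s, fs_lfp = 250)
  list(position = position, spikes = spikes, lfp = lfp, truth = truth)
}

make_theta_lfp <- function(params, t0, dur_s, fs_lfp = 250) {
  nl <- round(dur_s * fs_lfp)
  tl <- (seq_len(nl) - 1) / fs_lfp
  pink <- function(n) {
    w <- stats::rnorm(n)
    f <- stats::fft(w)
    fr <- c(1, seq_len(n - 1))
    fr <- pmin(fr, n - fr + 1)
    Re(stats::fft(f / sqrt(fr), inverse = TRUE)) / n
  }
  mk <- function(id, th_amp, delta_amp) {
    s <- th_amp * cos(2 * pi * params$theta_hz * tl) +
      delta_amp * cos(2 * pi * 3 * tl + 1) + 8 * pink(nl)
    list(channel_id = id, region = "CA1", rate_hz = fs_lfp,
         start_s = t0, samples = s)
  }
  list(mk("ca1_lfp_1", 40, 5), mk("ca1_lfp_2", 10, 25))
}

## ---- REST epoch ------------------------------------------------------------

#' Simulate a REST epoch with planted replay events
#'
#' Baseline Poisson spiking plus planted time-compressed trajectory events.
#' During each event every CA1 cell fires as an inhomogeneous Poisson process
#' with rate \code{replay_gain} times its track tuning evaluated at
#' x(t) = V* t + c*.  Under \code{dmec_coordination = "coordinated"},
#' theta-locked dMEC cells do the same with their own tuning, spike times
#' shifted by \code{dmec_lag_ms}; all other dMEC cells fire at an elevated
#' but trajectory-agnostic rate during events (matched in expected count).
#' With \code{structured = FALSE} (the pre-task rest), bursts carry no
#' trajectory and dMEC activity stays at baseline.
#'
#' @param params a \code{\link{sim_params}} list.
#' @param seed integer seed.
#' @param t0 epoch start (s).
#' @param dur_s epoch duration; default \code{params$rest_s}.
#' @param truth cell tuning list (built from params/seed when NULL).
#' @param geom track geometry.
#' @param structured plant coherent trajectories (TRUE) or structureless
#'   multi-unit bursts (FALSE).
#' @return A list with \code{spikes} and \code{events} (data.frame with
#'   start_s, end_s, v_star_m_s, c_star_m, direction).
#' @export
simulate_rest_epoch <- function(params, seed, t0 = 0, dur_s = params$rest_s,
                                truth = NULL, geom = track_geometry(),
                                structured = TRUE) {
  if (dur_s <= 0) stop("zero-duration REST epoch")
  if (is.null(truth)) truth <- make_cell_truth(params, geom, child_seed(seed, 1))
  set.seed(child_seed(seed, 3))
  total_m <- geom$total_cm / 100
  n_ev <- stats::rpois(1, params$event_rate_hz * dur_s)
  events <- NULL
  if (n_ev > 0) {
    starts <- sort(stats::runif(n_ev, 0.5, dur_s - 0.5))
    durs <- stats::runif(n_ev, params$event_dur_range_s[1],
                         params$event_dur_range_s[2])
    keep <- c(TRUE, diff(starts) > 0.5)  # non-overlapping, >=0.3 s apart
    starts <- starts[keep]; durs <- durs[keep]
    n_ev <- length(starts)
    vs <- sample(params$event_speeds_m_s, n_ev, replace = TRUE)
    c_star <- numeric(n_ev)
    for (i in seq_len(n_ev)) {
      span <- vs[i] * durs[i]
      lo <- max(0, -span); hi <- min(total_m, total_m - span)
      if (hi <= lo) stop("planted trajectory cannot fit on the track")
      c_star[i] <- stats::runif(1, lo, hi)
    }
    events <- data.frame(start_s = t0 + starts, end_s = t0 + starts + durs,
                         v_star_m_s = if (structured) vs else NA_real_,
                         c_star_m = if (structured) c_star else NA_real_,
                         direction = if (structured)
                           ifelse(vs > 0, "forward", "reverse") else NA_character_)
  } else {
    events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         v_star_m_s = numeric(0), c_star_m = numeric(0),
                         direction = character(0))
  }
  lag_s <- params$dmec_lag_ms / 1000
  # common event-elevation rate for trajectory-agnostic dMEC cells: a shared
  # population-level rate, so cell identity carries no information that a
  # cell-ID shuffle could detect
  dmec_cells <- Filter(function(x) x$region == "dMEC", truth)
  pop_mean_tun <- if (length(dmec_cells))
    mean(vapply(dmec_cells, function(cl)
      mean(track_rate(cl, seq(0, geom$total_cm, by = 1))), 0)) else 0
  spikes <- list()
  for (cell in truth) {
    base <- if (cell$region == "CA1") params$ca1_rest_hz else params$dmec_rest_hz
    st <- sim_inhom_poisson(rep(base, round(dur_s / 0.01)), 0.01, t0)
    coord <- cell$region == "dMEC" && structured &&
      params$dmec_coordination == "coordinated" && isTRUE(cell$theta_locked)
    mean_tun <- mean(track_rate(cell, seq(0, geom$total_cm, by = 1)))
    for (i in seq_len(nrow(events))) {
      dur <- events$end_s[i] - events$start_s[i]
      dte <- 0.001
      tau <- seq(0, dur - dte / 2, by = dte)
      if (cell$region == "CA1") {
        if (structured) {
          x_cm <- (events$c_star_m[i] + events$v_star_m_s[i] * tau) * 100
          r <- params$replay_gain * track_rate(cell, x_cm)
        } else {
          r <- rep(params$replay_gain * mean_tun, length(tau))
        }
        st <- c(st, sim_inhom_poisson(r, dte, events$start_s[i]))
      } else if (structured) {
        if (coord) {
          x_cm <- (events$c_star_m[i] + events$v_star_m_s[i] * tau) * 100
          r <- params$dmec_event_gain * track_rate(cell, x_cm)
          st <- c(st, sim_inhom_poisson(r, dte, events$start_s[i]) + lag_s)
        } else {
          # trajectory-agnostic elevation; scaled below the coordinated
          # cells' event drive so participation sits above chance but under
          # the coordinated group, as observed in vivo
          r <- rep(params$dmec_indep_frac * params$dmec_event_gain *
                     pop_mean_tun, length(tau))
          st <- c(st, sim_inhom_poisson(r, dte, events$start_s[i]) + lag_s)
        }
      }
    }
    st <- sort(st)
    spikes[[cell$cell_id]] <- st[st >= t0 & st < t0 + dur_s]
  }
  list(spikes = spikes, events = events, truth = truth)
}

## ---- open field ------------------------------------------------------------

#' Simulate an open-field foraging epoch
#'
#' Smoothed random walk in a square arena with reflecting walls; heading is
#' the direction of motion.  Spikes follow each cell's open-field tuning
#' (grid: thresholded sum of three cosine plane waves; head direction: von
#' Mises in heading; border: exponential fall-off from one wall; other
#' spatial: Gaussian blobs).
#'
#' @param params,seed,t0,truth,geom as in \code{\link{simulate_run_epoch}}.
#' @return A list with \code{position} and \code{spikes} (dMEC cells only).
#' @export
simulate_open_field <- function(params, seed, t0 = 0, truth = NULL,
                                geom = track_geometry()) {
  if (params$of_s <= 0) stop("zero-duration open-field epoch")
  if (is.null(truth)) truth <- make_cell_truth(params, geom, child_seed(seed, 1))
  set.seed(child_seed(seed, 4))
  fs <- 50; dt <- 1 / fs
  n <- round(params$of_s * fs)
  a <- params$arena_cm
  # Ornstein-Uhlenbeck velocity, reflected at walls
  vx <- numeric(n); vy <- numeric(n); x <- numeric(n); y <- numeric(n)
  x[1] <- a / 2; y[1] <- a / 2
  vx[1] <- 10; vy[1] <- 0
  for (i in 2:n) {
    vx[i] <- 0.97 * vx[i - 1] + stats::rnorm(1, 0, 3)
    vy[i] <- 0.97 * vy[i - 1] + stats::rnorm(1, 0, 3)
    x[i] <- x[i - 1] + vx[i] * dt
    y[i] <- y[i - 1] + vy[i] * dt
    if (x[i] < 0) { x[i] <- -x[i]; vx[i] <- -vx[i] }
    if (x[i] > a) { x[i] <- 2 * a - x[i]; vx[i] <- -vx[i] }
    if (y[i] < 0) { y[i] <- -y[i]; vy[i] <- -vy[i] }
    if (y[i] > a) { y[i] <- 2 * a - y[i]; vy[i] <- -vy[i] }
  }
  hd <- (atan2(vy, vx)) %% (2 * pi)
  tt <- t0 + (seq_len(n) - 1) * dt
  position <- data.frame(time_s = tt, x_cm = x, y_cm = y, hd_rad = hd)
  spikes <- list()
  for (cell in truth) {
    if (cell$region != "dMEC") next
    r <- of_rate(cell$of, x, y, hd)
    spikes[[cell$cell_id]] <- sim_inhom_poisson(r, dt, t0)
  }
  list(position = position, spikes = spikes, truth = truth)
}

## ---- full session ----------------------------------------------------------

#' Assemble a full synthetic session with ground truth
#'
#' Concatenates PRE_REST (structureless bursts, the preplay null), RUN, REST
#' (planted trajectory events) and OPEN_FIELD, and returns the paired ground
#' truth.  Identical (params, seed) give a bit-identical session.
#'
#' @param params a \code{\link{sim_params}} list.
#' @param seed integer seed.
#' @param config analysis configuration stored in the session.
#' @return A list with \code{session} (a \code{"replay_session"}) and
#'   \code{truth} (list with \code{cells} tuning/ground-truth descriptors,
#'   \code{events} planted REST events, \code{pre_events} PRE_REST bursts).
#' @export
assemble_session <- function(params, seed, config = default_config()) {
  geom <- track_geometry()
  truth <- make_cell_truth(params, geom, child_seed(seed, 1))
  t_pre <- 0
  t_run <- t_pre + params$pre_rest_s
  t_rest <- t_run + params$run_s
  t_of <- t_rest + params$rest_s
  t_end <- t_of + params$of_s
  pre <- simulate_rest_epoch(params, child_seed(seed, 11), t0 = t_pre,
                             dur_s = params$pre_rest_s, truth = truth,
                             geom = geom, structured = FALSE)
  run <- simulate_run_epoch(params, child_seed(seed, 12), t0 = t_run,
                            truth = truth, geom = geom)
  rest <- simulate_rest_epoch(params, child_seed(seed, 13), t0 = t_rest,
                              dur_s = params$rest_s, truth = truth,
                              geom = geom, structured = TRUE)
  of <- simulate_open_field(params, child_seed(seed, 14), t0 = t_of,
                            truth = truth, geom = geom)
  set.seed(child_seed(seed, 15))
  still <- function(t0, dur) {
    n <- round(dur * 50)
    tt <- t0 + (seq_len(n) - 1) / 50
    data.frame(time_s = tt, x_cm = -60 + stats::rnorm(n, 0, 0.05),
               y_cm = -60 + stats::rnorm(n, 0, 0.05),
               hd_rad = stats::runif(n, 0, 2 * pi))
  }
  ids <- names(truth)
  spikes <- lapply(ids, function(id) {
    sort(c(pre$spikes[[id]] %||% numeric(0), run$spikes[[id]] %||% numeric(0),
           rest$spikes[[id]] %||% numeric(0), of$spikes[[id]] %||% numeric(0)))
  })
  names(spikes) <- ids
  cells <- data.frame(
    cell_id = ids,
    region = vapply(truth, `[[`, "", "region"),
    animal_id = params$animal_id,
    day = params$session_day,
    stringsAsFactors = FALSE
  )
  epochs <- data.frame(
    label = c("PRE_REST", "RUN", "REST", "OPEN_FIELD"),
    start_s = c(t_pre, t_run, t_rest, t_of),
    end_s = c(t_run, t_rest, t_of, t_end))
  session <- new_session(
    epochs, cells, spikes,
    position = list(PRE_REST = still(t_pre, params$pre_rest_s),
                    RUN = run$position,
                    REST = still(t_rest, params$rest_s),
                    OPEN_FIELD = of$position),
    lfp = run$lfp, geometry = geom, config = config)
  list(session = session,
       truth = list(cells = truth, events = rest$events,
                    pre_events = pre$events, params = params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
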