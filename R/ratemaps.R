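#' Gaussian smoothing with edge renormalization
#'
#' Convolves a vector with a Gaussian kernel truncated at +/- 3 sigma and
#' renormalizes by the kernel mass that falls inside the vector, so values
#' near the edges are not deflated.
#'
#' @param x numeric vector.
#' @param sigma_bins kernel sigma in bins.
#' @return Smoothed vector of the same length.
#' @export
gauss_smooth_renorm <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- ceiling(3 * sigma_bins)
  k <- stats::dnorm(-half:half, sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  w <- stats::filter(wp, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(sm / w)
}

#' Linearize a position trace onto the Z-track
#'
#' Each sample is projected onto the 600 cm piecewise-linear skeleton.  Run
#' direction (outbound = increasing linearized coordinate) is labeled from
#' the sign of the smoothed along-track velocity; samples during
#' turn-arounds/pauses carry no direction.  Samples more than 30 cm off the
#' track are flagged (not fatal), and samples inside excluded zones or slower
#' than the running-speed threshold are flagged for exclusion from ratemaps.
#'
#' @param trace position data.frame (time_s, x_cm, y_cm, with derived
#'   speed_cm_s; see \code{\link{new_session}}).
#' @param geom a \code{\link{track_geometry}}.
#' @param config analysis configuration (speed threshold).
#' @return data.frame with time_s, lin_cm, direction ("outbound",
#'   "inbound" or NA), speed_cm_s, off_track, in_excluded_zone and
#'   \code{included} (TRUE for samples usable in ratemaps).
#' @export
linearize_position <- function(trace, geom = track_geometry(),
                               config = default_config()) {
  pr <- xy_to_lin(trace$x_cm, trace$y_cm, geom)
  n <- nrow(trace)
  off <- pr$dist_cm > 30
  spd <- if (!is.null(trace$speed_cm_s)) trace$speed_cm_s
         else add_derived_speed(trace)$speed_cm_s
  # direction from smoothed along-track velocity (~0.5 s window)
  direction <- rep(NA_character_, n)
  if (n >= 3) {
    dt <- stats::median(diff(trace$time_s))
    win <- max(3L, round(0.5 / dt))
    if (win %% 2 == 0) win <- win + 1L
    sm <- stats::filter(pr$lin_cm, rep(1 / win, win), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm)] <- pr$lin_cm[is.na(sm)]
    vlin <- c(0, diff(sm)) / dt
    direction[vlin > 1] <- "outbound"
    direction[vlin < -1] <- "inbound"
  }
  zone <- in_excluded_zone(pr$lin_cm, geom)
  included <- !off & !zone & spd >= config$speed_thresh_cm_s &
    !is.na(direction)
  data.frame(time_s = trace$time_s, lin_cm = pr$lin_cm,
             direction = direction, speed_cm_s = spd, off_track = off,
             in_excluded_zone = zone, included = included,
             stringsAsFactors = FALSE)
}

#' Directional linearized ratemaps
#'
#' Dwell time and spikes are binned into 2 cm bins separately for outbound
#' and inbound runs, each smoothed with a Gaussian kernel (sigma = 5 bins),
#' and the rate is the ratio of the smoothed maps.  Excluded bins (track
#' ends and corners) carry no spikes or dwell.  Spikes inherit the position,
#' direction and inclusion flag of their enclosing position sample.
#'
#' @param spikes named list of spike-time vectors.
#' @param lintrace output of \code{\link{linearize_position}}.
#' @param geom a \code{\link{track_geometry}}.
#' @param config analysis configuration.
#' @return A list per cell, each with elements \code{outbound} and
#'   \code{inbound}; each direction is a list with \code{rate} (Hz per bin),
#'   \code{occupancy_s} (raw dwell), \code{counts} (raw spike counts) and
#'   \code{excluded} (per-bin mask).  Class \code{"directional_ratemaps"}.
#' @export
compute_ratemaps <- function(spikes, lintrace, geom = track_geometry(),
                             config = default_config()) {
  nb <- geom$n_bins
  excl <- excluded_bins(geom)
  use <- lintrace$included
  if (!any(use)) stop("no valid position samples for ratemaps")
  dt <- stats::median(diff(lintrace$time_s))
  bin_of <- function(lin) pmin(pmax(floor(lin / geom$bin_cm), 0), nb - 1) + 1
  res <- list()
  t0 <- lintrace$time_s[1]
  t1 <- lintrace$time_s[nrow(lintrace)] + dt
  for (dir in c("outbound", "inbound")) {
    seldir <- use & !is.na(lintrace$direction) & lintrace$direction == dir
    occ <- numeric(nb)
    if (any(seldir)) {
      tb <- tabulate(bin_of(lintrace$lin_cm[seldir]), nbins = nb)
      occ <- tb * dt
    }
    occ[excl] <- 0
    res[[dir]] <- list(occ = occ, sel = seldir)
  }
  if (sum(res$outbound$occ) + sum(res$inbound$occ) == 0)
    stop("zero total dwell on track")
  maps <- list()
  for (id in names(spikes)) {
    st <- spikes[[id]]
    st <- st[st >= t0 & st < t1]
    idx <- findInterval(st, lintrace$time_s)
    idx <- idx[idx >= 1]
    m <- list()
    for (dir in c("outbound", "inbound")) {
      seldir <- res[[dir]]$sel
      occ <- res[[dir]]$occ
      sidx <- idx[seldir[idx]]
      counts <- tabulate(bin_of(lintrace$lin_cm[sidx]), nbins = nb)
      counts[excl] <- 0
      sm_c <- gauss_smooth_renorm(counts, config$ratemap_sigma_bins)
      sm_o <- gauss_smooth_renorm(occ, config$ratemap_sigma_bins)
      rate <- ifelse(sm_o > 0, sm_c / sm_o, 0)
      rate[excl] <- 0
      m[[dir]] <- list(rate = rate, occupancy_s = occ, counts = counts,
                       excluded = excl)
    }
    maps[[id]] <- m
  }
  structure(maps, class = "directional_ratemaps", bin_cm = geom$bin_cm)
}

#' Mean rate of a cell on the included track samples
#'
#' Total included spikes divided by total included dwell time.
#' @param spikes spike-time vector for one cell.
#' @param lintrace output of \code{\link{linearize_position}}.
#' @return Rate in Hz.
#' @export
track_mean_rate <- function(spikes, lintrace) {
  dt <- stats::median(diff(lintrace$time_s))
  use <- lintrace$included
  tot_t <- sum(use) * dt
  if (tot_t == 0) return(NA_real_)
  # only spikes within the trace's own epoch; findInterval would otherwise
  # pile later-epoch spikes onto the last sample
  n <- nrow(lintrace)
  spikes <- spikes[spikes >= lintrace$time_s[1] &
                     spikes < lintrace$time_s[n] + dt]
  idx <- findInterval(spikes, lintrace$time_s)
  sum(use[idx[idx >= 1]]) / tot_t
}

#' Place fields and place-cell classification
#'
#' Fields are maximal runs of bins whose rate exceeds the cell's track mean
#' rate; a cell is a place cell if either direction contains a field of at
#' least 20 contiguous bins and the peak rate exceeds 1 Hz.
#'
#' @param cell_maps one cell's entry of \code{\link{compute_ratemaps}}
#'   (list with outbound/inbound).
#' @param mean_rate_hz the cell's mean rate on the track.
#' @param config analysis configuration.
#' @return A list of class \code{"place_field_set"}: \code{fields}
#'   (data.frame direction/start_bin/end_bin/peak_hz/length_cm, 1-based
#'   inclusive bins), \code{is_place_cell}, \code{peak_hz}.
#' @export
classify_place_cell <- function(cell_maps, mean_rate_hz,
                                config = default_config()) {
  fields <- NULL
  peak <- 0
  bin_cm <- 2
  for (dir in c("outbound", "inbound")) {
    rate <- cell_maps[[dir]]$rate
    peak <- max(peak, rate)
    above <- rate > mean_rate_hz
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      fields <- rbind(fields, data.frame(
        direction = dir, start_bin = starts[k], end_bin = ends[k],
        peak_hz = max(rate[starts[k]:ends[k]]),
        length_cm = r$lengths[k] * bin_cm, stringsAsFactors = FALSE))
    }
  }
  if (is.null(fields))
    fields <- data.frame(direction = character(0), start_bin = integer(0),
                         end_bin = integer(0), peak_hz = numeric(0),
                         length_cm = numeric(0))
  long_enough <- any(fields$end_bin - fields$start_bin + 1 >=
                       config$place_field_min_bins)
  structure(list(fields = fields,
                 is_place_cell = long_enough && peak > config$place_field_peak_hz,
                 peak_hz = peak),
            class = "place_field_set")
}

#' Skaggs spatial information (bits per spike)
#'
#' I = sum_i p_i (r_i / rbar) log2(r_i / rbar) over occupied bins, where p_i
#' is the occupancy share and rbar the occupancy-weighted mean rate.  Bins
#' with zero rate contribute zero.  Works for linear and 2-D maps alike
#' (both are passed as vectors of bin rates and occupancies).
#'
#' @param rate per-bin firing rate (Hz).
#' @param occupancy per-bin dwell time (s).
#' @return Information in bits/spike.
#' @export
skaggs_information <- function(rate, occupancy) {
  sel <- occupancy > 0
  if (!any(sel)) stop("no occupied bins")
  p <- occupancy[sel] / sum(occupancy[sel])
  r <- rate[sel]
  rbar <- sum(p * r)
  if (rbar <= 0) stop("zero mean rate: Skaggs information undefined")
  pos <- r > 0
  sum(p[pos] * (r[pos] / rbar) * log2(r[pos] / rbar))
}

#' Mean place-field length of a cell
#'
#' @param pfs a \code{"place_field_set"}.
#' @return Mean field length in cm (NA when the cell has no field).
#' @export
field_size <- function(pfs) {
  if (nrow(pfs$fields) == 0) return(NA_real_)
  mean(pfs$fields$length_cm)
}

#' Spatial overlap between two linearized ratemaps
#'
#' Pearson correlation over bins where both maps are positive, computed per
#' direction and averaged over the directions with at least
#' \code{min_joint_bins} jointly positive bins.
#'
#' @param maps_a,maps_b per-cell entries of \code{\link{compute_ratemaps}}.
#' @param min_joint_bins minimum jointly positive bins (3).
#' @return Mean correlation, or NA when undefined in both directions.
#' @export
ratemap_overlap <- function(maps_a, maps_b, min_joint_bins = 3) {
  rs <- c()
  for (dir in c("outbound", "inbound")) {
    ra <- maps_a[[dir]]$rate; rb <- maps_b[[dir]]$rate
    sel <- ra > 0 & rb > 0
    if (sum(sel) >= min_joint_bins && stats::sd(ra[sel]) > 0 &&
        stats::sd(rb[sel]) > 0)
      rs <- c(rs, stats::cor(ra[sel], rb[sel]))
  }
  if (!length(rs)) return(NA_real_)
  mean(rs)
}

#' Task performance: proportion of incorrect corner turns
#'
#' Errors divided by laps per session, with a one-sided Pearson test of
#' improvement (negative correlation of error proportion with experience).
#'
#' @param errors integer vector of incorrect corner turns per session.
#' @param laps integer vector of completed laps per session.
#' @param day integer vector of session days (experience index).
#' @return A list with \code{proportion_incorrect} per session and, when
#'   \code{day} has at least 3 distinct values, \code{r} and one-sided
#'   \code{p_value} for improvement with experience.
#' @export
performance_score <- function(errors, laps, day = seq_along(errors)) {
  if (any(laps < 1)) stop("each session needs at least one lap")
  prop <- errors / laps
  out <- list(proportion_incorrect = prop)
  if (length(unique(day)) >= 3 && stats::sd(prop) > 0) {
    ct <- stats::cor.test(prop, day, alternative = "less")
    out$r <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  out
}
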