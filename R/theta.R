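#' Analytic signal via the FFT
#'
#' Standard construction: zero the negative-frequency half of the spectrum,
#' double the positive half, inverse-transform.  The modulus is the amplitude
#' envelope and the argument the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length Rbar, Z = n Rbar^2 and the standard small-sample
#' p approximation
#' p = exp(sqrt(1 + 4n + 4(n^2 - (n Rbar)^2)) - (1 + 2n)),
#' which tends to exp(-Z) for large n.
#'
#' @param phases numeric vector of angles (radians).
#' @return List with \code{n}, \code{rbar}, \code{z}, \code{p_value},
#'   \code{mean_phase} (in [0, 2 pi)).
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0) return(list(n = 0L, rbar = NA_real_, z = NA_real_,
                          p_value = NA_real_, mean_phase = NA_real_))
  C <- sum(cos(phases)); S <- sum(sin(phases))
  R <- sqrt(C^2 + S^2)
  rbar <- R / n
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(n = as.integer(n), rbar = rbar, z = z, p_value = min(1, p),
       mean_phase = atan2(S, C) %% (2 * pi))
}

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase FIR (Hamming window, order = \code{cycles} periods of the low
#' band edge) applied by centered convolution, which is exactly zero-phase
#' for a symmetric kernel.  Edges where the kernel does not fully overlap are
#' returned as NA.
#'
#' @param x signal vector.
#' @param band c(low, high) in Hz.
#' @param fs sampling rate in Hz.
#' @param cycles filter length in periods of the low edge (3).
#' @return Filtered vector with NA edges.
#' @export
fir_bandpass <- function(x, band, fs, cycles = 3) {
  h <- fir_design(band, fs, cycles)
  half <- (length(h) - 1) / 2
  y <- fft_conv_valid(x, h)
  c(rep(NA_real_, half), y, rep(NA_real_, half))
}

# cache FIR designs: the same (band, fs, cycles) is reused thousands of
# times inside the permutation tests
.fir_cache <- new.env(parent = emptyenv())

fir_design <- function(band, fs, cycles) {
  ord <- round(cycles / band[1] * fs)
  if (ord %% 2 == 1) ord <- ord + 1  # odd tap count -> symmetric center
  key <- paste(band[1], band[2], fs, ord, sep = "_")
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    h <- as.numeric(signal::fir1(ord, band / (fs / 2), type = "pass"))
    .fir_cache[[key]] <- h
  }
  h
}

# 'valid' part of the convolution of x with an odd-length symmetric kernel,
# via FFT at a fast composite length
fft_conv_valid <- function(x, h) {
  n <- length(x); m <- length(h)
  L <- stats::nextn(n + m - 1, c(2, 3))
  fx <- stats::fft(c(x, rep(0, L - n)))
  fh <- stats::fft(c(h, rep(0, L - m)))
  full <- Re(stats::fft(fx * fh, inverse = TRUE)) / L
  full[m:n]
}

# Signed spike-time differences within +/- max_lag_s, binned at bin_s.
# Returns counts over lags -L..L (2*nlag+1 bins); the zero-lag bin excludes
# self-pairs and is replaced by the mean of its +/-5 ms neighbors so the
# delta spike cannot dominate the broadband envelope.
spike_autocorrelogram <- function(st, max_lag_s, bin_s = 0.001) {
  nlag <- round(max_lag_s / bin_s)
  n <- length(st)
  pos <- integer(0)
  k <- 1
  while (k < n) {
    d <- st[(k + 1):n] - st[1:(n - k)]
    d <- d[d <= max_lag_s + bin_s / 2]
    if (!length(d)) break
    pos <- c(pos, as.integer(round(d / bin_s)))
    k <- k + 1
  }
  pos <- pos[pos <= nlag]
  counts <- tabulate(pos + 1L, nbins = nlag + 1L)  # lags 0..nlag
  ac <- c(rev(counts[-1]), counts)
  ctr <- nlag + 1L
  nb <- c((ctr - 5):(ctr - 1), (ctr + 1):(ctr + 5))
  ac[ctr] <- mean(ac[nb])
  ac
}

#' Theta modulation score of a spike train
#'
#' The spike-train autocorrelogram (1 ms bins) is smoothed with a 20 ms
#' Gaussian kernel, band-passed in the theta (5--12 Hz) and broad
#' (20--125 Hz) bands, and each band's amplitude envelope extracted with the
#' analytic-signal transform; the score is the ratio of the mean theta to
#' mean broadband envelope within the +/- 1 s lag window.  Lags beyond the
#' envelope window plus the filter supports cannot influence the score, so
#' the autocorrelogram is only materialized over that range.
#'
#' @param spike_times spike times (s) within the analysis window.
#' @param config analysis configuration.
#' @return The score (dimensionless, > 0), or NA when the train has fewer
#'   than \code{config$min_theta_spikes} spikes (untested, not "no").
#' @export
theta_modulation_score <- function(spike_times, config = default_config()) {
  if (length(spike_times) < config$min_theta_spikes) return(NA_real_)
  fs <- 1000
  envw <- config$env_halfwidth_s
  nseg <- 2048               # analytic-signal segment (power of two, > 2*envw*fs)
  margin <- 3 * config$acorr_smooth_s + (3 / config$theta_band[1]) / 2 + 0.01
  ac <- spike_autocorrelogram(sort(spike_times),
                              nseg / 2 / fs + margin)
  ac <- gauss_smooth_renorm(ac, config$acorr_smooth_s * fs)
  th <- fir_bandpass(ac, config$theta_band, fs)
  br <- fir_bandpass(ac, config$broad_band, fs)
  ctr <- (length(ac) + 1) / 2
  idx_seg <- (ctr - nseg / 2):(ctr + nseg / 2 - 1)
  env_th <- Mod(analytic_signal(th[idx_seg]))
  env_br <- Mod(analytic_signal(br[idx_seg]))
  idx_env <- (nseg / 2 + 1 - envw * fs):(nseg / 2 + 1 + envw * fs)
  mean(env_th[idx_env]) / mean(env_br[idx_env])
}

#' Permutation test for theta modulation
#'
#' The null redraws the same number of spike times uniformly within the
#' analysis window (a full permutation of spike times, not a jitter) and
#' recomputes the score; a cell is theta-modulated when its score is at or
#' above the stated percentile (97.5 by default, 99 as the stringent
#' alternative) of its own null distribution.
#'
#' @param spike_times spike times (s).
#' @param window c(start, end) of the analysis window (s); spikes outside are
#'   dropped and null spikes are drawn within it.
#' @param n_shuffles permutations (100).
#' @param percentile shuffle percentile (97.5 or 99).
#' @param seed integer seed.
#' @param config analysis configuration.
#' @return List of class \code{"theta_mod_result"}: \code{score},
#'   \code{shuffle_scores}, \code{threshold}, \code{percentile},
#'   \code{is_theta_modulated} ("yes"/"no"/"untested").
#' @export
theta_modulation_test <- function(spike_times, window, n_shuffles = 100,
                                  percentile = 97.5, seed = 1,
                                  config = default_config()) {
  st <- spikes_in_window(sort(spike_times), window)
  score <- theta_modulation_score(st, config)
  if (is.na(score)) {
    return(structure(list(score = NA_real_, shuffle_scores = numeric(0),
                          threshold = NA_real_, percentile = percentile,
                          is_theta_modulated = "untested"),
                     class = "theta_mod_result"))
  }
  set.seed(seed)
  shuf <- vapply(seq_len(n_shuffles), function(i) {
    theta_modulation_score(sort(stats::runif(length(st), window[1], window[2])),
                           config)
  }, 0)
  thr <- stats::quantile(shuf, percentile / 100, names = FALSE)
  structure(list(score = score, shuffle_scores = shuf, threshold = thr,
                 percentile = percentile,
                 is_theta_modulated = if (score >= thr) "yes" else "no"),
            class = "theta_mod_result")
}

#' Select the CA1 channel with the strongest theta
#'
#' Welch-style averaged periodogram per channel; the channel with the largest
#' theta (5--12 Hz) to delta (2--4 Hz) power ratio wins, ties going to the
#' lowest channel id.
#'
#' @param lfp list of LFP channels (see \code{\link{new_session}}).
#' @param config analysis configuration.
#' @return The selected channel id (character).
#' @export
select_theta_channel <- function(lfp, config = default_config()) {
  ca1 <- Filter(function(ch) ch$region == "CA1", lfp)
  if (!length(ca1)) stop("no CA1 LFP channel")
  ids <- vapply(ca1, `[[`, "", "channel_id")
  ord <- order(ids)
  ratios <- vapply(ca1[ord], function(ch) {
    n <- length(ch$samples)
    seg <- min(n, 4 * ch$rate_hz)
    nseg <- max(1L, floor(n / seg))
    pows <- sapply(seq_len(nseg), function(k) {
      x <- ch$samples[((k - 1) * seg + 1):(k * seg)]
      x <- (x - mean(x)) * signal::hamming(length(x))
      p <- Mod(stats::fft(x))^2
      freq <- (seq_along(p) - 1) * ch$rate_hz / length(p)
      c(theta = mean(p[freq >= config$theta_band[1] & freq <= config$theta_band[2]]),
        delta = mean(p[freq >= config$delta_band[1] & freq <= config$delta_band[2]]))
    })
    m <- rowMeans(matrix(pows, nrow = 2))
    m[1] / m[2]
  }, 0)
  ids[ord][which.max(ratios)]
}

#' Theta phase of each spike and Rayleigh phase locking
#'
#' The LFP channel is filtered in the theta band (FIR, Hamming window,
#' zero-phase), Hilbert-transformed, and the instantaneous phase interpolated
#' at each spike time (via the real and imaginary parts of the analytic
#' signal).  Only spikes emitted at running speed above 3 cm/s enter the
#' Rayleigh test.
#'
#' @param spike_times spike times (s).
#' @param channel one LFP channel (list with samples, rate_hz, start_s).
#' @param speed data.frame with \code{time_s} and \code{speed_cm_s} covering
#'   the epoch (NULL to skip the speed filter).
#' @param config analysis configuration.
#' @return List of class \code{"phase_lock_result"}: \code{phases} (radians,
#'   [0, 2 pi)), \code{n}, \code{rbar}, \code{rayleigh_p}, \code{mean_phase},
#'   \code{low_n} (TRUE when fewer than 10 qualifying spikes).
#' @export
spike_phases <- function(spike_times, channel, speed = NULL,
                         config = default_config()) {
  fs <- channel$rate_hz
  t0 <- channel$start_s %||% 0
  th <- fir_bandpass(channel$samples, config$theta_band, fs)
  an <- analytic_signal(ifelse(is.na(th), 0, th))
  tl <- t0 + (seq_along(th) - 1) / fs
  ok <- !is.na(th)
  st <- spike_times[spike_times >= min(tl[ok]) & spike_times <= max(tl[ok])]
  if (!is.null(speed)) {
    sp <- stats::approx(speed$time_s, speed$speed_cm_s, xout = st, rule = 2)$y
    st <- st[sp > config$speed_thresh_cm_s]
  }
  re <- stats::approx(tl, Re(an), xout = st)$y
  im <- stats::approx(tl, Im(an), xout = st)$y
  phases <- atan2(im, re) %% (2 * pi)
  phases <- phases[!is.na(phases)]
  rt <- rayleigh_test(phases)
  structure(list(phases = phases, n = rt$n, rbar = rt$rbar,
                 rayleigh_p = rt$p_value, mean_phase = rt$mean_phase,
                 low_n = rt$n < 10),
            class = "phase_lock_result")
}

#' Phase locking by learning period
#'
#' Groups cells into learning periods by recording day (early = days 1--2,
#' mid = 3--4, late = 5--6 by default), reports the mean Rayleigh value per
#' period (lower = stronger locking) and bootstrapped pairwise difference
#' tests with Bonferroni correction across period pairs.
#'
#' @param rayleigh_p per-cell Rayleigh p values.
#' @param day per-cell recording day.
#' @param periods named list of day vectors.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @param alpha family-wise alpha for the Bonferroni decisions.
#' @return List with \code{means} (per period), \code{n} (cells per period)
#'   and \code{comparisons} (data.frame of pairwise bootstrap p values and
#'   Bonferroni decisions).  Periods with no cells are dropped; with fewer
#'   than two populated periods no comparisons are returned.
#' @export
phase_locking_by_period <- function(rayleigh_p, day,
                                    periods = list(early = 1:2, mid = 3:4,
                                                   late = 5:6),
                                    n_boot = 10000, seed = 1, alpha = 0.05) {
  groups <- lapply(periods, function(d) rayleigh_p[day %in% d & !is.na(rayleigh_p)])
  groups <- groups[lengths(groups) > 0]
  if (!length(groups)) stop("no cells in any learning period")
  means <- vapply(groups, mean, 0)
  out <- list(means = means, n = lengths(groups))
  if (length(groups) >= 2) {
    prs <- utils::combn(names(groups), 2)
    cmp <- NULL
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      bd <- bootstrap_difference(groups[[a]], groups[[b]], n_boot = n_boot,
                                 seed = child_seed(seed, j))
      cmp <- rbind(cmp, data.frame(period_a = a, period_b = b,
                                   mean_diff = means[[a]] - means[[b]],
                                   p_value = bd$p_two_sided,
                                   stringsAsFactors = FALSE))
    }
    cmp$reject <- bonferroni_decisions(cmp$p_value, m = nrow(cmp), alpha = alpha)
    out$comparisons <- cmp
  }
  out
}
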