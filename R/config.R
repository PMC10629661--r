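#' Default analysis configuration
#'
#' All numeric constants of the pipeline in one list.  Values marked
#' \dQuote{convention} below are the published analysis constants this package
#' follows; the few values the source methods leave open are package design
#' decisions and are documented in the methods vignette.
#'
#' @param ... named overrides of any default field.
#'
#' @return A list of class \code{"analysis_config"} with fields:
#' \describe{
#'   \item{theta_band, broad_band, delta_band}{band edges in Hz
#'     (5--12, 20--125, 2--4).}
#'   \item{speed_thresh_cm_s}{running-speed inclusion threshold for ratemaps
#'     and phase locking (3 cm/s).}
#'   \item{awake_speed_cm_s}{immobility threshold for awake replay events
#'     (1 cm/s; 3 cm/s is the standard alternate).}
#'   \item{mua_bin_s, mua_sigma_s, mua_sd_thresh}{multi-unit activity binning
#'     (1 ms), Gaussian smoothing sigma (20 ms) and detection threshold
#'     (mean + 3 SD).}
#'   \item{min_event_s}{minimum candidate event duration (40 ms).}
#'   \item{min_cells_frac, min_cells_abs}{participation filter:
#'     at least max(15\% of the CA1 population, 5) cells.}
#'   \item{decode_bin_s}{Bayesian decoding window (10 ms).}
#'   \item{corridor_d_m}{half-width d of the line-fit corridor (0.30 m).}
#'   \item{v_max, v_step, v_excl}{trajectory-velocity search grid:
#'     |V| <= 50 m/s in 0.5 m/s steps, excluding (-2, 2).}
#'   \item{c_min, c_max, c_step}{intercept grid: -15 to 21 m in 0.01 m steps.}
#'   \item{n_shuffles_event}{ratemap-rotation shuffles per event (100).}
#'   \item{n_boot}{bootstrap iterations for AUC / group comparisons (10000).}
#'   \item{theta_percentile}{shuffle percentile for theta modulation
#'     (97.5; 99 is the stringent alternate).}
#'   \item{replay_p}{per-direction significance threshold for replay (0.025).}
#'   \item{dmec_rate_cap_hz}{dMEC cells with mean rate above 7 Hz excluded.}
#'   \item{ca1_interneuron_hz}{CA1 interneuron rate threshold (5 Hz; design
#'     decision, waveforms are not part of the data model).}
#'   \item{ratemap_bin_cm, ratemap_sigma_bins}{linear ratemap bin (2 cm) and
#'     Gaussian smoothing sigma (5 bins).}
#'   \item{place_field_min_bins, place_field_peak_hz}{place-cell criteria:
#'     >= 20 contiguous supra-mean bins and peak > 1 Hz.}
#'   \item{rate_floor_hz}{decoder rate floor epsilon (0.01 Hz).}
#'   \item{field_size_controls_cm}{maximum field-size control thresholds
#'     (100 and 150 cm).}
#'   \item{min_theta_spikes}{minimum spikes for a theta-modulation score (50).}
#'   \item{env_halfwidth_s}{half-width of the envelope window used by the
#'     theta modulation score (1 s).}
#'   \item{acorr_smooth_s}{autocorrelogram smoothing sigma (20 ms).}
#'   \item{kl_thresh, border_thresh, skaggs_thresh, gridness_pct}{functional
#'     classification thresholds: KL divergence > 0.10 for directionality,
#'     border score > 0.5, Skaggs information > 1 bit/spike, gridness above
#'     the 95th shuffle percentile.}
#'   \item{rng_seed}{seed from which all stochastic operations derive.}
#' }
#' @export
#' @examples
#' cfg <- default_config(rng_seed = 42)
#' cfg$corridor_d_m
default_config <- function(...) {
  cfg <- list(
    theta_band = c(5, 12),
    broad_band = c(20, 125),
    delta_band = c(2, 4),
    speed_thresh_cm_s = 3,
    awake_speed_cm_s = 1,
    mua_bin_s = 0.001,
    mua_sigma_s = 0.020,
    mua_sd_thresh = 3,
    min_event_s = 0.040,
    min_cells_frac = 0.15,
    min_cells_abs = 5,
    decode_bin_s = 0.010,
    corridor_d_m = 0.30,
    v_max = 50,
    v_step = 0.5,
    v_excl = 2,
    c_min = -15,
    c_max = 21,
    c_step = 0.01,
    n_shuffles_event = 100,
    n_boot = 10000,
    theta_percentile = 97.5,
    replay_p = 0.025,
    dmec_rate_cap_hz = 7,
    ca1_interneuron_hz = 5,
    ratemap_bin_cm = 2,
    ratemap_sigma_bins = 5,
    place_field_min_bins = 20,
    place_field_peak_hz = 1,
    rate_floor_hz = 0.01,
    field_size_controls_cm = c(100, 150),
    min_theta_spikes = 50,
    env_halfwidth_s = 1,
    acorr_smooth_s = 0.020,
    kl_thresh = 0.10,
    border_thresh = 0.5,
    skaggs_thresh = 1,
    gridness_pct = 95,
    rng_seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config> ", length(x), " fields\n", sep = "")
  invisible(x)
}

#' Derive a child seed from a base seed
#'
#' All stochastic operations take an explicit seed; pipeline stages derive
#' per-stage seeds deterministically from the single configured seed so that
#' identical (config, seed) reproduce every output bit-exactly.  Results stay
#' below 2^31 so they are always valid R integers.
#'
#' @param seed integer base seed.
#' @param k integer stage index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(k)) %% 2147483647)
}
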