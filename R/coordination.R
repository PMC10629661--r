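# spike counts in [s, e) for many intervals, with wrap-around at the epoch
# edges for intervals that overhang the window
interval_counts <- function(st, starts, ends, window = NULL) {
  st <- sort(st)
  cnt <- function(s, e) findInterval(e - 1e-12, st) - findInterval(s - 1e-12, st)
  if (is.null(window)) return(cnt(starts, ends))
  w0 <- window[1]; w1 <- window[2]
  base <- cnt(pmax(starts, w0), pmin(ends, w1))
  over <- pmax(0, ends - w1)
  base + ifelse(over > 0, cnt(rep(w0, length(over)), w0 + over), 0)
}

#' Normalized participation of a cell in candidate replay events
#'
#' The observed participation is the proportion of events in which the cell
#' fires at least one spike (or, for \code{measure = "rate"}, the mean
#' number of spikes per event).  Chance is estimated by adding an
#' independent uniform random time shift to each event (wrapping at the
#' epoch edges) and recomputing, 100 times; the normalized score is
#' observed / mean(shuffle), so 1 is chance and values above 1 indicate the
#' cell is active in more events than expected.  A cell is significantly
#' modulated when its observed value falls outside the 95\% interval of its
#' own shuffle distribution.
#'
#' @param spike_times the cell's spike times (s).
#' @param events data.frame with start_s, end_s (>= 5 events).
#' @param window c(start, end) of the epoch containing the events.
#' @param n_shuffles event-time shuffles (100).
#' @param seed integer seed.
#' @param measure "participation" or "rate".
#' @return List of class \code{"participation_result"}: \code{observed},
#'   \code{shuffle_mean}, \code{normalized}, \code{significant},
#'   \code{shuffle_values}, \code{untestable} (TRUE when the cell is silent
#'   in the epoch).
#' @export
normalized_participation <- function(spike_times, events, window,
                                     n_shuffles = 100, seed = 1,
                                     measure = c("participation", "rate")) {
  measure <- match.arg(measure)
  if (nrow(events) < 5) stop("need at least 5 events")
  st <- spikes_in_window(spike_times, window)
  res <- structure(list(observed = NA_real_, shuffle_mean = NA_real_,
                        normalized = NA_real_, significant = NA,
                        shuffle_values = numeric(0),
                        untestable = length(st) == 0, measure = measure),
                   class = "participation_result")
  if (res$untestable) return(res)
  stat <- function(starts, ends) {
    k <- interval_counts(st, starts, ends, window)
    if (measure == "participation") mean(k >= 1) else mean(k)
  }
  obs <- stat(events$start_s, events$end_s)
  set.seed(seed)
  dur <- window[2] - window[1]
  shuf <- vapply(seq_len(n_shuffles), function(i) {
    off <- stats::runif(nrow(events), 0, dur)
    s <- window[1] + (events$start_s - window[1] + off) %% dur
    stat(s, s + (events$end_s - events$start_s))
  }, 0)
  sm <- mean(shuf)
  res$observed <- obs
  res$shuffle_mean <- sm
  res$normalized <- if (sm > 0) obs / sm else NA_real_
  ci <- stats::quantile(shuf, c(0.025, 0.975), names = FALSE)
  res$significant <- obs < ci[1] || obs > ci[2]
  res$shuffle_values <- shuf
  res
}

#' dMEC-CA1 replay coherence score
#'
#' Corridor score of the dMEC posterior evaluated along the
#' best-fit line of the accompanying CA1 event: the mean per-time-bin
#' posterior mass within d = 30 cm of x = V t T + c, with (V, c) fixed to
#' the CA1 fit.  Uses the same integer-unit corridor predicate as the fit,
#' so the coherence of the CA1 posterior with its own fit equals the fit's
#' R exactly.
#'
#' @param fit a \code{"trajectory_fit"} from the CA1 posterior.
#' @param posterior a \code{"posterior_matrix"} (or bare matrix) decoded
#'   from dMEC spikes.
#' @param config analysis configuration.
#' @return Coherence in [0, 1].
#' @export
coherence_score <- function(fit, posterior, config = default_config()) {
  post <- if (inherits(posterior, "posterior_matrix")) posterior$prob else posterior
  if (is.null(post) || !ncol(post)) stop("no dMEC posterior for this event")
  unit <- 0.005
  a <- round(fit$V * config$decode_bin_s / unit)
  c_u <- round(fit$c / unit)
  if (abs(fit$V * config$decode_bin_s / unit - a) > 1e-9 ||
      abs(fit$c / unit - c_u) > 1e-9)
    stop("fit (V, c) off the 5 mm unit grid")
  m <- cpp_corridor_mass(post, as.integer(a), as.integer(c_u),
                         as.integer(round(config$corridor_d_m / unit)),
                         as.integer(round(0.02 / unit)))
  sum(m) / ncol(post)
}

#' Shuffle null for the coherence score
#'
#' Three regimes: \code{"cell_id"} permutes which dMEC cell gets which
#' ratemap (needs >= 2 cells); \code{"field_rotation"} circularly shifts
#' each dMEC ratemap by a random 10 to nb-10 bins; \code{"spike_time"}
#' shifts each cell's spikes within the event by a random 5 ms to
#' duration - 5 ms with wrap-around.  Each regime re-decodes the dMEC
#' posterior and re-scores coherence against the (unshuffled) CA1 best-fit
#' line, \code{n_shuffles} times.
#'
#' @param dmec_spikes named list of dMEC spike trains (decoding group).
#' @param window c(start, end) of the event.
#' @param rate_mat nb x n_cells dMEC rate matrix for the event's direction.
#' @param fit the CA1 \code{"trajectory_fit"}.
#' @param regime one of "cell_id", "field_rotation", "spike_time".
#' @param n_shuffles repetitions (100).
#' @param seed integer seed.
#' @param config analysis configuration.
#' @return Numeric vector of \code{n_shuffles} coherence scores.
#' @export
coherence_null <- function(dmec_spikes, window, rate_mat, fit,
                           regime = c("cell_id", "field_rotation", "spike_time"),
                           n_shuffles = 100, seed = 1,
                           config = default_config()) {
  regime <- match.arg(regime)
  ncell <- ncol(rate_mat)
  nb <- nrow(rate_mat)
  dur <- window[2] - window[1]
  if (regime == "cell_id" && ncell < 2)
    stop("cell_id shuffle needs at least 2 dMEC cells")
  if (regime == "spike_time" && dur < 0.010)
    stop("event too short for a spike-time shuffle")
  base <- bayesian_posterior(dmec_spikes, window, rate_mat, config)
  tau <- config$decode_bin_s
  set.seed(seed)
  vapply(seq_len(n_shuffles), function(i) {
    if (regime == "cell_id") {
      rm2 <- rate_mat[, sample.int(ncell), drop = FALSE]
      p2 <- posterior_from_counts(base$counts, rm2, tau, config$rate_floor_hz)
    } else if (regime == "field_rotation") {
      shifts <- sample(10:(nb - 10), ncell, replace = TRUE)
      rm2 <- rotate_rate_matrix(rate_mat, shifts)
      p2 <- posterior_from_counts(base$counts, rm2, tau, config$rate_floor_hz)
    } else {
      sp2 <- lapply(dmec_spikes, function(st) {
        ev <- st[st >= window[1] & st < window[2]]
        if (!length(ev)) return(ev)
        sh <- stats::runif(1, 0.005, dur - 0.005)
        sort(window[1] + (ev - window[1] + sh) %% dur)
      })
      p2 <- bayesian_posterior(sp2, window, rate_mat, config)$prob
    }
    coherence_score(fit, p2, config)
  }, 0)
}

#' Peri-event time histogram of dMEC activity around CA1 replay
#'
#' Mean firing rate of the pooled cell group aligned to candidate-event
#' midpoints, in 5 ms bins over +/- 0.5 s, normalized by the baseline rate
#' in the outer +/- (0.25..0.5) s flanks.  The peak lag is the bin with the
#' largest rate within +/- 100 ms of the event center.
#'
#' @param spike_list named list of spike trains (the cell group).
#' @param events data.frame with start_s, end_s (>= 10 events).
#' @param half_window_s window half-width (0.5).
#' @param bin_s bin width (0.005).
#' @return List: \code{lag_s} (bin centers), \code{rate_hz},
#'   \code{normalized}, \code{baseline_hz}, \code{peak_lag_s}.
#' @export
psth <- function(spike_list, events, half_window_s = 0.5, bin_s = 0.005) {
  if (nrow(events) < 10) stop("need at least 10 events for a PSTH")
  mids <- (events$start_s + events$end_s) / 2
  nb <- 2 * round(half_window_s / bin_s)
  edges <- -half_window_s + (0:nb) * bin_s
  ctrs <- edges[-1] - bin_s / 2
  counts <- numeric(nb)
  all_st <- sort(unlist(spike_list, use.names = FALSE))
  for (m in mids) {
    rel <- all_st[all_st >= m - half_window_s & all_st < m + half_window_s] - m
    counts <- counts + tabulate(floor((rel + half_window_s) / bin_s) + 1L,
                                nbins = nb)
  }
  rate <- counts / (length(mids) * bin_s * length(spike_list))
  flank <- abs(ctrs) >= half_window_s / 2
  base <- mean(rate[flank])
  core <- abs(ctrs) <= 0.1
  pk <- which(core)[which.max(rate[core])]
  # event-locked responses are plateaus (events of variable duration), so a
  # bare argmax wanders along the plateau; the excess-rate centroid is the
  # stable lag estimate
  w <- pmax(rate[core] - base, 0)
  cen <- if (sum(w) > 0) sum(ctrs[core] * w) / sum(w) else NA_real_
  list(lag_s = ctrs, rate_hz = rate,
       normalized = if (base > 0) rate / base else rate * NA,
       baseline_hz = base, peak_lag_s = cen, argmax_lag_s = ctrs[pk])
}

#' Coherence as a function of dMEC spike-time shift
#'
#' dMEC spikes are shifted by -80..+80 ms in 10 ms steps; at each shift the
#' mean replay coherence over long events (>= 80 ms) is recomputed.  A
#' coordination that lags CA1 by L ms produces a curve maximum at shift -L
#' (shifting dMEC spikes back by the lag re-aligns them with the CA1
#' trajectory).
#'
#' @param event_fits list of per-event lists with \code{window} (c(start,
#'   end)) and \code{fit} (CA1 \code{"trajectory_fit"}) and \code{direction}.
#' @param dmec_spikes named list of dMEC spike trains.
#' @param rate_mats list with outbound/inbound dMEC rate matrices.
#' @param shifts_s shift grid (seq(-0.08, 0.08, 0.01)).
#' @param min_dur_s minimum event duration (0.08).
#' @param config analysis configuration.
#' @return List: \code{shift_s}, \code{mean_coherence}, \code{best_shift_s},
#'   \code{n_events}.
#' @export
time_shift_coherence <- function(event_fits, dmec_spikes, rate_mats,
                                 shifts_s = seq(-0.08, 0.08, by = 0.01),
                                 min_dur_s = 0.08,
                                 config = default_config()) {
  long <- Filter(function(e) diff(e$window) >= min_dur_s, event_fits)
  if (length(long) < 10) stop("need at least 10 long (>= 80 ms) events")
  mc <- vapply(shifts_s, function(s) {
    sc <- vapply(long, function(e) {
      sp <- lapply(dmec_spikes, function(st) st + s)
      post <- bayesian_posterior(sp, e$window, rate_mats[[e$direction]], config)
      coherence_score(e$fit, post, config)
    }, 0)
    mean(sc)
  }, 0)
  list(shift_s = shifts_s, mean_coherence = mc,
       best_shift_s = shifts_s[which.max(mc)], n_events = length(long))
}

#' Participation and coherence analysis for one cell stratum
#'
#' Runs the full cross-regional battery for one group of dMEC cells:
#' per-cell normalized participation (with per-cell significance), per-event
#' coherence scores decoded from the group's spikes, the chosen shuffle
#' null, and the bootstrapped AUC comparison.
#'
#' @param cell_ids dMEC cell ids in the stratum.
#' @param dmec_spikes named list of all dMEC spike trains.
#' @param event_fits list of per-event lists with \code{window}, \code{fit},
#'   \code{direction} (significant CA1 replay events).
#' @param part_events data.frame of candidate events (start_s, end_s) for
#'   the participation analysis.
#' @param maps \code{\link{compute_ratemaps}} output covering the stratum.
#' @param window epoch window.
#' @param null_regime shuffle regime for coherence.
#' @param n_shuffles per-event shuffles (100).
#' @param n_boot AUC bootstraps (10000).
#' @param seed integer seed.
#' @param config analysis configuration.
#' @return List of class \code{"stratum_result"}: \code{participation}
#'   (data.frame per cell), \code{group_participation} (bootstrap vs
#'   chance), \code{coherence} (per-event scores), \code{shuffle_scores},
#'   \code{auc} (from \code{\link{auc_compare}}), \code{n_cells}.
#' @export
stratum_analysis <- function(cell_ids, dmec_spikes, event_fits, part_events,
                             maps, window, null_regime = "cell_id",
                             n_shuffles = 100, n_boot = 10000, seed = 1,
                             config = default_config()) {
  cell_ids <- intersect(cell_ids, names(dmec_spikes))
  out <- list(n_cells = length(cell_ids))
  class(out) <- "stratum_result"
  if (!length(cell_ids)) { out$untestable <- TRUE; return(out) }
  part <- NULL
  for (k in seq_along(cell_ids)) {
    id <- cell_ids[k]
    pr <- normalized_participation(dmec_spikes[[id]], part_events, window,
                                   seed = child_seed(seed, k))
    part <- rbind(part, data.frame(cell_id = id, observed = pr$observed,
                                   normalized = pr$normalized,
                                   significant = pr$significant,
                                   untestable = pr$untestable,
                                   stringsAsFactors = FALSE))
  }
  out$participation <- part
  vals <- part$normalized[!part$untestable & is.finite(part$normalized)]
  if (length(vals) >= 5) {
    set.seed(child_seed(seed, 1001))
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(vals, length(vals), replace = TRUE)), 0)
    out$group_participation <- list(
      mean = mean(vals), p_above_chance = mean(bm <= 1),
      ci95 = stats::quantile(bm, c(0.025, 0.975), names = FALSE),
      prop_significant = mean(part$significant[!part$untestable]))
  }
  if (length(event_fits)) {
    sp <- dmec_spikes[cell_ids]
    coh <- numeric(0); shuf <- numeric(0)
    for (k in seq_along(event_fits)) {
      e <- event_fits[[k]]
      rm <- ratemap_matrix(maps, e$direction, cell_ids)
      post <- bayesian_posterior(sp, e$window, rm, config)
      coh <- c(coh, coherence_score(e$fit, post, config))
      if (length(cell_ids) >= 2 || null_regime != "cell_id") {
        shuf <- c(shuf, coherence_null(sp, e$window, rm, e$fit,
                                       regime = null_regime,
                                       n_shuffles = n_shuffles,
                                       seed = child_seed(seed, 2000 + k),
                                       config = config))
      }
    }
    out$coherence <- coh
    out$shuffle_scores <- shuf
    if (length(coh) >= 10 && length(shuf) >= 10)
      out$auc <- auc_compare(coh, shuf, n_boot = n_boot,
                             seed = child_seed(seed, 3001))
  }
  out
}

#' Stratified cross-regional analyses
#'
#' Runs \code{\link{stratum_analysis}} for each stratum (theta-modulated vs
#' non-modulated groups, theta-score quartiles, functional classes,
#' field-size-controlled groups, learning periods, ...) and computes
#' pairwise between-stratum bootstrap comparisons of the normalized
#' (data - shuffle) AUC scores.  Empty strata are reported untestable, not
#' errors.
#'
#' @param strata named list of cell-id vectors.
#' @param ... passed to \code{\link{stratum_analysis}}.
#' @param n_boot bootstraps for between-stratum comparisons.
#' @return List of class \code{"stratified_result"}: \code{strata} (list of
#'   \code{"stratum_result"}), \code{comparisons} (data.frame with
#'   bootstrap p for each stratum pair, Bonferroni-corrected decisions).
#' @export
stratified_analyses <- function(strata, ..., n_boot = 10000) {
  res <- lapply(names(strata), function(nm)
    stratum_analysis(strata[[nm]], ...))
  names(res) <- names(strata)
  cmp <- NULL
  nms <- names(strata)
  if (length(nms) >= 2) {
    prs <- utils::combn(nms, 2)
    for (j in seq_len(ncol(prs))) {
      a <- res[[prs[1, j]]]; b <- res[[prs[2, j]]]
      if (is.null(a$auc) || is.null(b$auc)) next
      nb <- min(length(a$auc$boot_diffs), length(b$auc$boot_diffs))
      d <- a$auc$boot_diffs[seq_len(nb)] - b$auc$boot_diffs[seq_len(nb)]
      cmp <- rbind(cmp, data.frame(
        stratum_a = prs[1, j], stratum_b = prs[2, j],
        auc_diff = a$auc$auc_diff - b$auc$auc_diff,
        p_value = mean(d <= 0), stringsAsFactors = FALSE))
    }
    if (!is.null(cmp))
      cmp$reject <- bonferroni_decisions(cmp$p_value, m = nrow(cmp))
  }
  structure(list(strata = res, comparisons = cmp),
            class = "stratified_result")
}

#' Theta-score quartile strata
#'
#' Splits tested cells into four near-equal groups by theta modulation
#' score (quartile 1 = lowest).
#'
#' @param cell_ids cell ids.
#' @param scores matching theta modulation scores (NA = untested, dropped).
#' @return Named list of four cell-id vectors (q1..q4).
#' @export
theta_quartiles <- function(cell_ids, scores) {
  ok <- !is.na(scores)
  ids <- cell_ids[ok]; sc <- scores[ok]
  q <- cut(rank(sc, ties.method = "first"), breaks = 4, labels = FALSE)
  split(ids, paste0("q", q))
}
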