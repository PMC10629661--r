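#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates simulate -> ratemaps -> theta -> replay detection/decoding ->
#' cross-regional coordination on one synthetic session and returns all
#' headline tables plus the ground truth.  Stages: (1) session generation;
#' (2) linearized directional ratemaps and place-cell selection from RUN;
#' (3) theta-modulation permutation tests for dMEC cells and stratification
#' into modulated/non-modulated groups; (4) candidate-event detection in
#' REST, Bayesian decoding, line fitting and field-rotation significance;
#' (5) participation, coherence + cell-ID shuffle + AUC statistics per
#' stratum, PSTH and time-shift lag, and the PRE_REST (preplay) participation
#' control.  Re-running with identical (params, seed) reproduces every
#' stochastic output exactly.
#'
#' @param params a \code{\link{sim_params}} list.
#' @param seed integer master seed.
#' @param config analysis configuration.
#' @param out_dir when given, \code{summary.json} is written there.
#' @param n_shuffles per-event/per-cell shuffles (100).
#' @param n_boot bootstrap iterations (10000).
#' @param max_events cap on candidate events submitted to trajectory
#'   significance (Inf).
#' @param verbose print per-stage timing.
#' @return List of class \code{"pipeline_run"} with \code{summary} (the
#'   headline numbers), \code{events}, \code{replay}, \code{strata},
#'   \code{theta}, \code{psth}, \code{time_shift}, \code{preplay},
#'   \code{truth}, \code{session}, \code{seed}, \code{timing_s}.
#' @export
run_full_pipeline <- function(params = sim_params(), seed = 1,
                              config = default_config(), out_dir = NULL,
                              n_shuffles = 100, n_boot = 10000,
                              max_events = Inf, verbose = FALSE) {
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  stage <- function(nm) {
    timing[[nm]] <<- tic() - t0
    if (verbose) message(sprintf("[%s] %.1f s", nm, timing[[nm]]))
    t0 <<- tic()
  }

  sim <- assemble_session(params, seed, config)
  session <- sim$session
  stage("simulate")

  run_win <- epoch_window(session, "RUN")
  rest_win <- epoch_window(session, "REST")
  lintrace <- linearize_position(session$position$RUN, session$geometry, config)
  maps <- compute_ratemaps(session$spikes, lintrace, session$geometry, config)
  cells <- session$cells
  cells$mean_rate_run <- vapply(cells$cell_id, function(id)
    track_mean_rate(session$spikes[[id]], lintrace), 0)
  cells$mean_rate_rest <- vapply(cells$cell_id, function(id)
    length(spikes_in_window(session$spikes[[id]], rest_win)) /
      diff(rest_win), 0)
  ca1_ids <- cells$cell_id[cells$region == "CA1" &
                             cells$mean_rate_run <= config$ca1_interneuron_hz]
  place <- vapply(ca1_ids, function(id) {
    classify_place_cell(maps[[id]], cells$mean_rate_run[cells$cell_id == id],
                        config)$is_place_cell
  }, TRUE)
  place_ids <- ca1_ids[place]
  dmec_ids <- cells$cell_id[cells$region == "dMEC" &
                              cells$mean_rate_run <= config$dmec_rate_cap_hz]
  stage("ratemaps")

  theta <- NULL
  for (k in seq_along(dmec_ids)) {
    id <- dmec_ids[k]
    tm <- theta_modulation_test(session$spikes[[id]], run_win,
                                n_shuffles = n_shuffles,
                                percentile = config$theta_percentile,
                                seed = child_seed(seed, 100 + k),
                                config = config)
    theta <- rbind(theta, data.frame(cell_id = id, score = tm$score,
                                     threshold = tm$threshold,
                                     theta_modulated = tm$is_theta_modulated,
                                     stringsAsFactors = FALSE))
  }
  theta_ids <- theta$cell_id[theta$theta_modulated == "yes"]
  nontheta_ids <- theta$cell_id[theta$theta_modulated == "no"]
  stage("theta")

  ca1_spikes <- session$spikes[place_ids]
  events <- detect_candidate_events(ca1_spikes, rest_win, config)
  if (nrow(events) > max_events) events <- events[seq_len(max_events), ]
  rate_mats <- list(outbound = ratemap_matrix(maps, "outbound", place_ids),
                    inbound = ratemap_matrix(maps, "inbound", place_ids))
  replay <- list()
  fits <- NULL
  for (k in seq_len(nrow(events))) {
    win <- c(events$start_s[k], events$end_s[k])
    sig <- event_significance(ca1_spikes, win, rate_mats,
                              n_shuffles = n_shuffles,
                              seed = child_seed(seed, 200 + k),
                              config = config)
    for (dir in c("outbound", "inbound")) {
      f <- sig[[dir]]$fit
      fits <- rbind(fits, data.frame(event = k, direction = dir, V = f$V,
                                     c = f$c, R = f$R,
                                     p_value = sig[[dir]]$p_value,
                                     is_replay = sig[[dir]]$is_replay,
                                     class = f$direction_class,
                                     stringsAsFactors = FALSE))
    }
    if (!is.na(sig$best_direction)) {
      replay[[length(replay) + 1]] <-
        list(window = win, direction = sig$best_direction,
             fit = sig[[sig$best_direction]]$fit,
             p_value = sig[[sig$best_direction]]$p_value)
    }
  }
  stage("replay_detection")

  dmec_spikes <- session$spikes[dmec_ids]
  strata_def <- list(theta = theta_ids, nontheta = nontheta_ids)
  strat <- stratified_analyses(
    strata_def, dmec_spikes = dmec_spikes, event_fits = replay,
    part_events = events, maps = maps, window = rest_win,
    null_regime = "cell_id", n_shuffles = n_shuffles, n_boot = n_boot,
    seed = child_seed(seed, 300), config = config)
  psth_res <- lapply(strata_def, function(ids) {
    if (length(ids) && nrow(events) >= 10)
      psth(dmec_spikes[ids], events) else NULL
  })
  ts_res <- NULL
  if (length(theta_ids) && length(replay) >= 10) {
    ts_res <- tryCatch(
      time_shift_coherence(replay, dmec_spikes[theta_ids], list(
        outbound = ratemap_matrix(maps, "outbound", theta_ids),
        inbound = ratemap_matrix(maps, "inbound", theta_ids)), config = config),
      error = function(e) NULL)
  }
  stage("coordination")

  pre_win <- epoch_window(session, "PRE_REST")
  pre_events <- detect_candidate_events(ca1_spikes, pre_win, config,
                                        ref_window = rest_win)
  preplay <- lapply(strata_def, function(ids) {
    if (!length(ids) || nrow(pre_events) < 5) return(NULL)
    vals <- vapply(seq_along(ids), function(k) {
      normalized_participation(dmec_spikes[[ids[k]]], pre_events, pre_win,
                               seed = child_seed(seed, 400 + k))$normalized
    }, 0)
    vals <- vals[is.finite(vals)]
    list(mean_normalized = mean(vals), n_cells = length(vals))
  })
  stage("preplay")

  g <- function(x, f) if (is.null(x)) NA_real_ else f(x)
  summary <- list(
    schema_version = "1",
    seed = seed,
    n_ca1 = sum(cells$region == "CA1"),
    n_place_cells = length(place_ids),
    n_dmec = sum(cells$region == "dMEC"),
    n_theta_modulated = length(theta_ids),
    frac_theta_modulated = length(theta_ids) / max(1, nrow(theta)),
    n_candidate_events = nrow(events),
    n_replay_events = length(replay),
    theta_auc_diff = g(strat$strata$theta$auc, function(a) a$auc_diff),
    theta_auc_p = g(strat$strata$theta$auc, function(a) a$p_value),
    nontheta_auc_diff = g(strat$strata$nontheta$auc, function(a) a$auc_diff),
    nontheta_auc_p = g(strat$strata$nontheta$auc, function(a) a$p_value),
    theta_vs_nontheta_p = if (!is.null(strat$comparisons))
      strat$comparisons$p_value[1] else NA_real_,
    theta_participation = g(strat$strata$theta$group_participation,
                            function(p) p$mean),
    nontheta_participation = g(strat$strata$nontheta$group_participation,
                               function(p) p$mean),
    psth_peak_lag_ms = g(psth_res$theta, function(p) p$peak_lag_s * 1000),
    time_shift_best_ms = g(ts_res, function(t) t$best_shift_s * 1000),
    preplay_theta_participation = g(preplay$theta,
                                    function(p) p$mean_normalized),
    preplay_nontheta_participation = g(preplay$nontheta,
                                       function(p) p$mean_normalized))
  out <- structure(list(summary = summary, events = events, fits = fits,
                        replay = replay, strata = strat, theta = theta,
                        psth = psth_res, time_shift = ts_res,
                        preplay = preplay, truth = sim$truth,
                        session = session, cells = cells, maps = maps,
                        place_ids = place_ids, seed = seed,
                        timing_s = timing),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_run> seed ", s$seed, ": ", s$n_place_cells, " place cells, ",
      s$n_theta_modulated, "/", s$n_dmec, " theta-modulated dMEC, ",
      s$n_candidate_events, " candidate / ", s$n_replay_events,
      " replay events\n", sep = "")
  cat(sprintf("  theta AUC diff %.3f (p = %.4g), non-theta %.3f (p = %.4g)\n",
              s$theta_auc_diff, s$theta_auc_p, s$nontheta_auc_diff,
              s$nontheta_auc_p))
  invisible(x)
}
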