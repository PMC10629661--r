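#' Export directional ratemaps as TSV
#'
#' Long format: cell_id, direction, bin (1-based), rate_hz, occupancy_s.
#'
#' @param maps output of \code{\link{compute_ratemaps}}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
export_ratemaps <- function(maps, file) {
  rows <- list()
  for (id in names(maps)) {
    for (dir in c("outbound", "inbound")) {
      m <- maps[[id]][[dir]]
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = id, direction = dir, bin = seq_along(m$rate),
        rate_hz = m$rate, occupancy_s = m$occupancy_s,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the pipeline's result tables to a directory
#'
#' events.tsv (candidate events), fits.tsv (per-event per-direction
#' trajectory fits and significance), theta_results.tsv (per-cell theta
#' modulation), participation.tsv (per-cell normalized participation per
#' stratum) and summary.json.
#'
#' @param pr a \code{"pipeline_run"}.
#' @param dir output directory (created if absent).
#' @return Invisibly, \code{dir}.
#' @export
write_pipeline_tables <- function(pr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wr(pr$events, "events.tsv")
  wr(pr$fits, "fits.tsv")
  wr(pr$theta, "theta_results.tsv")
  part <- NULL
  for (nm in names(pr$strata$strata)) {
    p <- pr$strata$strata[[nm]]$participation
    if (!is.null(p)) {
      p$stratum <- nm
      part <- rbind(part, p)
    }
  }
  if (!is.null(part)) wr(part, "participation.tsv")
  coh <- NULL
  for (nm in names(pr$strata$strata)) {
    s <- pr$strata$strata[[nm]]
    if (!is.null(s$coherence))
      coh <- rbind(coh, data.frame(stratum = nm,
                                   event = seq_along(s$coherence),
                                   coherence = s$coherence,
                                   stringsAsFactors = FALSE))
  }
  if (!is.null(coh)) wr(coh, "coherence.tsv")
  jsonlite::write_json(pr$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Down-sampling control for between-stratum coherence comparisons
#'
#' Repeatedly subsamples a cell group to a target size, recomputes the
#' bootstrapped normalized AUC for each subsample, and averages the
#' bootstrap distributions across repetitions, so a larger stratum can be
#' compared with a smaller one at matched cell count.
#'
#' @param cell_ids cells of the (larger) stratum.
#' @param n_target subsample size (the smaller stratum's cell count).
#' @param n_rep subsampling repetitions (100).
#' @param seed integer seed.
#' @param ... passed to \code{\link{stratum_analysis}} (dmec_spikes,
#'   event_fits, part_events, maps, window, ...).
#' @return List: \code{auc_diff} (mean over repetitions),
#'   \code{boot_diffs} (bootstrap distribution averaged across
#'   repetitions), \code{n_rep}.
#' @export
downsampled_auc <- function(cell_ids, n_target, n_rep = 100, seed = 1, ...) {
  stopifnot(n_target >= 1, n_target <= length(cell_ids))
  set.seed(seed)
  subs <- lapply(seq_len(n_rep), function(i) sample(cell_ids, n_target))
  boot_sum <- NULL
  diffs <- numeric(0)
  for (i in seq_len(n_rep)) {
    res <- stratum_analysis(subs[[i]], seed = child_seed(seed, i), ...)
    if (is.null(res$auc)) next
    diffs <- c(diffs, res$auc$auc_diff)
    boot_sum <- if (is.null(boot_sum)) res$auc$boot_diffs
                else boot_sum + res$auc$boot_diffs
  }
  if (!length(diffs)) stop("no subsample produced an AUC (too few events?)")
  list(auc_diff = mean(diffs), boot_diffs = boot_sum / length(diffs),
       n_rep = length(diffs))
}
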