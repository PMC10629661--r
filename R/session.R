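#' Assemble a recording session container
#'
#' The session bundles everything one recording day produces: epoch intervals,
#' cell metadata, spike trains, position traces, LFP channels, the track
#' geometry and the analysis configuration.  Epoch intervals are half-open
#' [start, end) seconds from session start.
#'
#' @param epochs data.frame with columns \code{label} (one of PRE_REST, RUN,
#'   REST, OPEN_FIELD), \code{start_s}, \code{end_s}.
#' @param cells data.frame with at least \code{cell_id}, \code{region}
#'   (CA1 or dMEC), \code{animal_id}, \code{day}.  Optional columns
#'   (\code{functional_class}, \code{theta_modulated}, \code{theta_mod_score},
#'   \code{mean_rate_run}, \code{mean_rate_rest}) are added with defaults.
#' @param spikes named list of strictly nondecreasing numeric vectors of spike
#'   times (s), one per cell_id.
#' @param position named list (by epoch label) of data.frames with
#'   \code{time_s}, \code{x_cm}, \code{y_cm}, \code{hd_rad}.  Speed is derived
#'   by finite differences (distance between consecutive samples over dt,
#'   assigned to the later sample; the first sample inherits the second's
#'   value).
#' @param lfp list of channels, each a list with \code{channel_id},
#'   \code{region}, \code{rate_hz}, \code{samples}.
#' @param geometry a \code{\link{track_geometry}}.
#' @param config an \code{\link{default_config}} list.
#' @param validate run \code{\link{validate_session}} (default TRUE).
#' @return A list of class \code{"replay_session"}.
#' @export
new_session <- function(epochs, cells, spikes, position, lfp = list(),
                        geometry = track_geometry(), config = default_config(),
                        validate = TRUE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  defaults <- list(functional_class = "unclassified",
                   theta_modulated = "untested",
                   theta_mod_score = NA_real_,
                   mean_rate_run = NA_real_, mean_rate_rest = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(cells[[nm]])) cells[[nm]] <- defaults[[nm]]
  }
  position <- lapply(position, add_derived_speed)
  s <- structure(list(epochs = as.data.frame(epochs), cells = cells,
                      spikes = spikes, position = position, lfp = lfp,
                      geometry = geometry, config = config),
                 class = "replay_session")
  if (validate) validate_session(s)
  s
}

#' @export
print.replay_session <- function(x, ...) {
  cat("<replay_session> ", nrow(x$cells), " cells (",
      sum(x$cells$region == "CA1"), " CA1, ",
      sum(x$cells$region == "dMEC"), " dMEC), epochs: ",
      paste(x$epochs$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

add_derived_speed <- function(pos) {
  pos <- as.data.frame(pos, stringsAsFactors = FALSE)
  n <- nrow(pos)
  if (n >= 2) {
    dt <- diff(pos$time_s)
    d <- sqrt(diff(pos$x_cm)^2 + diff(pos$y_cm)^2)
    sp <- d / dt
    pos$speed_cm_s <- c(sp[1], sp)
  } else {
    pos$speed_cm_s <- rep(0, n)
  }
  pos
}

epoch_window <- function(session, label) {
  i <- match(label, session$epochs$label)
  if (is.na(i)) stop("session has no epoch '", label, "'")
  c(session$epochs$start_s[i], session$epochs$end_s[i])
}

spikes_in_window <- function(times, win) {
  times[times >= win[1] & times < win[2]]
}

#' Validate a session container
#'
#' Checks every type invariant: unique cell ids, every spike train has
#' metadata, sorted in-range spike times, strictly increasing position
#' timestamps, non-overlapping epochs, nonnegative rates, day >= 1 and LFP
#' sample rates of at least 250 Hz.
#'
#' @param session a \code{"replay_session"}.
#' @return Invisibly TRUE; stops with a descriptive error otherwise.
#' @export
validate_session <- function(session) {
  ep <- session$epochs
  if (nrow(ep) == 0) stop("session has no epochs")
  if (any(ep$end_s <= ep$start_s)) stop("epoch with nonpositive duration")
  o <- order(ep$start_s)
  if (any(ep$end_s[o][-nrow(ep)] > ep$start_s[o][-1] + 1e-12))
    stop("epoch intervals overlap")
  cells <- session$cells
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in session")
  if (!all(cells$region %in% c("CA1", "dMEC")))
    stop("cell region must be CA1 or dMEC")
  if (any(!is.na(cells$day) & cells$day < 1)) stop("session day must be >= 1")
  for (nm in c("mean_rate_run", "mean_rate_rest")) {
    v <- cells[[nm]]
    if (any(!is.na(v) & v < 0)) stop(nm, " must be >= 0")
  }
  smax <- max(ep$end_s)
  if (!all(names(session$spikes) %in% cells$cell_id))
    stop("spike train without cell metadata: ",
         paste(setdiff(names(session$spikes), cells$cell_id), collapse = ", "))
  for (id in names(session$spikes)) {
    tt <- session$spikes[[id]]
    if (length(tt) && is.unsorted(tt))
      stop("spike times not sorted for cell ", id)
    if (length(tt) && (tt[1] < 0 || tt[length(tt)] > smax))
      stop("spike time outside session duration for cell ", id)
  }
  for (lab in names(session$position)) {
    pos <- session$position[[lab]]
    if (nrow(pos) >= 2 && any(diff(pos$time_s) <= 0))
      stop("position timestamps not strictly increasing in epoch ", lab)
    if (any(pos$speed_cm_s < 0)) stop("negative derived speed in epoch ", lab)
    if (any(pos$hd_rad < 0 | pos$hd_rad >= 2 * pi + 1e-9))
      stop("head direction outside [0, 2*pi) in epoch ", lab)
  }
  for (ch in session$lfp) {
    if (ch$rate_hz < 250) stop("LFP sample rate below 250 Hz on channel ",
                               ch$channel_id)
  }
  invisible(TRUE)
}

fmt_num <- function(x) {
  out <- formatC(x, format = "f", digits = 9, drop0trailing = FALSE)
  out[is.na(x)] <- "NA"
  out
}

#' Write a session to an interchange directory
#'
#' Plain delimited text tables: \code{cells.tsv}, \code{spikes.tsv},
#' \code{epochs.tsv}, \code{position_<epoch>.tsv} per epoch,
#' \code{lfp_channels.tsv} plus \code{lfp_<channel>.tsv} per channel, and
#' \code{config.yaml}.  Numeric fields are written with 9 decimal places so
#' output is byte-stable for identical input and round-trips within 1e-9.
#'
#' @param session a valid \code{"replay_session"}.
#' @param path output directory (created if absent).
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{load_session}}
#' @export
save_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  ep <- session$epochs
  wr(data.frame(label = ep$label, start_s = fmt_num(ep$start_s),
                end_s = fmt_num(ep$end_s)), "epochs.tsv")
  cl <- session$cells
  wr(data.frame(cell_id = cl$cell_id, region = cl$region,
                animal_id = cl$animal_id, day = cl$day,
                functional_class = cl$functional_class,
                theta_modulated = cl$theta_modulated,
                theta_mod_score = fmt_num(cl$theta_mod_score),
                mean_rate_run = fmt_num(cl$mean_rate_run),
                mean_rate_rest = fmt_num(cl$mean_rate_rest)), "cells.tsv")
  ids <- rep(names(session$spikes), lengths(session$spikes))
  tt <- unlist(session$spikes, use.names = FALSE)
  if (is.null(tt)) tt <- numeric(0)
  wr(data.frame(cell_id = ids, time_s = fmt_num(tt)), "spikes.tsv")
  for (lab in names(session$position)) {
    pos <- session$position[[lab]]
    wr(data.frame(time_s = fmt_num(pos$time_s), x_cm = fmt_num(pos$x_cm),
                  y_cm = fmt_num(pos$y_cm), hd_rad = fmt_num(pos$hd_rad)),
       paste0("position_", tolower(lab), ".tsv"))
  }
  chans <- data.frame(channel_id = character(0), region = character(0),
                      rate_hz = numeric(0))
  for (ch in session$lfp) {
    chans <- rbind(chans, data.frame(channel_id = ch$channel_id,
                                     region = ch$region, rate_hz = ch$rate_hz))
    wr(data.frame(sample_uv = fmt_num(ch$samples)),
       paste0("lfp_", ch$channel_id, ".tsv"))
  }
  wr(chans, "lfp_channels.tsv")
  geom <- session$geometry
  cfg <- unclass(session$config)
  yaml::write_yaml(list(
    geometry = list(arm_cm = geom$arm_cm, diag_cm = geom$diag_cm,
                    bin_cm = geom$bin_cm, end_excl_cm = geom$end_excl_cm,
                    corner_excl_cm = geom$corner_excl_cm),
    config = cfg), file.path(path, "config.yaml"))
  invisible(path)
}

read_tsv_checked <- function(path, file, required) {
  f <- file.path(path, file)
  if (!file.exists(f)) stop("missing mandatory table: ", file)
  df <- tryCatch(
    utils::read.delim(f, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("parse error in ", file, ": ", conditionMessage(e))
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("table ", file, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Load a session from an interchange directory
#'
#' Inverse of \code{\link{save_session}}; the returned session is fully
#' validated and derived speed is recomputed from the position samples.
#'
#' @param path directory written by \code{\link{save_session}}.
#' @return A \code{"replay_session"}.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop("no such session directory: ", path)
  ep <- read_tsv_checked(path, "epochs.tsv", c("label", "start_s", "end_s"))
  ep$start_s <- as.numeric(ep$start_s); ep$end_s <- as.numeric(ep$end_s)
  cl <- read_tsv_checked(path, "cells.tsv",
                         c("cell_id", "region", "animal_id", "day"))
  cl$cell_id <- as.character(cl$cell_id)
  cl$animal_id <- as.character(cl$animal_id)
  for (nm in c("theta_mod_score", "mean_rate_run", "mean_rate_rest"))
    if (!is.null(cl[[nm]])) cl[[nm]] <- as.numeric(cl[[nm]])
  sp <- read_tsv_checked(path, "spikes.tsv", c("cell_id", "time_s"))
  spikes <- lapply(split(as.numeric(sp$time_s), as.character(sp$cell_id)),
                   as.numeric)
  spikes <- spikes[intersect(cl$cell_id, names(spikes))]
  for (id in setdiff(cl$cell_id, names(spikes))) spikes[[id]] <- numeric(0)
  spikes <- spikes[cl$cell_id]
  position <- list()
  for (lab in ep$label) {
    f <- paste0("position_", tolower(lab), ".tsv")
    if (file.exists(file.path(path, f))) {
      pos <- read_tsv_checked(path, f, c("time_s", "x_cm", "y_cm", "hd_rad"))
      position[[lab]] <- data.frame(time_s = as.numeric(pos$time_s),
                                    x_cm = as.numeric(pos$x_cm),
                                    y_cm = as.numeric(pos$y_cm),
                                    hd_rad = as.numeric(pos$hd_rad))
    }
  }
  lfp <- list()
  lfpc_file <- file.path(path, "lfp_channels.tsv")
  if (file.exists(lfpc_file)) {
    chans <- utils::read.delim(lfpc_file, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(chans))) {
      samp <- utils::read.delim(
        file.path(path, paste0("lfp_", chans$channel_id[i], ".tsv")))
      lfp[[length(lfp) + 1]] <- list(channel_id = as.character(chans$channel_id[i]),
                                     region = chans$region[i],
                                     rate_hz = chans$rate_hz[i],
                                     samples = as.numeric(samp$sample_uv))
    }
  }
  yml <- yaml::read_yaml(file.path(path, "config.yaml"))
  geom <- do.call(track_geometry, yml$geometry)
  cfg <- yml$config
  # yaml flattens length-2 numeric vectors into lists; restore
  cfg <- lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- do.call(default_config, cfg)
  new_session(ep, cl, spikes, position, lfp, geom, cfg, validate = TRUE)
}
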