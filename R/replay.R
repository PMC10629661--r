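#' Detect candidate replay events from CA1 multi-unit activity
#'
#' Pooled CA1 place-cell spikes are binned at 1 ms and smoothed with a
#' Gaussian kernel (sigma = 20 ms).  Periods when this multi-unit activity
#' exceeds 3 SD above the mean (both taken from the reference rest epoch)
#' are flagged; event boundaries are where the activity falls back to the
#' reference mean.  Events shorter than 40 ms or with fewer than
#' max(15\% of the CA1 population, 5) participating cells are rejected.
#' For awake events a mean-speed-below-threshold filter is applied.
#'
#' @param spikes named list of spike trains of the included CA1 place cells.
#' @param window c(start, end) of the epoch to scan (s).
#' @param config analysis configuration.
#' @param ref_window epoch used for the mean/SD of the MUA (the rest
#'   session); defaults to \code{window}.
#' @param speed optional data.frame (time_s, speed_cm_s); when given, events
#'   whose mean speed exceeds \code{speed_thresh_cm_s} are rejected and the
#'   state is "awake_immobile".
#' @param speed_thresh_cm_s immobility threshold for awake events
#'   (default \code{config$awake_speed_cm_s} = 1; 3 is the alternate).
#' @return data.frame of class \code{"candidate_events"}: start_s, end_s,
#'   duration_ms, n_cells, state.
#' @export
detect_candidate_events <- function(spikes, window, config = default_config(),
                                    ref_window = window, speed = NULL,
                                    speed_thresh_cm_s = config$awake_speed_cm_s) {
  if (!length(spikes)) stop("empty spike set")
  n_pop <- length(spikes)
  binw <- config$mua_bin_s
  smoothed_mua <- function(win) {
    nb <- ceiling((win[2] - win[1]) / binw)
    tt <- unlist(lapply(spikes, spikes_in_window, win), use.names = FALSE)
    counts <- tabulate(pmin(floor((tt - win[1]) / binw), nb - 1) + 1L,
                       nbins = nb)
    gauss_smooth_renorm(counts, config$mua_sigma_s / binw)
  }
  ref <- if (isTRUE(all.equal(ref_window, window))) NULL else smoothed_mua(ref_window)
  mua <- smoothed_mua(window)
  if (is.null(ref)) ref <- mua
  m <- mean(ref); s <- stats::sd(ref)
  thr <- m + config$mua_sd_thresh * s
  elev <- mua > m
  r <- rle(elev)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- NULL
  min_cells <- max(config$min_cells_frac * n_pop, config$min_cells_abs)
  for (k in which(r$values)) {
    if (max(mua[starts[k]:ends[k]]) <= thr) next
    ev_s <- window[1] + (starts[k] - 1) * binw
    ev_e <- window[1] + ends[k] * binw
    if (ev_e - ev_s < config$min_event_s) next
    n_cells <- sum(vapply(spikes, function(st)
      any(st >= ev_s & st < ev_e), TRUE))
    if (n_cells < min_cells) next
    state <- "rest"
    if (!is.null(speed)) {
      sp <- stats::approx(speed$time_s, speed$speed_cm_s,
                          xout = seq(ev_s, ev_e, by = 0.01), rule = 2)$y
      if (mean(sp) >= speed_thresh_cm_s) next
      state <- "awake_immobile"
    }
    out <- rbind(out, data.frame(start_s = ev_s, end_s = ev_e,
                                 duration_ms = (ev_e - ev_s) * 1000,
                                 n_cells = n_cells, state = state,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), n_cells = integer(0),
                      state = character(0), stringsAsFactors = FALSE)
  class(out) <- c("candidate_events", "data.frame")
  out
}

#' Rate matrix of a ratemap set for decoding
#'
#' @param maps output of \code{\link{compute_ratemaps}}.
#' @param direction "outbound" or "inbound".
#' @param cell_ids cells to include (default all in \code{maps}).
#' @return nb x n_cells matrix of rates (Hz), one column per cell.
#' @export
ratemap_matrix <- function(maps, direction, cell_ids = names(maps)) {
  do.call(cbind, lapply(maps[cell_ids], function(m) m[[direction]]$rate))
}

#' Bayesian posterior position decoding of one event
#'
#' The event is divided into 10 ms bins; per bin, with a uniform prior and
#' independent-Poisson spiking, P(x | spikes) is proportional to
#' prod_j (tau r_j(x))^(k_j) exp(-tau r_j(x)), normalized per bin.  Rates
#' are floored at epsilon (0.01 Hz) so no position has zero likelihood.
#' Time bins are half-open; a trailing partial bin is dropped.
#'
#' @param spikes named list of spike trains (the decoding population).
#' @param window c(start, end) of the event (s).
#' @param rate_mat nb x n_cells rate matrix (see
#'   \code{\link{ratemap_matrix}}); column order must match \code{spikes}.
#' @param config analysis configuration.
#' @return List of class \code{"posterior_matrix"}: \code{prob} (nb x nt,
#'   columns sum to 1), \code{window}, \code{nt}, \code{counts}.
#' @export
bayesian_posterior <- function(spikes, window, rate_mat,
                               config = default_config()) {
  tau <- config$decode_bin_s
  nt <- floor((window[2] - window[1]) / tau + 1e-9)
  if (nt < 1) stop("event shorter than one decoding bin")
  if (all(rate_mat <= 0)) stop("all-zero ratemaps")
  ncell <- ncol(rate_mat)
  stopifnot(ncell == length(spikes))
  K <- matrix(0, nrow = ncell, ncol = nt)
  for (j in seq_len(ncell)) {
    st <- spikes[[j]]
    st <- st[st >= window[1] & st < window[1] + nt * tau]
    if (length(st))
      K[j, ] <- tabulate(floor((st - window[1]) / tau) + 1L, nbins = nt)
  }
  post <- posterior_from_counts(K, rate_mat, tau)
  structure(list(prob = post, window = window, nt = nt, counts = K),
            class = "posterior_matrix")
}

posterior_from_counts <- function(K, rate_mat, tau,
                                  floor_hz = default_config()$rate_floor_hz) {
  r <- pmax(rate_mat, floor_hz)
  logL <- log(r) %*% K - tau * rowSums(r)
  logL <- sweep(logL, 2, apply(logL, 2, max))
  L <- exp(logL)
  sweep(L, 2, colSums(L), "/")
}

line_grid <- function(config) {
  unit <- 0.005
  chk <- function(x, nm) {
    if (any(abs(x / unit - round(x / unit)) > 1e-9))
      stop(nm, " must be a multiple of 5 mm for the exact grid search")
    as.integer(round(x / unit))
  }
  v_all <- seq(-config$v_max, config$v_max, by = config$v_step)
  v_vals <- v_all[abs(v_all) >= config$v_excl - 1e-12]
  voff <- chk(v_vals * config$decode_bin_s, "V*T")
  list(v_vals = v_vals, voff = voff,
       cmin_u = chk(config$c_min, "c_min"),
       cstep_u = chk(config$c_step, "c_step"),
       nc = as.integer(round((config$c_max - config$c_min) / config$c_step)) + 1L,
       d_u = chk(config$corridor_d_m, "d"),
       w_u = chk(0.02, "bin width"))
}

#' Fit the best straight-line trajectory to a posterior
#'
#' Maximizes R(V, c) = (1/n) sum_t [posterior mass within d = 30 cm of the
#' line x = V t T + c at time bin t] by exhaustive search over V in
#' [-50, 50] m/s (0.5 m/s steps, excluding (-2, 2)) and c in [-15, 21] m
#' (0.01 m steps).  Ties resolve to the first cell in scan order (ascending
#' V, then ascending c).  \code{method = "fast"} uses the compiled sparse
#' accumulation; \code{method = "naive"} evaluates every (V, c) cell
#' directly from the definition and is the reference implementation (the
#' two agree exactly).
#'
#' @param posterior a \code{"posterior_matrix"} (or bare nb x nt matrix).
#' @param config analysis configuration.
#' @param method "fast" or "naive".
#' @return List of class \code{"trajectory_fit"}: \code{V} (m/s), \code{c}
#'   (m), \code{R} in [0, 1], \code{n} time bins, \code{direction_class}
#'   ("forward" for positive slope, else "reverse").
#' @export
fit_trajectory_line <- function(posterior, config = default_config(),
                                method = c("fast", "naive")) {
  method <- match.arg(method)
  post <- if (inherits(posterior, "posterior_matrix")) posterior$prob else posterior
  if (ncol(post) < 2) stop("need at least 2 time bins to fit a line")
  g <- line_grid(config)
  if (method == "fast") {
    res <- cpp_line_fit(post, g$voff, g$cmin_u, g$cstep_u, g$nc, g$d_u, g$w_u)
    V <- g$v_vals[res$v_index]
    cc <- config$c_min + (res$c_index - 1) * config$c_step
    R <- res$R
  } else {
    nb <- nrow(post); nt <- ncol(post)
    best <- -1; V <- NA; cc <- NA
    tseq <- 0:(nt - 1)
    # per (V, c, t): directly sum the bins whose centers (w_u*k + w_u/2)
    # fall within d_u of the line, in integer 5 mm units
    for (vi in seq_along(g$voff)) {
      offs <- g$voff[vi] * tseq
      for (ci in seq_len(g$nc)) {
        x_u <- offs + g$cmin_u + g$cstep_u * (ci - 1)
        tot <- 0
        for (t in seq_len(nt)) {
          klo <- max(1, ceiling((2 * (x_u[t] - g$d_u) - g$w_u) / (2 * g$w_u)) + 1)
          khi <- min(nb, floor((2 * (x_u[t] + g$d_u) - g$w_u) / (2 * g$w_u)) + 1)
          if (khi >= klo) tot <- tot + sum(post[klo:khi, t])
        }
        if (tot > best) {
          best <- tot; V <- g$v_vals[vi]
          cc <- config$c_min + (ci - 1) * config$c_step
        }
      }
    }
    R <- best / nt
  }
  structure(list(V = V, c = cc, R = R, n = ncol(post),
                 direction_class = if (V > 0) "forward" else "reverse"),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> V = %.1f m/s, c = %.2f m, R = %.3f (%s, n = %d)\n",
              x$V, x$c, x$R, x$direction_class, x$n))
  invisible(x)
}

# rotate each cell's ratemap by a per-cell number of bins (wrap-around)
rotate_rate_matrix <- function(rate_mat, shifts) {
  nb <- nrow(rate_mat)
  out <- rate_mat
  for (j in seq_len(ncol(rate_mat))) {
    s <- shifts[j] %% nb
    if (s > 0) out[, j] <- rate_mat[c((nb - s + 1):nb, 1:(nb - s)), j]
  }
  out
}

#' Field-rotation significance of a candidate event
#'
#' The null rotates each CA1 ratemap independently by a random number of
#' bins (1 to nb-1, wrap-around), re-decodes and re-fits the event; the
#' p value is the fraction of null R at or above the observed R, per
#' direction.  An event is a replay trajectory when p < 0.025 in a
#' direction (the threshold halves 0.05 to control for testing both run
#' directions).
#'
#' @param spikes named list of CA1 place-cell spike trains.
#' @param window c(start, end) of the event.
#' @param rate_mats named list with elements \code{outbound} and
#'   \code{inbound}, each an nb x n_cells rate matrix.
#' @param n_shuffles rotations per event (100).
#' @param seed integer seed.
#' @param config analysis configuration.
#' @return List of class \code{"replay_significance"} with one entry per
#'   direction (fit, p_value, is_replay, null_R) plus \code{best_direction}
#'   (larger significant R; NA when neither direction is significant).
#' @export
event_significance <- function(spikes, window, rate_mats, n_shuffles = 100,
                               seed = 1, config = default_config()) {
  set.seed(seed)
  out <- list()
  for (dir in c("outbound", "inbound")) {
    rm <- rate_mats[[dir]]
    post <- bayesian_posterior(spikes, window, rm, config)
    fit <- fit_trajectory_line(post, config)
    nb <- nrow(rm)
    nullR <- vapply(seq_len(n_shuffles), function(i) {
      shifts <- sample.int(nb - 1, ncol(rm), replace = TRUE)
      rshuf <- rotate_rate_matrix(rm, shifts)
      p2 <- posterior_from_counts(post$counts, rshuf, config$decode_bin_s,
                                  config$rate_floor_hz)
      fit_trajectory_line(p2, config)$R
    }, 0)
    p <- mean(nullR >= fit$R)
    out[[dir]] <- list(fit = fit, p_value = p,
                       is_replay = p < config$replay_p, null_R = nullR)
  }
  sig <- vapply(out, function(d) d$is_replay, TRUE)
  best <- NA_character_
  if (any(sig)) {
    rs <- vapply(out, function(d) d$fit$R, 0)
    rs[!sig] <- -Inf
    best <- names(out)[which.max(rs)]
  }
  out$best_direction <- best
  class(out) <- "replay_significance"
  out
}
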