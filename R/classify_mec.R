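#' Open-field ratemap (2 cm bins)
#'
#' Dwell and spikes binned on a square grid and smoothed with a separable
#' Gaussian; rate is the ratio of the smoothed maps.  Bins never visited are
#' NA.
#'
#' @param spike_times spike times (s).
#' @param position open-field position data.frame (time_s, x_cm, y_cm,
#'   hd_rad).
#' @param arena_cm arena side length (100).
#' @param bin_cm bin size (2).
#' @param sigma_bins smoothing sigma (2 bins).
#' @return List of class \code{"open_field_map"}: \code{rate} (matrix,
#'   x along rows), \code{occupancy_s}, \code{counts}, \code{mean_rate_hz}.
#' @export
open_field_map <- function(spike_times, position, arena_cm = 100,
                           bin_cm = 2, sigma_bins = 2, precomp = NULL) {
  if (is.null(precomp))
    precomp <- of_map_precompute(position, arena_cm, bin_cm, sigma_bins)
  nb <- precomp$nb
  idx <- findInterval(spike_times, position$time_s)
  idx <- idx[idx >= 1 & idx <= nrow(position)]
  cnt <- matrix(tabulate(precomp$cell_idx[idx], nbins = nb * nb), nb, nb)
  sc <- precomp$sm2(cnt)
  so <- precomp$so
  rate <- ifelse(so > 0, sc / so, 0)
  rate[precomp$occ == 0 & so == 0] <- NA
  structure(list(rate = rate, occupancy_s = precomp$occ, counts = cnt,
                 mean_rate_hz = if (precomp$tot_t > 0)
                   sum(cnt) / precomp$tot_t else NA_real_,
                 bin_cm = bin_cm, arena_cm = arena_cm),
            class = "open_field_map")
}

# occupancy, bin indices and the smoothing closure for one trajectory;
# reused across cells and across shuffles (only spike counts change)
of_map_precompute <- function(position, arena_cm = 100, bin_cm = 2,
                              sigma_bins = 2) {
  nb <- ceiling(arena_cm / bin_cm)
  dt <- stats::median(diff(position$time_s))
  bx <- pmin(pmax(floor(position$x_cm / bin_cm), 0), nb - 1) + 1
  by <- pmin(pmax(floor(position$y_cm / bin_cm), 0), nb - 1) + 1
  cell_idx <- (by - 1L) * nb + bx
  occ <- matrix(tabulate(cell_idx, nbins = nb * nb), nb, nb) * dt
  # separable smoothing; stats::filter runs over each matrix column at once
  half <- ceiling(3 * sigma_bins)
  kk <- stats::dnorm(-half:half, sd = sigma_bins); kk <- kk / sum(kk)
  colsm <- function(m) {
    n <- nrow(m)
    mp <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- stats::filter(mp, kk, sides = 2)
    matrix(out[(half + 1):(half + n), ], n, ncol(m))
  }
  wcol <- colsm(matrix(1, nb, 1))[, 1]  # edge renormalization weights
  sm2 <- function(m) {
    s <- t(colsm(t(colsm(m) / wcol))) / rep(wcol, each = nb)
    s
  }
  list(nb = nb, dt = dt, cell_idx = cell_idx, occ = occ, so = sm2(occ),
       sm2 = sm2, tot_t = sum(occ))
}

# full 2-D cross-correlation sum_i A(i) B(i + tau) via FFT, all offsets
fft_xcorr2 <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  pr <- 2 * nr - 1; pc <- 2 * nc - 1
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[1:nr, 1:nc] <- A
  pb[1:nr, 1:nc] <- B
  fa <- stats::fft(pa); fb <- stats::fft(pb)
  out <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
  # reorder so that offset (0,0) is at the center
  out[c((nr + 1):pr, 1:nr), c((nc + 1):pc, 1:nc)]
}

#' Spatial autocorrelogram of an open-field map
#'
#' Sliding Pearson correlation of the rate map with itself at every spatial
#' offset, computed over the overlapping valid bins; offsets with fewer than
#' \code{min_overlap} valid bins are NA.  The result is symmetric under 180
#' degree rotation.
#'
#' @param map an \code{"open_field_map"} or a bare rate matrix (NA = unvisited).
#' @param min_overlap minimum overlapping bins (20).
#' @return (2n-1) x (2n-1) correlation matrix.
#' @export
spatial_autocorrelogram <- function(map, min_overlap = 20) {
  M <- if (inherits(map, "open_field_map")) map$rate else map
  ok <- is.finite(M)
  Z <- ifelse(ok, M, 0)
  W <- ok * 1
  n <- fft_xcorr2(W, W)
  sx <- fft_xcorr2(Z, W)
  sy <- fft_xcorr2(W, Z)
  sxy <- fft_xcorr2(Z, Z)
  sxx <- fft_xcorr2(Z^2, W)
  syy <- fft_xcorr2(W, Z^2)
  n <- round(n)
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  r <- ifelse(n >= min_overlap & den > 1e-12, num / den, NA)
  pmin(pmax(r, -1), 1)
}

# cache of bilinear rotation stencils keyed by "nr x nc x angle"
.rot_cache <- new.env(parent = emptyenv())

rotate_matrix_bilinear <- function(M, angle_deg) {
  nr <- nrow(M); nc <- ncol(M)
  key <- paste(nr, nc, angle_deg, sep = "x")
  st <- .rot_cache[[key]]
  if (is.null(st)) {
    th <- angle_deg * pi / 180
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    g <- expand.grid(i = seq_len(nr), j = seq_len(nc))
    # source coordinates: rotate backwards
    si <- cy + cos(th) * (g$i - cy) + sin(th) * (g$j - cx)
    sj <- cx - sin(th) * (g$i - cy) + cos(th) * (g$j - cx)
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    v <- i0 >= 1 & i0 + 1 <= nr & j0 >= 1 & j0 + 1 <= nc
    id <- function(i, j) (j - 1) * nr + i
    st <- list(valid = v,
               i00 = id(i0[v], j0[v]), i10 = id(i0[v] + 1, j0[v]),
               i01 = id(i0[v], j0[v] + 1), i11 = id(i0[v] + 1, j0[v] + 1),
               w00 = (1 - fi[v]) * (1 - fj[v]), w10 = fi[v] * (1 - fj[v]),
               w01 = (1 - fi[v]) * fj[v], w11 = fi[v] * fj[v])
    .rot_cache[[key]] <- st
  }
  out <- rep(NA_real_, nr * nc)
  m <- as.numeric(M)
  out[st$valid] <- st$w00 * m[st$i00] + st$w10 * m[st$i10] +
    st$w01 * m[st$i01] + st$w11 * m[st$i11]
  matrix(out, nr, nc)
}

#' Gridness score of a spatial autocorrelogram
#'
#' Standard rotational-symmetry measure: an annulus around the central peak
#' is correlated with itself rotated by 30/60/90/120/150 degrees and the
#' score is min(corr at 60, 120) - max(corr at 30, 90, 150), maximized over
#' annulus outer radii from just outside the central peak to half the map
#' extent (1-bin steps).  The central peak radius is the first radius whose
#' ring minimum drops below zero; when no such radius exists the score is
#' undefined (NA, not a grid cell).
#'
#' @param ac autocorrelogram matrix from
#'   \code{\link{spatial_autocorrelogram}}.
#' @return Gridness score (dimensionless) or NA.
#' @export
.grid_geom_cache <- new.env(parent = emptyenv())

grid_geom <- function(nr, nc) {
  key <- paste(nr, nc, sep = "x")
  gg <- .grid_geom_cache[[key]]
  if (is.null(gg)) {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    dist <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
    ord <- order(dist)
    gg <- list(dist = dist, ord = ord, dist_sorted = dist[ord],
               rmax = floor(min(nr, nc) / 2))
    .grid_geom_cache[[key]] <- gg
  }
  gg
}

gridness_score <- function(ac) {
  nr <- nrow(ac); nc <- ncol(ac)
  gg <- grid_geom(nr, nc)
  rmax <- gg$rmax
  # central peak radius: first radius whose ring minimum goes negative
  r0 <- NA
  for (r in 1:rmax) {
    ring <- ac[gg$ord[gg$dist_sorted > r - 1 & gg$dist_sorted <= r]]
    if (length(ring) && min(ring, na.rm = TRUE) < 0) { r0 <- r; break }
  }
  if (is.na(r0) || r0 + 2 > rmax) return(NA_real_)
  rots <- c(30, 60, 90, 120, 150)
  # annuli r0 < dist <= rout are contiguous ranges of the sorted-by-distance
  # order, so Pearson correlations over all outer radii come from cumulative
  # sums in one pass per rotation
  i_start <- findInterval(r0 + 1e-9, gg$dist_sorted) + 1L
  x_all <- ac[gg$ord]
  routs <- seq(r0 + 2, rmax)
  i_ends <- findInterval(routs + 1e-9, gg$dist_sorted)
  keep <- i_ends >= i_start
  routs <- routs[keep]; i_ends <- i_ends[keep]
  if (!length(routs)) return(NA_real_)
  cors <- matrix(NA_real_, length(i_ends), 5)
  for (j in seq_along(rots)) {
    y_all <- rotate_matrix_bilinear(ac, rots[j])[gg$ord]
    okv <- is.finite(x_all) & is.finite(y_all)
    x0 <- x_all; x0[!okv] <- 0
    y0 <- y_all; y0[!okv] <- 0
    at <- function(v) { cs <- cumsum(v); cs[i_ends] - cs[i_start - 1] }
    n <- at(okv)
    sx <- at(x0); sy <- at(y0)
    sxx <- at(x0 * x0); syy <- at(y0 * y0); sxy <- at(x0 * y0)
    num <- n * sxy - sx * sy
    den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
    cors[, j] <- ifelse(n >= 20 & den > 1e-12, num / den, NA)
  }
  best <- -Inf
  for (i in seq_along(i_ends)) {
    cr <- cors[i, ]
    if (any(is.na(cr))) next
    g <- min(cr[c(2, 4)]) - max(cr[c(1, 3, 5)])
    if (g > best) best <- g
  }
  if (!is.finite(best)) return(NA_real_)
  best
}

#' Grid-cell shuffle test
#'
#' The observed gridness is compared with a null distribution from circular
#' shifts of the spike train relative to the trajectory by at least 30 s;
#' a cell is a grid cell when its score reaches the 95th percentile of its
#' own null.
#'
#' @param spike_times spike times (s) in the open-field epoch.
#' @param position open-field position data.frame.
#' @param n_shuffles null size (100).
#' @param seed integer seed.
#' @param arena_cm,bin_cm,sigma_bins map parameters.
#' @param pct null percentile (95).
#' @return List: \code{score}, \code{threshold}, \code{is_grid},
#'   \code{null_scores}.
#' @export
grid_cell_test <- function(spike_times, position, n_shuffles = 100, seed = 1,
                           arena_cm = 100, bin_cm = 2, sigma_bins = 2,
                           pct = 95) {
  t0 <- position$time_s[1]
  t1 <- position$time_s[nrow(position)]
  dur <- t1 - t0
  if (dur <= 60) stop("open-field epoch too short for a >=30 s shift null")
  pre <- of_map_precompute(position, arena_cm, bin_cm, sigma_bins)
  mk_score <- function(st) {
    m <- open_field_map(st, position, arena_cm, bin_cm, sigma_bins,
                        precomp = pre)
    gridness_score(spatial_autocorrelogram(m))
  }
  obs <- mk_score(spike_times)
  set.seed(seed)
  nulls <- vapply(seq_len(n_shuffles), function(i) {
    sh <- stats::runif(1, 30, dur - 30)
    st <- t0 + (spike_times - t0 + sh) %% dur
    s <- mk_score(sort(st))
    if (is.na(s)) -Inf else s
  }, 0)
  thr <- stats::quantile(nulls[is.finite(nulls)], pct / 100, names = FALSE)
  list(score = obs, threshold = thr,
       is_grid = !is.na(obs) && is.finite(thr) && obs >= thr,
       null_scores = nulls)
}

#' Polar (head-direction) ratemap
#'
#' Rate per 10-degree heading bin, plus its normalized form (a probability
#' distribution over the 36 bins).
#'
#' @param spike_times spike times (s).
#' @param position data.frame with time_s and hd_rad.
#' @param n_bins direction bins (36).
#' @return List of class \code{"polar_ratemap"}: \code{rate},
#'   \code{occupancy_s}, \code{tau1} (sums to 1).
#' @export
polar_ratemap <- function(spike_times, position, n_bins = 36) {
  dt <- stats::median(diff(position$time_s))
  b <- pmin(floor(position$hd_rad / (2 * pi) * n_bins), n_bins - 1) + 1
  occ <- tabulate(b, nbins = n_bins) * dt
  idx <- findInterval(spike_times, position$time_s)
  idx <- idx[idx >= 1 & idx <= nrow(position)]
  cnt <- tabulate(b[idx], nbins = n_bins)
  rate <- ifelse(occ > 0, cnt / occ, 0)
  tot <- sum(rate)
  structure(list(rate = rate, occupancy_s = occ,
                 tau1 = if (tot > 0) rate / tot else rep(NA_real_, n_bins)),
            class = "polar_ratemap")
}

#' Kullback-Leibler directionality of a polar ratemap
#'
#' D_KL = sum_i tau1(i) ln(tau1(i) / tau2(i)) against the uniform
#' distribution tau2 with the same number of bins; empty bins contribute
#' zero.  Natural log; the 0.10 directionality threshold is calibrated on
#' this scale.
#'
#' @param tau1 normalized polar ratemap (sums to 1), or a
#'   \code{"polar_ratemap"}.
#' @return D_KL in nats (>= 0, 0 iff uniform).
#' @export
kl_directionality <- function(tau1) {
  if (inherits(tau1, "polar_ratemap")) tau1 <- tau1$tau1
  if (!length(tau1) || any(is.na(tau1))) stop("empty polar map")
  if (abs(sum(tau1) - 1) > 1e-6) stop("tau1 must sum to 1")
  n <- length(tau1)
  pos <- tau1 > 0
  sum(tau1[pos] * log(tau1[pos] * n))
}

# connected components (4-neighborhood) of a logical matrix
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      for (q in c(if (i > 1) p - 1, if (i < nr) p + 1,
                  if (j > 1) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Border score of an open-field map
#'
#' Firing fields are connected groups of bins above 30\% of the peak rate
#' covering less than 70\% of the arena.  The score is
#' (cM - dbar) / (cM + dbar), where cM is the largest fraction of any single
#' wall covered by a single field and dbar the firing-rate-weighted mean
#' distance of field bins to the nearest wall, normalized by half the arena
#' width.  Cells with a score above 0.5 are border cells.
#'
#' @param map an \code{"open_field_map"}.
#' @return List: \code{score} in [-1, 1] (NA when no field),
#'   \code{n_fields}.
#' @export
border_score <- function(map) {
  M <- map$rate
  M[is.na(M)] <- 0
  pk <- max(M)
  if (pk <= 0) return(list(score = NA_real_, n_fields = 0L))
  nb <- nrow(M)
  lab <- connected_components(M > 0.3 * pk)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > 0 & sizes < 0.7 * nb * nb)
  if (!length(keep)) return(list(score = NA_real_, n_fields = 0L))
  cm <- 0
  for (f in keep) {
    sel <- lab == f
    cov <- c(mean(sel[1, ]), mean(sel[nb, ]), mean(sel[, 1]), mean(sel[, nb]))
    cm <- max(cm, cov)
  }
  field_mask <- lab %in% keep & lab > 0
  ii <- row(M)[field_mask]; jj <- col(M)[field_mask]
  w <- M[field_mask]
  dwall <- pmin(ii - 1, nb - ii, jj - 1, nb - jj) + 0.5  # bins to wall
  dbar <- sum(w * dwall) / sum(w) / (nb / 2)
  list(score = (cm - dbar) / (cm + dbar), n_fields = length(keep))
}

#' Classify a dMEC cell into functional types
#'
#' Precedence: grid (conjunctive when also directional) > border >
#' head direction > other spatial (Skaggs information > 1 bit/spike) >
#' unclassified.  Cells with mean rate above 7 Hz are excluded
#' ("interneuron").  Directionality uses D_KL > 0.10 on the cell's polar
#' map; the same criterion distinguishes conjunctive from pure grid cells.
#'
#' @param spike_times spike times (s) in the classification epoch.
#' @param position position data.frame for that epoch (open field by
#'   default; a track trace may be substituted for the track-based variant,
#'   bar grid classification).
#' @param config analysis configuration.
#' @param n_shuffles gridness null size (100).
#' @param seed integer seed.
#' @param arena_cm arena side (100).
#' @return List of class \code{"dmec_classification"}: \code{class},
#'   \code{gridness}, \code{gridness_threshold}, \code{kl}, \code{border},
#'   \code{skaggs}, \code{mean_rate_hz}.
#' @export
classify_dmec <- function(spike_times, position, config = default_config(),
                          n_shuffles = 100, seed = 1, arena_cm = 100) {
  map <- open_field_map(spike_times, position, arena_cm)
  mean_rate <- map$mean_rate_hz
  res <- list(class = "unclassified", gridness = NA_real_,
              gridness_threshold = NA_real_, kl = NA_real_,
              border = NA_real_, skaggs = NA_real_, mean_rate_hz = mean_rate)
  class(res) <- "dmec_classification"
  if (is.na(mean_rate)) return(res)
  if (mean_rate > config$dmec_rate_cap_hz) {
    res$class <- "interneuron"
    return(res)
  }
  pol <- polar_ratemap(spike_times, position)
  res$kl <- if (any(is.na(pol$tau1))) NA_real_ else kl_directionality(pol)
  gt <- grid_cell_test(spike_times, position, n_shuffles = n_shuffles,
                       seed = seed, arena_cm = arena_cm, pct = config$gridness_pct)
  res$gridness <- gt$score
  res$gridness_threshold <- gt$threshold
  bs <- border_score(map)
  res$border <- bs$score
  occv <- as.numeric(map$occupancy_s)
  ratev <- as.numeric(map$rate)
  ratev[is.na(ratev)] <- 0
  res$skaggs <- if (sum(ratev * occv) > 0) skaggs_information(ratev, occv)
                else NA_real_
  directional <- !is.na(res$kl) && res$kl > config$kl_thresh
  if (isTRUE(gt$is_grid)) {
    res$class <- if (directional) "conjunctive" else "grid"
  } else if (!is.na(res$border) && res$border > config$border_thresh) {
    res$class <- "border"
  } else if (directional) {
    res$class <- "head_direction"
  } else if (!is.na(res$skaggs) && res$skaggs > config$skaggs_thresh) {
    res$class <- "other_spatial"
  }
  res
}
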