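#' Z-track geometry
#'
#' The elevated Z-shaped track: two parallel arms of 190 cm joined by a
#' 220 cm diagonal, linearized to a single 600 cm coordinate binned at 2 cm
#' (300 bins).  The final 10 cm at either end and 5 cm around each of the two
#' corners are excluded from ratemaps (non-perambulatory behavior zones).
#'
#' The 2-D skeleton places the first arm at height H = sqrt(220^2 - 190^2)
#' (about 110.9 cm), the diagonal running down to the origin, and the second
#' arm along y = 0, so that arc length along the skeleton equals the
#' linearized coordinate.
#'
#' @param arm_cm length of each parallel arm (190).
#' @param diag_cm length of the diagonal section (220).
#' @param bin_cm spatial bin size (2).
#' @param end_excl_cm excluded zone at each track end (10).
#' @param corner_excl_cm excluded zone around each corner (5).
#' @return A list of class \code{"track_geometry"} with the segment table,
#'   total length, bin size/count and exclusion windows (in linearized cm).
#' @export
#' @examples
#' geom <- track_geometry()
#' geom$total_cm  # 600
track_geometry <- function(arm_cm = 190, diag_cm = 220, bin_cm = 2,
                           end_excl_cm = 10, corner_excl_cm = 5) {
  stopifnot(arm_cm > 0, diag_cm > arm_cm, bin_cm > 0)
  h <- sqrt(diag_cm^2 - arm_cm^2)
  # vertices: arm1 left->right (top), diagonal right-top -> left-bottom, arm2
  verts <- rbind(c(0, h), c(arm_cm, h), c(0, 0), c(arm_cm, 0))
  seg_len <- c(arm_cm, diag_cm, arm_cm)
  cum0 <- c(0, cumsum(seg_len))
  total <- cum0[4]
  corners <- cum0[2:3]
  excl <- rbind(
    c(0, end_excl_cm),
    c(total - end_excl_cm, total),
    c(corners[1] - corner_excl_cm, corners[1] + corner_excl_cm),
    c(corners[2] - corner_excl_cm, corners[2] + corner_excl_cm)
  )
  structure(list(
    vertices = verts, seg_len = seg_len, seg_start = cum0[1:3],
    total_cm = total, bin_cm = bin_cm, n_bins = as.integer(round(total / bin_cm)),
    corners_cm = corners, excluded_cm = excl,
    arm_cm = arm_cm, diag_cm = diag_cm,
    end_excl_cm = end_excl_cm, corner_excl_cm = corner_excl_cm
  ), class = "track_geometry")
}

#' @export
print.track_geometry <- function(x, ...) {
  cat("<track_geometry> ", x$total_cm, " cm linearized, ",
      x$n_bins, " bins of ", x$bin_cm, " cm\n", sep = "")
  invisible(x)
}

#' Map linearized coordinates to 2-D track coordinates
#'
#' @param lin_cm numeric vector of linearized positions (cm, 0..600).
#' @param geom a \code{\link{track_geometry}}.
#' @return A two-column matrix of (x, y) in cm.
#' @export
lin_to_xy <- function(lin_cm, geom) {
  lin <- pmin(pmax(lin_cm, 0), geom$total_cm)
  seg <- findInterval(lin, c(geom$seg_start, Inf), rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), 3L)
  frac <- (lin - geom$seg_start[seg]) / geom$seg_len[seg]
  v <- geom$vertices
  a <- rbind(v[1, ], v[2, ], v[3, ])[seg, , drop = FALSE]
  b <- rbind(v[2, ], v[3, ], v[4, ])[seg, , drop = FALSE]
  a + frac * (b - a)
}

#' Project 2-D coordinates onto the track skeleton
#'
#' Each (x, y) sample is mapped to the nearest point on the piecewise-linear
#' skeleton; the result is the arc-length coordinate of that point plus the
#' off-track distance.
#'
#' @param x,y numeric vectors of coordinates (cm).
#' @param geom a \code{\link{track_geometry}}.
#' @return A list with \code{lin_cm} (arc length of the projection) and
#'   \code{dist_cm} (distance from sample to skeleton).
#' @export
xy_to_lin <- function(x, y, geom) {
  v <- geom$vertices
  seg_a <- rbind(v[1, ], v[2, ], v[3, ])
  seg_b <- rbind(v[2, ], v[3, ], v[4, ])
  n <- length(x)
  best_d2 <- rep(Inf, n)
  best_lin <- numeric(n)
  for (s in 1:3) {
    ax <- seg_a[s, 1]; ay <- seg_a[s, 2]
    dx <- seg_b[s, 1] - ax; dy <- seg_b[s, 2] - ay
    len2 <- dx * dx + dy * dy
    t <- ((x - ax) * dx + (y - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- ax + t * dx; py <- ay + t * dy
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lin[upd] <- geom$seg_start[s] + t[upd] * geom$seg_len[s]
  }
  list(lin_cm = best_lin, dist_cm = sqrt(best_d2))
}

#' Per-bin exclusion mask for the linearized track
#'
#' @param geom a \code{\link{track_geometry}}.
#' @return Logical vector of length \code{geom$n_bins}; TRUE for bins whose
#'   center falls inside an excluded zone.  Bins are 0-based half-open:
#'   bin k covers [2k, 2k+2) cm.
#' @export
excluded_bins <- function(geom) {
  centers <- (seq_len(geom$n_bins) - 0.5) * geom$bin_cm
  excl <- rep(FALSE, geom$n_bins)
  for (i in seq_len(nrow(geom$excluded_cm))) {
    excl <- excl | (centers >= geom$excluded_cm[i, 1] &
                    centers <= geom$excluded_cm[i, 2])
  }
  excl
}

#' Flag samples inside excluded track zones
#'
#' @param lin_cm linearized positions (cm).
#' @param geom a \code{\link{track_geometry}}.
#' @return Logical vector, TRUE where the sample lies in an excluded zone.
#' @export
in_excluded_zone <- function(lin_cm, geom) {
  out <- rep(FALSE, length(lin_cm))
  for (i in seq_len(nrow(geom$excluded_cm))) {
    out <- out | (lin_cm >= geom$excluded_cm[i, 1] &
                  lin_cm <= geom$excluded_cm[i, 2])
  }
  out
}
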