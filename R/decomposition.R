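# Decomposition of a six-dot sequence into the posture element (body-frame
# motion of the dots) and the motion-trajectory element (path of the centre
# of mass), and their recomposition into a stimulus.

#' Travel angle of a dot frame
#'
#' Angle of the vector from p6 to p1 (tail to head) in screen coordinates;
#' counter-clockwise positive, 0 = +x.
#'
#' @param p numeric 6 x 2 matrix, one dot frame (rows p1..p6).
#' @return angle in radians in (-pi, pi].
#' @export
travel_angle <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 6L, ncol(p) == 2L)
  v <- p[1, ] - p[6, ]
  if (all(v == 0)) stop("p1 equals p6: travel angle undefined")
  atan2(v[2], v[1])
}

#' Extract the motion-trajectory element
#'
#' Per-frame centre of mass and travel angle. The centre of mass is the area
#' centroid of the matching contour when contours are supplied; without
#' contours it falls back to the arithmetic mean of the six dots. The travel
#' angle is the p1-p6 angle of the same frame; a frame with p1 = p6 carries
#' the previous frame's angle (an error on the first frame).
#'
#' @param dots a [dot_sequence()].
#' @param contours optional [contour_sequence()] with matching frame count.
#' @return a [trajectory()].
#' @export
extract_trajectory <- function(dots, contours = NULL) {
  stopifnot(inherits(dots, "dot_sequence"))
  nf <- dim(dots$coords)[1]
  if (!is.null(contours)) {
    stopifnot(inherits(contours, "contour_sequence"))
    if (length(contours$frames) != nf)
      stop("contour and dot sequences have different frame counts")
    com <- t(vapply(contours$frames, polygon_centroid, numeric(2)))
  } else {
    com <- cbind(rowMeans(dots$coords[, , 1, drop = FALSE]),
                 rowMeans(dots$coords[, , 2, drop = FALSE]))
  }
  angle <- numeric(nf)
  for (i in seq_len(nf)) {
    p <- dots$coords[i, , ]
    if (all(p[1, ] == p[6, ])) {
      if (i == 1L) stop("p1 equals p6 on the first frame")
      angle[i] <- angle[i - 1]
    } else {
      angle[i] <- travel_angle(p)
    }
  }
  trajectory(com, angle, fps = dots$fps)
}

#' Extract the posture element
#'
#' Expresses each frame's dots in the rotated body frame: translate by minus
#' the centre of mass, then rotate by minus the travel angle, so the centre
#' of mass is at the origin and the centre line lies along +x with the head
#' (p1) on the positive side. No re-centering is applied when the centre of
#' mass comes from the contour rather than the dot mean.
#'
#' @param dots a [dot_sequence()].
#' @param traj a [trajectory()] with matching frame count (typically from
#'   [extract_trajectory()]).
#' @return a [posture_sequence()].
#' @export
extract_posture <- function(dots, traj) {
  stopifnot(inherits(dots, "dot_sequence"), inherits(traj, "trajectory"))
  nf <- dim(dots$coords)[1]
  if (nrow(traj$com) != nf) stop("frame counts differ")
  out <- array(NA_real_, dim(dots$coords))
  ca <- cos(traj$angle); sa <- sin(traj$angle)
  for (i in seq_len(nf)) {
    dx <- dots$coords[i, , 1] - traj$com[i, 1]
    dz <- dots$coords[i, , 2] - traj$com[i, 2]
    out[i, , 1] <-  ca[i] * dx + sa[i] * dz
    out[i, , 2] <- -sa[i] * dx + ca[i] * dz
  }
  posture_sequence(out, fps = dots$fps)
}

#' Recompose posture and trajectory into a dot sequence
#'
#' Inverse of the decomposition: per frame, rotate the body-frame dots by the
#' travel angle and translate by the centre of mass. With the posture and
#' trajectory extracted from the same sequence this reproduces it exactly
#' (roundtrip identity). When the two factors have different lengths the
#' shorter one is recycled only if `loop = TRUE`; otherwise it is an error.
#'
#' @param posture a [posture_sequence()].
#' @param traj a [trajectory()].
#' @param loop recycle the shorter factor circularly.
#' @return a [dot_sequence()].
#' @export
recompose <- function(posture, traj, loop = FALSE) {
  stopifnot(inherits(posture, "posture_sequence"), inherits(traj, "trajectory"))
  if (posture$fps != traj$fps) stop("fps of posture and trajectory differ")
  np <- dim(posture$coords)[1]
  nt <- nrow(traj$com)
  if (np != nt && !loop)
    stop("frame counts differ (", np, " vs ", nt, "); set loop = TRUE to recycle")
  nf <- max(np, nt)
  out <- array(NA_real_, c(nf, 6L, 2L))
  ca <- cos(traj$angle); sa <- sin(traj$angle)
  for (i in seq_len(nf)) {
    ip <- (i - 1L) %% np + 1L
    it <- (i - 1L) %% nt + 1L
    bx <- posture$coords[ip, , 1]
    bz <- posture$coords[ip, , 2]
    out[i, , 1] <- ca[it] * bx - sa[it] * bz + traj$com[it, 1]
    out[i, , 2] <- sa[it] * bx + ca[it] * bz + traj$com[it, 2]
  }
  dot_sequence(out, fps = traj$fps)
}

#' Time-constant straight-line posture ("no posture motion")
#'
#' The posture factor of the bio-trajectory and non-bio stimuli: six dots
#' fixed on the body-frame centre line at regular intervals, centred on the
#' origin, head-most dot at +2.5 * spacing. Its temporal variance is zero in
#' every coordinate.
#'
#' @param spacing consecutive dot spacing, mm (> 0).
#' @param n_frames number of frames.
#' @param fps frame rate, frames per second.
#' @return a [posture_sequence()].
#' @export
no_posture <- function(spacing, n_frames, fps) {
  stopifnot(spacing > 0, n_frames >= 1, fps > 0)
  xs <- spacing * seq(2.5, -2.5, by = -1)
  coords <- array(0, c(n_frames, 6L, 2L))
  coords[, , 1] <- matrix(xs, n_frames, 6L, byrow = TRUE)
  posture_sequence(coords, fps = fps)
}
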