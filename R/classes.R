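#' Contour sequence
#'
#' Ordered per-frame closed polygons outlining a fish in the screen plane.
#' Polygons are stored as n x 2 matrices of (x, z) vertices in mm; the closing
#' edge from the last vertex back to the first is implicit.
#'
#' @param frames list of numeric matrices, one polygon per frame (>= 8 vertices
#'   each, 2 columns).
#' @param fps frame rate, frames per second.
#' @param units coordinate units (informational; always mm in this package).
#' @return An object of class `contour_sequence` with fields `frames`, `fps`,
#'   `units`.
#' @export
contour_sequence <- function(frames, fps, units = "mm") {
  stopifnot(is.list(frames), length(frames) >= 1L, is.numeric(fps), fps > 0)
  for (f in frames) {
    stopifnot(is.matrix(f), ncol(f) == 2L, nrow(f) >= 8L, all(is.finite(f)))
  }
  structure(list(frames = frames, fps = fps, units = units),
            class = "contour_sequence")
}

#' @export
print.contour_sequence <- function(x, ...) {
  cat(sprintf("<contour_sequence> %d frames at %g fps (%s), %d-%d vertices\n",
              length(x$frames), x$fps, x$units,
              min(vapply(x$frames, nrow, 1L)),
              max(vapply(x$frames, nrow, 1L))))
  invisible(x)
}

#' Six-dot point-light sequence
#'
#' The currency of the stimulus pipeline: per-frame positions of the six
#' point-light dots p1..p6, ordered head to tail, in screen coordinates (mm).
#'
#' @param coords numeric array of dimension (frames, 6, 2); `coords[i, d, ]`
#'   is the (x, z) position of dot d in frame i.
#' @param fps frame rate, frames per second.
#' @return An object of class `dot_sequence`.
#' @export
dot_sequence <- function(coords, fps) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 6L, dim(coords)[3] == 2L,
            all(is.finite(coords)), is.numeric(fps), fps > 0)
  structure(list(coords = coords, fps = fps), class = "dot_sequence")
}

#' @export
print.dot_sequence <- function(x, ...) {
  cat(sprintf("<dot_sequence> %d frames x 6 dots at %g fps\n",
              dim(x$coords)[1], x$fps))
  invisible(x)
}

#' Posture sequence (body-frame dots)
#'
#' Six dots per frame expressed in the rotated body frame: origin at the
#' centre of mass, centre line along +x with the head on the positive side.
#'
#' @param coords numeric array (frames, 6, 2) of body-frame (x, z), mm.
#' @param fps frame rate, frames per second.
#' @return An object of class `posture_sequence`.
#' @export
posture_sequence <- function(coords, fps) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 6L, dim(coords)[3] == 2L,
            all(is.finite(coords)), is.numeric(fps), fps > 0)
  structure(list(coords = coords, fps = fps), class = "posture_sequence")
}

#' @export
print.posture_sequence <- function(x, ...) {
  cat(sprintf("<posture_sequence> %d frames x 6 dots at %g fps\n",
              dim(x$coords)[1], x$fps))
  invisible(x)
}

#' Motion trajectory
#'
#' Per-frame centre-of-mass position and travel angle: the entire-field
#' (motion-trajectory) element of a moving stimulus.
#'
#' @param com numeric matrix (frames x 2) of centre-of-mass (x, z), mm.
#' @param angle numeric vector of travel angles, radians, wrapped to
#'   (-pi, pi], counter-clockwise positive, 0 = +x.
#' @param fps frame rate, frames per second.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(com, angle, fps) {
  stopifnot(is.matrix(com), ncol(com) == 2L, all(is.finite(com)),
            is.numeric(angle), length(angle) == nrow(com),
            all(is.finite(angle)), is.numeric(fps), fps > 0)
  angle <- wrap_angle(angle)
  structure(list(com = com, angle = angle, fps = fps), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames at %g fps, mean speed %.2f mm/s\n",
              nrow(x$com), x$fps,
              if (nrow(x$com) >= 2) mean_speed(x) else NA_real_))
  invisible(x)
}

# wrap radians to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Behavioural track
#'
#' Top-view position time series of a test fish, with the y coordinate the
#' distance toward the stimulus display (smaller = closer) and the stimulus
#' onset time recorded.
#'
#' @param t time, seconds, strictly increasing.
#' @param x,y positions, mm.
#' @param onset stimulus onset time, seconds.
#' @param fps nominal frame rate, frames per second.
#' @return A data frame of class `behavior_track` with columns `t`, `x`, `y`
#'   and attributes `onset`, `fps`.
#' @export
behavior_track <- function(t, x, y, onset, fps) {
  stopifnot(is.numeric(t), all(diff(t) > 0), length(x) == length(t),
            length(y) == length(t), all(is.finite(c(t, x, y))),
            is.numeric(onset), onset >= 0, fps > 0)
  structure(data.frame(t = t, x = x, y = y),
            onset = onset, fps = fps,
            class = c("behavior_track", "data.frame"))
}

#' Number of frames of a pipeline object
#'
#' @param x a `contour_sequence`, `dot_sequence`, `posture_sequence`,
#'   `trajectory`, `stimulus_clip` or `behavior_track`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "contour_sequence")) return(length(x$frames))
  if (inherits(x, "dot_sequence") || inherits(x, "posture_sequence"))
    return(dim(x$coords)[1])
  if (inherits(x, "trajectory")) return(nrow(x$com))
  if (inherits(x, "stimulus_clip")) return(dim(x$dots$coords)[1])
  if (inherits(x, "behavior_track")) return(nrow(x))
  stop("no frame count for objects of class ", paste(class(x), collapse = "/"))
}
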