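# Synthesis of the 2x2 stimulus family: biological vs non-biological posture
# crossed with biological vs non-biological trajectory.

STIMULUS_LABELS <- c("biomotion", "bio-posture", "bio-trajectory", "non-bio")

#' Screen region for stimulus presentation
#'
#' @param width,height stimulus area, mm.
#' @param margin dot-to-edge clearance, mm.
#' @return list of class `screen_region`.
#' @export
screen_region <- function(width = 150, height = 150, margin = 10) {
  stopifnot(width > 2 * margin, height > 2 * margin, margin >= 0)
  structure(list(width = width, height = height, margin = margin),
            class = "screen_region")
}

#' Non-biological trajectory: constant speed, random turns at the edges
#'
#' Piecewise-linear motion with a per-frame step of exactly `speed / fps`.
#' When the next step would leave the margin-inset rectangle, a new heading
#' is drawn uniformly from the directions pointing at least 20 degrees into
#' the interior of the contacted wall (so the path cannot graze along the
#' boundary); the travel angle equals the instantaneous heading.
#'
#' @param region a [screen_region()].
#' @param speed constant speed, mm/s (> 0); usually the [mean_speed()] of a
#'   biological trajectory.
#' @param duration clip length, seconds.
#' @param fps frame rate, frames per second.
#' @param seed integer seed.
#' @param grazing_deg minimum angle from the wall, degrees.
#' @return a [trajectory()].
#' @export
synthesize_nonbio_trajectory <- function(region, speed, duration, fps = 30,
                                         seed = NULL, grazing_deg = 20) {
  stopifnot(inherits(region, "screen_region"), speed > 0, duration > 0)
  step <- speed / fps
  lo <- c(region$margin, region$margin)
  hi <- c(region$width - region$margin, region$height - region$margin)
  if (step >= min(hi - lo)) stop("per-frame step exceeds the region extent")
  n <- round(duration * fps)
  graze <- grazing_deg * pi / 180
  inside <- function(p) all(p >= lo) && all(p <= hi)
  with_seed(seed, {
    pos <- matrix(NA_real_, n, 2)
    ang <- numeric(n)
    pos[1, ] <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    th <- runif(1, 0, 2 * pi)
    if (n >= 2) for (i in 1:(n - 1)) {
      cand <- pos[i, ] + step * c(cos(th), sin(th))
      if (!inside(cand)) {
        # inward normals of the walls the step would cross
        normals <- list()
        if (cand[1] < lo[1]) normals <- c(normals, list(0))
        if (cand[1] > hi[1]) normals <- c(normals, list(pi))
        if (cand[2] < lo[2]) normals <- c(normals, list(pi / 2))
        if (cand[2] > hi[2]) normals <- c(normals, list(-pi / 2))
        ok <- FALSE
        for (try in 1:400) {
          th_new <- runif(1, 0, 2 * pi)
          if (!all(vapply(normals, function(nrm)
            abs(wrap_angle(th_new - nrm)) <= pi / 2 - graze, TRUE))) next
          cand <- pos[i, ] + step * c(cos(th_new), sin(th_new))
          if (inside(cand)) { th <- th_new; ok <- TRUE; break }
        }
        if (!ok) {          # pathological corner: aim at the region centre
          th <- atan2(mean(lo[2] + hi[2]) / 2 - pos[i, 2],
                      mean(lo[1] + hi[1]) / 2 - pos[i, 1])
          cand <- pos[i, ] + step * c(cos(th), sin(th))
        }
      }
      ang[i] <- th
      pos[i + 1, ] <- cand
    }
    ang[n] <- th
    trajectory(pos, ang, fps = fps)
  })
}

#' Mean speed of a trajectory
#'
#' Mean per-frame centre-of-mass displacement times the frame rate.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @return speed in mm/s.
#' @export
mean_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj$com) < 2) stop("mean speed needs at least 2 frames")
  mean(sqrt(rowSums(diff(traj$com)^2))) * traj$fps
}

#' Compose a stimulus clip from posture and trajectory factors
#'
#' Recombines a posture factor (a biological [posture_sequence()] or `NULL`
#' for the straight-line no-posture configuration) with a trajectory factor
#' (biological or non-biological) into one of the four stimulus classes,
#' looped `loop_count` times with no interstimulus interval.
#'
#' @param posture a [posture_sequence()] or `NULL`; when `NULL`, a
#'   [no_posture()] configuration with dot interval `spacing` is used.
#' @param traj a [trajectory()] of the same fps and frame count.
#' @param label one of `"biomotion"`, `"bio-posture"`, `"bio-trajectory"`,
#'   `"non-bio"`.
#' @param loop_count number of back-to-back repeats of the clip.
#' @param spacing dot spacing, mm, required when `posture` is `NULL`;
#'   typically [mean_dot_spacing()] of the source biological sequence so the
#'   total extent matches the fish.
#' @return list of class `stimulus_clip` with fields `dots`
#'   (a [dot_sequence()] over all loops), `label`, `fps`, `duration_s` (one
#'   loop), `loop_count`.
#' @export
compose_stimulus <- function(posture, traj, label, loop_count = 5,
                             spacing = NULL) {
  label <- match.arg(label, STIMULUS_LABELS)
  stopifnot(inherits(traj, "trajectory"), loop_count >= 1)
  nf <- nrow(traj$com)
  if (is.null(posture)) {
    if (is.null(spacing)) stop("spacing is required when posture is NULL")
    posture <- no_posture(spacing, nf, traj$fps)
  }
  stopifnot(inherits(posture, "posture_sequence"))
  if (posture$fps != traj$fps) stop("fps of posture and trajectory differ")
  if (dim(posture$coords)[1] != nf) stop("factor durations differ")
  one <- recompose(posture, traj)
  coords <- one$coords
  if (loop_count > 1) {
    idx <- rep(seq_len(nf), loop_count)
    coords <- coords[idx, , , drop = FALSE]
  }
  structure(list(dots = dot_sequence(coords, traj$fps), label = label,
                 fps = traj$fps, duration_s = nf / traj$fps,
                 loop_count = as.integer(loop_count)),
            class = "stimulus_clip")
}

#' @export
print.stimulus_clip <- function(x, ...) {
  cat(sprintf("<stimulus_clip> %s: %d frames (%g s x %d loops) at %g fps\n",
              x$label, dim(x$dots$coords)[1], x$duration_s, x$loop_count,
              x$fps))
  invisible(x)
}

#' Mean consecutive-dot spacing of a dot sequence
#'
#' Average over frames and adjacent dot pairs of the inter-dot distance;
#' the default spacing for the no-posture configuration.
#'
#' @param dots a [dot_sequence()].
#' @return spacing in mm.
#' @export
mean_dot_spacing <- function(dots) {
  stopifnot(inherits(dots, "dot_sequence"))
  d <- dots$coords[, 2:6, , drop = FALSE] - dots$coords[, 1:5, , drop = FALSE]
  mean(sqrt(d[, , 1]^2 + d[, , 2]^2))
}

#' Build the full 2x2 stimulus family from a tracked sequence
#'
#' From a biological six-dot sequence, extracts the posture and trajectory
#' elements, draws one non-biological trajectory matched to the biological
#' mean speed, and composes the four clips sharing those factors:
#' biomotion (bio posture + bio trajectory), bio-posture (bio posture +
#' non-bio trajectory), bio-trajectory (no posture + bio trajectory) and
#' non-bio (no posture + non-bio trajectory).
#'
#' @param dots a biological [dot_sequence()] (one loop).
#' @param region a [screen_region()] for the non-biological trajectory.
#' @param loop_count repeats per clip.
#' @param seed integer seed for the non-biological trajectory.
#' @return named list of four [compose_stimulus()] clips plus the shared
#'   factors (`posture_bio`, `traj_bio`, `traj_nonbio`, `spacing`).
#' @export
make_stimulus_set <- function(dots, region = screen_region(), loop_count = 1,
                              seed = NULL) {
  stopifnot(inherits(dots, "dot_sequence"))
  traj_bio <- extract_trajectory(dots)
  posture_bio <- extract_posture(dots, traj_bio)
  spacing <- mean_dot_spacing(dots)
  nf <- dim(dots$coords)[1]
  traj_nonbio <- synthesize_nonbio_trajectory(
    region, speed = mean_speed(traj_bio), duration = nf / dots$fps,
    fps = dots$fps, seed = seed)
  list(
    biomotion = compose_stimulus(posture_bio, traj_bio, "biomotion",
                                 loop_count),
    `bio-posture` = compose_stimulus(posture_bio, traj_nonbio, "bio-posture",
                                     loop_count),
    `bio-trajectory` = compose_stimulus(NULL, traj_bio, "bio-trajectory",
                                        loop_count, spacing = spacing),
    `non-bio` = compose_stimulus(NULL, traj_nonbio, "non-bio", loop_count,
                                 spacing = spacing),
    posture_bio = posture_bio, traj_bio = traj_bio,
    traj_nonbio = traj_nonbio, spacing = spacing)
}
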