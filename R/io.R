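# Plain-text interchange formats: JSON-lines contours, CSV dot/posture/
# trajectory/behaviour tables with JSON sidecars for metadata.

#' Write and read contour sequences as JSON-lines
#'
#' One JSON object per line per frame:
#' `{"frame": i, "t_s": t, "vertices": [[x_mm, z_mm], ...]}`. The frame rate
#' is recovered on read from the `t_s` spacing.
#'
#' @param contours a [contour_sequence()].
#' @param path file path.
#' @return `write_contours_jsonl` returns `path` invisibly;
#'   `read_contours_jsonl` returns a [contour_sequence()].
#' @export
write_contours_jsonl <- function(contours, path) {
  stopifnot(inherits(contours, "contour_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(contours$frames)) {
    writeLines(jsonlite::toJSON(list(
      frame = i, t_s = (i - 1) / contours$fps,
      vertices = unname(contours$frames[[i]])), auto_unbox = TRUE,
      digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_contours_jsonl
#' @export
read_contours_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  frames <- lapply(recs, function(r) matrix(r$vertices, ncol = 2))
  fps <- if (length(recs) >= 2) 1 / (recs[[2]]$t_s - recs[[1]]$t_s) else 30
  contour_sequence(frames, fps = fps)
}

#' Write and read dot sequences as CSV
#'
#' Long format with header `frame,t_s,dot_id,x_mm,z_mm` (dot_id 1..6).
#'
#' @param dots a [dot_sequence()].
#' @param path file path.
#' @return `write_dots_csv` returns `path` invisibly; `read_dots_csv`
#'   returns a [dot_sequence()].
#' @export
write_dots_csv <- function(dots, path) {
  stopifnot(inherits(dots, "dot_sequence"))
  nf <- dim(dots$coords)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = 6L),
    t_s = rep((seq_len(nf) - 1) / dots$fps, each = 6L),
    dot_id = rep(1:6, nf),
    x_mm = as.numeric(t(dots$coords[, , 1])),
    z_mm = as.numeric(t(dots$coords[, , 2])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dots_csv
#' @export
read_dots_csv <- function(path) {
  df <- read.csv(path)
  nf <- max(df$frame)
  coords <- array(NA_real_, c(nf, 6L, 2L))
  ord <- order(df$frame, df$dot_id)
  coords[, , 1] <- matrix(df$x_mm[ord], nf, 6L, byrow = TRUE)
  coords[, , 2] <- matrix(df$z_mm[ord], nf, 6L, byrow = TRUE)
  fps <- if (nf >= 2) 1 / (df$t_s[df$frame == 2][1] - df$t_s[df$frame == 1][1])
         else 30
  dot_sequence(coords, fps = fps)
}

#' Write a behavioural track as CSV with a JSON sidecar
#'
#' CSV header `frame,t_s,x_mm,y_mm`; the stimulus onset and frame rate go to
#' `<path>.json` as `{"onset_s": ..., "fps": ...}`.
#'
#' @param track a [behavior_track()].
#' @param path CSV file path.
#' @return `write_behavior_csv` returns `path` invisibly;
#'   `read_behavior_csv` returns a [behavior_track()].
#' @export
write_behavior_csv <- function(track, path) {
  stopifnot(inherits(track, "behavior_track"))
  df <- data.frame(frame = seq_len(nrow(track)), t_s = track$t,
                   x_mm = track$x, y_mm = track$y)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(onset_s = attr(track, "onset"),
                            fps = attr(track, "fps")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  behavior_track(df$t_s, df$x_mm, df$y_mm, onset = meta$onset_s,
                 fps = meta$fps)
}

#' Write a trajectory or posture sequence as CSV
#'
#' Trajectory: `frame,t_s,x_mm,z_mm,angle_rad`. Posture:
#' `frame,t_s,dot_id,xb_mm,zb_mm`.
#'
#' @param traj a [trajectory()].
#' @param posture a [posture_sequence()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- nrow(traj$com)
  df <- data.frame(frame = seq_len(nf), t_s = (seq_len(nf) - 1) / traj$fps,
                   x_mm = traj$com[, 1], z_mm = traj$com[, 2],
                   angle_rad = traj$angle)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_posture_csv <- function(posture, path) {
  stopifnot(inherits(posture, "posture_sequence"))
  nf <- dim(posture$coords)[1]
  df <- data.frame(
    frame = rep(seq_len(nf), each = 6L),
    t_s = rep((seq_len(nf) - 1) / posture$fps, each = 6L),
    dot_id = rep(1:6, nf),
    xb_mm = as.numeric(t(posture$coords[, , 1])),
    zb_mm = as.numeric(t(posture$coords[, , 2])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
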