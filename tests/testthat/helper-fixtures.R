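# Small geometric fixtures built in code.

# regular n-gon approximating a circle of given circumference
circle_polygon <- function(circumference = 14, n = 280) {
  # chord-corrected radius so the polygon perimeter equals `circumference`
  r <- circumference / (2 * n * sin(pi / n))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

ellipse_polygon <- function(a = 20, b = 5, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# L-shaped hexagon with analytic centroid (2.5/3, 2.5/3)
l_shape <- function() {
  cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
}

# a random six-dot sequence with p1 != p6 everywhere
random_dot_sequence <- function(n_frames, fps = 30) {
  coords <- array(runif(n_frames * 12, 20, 130), c(n_frames, 6L, 2L))
  coords[, 1, 1] <- coords[, 6, 1] + runif(n_frames, 5, 15)  # separate head
  dot_sequence(coords, fps = fps)
}

# a smooth, fish-like six-dot sequence: slowly meandering centre path with a
# gently undulating line of dots (structured enough that circular windows of
# the clip generalize to one another)
smooth_dot_sequence <- function(n_frames, fps = 30) {
  t <- (seq_len(n_frames) - 1) / fps
  cx <- 75 + 30 * sin(2 * pi * 0.05 * t)
  cz <- 75 + 30 * cos(2 * pi * 0.07 * t)
  th <- 2 * pi * 0.03 * t
  coords <- array(NA_real_, c(n_frames, 6L, 2L))
  xs <- seq(12, -12, length.out = 6)
  for (i in seq_len(n_frames)) {
    zs <- 2 * sin(2 * pi * 2 * t[i] - seq(0, pi, length.out = 6))
    coords[i, , 1] <- cx[i] + xs * cos(th[i]) - zs * sin(th[i])
    coords[i, , 2] <- cz[i] + xs * sin(th[i]) + zs * cos(th[i])
  }
  dot_sequence(coords, fps = fps)
}

# rigid six-dot shape placed with given per-frame rotation and translation
rigid_dot_sequence <- function(shape, angles, centres, fps = 30) {
  n <- length(angles)
  coords <- array(NA_real_, c(n, 6L, 2L))
  for (i in seq_len(n)) {
    R <- matrix(c(cos(angles[i]), sin(angles[i]),
                  -sin(angles[i]), cos(angles[i])), 2, 2)
    coords[i, , ] <- sweep(shape %*% t(R), 2, centres[i, ], "+")
  }
  dot_sequence(coords, fps = fps)
}
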