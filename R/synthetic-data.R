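# Synthetic-data generators: articulated swimming-fish contours, power-law
# signals, and behavioural response tracks with known ground truth. These
# define the study conditions under which the downstream analyses are
# exercised and tested.

#' Synthesize a signal with a power-law power spectral density
#'
#' Spectral synthesis: a white complex-Gaussian spectrum is shaped so the
#' expected one-sided PSD follows f^beta over the resolvable band, then
#' inverse-transformed. The envelope is truncated at the fundamental
#' frequency and the DC bin is set to zero, so no divergence occurs for
#' beta < 0. The output is standardized to mean 0 and the requested SD.
#'
#' @param n_samples number of samples (>= 4).
#' @param exponent PSD slope beta (PSD proportional to f^beta); 0 gives white
#'   noise, -1 gives 1/f noise.
#' @param scale standard deviation of the output, native units.
#' @param seed integer seed; the call is deterministic given the seed and
#'   leaves the global random state untouched.
#' @return numeric vector of length `n_samples`.
#' @export
generate_powerlaw_signal <- function(n_samples, exponent, scale = 1, seed = NULL) {
  stopifnot(n_samples >= 4, is.finite(exponent), scale >= 0)
  n <- as.integer(n_samples)
  with_seed(seed, {
    nf <- n %/% 2L
    k <- seq_len(nf)                       # cycles per record, 1 .. n/2
    env <- k^(exponent / 2)
    half <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * env
    if (n %% 2L == 0L) {
      # Nyquist coefficient must be real for a real signal
      half[nf] <- complex(real = Re(half[nf]), imaginary = 0)
      spec <- c(0 + 0i, half, Conj(rev(half[-nf])))
    } else {
      spec <- c(0 + 0i, half, Conj(rev(half)))
    }
    x <- Re(fft(spec, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- sd(x)
    if (s > 0) x <- x / s * scale
    x
  })
}

#' Simulate per-frame contours of an undulating swimming fish
#'
#' A 2-D articulated fish: a teardrop half-width profile (maximum width 20%
#' of body length) around a straight body axis, with a curvature wave
#' traveling head to tail whose amplitude is modulated by a 1/f signal. The
#' body translates along a bounded random-walk trajectory whose speed also
#' fluctuates with a power-law spectrum, reflecting at the arena walls.
#' With `undulation_amplitude = 0` and `speed = 0` the fish is rigid and
#' static, so every frame's polygon is identical.
#'
#' @param body_length body length, mm.
#' @param n_vertices vertices per contour polygon (even, >= 8).
#' @param undulation_amplitude peak lateral tail deflection, mm.
#' @param undulation_frequency tail-beat frequency, Hz.
#' @param fps frame rate, frames per second.
#' @param duration clip length, seconds.
#' @param arena_size side of the square arena, mm.
#' @param speed nominal swimming speed, mm/s; 0 pins the fish in place with a
#'   fixed heading.
#' @param seed integer seed (see [generate_powerlaw_signal()]).
#' @param check_geometry verify each polygon is simple; a self-intersecting
#'   frame (possible at extreme undulation) is regenerated with damped
#'   amplitude and a message is emitted.
#' @return a [contour_sequence()]; the programmed ground-truth path and
#'   heading are attached as attributes `centre` (n x 2 matrix, the exact
#'   per-frame polygon centroid) and `heading` (radians).
#' @export
generate_fish_contours <- function(body_length = 30, n_vertices = 40,
                                   undulation_amplitude = 3,
                                   undulation_frequency = 2.5,
                                   fps = 30, duration = 60,
                                   arena_size = 150, speed = 30,
                                   seed = NULL, check_geometry = TRUE) {
  stopifnot(body_length > 0, fps > 0, duration > 0, n_vertices >= 8,
            undulation_amplitude >= 0, speed >= 0, arena_size > 0)
  n <- max(1L, round(duration * fps))
  n_side <- as.integer(n_vertices) %/% 2L
  margin <- 0.5 * body_length + 2 * undulation_amplitude + 4
  if (arena_size <= 2 * margin)
    stop("arena too small for the requested body length and amplitude")
  tt <- (seq_len(n) - 1) / fps

  with_seed(seed, {
    if (speed > 0 && n >= 4) {
      u <- generate_powerlaw_signal(n, exponent = -1, scale = 1)
      v <- pmin(speed * exp(0.4 * u), 3 * speed)
      dth <- rnorm(n, 0, 0.12)
      th0 <- runif(1, 0, 2 * pi)
      start <- runif(2, margin, arena_size - margin)
    } else {
      v <- rep(0, n); dth <- rep(0, n)
      th0 <- 0
      start <- rep(arena_size / 2, 2)
    }
    if (undulation_amplitude > 0 && n >= 4) {
      u2 <- generate_powerlaw_signal(n, exponent = -1, scale = 1)
      amp_t <- undulation_amplitude * pmin(pmax(exp(0.35 * u2), 0.3), 2)
    } else {
      amp_t <- rep(undulation_amplitude, n)
    }

    # bounded centre trajectory with wall reflection
    centre <- matrix(0, n, 2)
    heading <- numeric(n)
    centre[1, ] <- start
    heading[1] <- th0
    if (n >= 2) for (i in 2:n) {
      th <- heading[i - 1] + dth[i]
      step <- (v[i] / fps) * c(cos(th), sin(th))
      p <- centre[i - 1, ] + step
      for (d in 1:2) {
        if (p[d] < margin || p[d] > arena_size - margin) {
          step[d] <- -step[d]
          p <- centre[i - 1, ] + step
        }
      }
      if (any(step != 0)) th <- atan2(step[2], step[1])
      centre[i, ] <- pmin(pmax(p, margin), arena_size - margin)
      heading[i] <- th
    }

    # body shape: arc-length parameter s in (0, 1), head at s = 0
    sgrid <- (seq_len(n_side) - 0.5) / n_side
    halfw <- 0.1 * body_length * sqrt(4 * sgrid * (1 - sgrid)) * (1 - 0.45 * sgrid)
    along <- (0.5 - sgrid) * body_length
    wave_env <- sgrid^1.5

    frames <- vector("list", n)
    warned <- FALSE
    for (i in seq_len(n)) {
      a <- amp_t[i]
      for (try in 0:5) {
        defl <- a * wave_env *
          sin(2 * pi * (undulation_frequency * tt[i] - 1.2 * sgrid))
        ax <- c(cos(heading[i]), sin(heading[i]))
        nr <- c(-ax[2], ax[1])
        mid <- cbind(centre[i, 1] + along * ax[1] + defl * nr[1],
                     centre[i, 2] + along * ax[2] + defl * nr[2])
        upper <- mid + cbind(halfw * nr[1], halfw * nr[2])
        lower <- mid - cbind(halfw * nr[1], halfw * nr[2])
        poly <- rbind(upper, lower[n_side:1, , drop = FALSE])
        # pin the polygon centroid on the programmed path so the path is
        # exact ground truth for the extracted centre of mass
        poly <- sweep(poly, 2, polygon_centroid(poly) - centre[i, ])
        if (!check_geometry || polygon_is_simple(poly)) break
        a <- a * 0.6
        if (!warned) {
          message("self-intersecting contour regenerated with damped amplitude")
          warned <- TRUE
        }
      }
      frames[[i]] <- poly
    }
    out <- contour_sequence(frames, fps = fps)
    # ground truth for tests: programmed centre path and heading
    attr(out, "centre") <- centre
    attr(out, "heading") <- heading
    out
  })
}

#' Simulate behavioural response tracks with known relaxation kinetics
#'
#' Each simulated fish holds a mean distance `y_eq` from the display before
#' `t0`, jumps to the attracted distance `y0` at `t0`, and relaxes back as
#' y(t) = (y0 - y_eq) * exp(-k (t - t0)) + y_eq, with additive stationary
#' AR(1) noise on y. The x coordinate is an independent reflected random
#' walk. Both coordinates are folded into the arena by reflection.
#'
#' @param k_true relaxation rate, 1/s (ground truth; 0 keeps y at `y0` after
#'   `t0`).
#' @param t0 start of relaxation, seconds.
#' @param y0 attracted distance at `t0`, mm.
#' @param y_eq equilibrium (baseline) distance, mm.
#' @param noise_sd stationary SD of the AR(1) noise, mm.
#' @param ar1_coeff AR(1) coefficient in [0, 1).
#' @param n_fish number of tracks.
#' @param fps frame rate, frames per second.
#' @param duration session length, seconds.
#' @param onset stimulus onset recorded on each track, seconds.
#' @param arena_size arena side, mm.
#' @param seed integer seed.
#' @return list of [behavior_track()] objects, length `n_fish`.
#' @export
generate_behavior_tracks <- function(k_true, t0 = 77, y0 = 10, y_eq = 41,
                                     noise_sd = 3, ar1_coeff = 0.9,
                                     n_fish = 16, fps = 30, duration = 360,
                                     onset = 60, arena_size = 150,
                                     seed = NULL) {
  stopifnot(k_true >= 0, noise_sd >= 0, ar1_coeff >= 0, ar1_coeff < 1,
            n_fish >= 1, fps > 0, duration > t0,
            y0 >= 0, y0 <= arena_size, y_eq >= 0, y_eq <= arena_size)
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  m <- ifelse(t < t0, y_eq, (y0 - y_eq) * exp(-k_true * (t - t0)) + y_eq)
  with_seed(seed, {
    lapply(seq_len(n_fish), function(i) {
      innov <- rnorm(n, 0, noise_sd * sqrt(1 - ar1_coeff^2))
      e0 <- rnorm(1, 0, noise_sd)
      e <- as.numeric(stats::filter(innov, ar1_coeff, method = "recursive",
                                    init = e0))
      y <- reflect_into(m + e, 0, arena_size)
      x <- reflect_into(arena_size / 2 + cumsum(rnorm(n, 0, 2)), 0, arena_size)
      behavior_track(t, x, y, onset = onset, fps = fps)
    })
  })
}
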