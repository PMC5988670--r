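# Quantitative characterization of the stimulus clips: body-shape-level
# similarity, power-spectral slope of per-dot speed, and a single-hidden-
# layer classifier probe.

# accept a stimulus_clip or a bare dot_sequence
as_dot_coords <- function(x) {
  if (inherits(x, "stimulus_clip")) x$dots$coords
  else if (inherits(x, "dot_sequence")) x$coords
  else stop("expected a stimulus_clip or dot_sequence")
}

clip_fps <- function(x) {
  if (inherits(x, "stimulus_clip")) x$fps
  else if (inherits(x, "dot_sequence")) x$fps
  else stop("expected a stimulus_clip or dot_sequence")
}

#' Dot positions relative to the centre of mass
#'
#' Per frame, the six dot coordinates minus their centroid — the body-shape-
#' level position without normalizing the traveling direction (no rotation is
#' removed). The per-frame centroid of the output is exactly (0, 0).
#'
#' @param clip a `stimulus_clip` or [dot_sequence()].
#' @return numeric array (frames, 6, 2) of relative (x, z), mm.
#' @export
relative_position_series <- function(clip) {
  coords <- as_dot_coords(clip)
  cen_x <- rowMeans(coords[, , 1, drop = FALSE])
  cen_z <- rowMeans(coords[, , 2, drop = FALSE])
  out <- coords
  out[, , 1] <- coords[, , 1] - cen_x
  out[, , 2] <- coords[, , 2] - cen_z
  out
}

#' Relative similarity of a stimulus to the biomotion and non-bio references
#'
#' 1 - dB / (dB + dN), where dB and dN are the Euclidean distances of the
#' stimulus time series from the biomotion and non-bio reference series (flat
#' norms over the full stacked frames x dots x coordinates arrays). The
#' score is 1 if the stimulus is identical to the biomotion reference and 0
#' if identical to the non-bio reference; when all three series coincide
#' (dB + dN = 0) the symmetric value 0.5 is returned.
#'
#' @param s,b,n aligned arrays from [relative_position_series()]: the
#'   stimulus, the biomotion reference and the non-bio reference.
#' @return list of class `similarity_score` with `value`, `d_B`, `d_N`.
#' @export
relative_similarity <- function(s, b, n) {
  if (!all(dim(s) == dim(b)) || !all(dim(s) == dim(n)))
    stop("misaligned series: dimensions differ")
  d_B <- sqrt(sum((s - b)^2))
  d_N <- sqrt(sum((s - n)^2))
  value <- if (d_B + d_N == 0) 0.5 else 1 - d_B / (d_B + d_N)
  structure(list(value = value, d_B = d_B, d_N = d_N),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("relative similarity %.4f (d_B = %.3g, d_N = %.3g)\n",
              x$value, x$d_B, x$d_N))
  invisible(x)
}

#' Per-dot speed of the body-shape-level motion
#'
#' Speed of the change in the position of each dot relative to the centre of
#' mass: the Euclidean displacement of the relative position between
#' consecutive frames times the frame rate.
#'
#' @param clip a `stimulus_clip` or [dot_sequence()] with >= 2 frames.
#' @return numeric matrix (frames - 1) x 6 of speeds, mm/s.
#' @export
dot_speed_series <- function(clip) {
  rel <- relative_position_series(clip)
  if (dim(rel)[1] < 2) stop("need at least 2 frames")
  dx <- rel[-1, , 1, drop = FALSE] - rel[-dim(rel)[1], , 1, drop = FALSE]
  dz <- rel[-1, , 2, drop = FALSE] - rel[-dim(rel)[1], , 2, drop = FALSE]
  matrix(sqrt(dx^2 + dz^2) * clip_fps(clip), ncol = dim(rel)[2])
}

#' Power-spectral-density slope of per-dot speed series
#'
#' One-sided periodogram per dot (raw FFT periodogram, no taper, DC
#' excluded), normalized by each dot's mean PSD, averaged within logarithmic
#' frequency bins as the logarithmic mean (mean of log10, i.e. the log of
#' the geometric mean, whose sampling bias is the same constant in every bin
#' and so leaves the slope unbiased), and pooled across all dots and bins
#' into a simple linear regression of log10 PSD on log10 frequency.
#' The slope and the Pearson correlation-test p-value of the pooled points
#' are returned; a power-law spectrum f^beta yields slope ~ beta. Dots with
#' no motion (all-zero speed) are dropped and flagged; with no moving dot
#' the slope is undefined.
#'
#' @param speeds numeric matrix (samples x dots) of speed series, or a
#'   vector for a single dot; >= 64 samples.
#' @param fps sampling rate of the series, frames per second.
#' @param bins_per_decade logarithmic bins per frequency decade.
#' @return list of class `psd_result`: `freqs` (Hz), `psd` (matrix
#'   freq x dot), `bin_centers` (Hz), `bin_logmeans` (bin x dot, log10 of
#'   binned normalized PSD), `slope`, `slope_p`, `flagged`.
#' @export
psd_slope <- function(speeds, fps, bins_per_decade = 4) {
  if (is.vector(speeds)) speeds <- matrix(speeds, ncol = 1)
  stopifnot(is.matrix(speeds), nrow(speeds) >= 64, fps > 0,
            bins_per_decade >= 1)
  nd <- ncol(speeds)
  active <- apply(speeds, 2, function(x) any(x != x[1]) && sd(x) > 0)
  pg1 <- spec.pgram(speeds[, 1], taper = 0, detrend = FALSE, demean = TRUE,
                    fast = FALSE, plot = FALSE)
  freqs <- pg1$freq * fps
  psd <- matrix(NA_real_, length(freqs), nd)
  for (d in seq_len(nd)) {
    if (!active[d]) next
    psd[, d] <- spec.pgram(speeds[, d], taper = 0, detrend = FALSE,
                           demean = TRUE, fast = FALSE, plot = FALSE)$spec
  }
  if (!any(active)) {
    return(structure(list(freqs = freqs, psd = psd, bin_centers = numeric(0),
                          bin_logmeans = NULL, slope = NA_real_,
                          slope_p = NA_real_, flagged = !active),
                     class = "psd_result"))
  }
  lo <- log10(min(freqs)); hi <- log10(max(freqs))
  breaks <- seq(lo, hi, by = 1 / bins_per_decade)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  bin <- findInterval(log10(freqs), breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1
  centers <- 10^((breaks[-length(breaks)] + breaks[-1]) / 2)
  logmeans <- matrix(NA_real_, nb, nd)
  for (d in which(active)) {
    pn <- psd[, d] / mean(psd[, d])
    mb <- tapply(log10(pn), factor(bin, levels = seq_len(nb)), mean)
    logmeans[, d] <- as.numeric(mb)
  }
  xs <- rep(log10(centers), nd)
  ys <- as.numeric(logmeans)
  ok <- is.finite(xs) & is.finite(ys)
  fitlm <- lm(ys[ok] ~ xs[ok])
  ct <- cor.test(xs[ok], ys[ok])
  structure(list(freqs = freqs, psd = psd, bin_centers = centers,
                 bin_logmeans = logmeans,
                 slope = unname(coef(fitlm)[2]), slope_p = ct$p.value,
                 flagged = !active),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  if (is.na(x$slope)) cat("<psd_result> undefined slope (no motion)\n")
  else cat(sprintf("<psd_result> slope %.3f (correlation p = %.3g), %d bins x %d dots\n",
                   x$slope, x$slope_p, length(x$bin_centers),
                   ncol(x$bin_logmeans)))
  invisible(x)
}
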