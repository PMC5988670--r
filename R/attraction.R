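# Quantification of attraction from behavioural tracks: per-minute means,
# Welch t-tests with Benjamini-Hochberg FDR control, the one-sided z-test
# against the baseline distribution, and the single-parameter exponential
# relaxation fit whose inverse rate is the retention time.

#' Per-minute mean distance of a behavioural track
#'
#' Arithmetic mean of y over each minute window [60 m, 60 (m + 1)). Windows
#' with more than 5% of their expected frames missing (NA) are flagged via
#' the `"flagged"` attribute.
#'
#' @param track a [behavior_track()].
#' @param minutes which minute windows (1-based); defaults to all whole
#'   minutes covered by the track.
#' @return named numeric vector of minute means, with attribute `flagged`.
#' @export
minute_means <- function(track, minutes = NULL) {
  stopifnot(inherits(track, "behavior_track"))
  fps <- attr(track, "fps")
  if (is.null(minutes))
    minutes <- seq_len(floor((max(track$t) + 1 / fps) / 60 + 1e-9))
  if (max(track$t) + 1 / fps < 60 * max(minutes) - 1e-9)
    stop("track does not cover the requested minutes")
  out <- numeric(length(minutes))
  flagged <- logical(length(minutes))
  for (j in seq_along(minutes)) {
    m <- minutes[j]
    sel <- track$t >= 60 * (m - 1) & track$t < 60 * m
    yv <- track$y[sel]
    out[j] <- mean(yv, na.rm = TRUE)
    flagged[j] <- sum(!is.na(yv)) < 0.95 * 60 * fps
  }
  names(out) <- paste0("min", minutes)
  attr(out, "flagged") <- flagged
  out
}

#' Benjamini-Hochberg decisions at a given FDR level
#'
#' Step-up FDR control: with raw p-values the adjustment is applied first;
#' with `adjusted = TRUE` the inputs are taken as already BH-adjusted and
#' only thresholded.
#'
#' @param p numeric vector of p-values (raw or adjusted).
#' @param level FDR level.
#' @param adjusted are the inputs already BH-adjusted?
#' @return logical vector of rejections, with the adjusted values as the
#'   `"p_adjusted"` attribute.
#' @export
fdr_decisions <- function(p, level = 0.1, adjusted = FALSE) {
  stopifnot(all(p >= 0 & p <= 1), level > 0, level < 1)
  padj <- if (adjusted) p else p.adjust(p, method = "BH")
  structure(padj <= level, p_adjusted = padj)
}

#' Welch tests of attraction across stimuli with FDR control
#'
#' For each stimulus group, a two-sample Welch (unequal-variance) t-test of
#' the per-fish minute means in the window just after stimulus onset against
#' those in the window before onset, with one-sided alternative "less"
#' optional; p-values are corrected across stimuli by the Benjamini-Hochberg
#' step-up procedure at `fdr_level`.
#'
#' @param groups named list, one entry per stimulus, each a numeric matrix of
#'   per-fish minute means (fish x minutes) as from [minute_means()].
#' @param fdr_level FDR level for the BH procedure.
#' @param baseline_minute,test_minute 1-based minute columns compared
#'   (defaults: minute 1, before onset, vs minute 2, just after onset).
#' @param alternative passed to [stats::t.test()] (default two-sided).
#' @return data frame with columns `stimulus`, `mean_baseline`, `mean_test`,
#'   `df`, `p`, `p_adjusted`, `significant`.
#' @export
attraction_test <- function(groups, fdr_level = 0.1, baseline_minute = 1,
                            test_minute = 2, alternative = "two.sided") {
  stopifnot(is.list(groups), length(groups) >= 1)
  res <- lapply(groups, function(g) {
    stopifnot(is.matrix(g), nrow(g) >= 2,
              ncol(g) >= max(baseline_minute, test_minute))
    a <- g[, baseline_minute]
    b <- g[, test_minute]
    if (sd(a) == 0 && sd(b) == 0) stop("degenerate variance in both windows")
    tt <- t.test(b, a, var.equal = FALSE, alternative = alternative)
    c(mean(a), mean(b), unname(tt$parameter), tt$p.value)
  })
  m <- do.call(rbind, res)
  dec <- fdr_decisions(m[, 4], level = fdr_level)
  data.frame(stimulus = names(groups) %||% seq_along(groups),
             mean_baseline = m[, 1], mean_test = m[, 2], df = m[, 3],
             p = m[, 4], p_adjusted = attr(dec, "p_adjusted"),
             significant = as.logical(dec), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sided z-test of an attracted position against the baseline
#'
#' Lower-tail probability of observing `value` or less under the baseline
#' Normal(mu_y, sigma) distribution of the distance to the display.
#'
#' @param value observed distance, mm.
#' @param mu_y baseline mean distance, mm.
#' @param sigma baseline SD, mm (> 0).
#' @return one-sided probability.
#' @export
ztest_attraction <- function(value, mu_y, sigma) {
  stopifnot(sigma > 0)
  pnorm((value - mu_y) / sigma)
}

#' Across-fish mean distance series at fixed time resolution
#'
#' Averages y over all fish and all frames within each time bin; the series
#' fed to [fit_relaxation()] (the group-mean curve at 1-s resolution).
#'
#' @param tracks list of [behavior_track()] objects on a common time base.
#' @param resolution bin width, seconds.
#' @return data frame with columns `t` (bin centres) and `y` (mean, mm).
#' @export
mean_y_series <- function(tracks, resolution = 1) {
  stopifnot(length(tracks) >= 1, resolution > 0)
  t <- tracks[[1]]$t
  ymat <- vapply(tracks, function(tr) {
    stopifnot(inherits(tr, "behavior_track"), nrow(tr) == length(t))
    tr$y
  }, numeric(length(t)))
  ybar <- rowMeans(ymat)
  bin <- floor(t / resolution)
  ys <- tapply(ybar, bin, mean)
  data.frame(t = (as.numeric(names(ys)) + 0.5) * resolution,
             y = as.numeric(ys))
}
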