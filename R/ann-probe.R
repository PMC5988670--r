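# Single-hidden-layer classifier probe of the stimulus family. The network
# is a reference indicator of what a simple (near-linear) recognizer can
# separate; it bears no relation to the fish's nervous system.

# Full-batch iRprop- training of a one-hidden-layer logistic network with
# cross-entropy loss. Rprop adapts a per-weight step from gradient signs
# only, which makes training deterministic, scale-robust and O(p) in
# memory — necessary here because a 60-s six-dot window yields 21600 inputs
# and ~2e5 weights.
mlp_train <- function(X, y, hidden = 10, maxit = 200) {
  d <- ncol(X); h <- hidden; n <- nrow(X)
  W1 <- matrix(runif(d * h, -0.5, 0.5) / sqrt(d), d, h)
  b1 <- numeric(h)
  W2 <- matrix(runif(h, -0.5, 0.5) / sqrt(h), h, 1)
  b2 <- 0
  step <- list(W1 = matrix(0.01, d, h), b1 = rep(0.01, h),
               W2 = matrix(0.01, h, 1), b2 = 0.01)
  prev <- list(W1 = matrix(0, d, h), b1 = numeric(h),
               W2 = matrix(0, h, 1), b2 = 0)
  up <- 1.2; down <- 0.5; smax <- 1; smin <- 1e-6
  rprop <- function(w, g, nm) {
    s <- sign(g)
    ch <- s * prev[[nm]]
    st <- step[[nm]]
    st[ch > 0] <- pmin(st[ch > 0] * up, smax)
    st[ch < 0] <- pmax(st[ch < 0] * down, smin)
    s[ch < 0] <- 0                      # iRprop-: skip after a sign flip
    step[[nm]] <<- st
    prev[[nm]] <<- s
    w - s * st
  }
  for (it in seq_len(maxit)) {
    H <- plogis(sweep(X %*% W1, 2, b1, "+"))
    o <- plogis(drop(H %*% W2) + b2)
    do <- (o - y) / n
    gW2 <- crossprod(H, do)
    gb2 <- sum(do)
    dH <- (do %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(X, dH)
    gb1 <- colSums(dH)
    W1 <- rprop(W1, gW1, "W1"); b1 <- rprop(b1, gb1, "b1")
    W2 <- rprop(W2, gW2, "W2"); b2 <- rprop(b2, gb2, "b2")
  }
  list(predict = function(newX) {
    H <- plogis(sweep(newX %*% W1, 2, b1, "+"))
    plogis(drop(H %*% W2) + b2)
  })
}

# circularly shifted flattened windows: rows = windows, cols = frames x dots
# x coords of a window_s-long excerpt starting at a random frame
clip_windows <- function(clip, starts, wlen) {
  coords <- as_dot_coords(clip)
  nf <- dim(coords)[1]
  t(vapply(starts, function(s0) {
    idx <- ((s0 - 1L + 0:(wlen - 1L)) %% nf) + 1L
    as.numeric(coords[idx, , , drop = FALSE])
  }, numeric(wlen * 12L)))
}

#' Probe the stimulus family with a single-hidden-layer classifier
#'
#' Trains a feed-forward network with one hidden layer of `hidden` logistic
#' units on flattened x-z dot time series over circularly shifted windows of
#' the training clips (target 1 for biomotion, 0 for non-bio), then reports
#' the mean and SD of the output over `n_windows` random windows of each
#' test clip. Window starting frames are drawn uniformly with the time axis
#' treated as circular. Deterministic given the seed.
#'
#' @param train list of `stimulus_clip`s to train on; targets default to 1
#'   for label `"biomotion"` and 0 for `"non-bio"` (training on a single
#'   class is an error).
#' @param test named list of `stimulus_clip`s to evaluate.
#' @param hidden hidden-layer size.
#' @param n_windows windows per clip for both training and testing.
#' @param window_s window length, seconds (60 s at 30 fps = 1800 frames,
#'   21600 inputs).
#' @param seed integer seed.
#' @param targets optional numeric vector of training targets in [0, 1],
#'   overriding the label rule.
#' @param maxit training iterations.
#' @return list of class `probe_result`: `outputs` (per test clip: `mean`,
#'   `sd`, `values`), `hidden`, `n_windows`, `window_s`, `seed`.
#' @export
ann_probe <- function(train, test, hidden = 10, n_windows = 100,
                      window_s = 60, seed = NULL, targets = NULL,
                      maxit = 200) {
  stopifnot(is.list(train), length(train) >= 2, is.list(test),
            hidden >= 1, n_windows >= 1, window_s > 0)
  if (is.null(targets)) {
    labs <- vapply(train, function(cl) cl$label, "")
    if (!all(labs %in% c("biomotion", "non-bio")))
      stop("default targets need clips labelled biomotion or non-bio; ",
           "pass `targets` explicitly otherwise")
    targets <- as.numeric(labs == "biomotion")
  }
  stopifnot(length(targets) == length(train))
  if (length(unique(targets)) < 2)
    stop("training set contains a single class")
  fps <- clip_fps(train[[1]])
  wlen <- round(window_s * fps)
  with_seed(seed, {
    Xtr <- do.call(rbind, lapply(train, function(cl) {
      nf <- dim(as_dot_coords(cl))[1]
      clip_windows(cl, sample.int(nf, n_windows, replace = TRUE), wlen)
    }))
    ytr <- rep(targets, each = n_windows)
    mu <- mean(Xtr); sdv <- sd(Xtr)
    if (sdv == 0) sdv <- 1
    net <- mlp_train((Xtr - mu) / sdv, ytr, hidden = hidden, maxit = maxit)
    outputs <- lapply(test, function(cl) {
      nf <- dim(as_dot_coords(cl))[1]
      Xte <- clip_windows(cl, sample.int(nf, n_windows, replace = TRUE), wlen)
      v <- net$predict((Xte - mu) / sdv)
      list(mean = mean(v), sd = sd(v), values = v)
    })
    structure(list(outputs = outputs, hidden = hidden,
                   n_windows = n_windows, window_s = window_s, seed = seed),
              class = "probe_result")
  })
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result> hidden = %d, %d windows of %g s\n",
              x$hidden, x$n_windows, x$window_s))
  for (nm in names(x$outputs))
    cat(sprintf("  %-15s %.3f +/- %.3f\n", nm, x$outputs[[nm]]$mean,
                x$outputs[[nm]]$sd))
  invisible(x)
}
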