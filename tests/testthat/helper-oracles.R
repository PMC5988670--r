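# Independent oracles used to freeze or cross-check expected values. These
# deliberately re-derive quantities from first principles rather than calling
# the implementation under test.

# direct evaluation of the link-evenness objective from its definition
oracle_fitness <- function(L) {
  X <- c(2 * L[1], L[2:6], 2 * L[7])
  d <- 7 * sum(X^2) - sum(X)^2
  if (d <= 1e-12) 1e9 else sum(L) / sqrt(d)
}

oracle_effective_cv <- function(L) {
  X <- c(2 * L[1], L[2:6], 2 * L[7])
  sqrt(mean((X - mean(X))^2)) / mean(X)
}

# point at arc position s (from vertex 1) along the closed polyline
oracle_point_at <- function(poly, s) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  el <- sqrt(rowSums((nxt - poly)^2))
  cum <- c(0, cumsum(el))
  s <- s %% cum[n + 1]
  i <- findInterval(s, cum, all.inside = TRUE)
  poly[i, ] + (s - cum[i]) / el[i] * (nxt[i, ] - poly[i, ])
}

# Coarse-grid brute force over the even-spacing family: endpoint arc
# positions on an n_grid lattice, flank control points at even arc intervals
# between them; global within that family.
oracle_grid_search <- function(poly, n_grid = 36) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  per <- sum(sqrt(rowSums((nxt - poly)^2)))
  best <- -Inf
  for (i in 0:(n_grid - 1)) for (j in 0:(n_grid - 1)) {
    s0 <- per * i / n_grid
    s7 <- per * j / n_grid
    la <- (s7 - s0) %% per
    lb <- per - la
    if (la < 0.15 * per || lb < 0.15 * per) next
    sa <- s0 + la * (1:6) / 7        # c1a .. c6a
    sb <- s7 + lb * (1:6) / 7        # c6b .. c1b
    c0 <- oracle_point_at(poly, s0)
    c7 <- oracle_point_at(poly, s7)
    p <- matrix(NA_real_, 6, 2)
    for (k in 1:6) {
      p[k, ] <- (oracle_point_at(poly, sa[k]) +
                   oracle_point_at(poly, sb[7 - k])) / 2
    }
    chain <- rbind(c0, p, c7)
    L <- sqrt(rowSums(diff(chain)^2))
    f <- oracle_fitness(L)
    if (f > best) best <- f
  }
  best
}

# Benjamini-Hochberg step-up by direct enumeration of the definition
oracle_bh_stepup <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * level) kmax <- i
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}
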