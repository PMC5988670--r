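# Conversion of a fish contour into six point-light dots. Fourteen control
# points (c0, c1a..c6a, c7, c6b..c1b) live on the contour at arc-length
# positions; the dots p1..p6 are the midpoints of the flank pairs (c_na,
# c_nb), and the seven links of the chain c0, p1..p6, c7 are driven toward
# equal effective length by random-shift hill climbing of a fitness ratio.

# index layout of a control set, marching once around the contour
CP_NAMES <- c("c0", paste0("c", 1:6, "a"), "c7", paste0("c", 6:1, "b"))
# permutation that swaps head and tail labels
CP_REVERSE <- c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L, 14L, 13L, 12L, 11L, 10L, 9L)

#' Initial control points at even arc-length intervals
#'
#' Places the fourteen control points on the contour at even intervals
#' (perimeter/14), starting from the contour vertex nearest the head end, in
#' the order c0, c1a..c6a, c7, c6b..c1b around the loop so that flank pairs
#' face each other across the body.
#'
#' @param polygon numeric matrix (n x 2), the fish contour.
#' @param head_arc optional arc-length position (mm, from vertex 1) of the
#'   head; when `NULL` the head is identified from the shape (the wider end
#'   of the major principal axis) or, if `direction` is given, as the extreme
#'   along the direction of motion.
#' @param direction optional length-2 vector, the recent displacement of the
#'   fish, used to orient the head.
#' @return A list of class `control_points` with fields `arc` (14 arc-length
#'   positions, named), `points` (14 x 2 coordinates), `perimeter`, and
#'   `polygon`.
#' @export
init_control_points <- function(polygon, head_arc = NULL, direction = NULL) {
  per <- polygon_perimeter(polygon)
  if (is.null(head_arc)) head_arc <- head_arc_position(polygon, direction)
  arc <- (head_arc + per * (0:13) / 14) %% per
  names(arc) <- CP_NAMES
  control_points(polygon, arc)
}

# package a (polygon, arc-position) state, recomputing coordinates
control_points <- function(polygon, arc) {
  pts <- contour_interpolate(polygon, arc)
  rownames(pts) <- names(arc) <- CP_NAMES
  structure(list(arc = arc, points = pts,
                 perimeter = polygon_perimeter(polygon), polygon = polygon),
            class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  cat(sprintf("<control_points> 14 points on a contour of perimeter %.2f mm\n",
              x$perimeter))
  invisible(x)
}

# Arc position of the head vertex: the extreme of the major principal axis,
# oriented by `direction` when supplied, otherwise toward the wider body end.
head_arc_position <- function(polygon, direction = NULL) {
  ctr <- colMeans(polygon)
  V <- sweep(polygon, 2, ctr)
  ev <- eigen(crossprod(V) / nrow(V), symmetric = TRUE)$vectors[, 1]
  proj <- drop(V %*% ev)
  if (!is.null(direction) && sum(direction^2) > 0) {
    if (sum(ev * direction) < 0) { ev <- -ev; proj <- -proj }
  } else {
    perp <- drop(V %*% c(-ev[2], ev[1]))
    hi <- proj >= quantile(proj, 0.7)
    lo <- proj <= quantile(proj, 0.3)
    if (sum(lo) >= 2 && sum(hi) >= 2 && sd(perp[lo]) > sd(perp[hi])) {
      proj <- -proj
    }
  }
  iv <- which.max(proj)
  n <- nrow(polygon)
  el <- sqrt(rowSums((polygon[c(2:n, 1), , drop = FALSE] - polygon)^2))
  c(0, cumsum(el))[iv]
}

# p1..p6 as midpoints of the facing flank pairs (c_na, c_nb)
dots_from_control <- function(cps) {
  p <- (cps$points[2:7, , drop = FALSE] +
          cps$points[14:9, , drop = FALSE]) / 2
  rownames(p) <- paste0("p", 1:6)
  p
}

#' Link lengths of the eight-point chain
#'
#' Lengths L1..L7 of the links of the chain c0, p1, ..., p6, c7, where each
#' p_n is the midpoint of the flank pair (c_na, c_nb).
#'
#' @param cps a `control_points` object from [init_control_points()].
#' @return numeric vector of 7 non-negative lengths, mm.
#' @export
link_lengths <- function(cps) {
  stopifnot(inherits(cps, "control_points"))
  chain <- rbind(cps$points[1, ], dots_from_control(cps), cps$points[8, ])
  d <- diff(chain)
  L <- sqrt(rowSums(d^2))
  names(L) <- paste0("L", 1:7)
  L
}

#' Link-length evenness fitness
#'
#' The objective maximized when converting a contour to six dots. With
#' effective lengths X = (2 L1, L2, ..., L6, 2 L7), the fitness is
#' sum(L) / sqrt(n sum(X^2) - (sum X)^2) with n = 7, which diverges as the
#' effective lengths approach equality; exact equality (discriminant below
#' `eps`) returns the finite cap `fitness_max` so the hill climb stays
#' totally ordered. The ratio is invariant to uniform rescaling of L.
#'
#' @param L numeric vector of 7 non-negative link lengths.
#' @param fitness_max value returned at zero discriminant.
#' @param eps discriminant floor, mm^2.
#' @return scalar fitness.
#' @export
dot_fitness <- function(L, fitness_max = 1e9, eps = 1e-12) {
  stopifnot(length(L) == 7L, all(L >= 0))
  if (all(L == 0)) stop("all link lengths are zero")
  X <- L
  X[c(1, 7)] <- 2 * X[c(1, 7)]
  disc <- 7 * sum(X^2) - sum(X)^2
  if (disc <= eps) fitness_max else sum(L) / sqrt(disc)
}

# coefficient of variation of the effective lengths (diagnostic)
effective_cv <- function(L) {
  X <- L
  X[c(1, 7)] <- 2 * X[c(1, 7)]
  sqrt(mean((X - mean(X))^2)) / mean(X)
}

#' Fit six dots to a contour by random-shift hill climbing
#'
#' Starting from control points at even arc intervals (or a supplied warm
#' start), one of the fourteen points is picked uniformly at random per
#' iteration and its arc-length position shifted by a random signed step
#' (uniform within +/- `step_frac` of the perimeter); the move is kept iff
#' the fitness does not decrease. All fourteen points, endpoints included,
#' are movable. The returned state never has lower fitness than the
#' initialization, and the call is deterministic given the seed.
#'
#' @param polygon numeric matrix (n x 2), the fish contour.
#' @param iterations number of random shifts (0 returns the initialization).
#' @param seed integer seed.
#' @param init optional warm-start `control_points` arc positions (numeric
#'   length 14) on this polygon.
#' @param step_frac maximum shift as a fraction of the perimeter.
#' @param direction optional motion direction for head identification.
#' @return list with `dots` (6 x 2 matrix p1..p6, head first), `control`
#'   (final `control_points`), `fitness`, `link_lengths`.
#' @export
fit_six_points <- function(polygon, iterations = 1000, seed = NULL,
                           init = NULL, step_frac = 0.01, direction = NULL) {
  cps <- if (is.null(init)) init_control_points(polygon, direction = direction)
         else control_points(polygon, init)
  per <- cps$perimeter
  arc <- cps$arc
  pts <- cps$points
  state_fit <- function(p) {
    chain <- rbind(p[1, ], (p[2:7, , drop = FALSE] + p[14:9, , drop = FALSE]) / 2,
                   p[8, ])
    dot_fitness(sqrt(rowSums(diff(chain)^2)))
  }
  f <- state_fit(pts)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      j <- sample.int(14L, 1L)
      cand_arc <- (arc[j] + runif(1, -per * step_frac, per * step_frac)) %% per
      cand_pts <- pts
      cand_pts[j, ] <- contour_interpolate(polygon, cand_arc)
      fc <- state_fit(cand_pts)
      if (fc >= f) {
        arc[j] <- cand_arc
        pts <- cand_pts
        f <- fc
      }
    }
  })
  cps <- control_points(polygon, arc)
  list(dots = dots_from_control(cps), control = cps, fitness = f,
       link_lengths = link_lengths(cps))
}

#' Track a contour sequence into a six-dot sequence
#'
#' Applies [fit_six_points()] to every frame. The first frame is initialized
#' from even arc spacing with the head at the wider body end; each later
#' frame is warm-started from the previous frame's arc positions (rescaled to
#' the new perimeter) and optimized for `warm_iterations` shifts. Head/tail
#' label consistency is enforced by flipping the dot order whenever the
#' reversed labelling brings p1 closer to the previous frame's p1. A frame
#' with degenerate geometry is carried forward from the previous frame with
#' a warning.
#'
#' @param contours a [contour_sequence()].
#' @param iterations hill-climb iterations for the first frame.
#' @param warm_iterations iterations for warm-started frames (defaults to
#'   `iterations`).
#' @param seed integer seed covering the whole sequence.
#' @param step_frac maximum shift as a fraction of the perimeter.
#' @return a [dot_sequence()] with one frame per contour frame.
#' @export
track_sequence <- function(contours, iterations = 1000,
                           warm_iterations = iterations, seed = NULL,
                           step_frac = 0.01) {
  stopifnot(inherits(contours, "contour_sequence"))
  nf <- length(contours$frames)
  coords <- array(NA_real_, c(nf, 6L, 2L))
  with_seed(seed, {
    prev_arc <- NULL
    prev_per <- NULL
    prev_p1 <- NULL
    prev_dots <- NULL
    for (i in seq_len(nf)) {
      poly <- contours$frames[[i]]
      res <- tryCatch({
        init <- if (!is.null(prev_arc))
          prev_arc * (polygon_perimeter(poly) / prev_per) else NULL
        fit_six_points(poly,
                       iterations = if (i == 1L) iterations else warm_iterations,
                       init = init, step_frac = step_frac)
      }, error = function(e) {
        warning(sprintf("frame %d degenerate (%s); carrying previous dots",
                        i, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        if (is.null(prev_dots)) stop("first frame is degenerate")
        coords[i, , ] <- prev_dots
        next
      }
      dots <- res$dots
      arc <- res$control$arc
      if (!is.null(prev_p1)) {
        if (sum((dots[6, ] - prev_p1)^2) < sum((dots[1, ] - prev_p1)^2)) {
          arc <- arc[CP_REVERSE]
          dots <- dots_from_control(control_points(poly, arc))
        }
      }
      coords[i, , ] <- dots
      prev_arc <- unname(arc)
      prev_per <- res$control$perimeter
      prev_p1 <- dots[1, ]
      prev_dots <- dots
    }
  })
  dot_sequence(coords, fps = contours$fps)
}
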