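test_that("polygon centroid matches closed forms and a grid-sampling oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_centroid(sq), c(0.5, 0.5))
  tri <- cbind(c(0, 3, 0), c(0, 0, 3))
  expect_equal(polygon_centroid(tri), c(1, 1))
  # L-shaped hexagon: dense-grid interior sampling oracle
  g <- expand.grid(x = seq(0.0005, 2, by = 0.001), y = seq(0.0005, 2, by = 0.001))
  inside <- (g$x <= 2 & g$y <= 1) | (g$x <= 1 & g$y <= 2)
  oracle <- c(mean(g$x[inside]), mean(g$y[inside]))
  expect_equal(polygon_centroid(l_shape()), oracle, tolerance = 1e-3)
  expect_error(polygon_centroid(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
})

test_that("initial control points sit at even arc intervals on the contour", {
  circ <- circle_polygon(circumference = 14)
  cps <- init_control_points(circ)
  arcs <- sort(cps$arc)
  expect_equal(unname(diff(arcs)), rep(1, 13), tolerance = 1e-9)
  # deterministic: no randomness involved
  expect_identical(cps, init_control_points(circ))
  # all points on the polyline (4:1 ellipse)
  ell <- ellipse_polygon(20, 5)
  cpe <- init_control_points(ell)
  for (k in 1:14) {
    on <- oracle_point_at(ell, cpe$arc[k])
    expect_lt(sqrt(sum((cpe$points[k, ] - on)^2)), 1e-9)
  }
})

test_that("link lengths follow the chain definition", {
  # rectangle [0,7] x [-1,1]: flank pairs at (k, -1)/(k, 1) give a collinear
  # chain c0=(0,0), p1..p6=(1..6, 0), c7=(7,0) with unit links
  rect <- cbind(c(0, 7, 7, 0), c(-1, -1, 1, 1))
  arc <- c(17, 1:6, 8, 16 - (6:1))
  cps <- biomotion:::control_points(rect, arc)
  expect_equal(unname(link_lengths(cps)), rep(1, 7), tolerance = 1e-12)

  # degenerate flank pairs (c_na = c_nb): dots lie on the contour itself
  circ <- circle_polygon(14)
  arc2 <- c(0, 1:6, 7, 6:1)
  cps2 <- biomotion:::control_points(circ, arc2)
  p <- (cps2$points[2:7, ] + cps2$points[14:9, ]) / 2
  expect_equal(p, unname(cps2$points[2:7, ]), ignore_attr = TRUE)

  # random control sets match an independent per-segment recomputation
  set.seed(4)
  ell <- ellipse_polygon()
  per <- polygon_perimeter(ell)
  for (r in 1:5) {
    arc3 <- sort(runif(14, 0, per))
    cps3 <- biomotion:::control_points(ell, arc3)
    pts <- cps3$points
    chain <- rbind(pts[1, ], (pts[2:7, ] + pts[14:9, ]) / 2, pts[8, ])
    L_direct <- sqrt(rowSums((chain[-1, ] - chain[-8, ])^2))
    expect_equal(unname(link_lengths(cps3)), unname(L_direct))
  }
})

test_that("the evenness fitness matches direct evaluation, caps at equality, and is scale-free", {
  expect_equal(dot_fitness(c(1, 2, 2, 2, 2, 2, 1)), 1e9)
  expect_equal(dot_fitness(c(1, 2, 2, 2, 2, 2, 2)), 13 / sqrt(24))
  set.seed(7)
  for (r in 1:10) {
    L <- runif(7, 0.5, 3)
    expect_equal(dot_fitness(L), oracle_fitness(L))
    expect_equal(dot_fitness(3.7 * L), dot_fitness(L), tolerance = 1e-12)
  }
  expect_error(dot_fitness(rep(0, 7)))
})

test_that("hill climbing is seed-deterministic, monotone, and a no-op at zero iterations", {
  ell <- ellipse_polygon()
  f0 <- fit_six_points(ell, iterations = 0)
  init <- init_control_points(ell)
  expect_equal(f0$dots, biomotion:::dots_from_control(init))
  a <- fit_six_points(ell, iterations = 500, seed = 3)
  b <- fit_six_points(ell, iterations = 500, seed = 3)
  expect_identical(a, b)
  expect_gte(a$fitness, f0$fitness)
  # monotonicity across a variety of shapes
  for (s in 1:4) {
    poly <- generate_fish_contours(duration = 1 / 30, seed = s,
                                   undulation_amplitude = 4)$frames[[1]]
    expect_gte(fit_six_points(poly, iterations = 300, seed = s)$fitness,
               fit_six_points(poly, iterations = 0)$fitness)
  }
})

test_that("hill climbing on a symmetric ellipse equalizes the effective link lengths", {
  fit <- fit_six_points(ellipse_polygon(), iterations = 1000, seed = 11)
  expect_lt(oracle_effective_cv(fit$link_lengths), 0.05)
})

test_that("tracking emits one six-dot frame per contour with stable labels", {
  poly <- generate_fish_contours(duration = 1 / 30, seed = 2)$frames[[1]]
  static <- contour_sequence(rep(list(poly), 10), fps = 30)
  ds <- track_sequence(static, iterations = 200, warm_iterations = 0, seed = 5)
  expect_equal(dim(ds$coords), c(10, 6, 2))
  for (i in 2:10) expect_equal(ds$coords[i, , ], ds$coords[1, , ])

  # rigid translation: warm-started frames translate with the contour
  shift <- c(12, -7)
  moved <- contour_sequence(list(poly, sweep(poly, 2, shift, "+")), fps = 30)
  dm <- track_sequence(moved, iterations = 200, warm_iterations = 0, seed = 5)
  expect_equal(dm$coords[2, , ],
               sweep(dm$coords[1, , ], 2, shift, "+"),
               tolerance = 1e-6)
})

test_that("structural constants hold: 14 control points, 6 dots, 7 links", {
  poly <- generate_fish_contours(duration = 1 / 30, seed = 9)$frames[[1]]
  cps <- init_control_points(poly)
  expect_length(cps$arc, 14)
  fit <- fit_six_points(poly, iterations = 50, seed = 1)
  expect_equal(dim(fit$dots), c(6L, 2L))
  expect_length(fit$link_lengths, 7)
})
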