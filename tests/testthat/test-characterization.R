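test_that("relative positions are centred per frame and keep rotation", {
  set.seed(3)
  shape <- cbind(seq(10, 0, length.out = 6), c(0, 1, 0.5, -0.5, -1, 0))
  n <- 10
  # translating rigid configuration -> constant series
  cen <- cbind(seq(20, 80, length.out = n), rep(40, n))
  tra <- rigid_dot_sequence(shape, rep(0.4, n), cen)
  rel_t <- relative_position_series(tra)
  for (i in 2:n) expect_equal(rel_t[i, , ], rel_t[1, , ], tolerance = 1e-9)
  # rotating rigid configuration -> rotation is NOT removed
  rot <- rigid_dot_sequence(shape, seq(0, 1, length.out = n),
                            matrix(60, n, 2))
  rel_r <- relative_position_series(rot)
  expect_gt(max(abs(rel_r[n, , ] - rel_r[1, , ])), 0.1)
  # per-frame centroid is exactly zero
  ds <- random_dot_sequence(20)
  rel <- relative_position_series(ds)
  expect_lt(max(abs(apply(rel, c(1, 3), mean))), 1e-12)
})

test_that("relative similarity hits its boundary and symmetric values", {
  set.seed(4)
  b <- relative_position_series(random_dot_sequence(12))
  n <- relative_position_series(random_dot_sequence(12))
  expect_identical(relative_similarity(b, b, n)$value, 1)
  expect_identical(relative_similarity(n, b, n)$value, 0)
  # equidistant by construction: s is the midpoint series
  s <- (b + n) / 2
  expect_equal(relative_similarity(s, b, n)$value, 0.5)
  # all-identical degenerate case
  expect_equal(relative_similarity(b, b, b)$value, 0.5)
  expect_error(relative_similarity(b[1:5, , ], b, n), "misaligned")
  v <- relative_similarity((b + 3 * n) / 4, b, n)$value
  expect_true(v >= 0 && v <= 1)
})

test_that("dot speeds match a finite-difference oracle and known kinematics", {
  set.seed(5)
  ds <- random_dot_sequence(40)
  sp <- dot_speed_series(ds)
  rel <- relative_position_series(ds)
  for (d in 1:6) {
    oracle <- sqrt(diff(rel[, d, 1])^2 + diff(rel[, d, 2])^2) * 30
    expect_equal(sp[, d], oracle)
  }
  # rigid translation -> all speeds zero
  shape <- cbind(seq(10, 0, length.out = 6), rep(0, 6))
  cen <- cbind(seq(20, 100, length.out = 30), seq(30, 90, length.out = 30))
  tra <- rigid_dot_sequence(shape, rep(0, 30), cen)
  expect_equal(max(dot_speed_series(tra)), 0)
  # oscillation at f Hz with amplitude A peaks near 2*pi*f*A
  fps <- 100; f <- 2; A <- 3
  t <- (0:999) / fps
  coords <- array(0, c(1000, 6, 2))
  coords[, , 1] <- matrix(seq(10, 0, length.out = 6), 1000, 6, byrow = TRUE)
  coords[, 1, 2] <- A * sin(2 * pi * f * t)   # dot 1 oscillates in z
  osc <- dot_sequence(coords, fps = fps)
  peak <- max(dot_speed_series(osc)[, 1])
  # dot 1 keeps 5/6 of its amplitude relative to the centroid
  expect_equal(peak, 2 * pi * f * A * 5 / 6, tolerance = 0.02)
})

test_that("the PSD slope is scale-invariant and flags motionless input", {
  x <- generate_powerlaw_signal(1024, -1, seed = 6)
  sp <- cbind(abs(x), 2 * abs(x), 5 * abs(x))
  r1 <- psd_slope(sp, fps = 30)
  r2 <- psd_slope(100 * sp, fps = 30)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-12)
  expect_equal(r1$bin_logmeans[, 1], r1$bin_logmeans[, 2], tolerance = 1e-12)
  still <- matrix(0, 128, 6)
  rs <- psd_slope(still, fps = 30)
  expect_true(all(rs$flagged))
  expect_true(is.na(rs$slope))
  expect_error(psd_slope(matrix(1, 10, 2), fps = 30))
})

test_that("the classifier probe memorizes its training clips and separates offsets", {
  set.seed(7)
  ds <- smooth_dot_sequence(90)
  tr <- extract_trajectory(ds)
  po <- extract_posture(ds, tr)
  bio <- compose_stimulus(po, tr, "biomotion", loop_count = 1)
  nb_tr <- synthesize_nonbio_trajectory(screen_region(), 300, 3, 30, seed = 2)
  nb <- compose_stimulus(NULL, nb_tr, "non-bio", loop_count = 1, spacing = 4)
  pr <- ann_probe(list(bio, nb), list(bio = bio, nb = nb), n_windows = 40,
                  window_s = 2, seed = 8, maxit = 150)
  expect_lt(abs(pr$outputs$bio$mean - 1), 0.2)
  expect_lt(abs(pr$outputs$nb$mean - 0), 0.2)
  expect_true(all(unlist(lapply(pr$outputs, `[[`, "values")) >= 0 &
                    unlist(lapply(pr$outputs, `[[`, "values")) <= 1))

  # clips differing only by a large constant trajectory offset are separable
  ds2 <- dot_sequence(sweep(ds$coords, 3, c(400, 0), "+"), fps = 30)
  tr2 <- extract_trajectory(ds2)
  po2 <- extract_posture(ds2, tr2)
  far <- compose_stimulus(po2, tr2, "non-bio", loop_count = 1)
  pr2 <- ann_probe(list(bio, far), list(near = bio, far = far),
                   n_windows = 40, window_s = 2, seed = 9, maxit = 150,
                   targets = c(1, 0))
  expect_gt(pr2$outputs$near$mean, 0.8)
  expect_lt(pr2$outputs$far$mean, 0.2)
})

test_that("probe training is deterministic and rejects a single class", {
  set.seed(9)
  ds <- random_dot_sequence(60)
  tr <- extract_trajectory(ds)
  bio <- compose_stimulus(extract_posture(ds, tr), tr, "biomotion", 1)
  nb_tr <- synthesize_nonbio_trajectory(screen_region(), 200, 2, 30, seed = 1)
  nb <- compose_stimulus(NULL, nb_tr, "non-bio", 1, spacing = 4)
  a <- ann_probe(list(bio, nb), list(x = nb), n_windows = 15, window_s = 1,
                 seed = 3, maxit = 60)
  b <- ann_probe(list(bio, nb), list(x = nb), n_windows = 15, window_s = 1,
                 seed = 3, maxit = 60)
  expect_identical(a$outputs$x$values, b$outputs$x$values)
  expect_error(ann_probe(list(bio, bio), list(x = bio), seed = 1),
               "single class")
})
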