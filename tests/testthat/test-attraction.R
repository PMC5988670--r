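test_that("minute means reproduce closed forms and direct windowed averages", {
  fps <- 30
  t <- (0:(6 * 60 * fps - 1)) / fps
  const <- behavior_track(t, rep(75, length(t)), rep(33, length(t)),
                          onset = 60, fps = fps)
  expect_equal(unname(minute_means(const)), rep(33, 6), ignore_attr = TRUE)
  ramp <- behavior_track(t, rep(75, length(t)), pmin(t, 149),
                         onset = 60, fps = fps)
  expect_equal(unname(minute_means(ramp))[1], mean(t[t < 60]))
  expect_equal(unname(minute_means(ramp))[1], 30, tolerance = 0.05)
  # synthetic relaxation track vs direct windowed average
  tr <- generate_behavior_tracks(0.02, noise_sd = 3, ar1_coeff = 0.9,
                                 n_fish = 1, seed = 3)[[1]]
  direct <- vapply(0:5, function(m)
    mean(tr$y[tr$t >= 60 * m & tr$t < 60 * (m + 1)]), numeric(1))
  expect_equal(unname(minute_means(tr)), direct, ignore_attr = TRUE)
  expect_error(minute_means(const, minutes = 7), "cover")
})

test_that("the published FDR pattern yields exactly three significant stimuli", {
  dec <- fdr_decisions(c(0.0002, 0.001, 0.001, 0.81), level = 0.1,
                       adjusted = TRUE)
  expect_equal(sum(dec), 3)
  expect_equal(as.logical(dec), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("BH adjustment agrees with brute-force step-up enumeration", {
  set.seed(12)
  for (m in c(2, 4, 8)) {
    for (r in 1:20) {
      p <- runif(m)^2
      lvl <- runif(1, 0.02, 0.2)
      expect_identical(as.logical(fdr_decisions(p, lvl)),
                       oracle_bh_stepup(p, lvl))
    }
  }
})

test_that("identical windows are rarely declared significant (type-I control)", {
  set.seed(13)
  hits <- 0
  for (r in 1:100) {
    groups <- lapply(1:4, function(g)
      cbind(rnorm(16, 41, 6), rnorm(16, 41, 6)))
    names(groups) <- letters[1:4]
    res <- attraction_test(groups, fdr_level = 0.1)
    hits <- hits + any(res$significant)
  }
  expect_lt(hits / 100, 0.25)
})

test_that("attraction is detected for responding groups but not a flat one", {
  att <- generate_behavior_tracks(0.02, t0 = 77, y0 = 10, y_eq = 41,
                                  noise_sd = 3, ar1_coeff = 0.9, n_fish = 16,
                                  seed = 31)
  # a non-responding group: no drop at t0
  flat <- generate_behavior_tracks(0.02, t0 = 77, y0 = 41, y_eq = 41,
                                   noise_sd = 3, ar1_coeff = 0.9, n_fish = 16,
                                   seed = 32)
  mm <- function(trks) t(vapply(trks, minute_means, numeric(6)))
  groups <- list(biomotion = mm(att), `bio-posture` = mm(att),
                 `bio-trajectory` = mm(att), `non-bio` = mm(flat))
  res <- attraction_test(groups, fdr_level = 0.1)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_lt(res$mean_test[1], res$mean_baseline[1])
})

test_that("the z-test reproduces normal tail probabilities", {
  expect_equal(ztest_attraction(24, 41, 8.5), pnorm(-2), tolerance = 1e-12)
  expect_equal(signif(ztest_attraction(24, 41, 8.5), 2), 0.023)
  expect_equal(ztest_attraction(41, 41, 8.5), 0.5)
  expect_equal(ztest_attraction(41 - 1.644854 * 8.5, 41, 8.5), 0.05,
               tolerance = 1e-4)
  expect_equal(ztest_attraction(41 - 2.326348 * 8.5, 41, 8.5), 0.01,
               tolerance = 1e-4)
})

test_that("the relaxation rate is recovered exactly from a noiseless curve", {
  t <- seq(77.5, 359.5)
  y <- (10 - 41) * exp(-0.05 * (t - 77)) + 41
  fit <- fit_relaxation(t, y, t0 = 77, y0 = 10, y_eq = 41)
  expect_lt(abs(fit$k - 0.05), 1e-6)
  expect_equal(retention_time(fit), 20, tolerance = 1e-3)
  expect_equal(unname(coef(fit)), fit$k)
  expect_equal(predict(fit, t), y, tolerance = 1e-4)
  expect_equal(predict(fit, 50), 41)  # pre-relaxation level
})

test_that("a flat series at y0 is flagged as unbounded retention", {
  t <- seq(77, 360)
  fit <- fit_relaxation(t, rep(10, length(t)), t0 = 77, y0 = 10, y_eq = 41)
  expect_true(fit$unbounded)
  expect_identical(retention_time(fit), Inf)
})

test_that("re-expressing y in other units leaves the fitted rate unchanged", {
  trks <- generate_behavior_tracks(0.02, noise_sd = 3, ar1_coeff = 0.9,
                                   n_fish = 16, seed = 41)
  ys <- mean_y_series(trks)
  f_mm <- fit_relaxation(ys$t, ys$y, t0 = 77, y0 = 10, y_eq = 41)
  f_cm <- fit_relaxation(ys$t, ys$y / 10, t0 = 77, y0 = 1, y_eq = 4.1)
  expect_equal(f_cm$k, f_mm$k, tolerance = 1e-7)
  expect_equal(f_cm$se_k, f_mm$se_k, tolerance = 1e-6)
})

test_that("Bonferroni correction widens the retention interval", {
  trks <- generate_behavior_tracks(0.02, noise_sd = 3, ar1_coeff = 0.9,
                                   n_fish = 16, seed = 43)
  ys <- mean_y_series(trks)
  plain <- fit_relaxation(ys$t, ys$y)
  bonf <- fit_relaxation(ys$t, ys$y, bonferroni_m = 6)
  expect_gt(diff(bonf$retention_ci), diff(plain$retention_ci))
  expect_equal(bonf$k, plain$k)
})
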