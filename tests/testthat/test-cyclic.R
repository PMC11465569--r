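test_that("cyclic basis wraps, sums to one, and penalizes only non-constants", {
  b <- cyclic_basis(c(0, 24, 3.7, 3.7 + 24), period = 24, k = 5)
  expect_equal(b$design[1, ], b$design[2, ], tolerance = 1e-12)
  expect_equal(b$design[3, ], b$design[4, ], tolerance = 1e-12)
  # B-splines (after cyclic folding) form a partition of unity, so a
  # constant is exactly representable and unpenalized
  xs <- seq(0, 24, by = 0.1)
  B <- cyclic_basis(xs, 24, 5)$design
  expect_equal(rowSums(B), rep(1, length(xs)), tolerance = 1e-10)
  expect_equal(max(abs(b$penalty %*% rep(1, 5))), 0, tolerance = 1e-12)
  expect_error(cyclic_basis(1, 24, 2), "k >= 3")
})

test_that("an unpenalized basis regression reproduces a smooth periodic signal", {
  xs <- seq(0, 24, length.out = 200)[-200]
  y <- sin(2 * pi * xs / 24)
  B <- cyclic_basis(xs, 24, 10)$design
  coef <- qr.solve(B, y)
  expect_lt(max(abs(B %*% coef - y)), 1e-3)
})

test_that("the cyclic additive model shrinks to constants and recovers harmonics", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  # constant response: flat predictions, near-zero smooth edf
  fitc <- fit_cyclic_gam(g$hour, g$period - 1, rep(2.5, nrow(g)))
  expect_equal(unname(fitc$fitted), rep(2.5, nrow(g)), tolerance = 1e-6)
  expect_lt(fitc$edf[["hour"]], 1 + 0.01)
  expect_lt(fitc$edf[["year"]], 1 + 0.01)
  s <- predict_surface(fitc)
  expect_equal(max(s) - min(s), 0, tolerance = 1e-6)
  # noise-free diel harmonic: hour smooth recovers it, year smooth stays flat
  y <- 0.4 + 1 * cos(2 * pi * g$hour / 24)
  fith <- fit_cyclic_gam(g$hour, g$period - 1, y)
  expect_lt(max(abs(fith$fitted - y)), 1e-2)
  expect_lt(fith$edf[["year"]], 0.5)
  expect_gt(fith$edf[["hour"]], 1.5)
  # full shrinkage limit: grand mean
  set.seed(41)
  yn <- rnorm(nrow(g))
  fitl <- fit_cyclic_gam(g$hour, g$period - 1, yn, lambda_grid = 1e12)
  expect_equal(unname(fitl$fitted), rep(mean(yn), nrow(g)), tolerance = 1e-4)
  expect_error(fit_cyclic_gam(0:10, 0:10, rnorm(11)), "at least 50")
})

test_that("GCV picks the grid minimum and predictions wrap at both seams", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  set.seed(42)
  y <- 0.3 * cos(2 * pi * g$hour / 24) + rnorm(nrow(g), sd = 0.3)
  fit <- fit_cyclic_gam(g$hour, g$period - 1, y)
  gg <- fit$gcv_grid
  expect_equal(fit$gcv, min(gg$gcv), tolerance = 1e-6)
  # diel seam: hour 24 equals hour 0; seasonal seam: day 365 sits at the
  # wrap point and meets day 1
  d <- sample(1:365, 20)
  expect_equal(predict(fit, d, rep(24 - 1e-9, 20)),
               predict(fit, d, rep(0, 20)), tolerance = 1e-4)
  expect_equal(predict(fit, rep(365, 24), 0:23),
               predict(fit, rep(1, 24), 0:23), tolerance = 1e-4)
  # grid mean equals the intercept for centered terms on the balanced grid
  fit0 <- fit_cyclic_gam(g$hour, g$period - 1,
                         0.7 + 0.5 * cos(2 * pi * (g$period - 1) / 26))
  expect_equal(mean(fit0$fitted), fit0$coefficients[1], tolerance = 1e-8)
})

test_that("tensor interaction recovers a separable product signal", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  y <- 0.8 * cos(2 * pi * g$hour / 24) * cos(2 * pi * (g$period - 1) / 26)
  fit <- fit_cyclic_gam(g$hour, g$period - 1, y)
  expect_gt(cor(fit$fitted, y), 0.99)
  expect_gt(fit$edf[["interaction"]], 2)
})

test_that("the cyclic fit tracks an mgcv reference on the same data", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  set.seed(43)
  y <- 0.5 + cos(2 * pi * g$hour / 24) +
    0.6 * sin(2 * pi * (g$period - 1) / 26) + rnorm(nrow(g), sd = 0.25)
  fit <- fit_cyclic_gam(g$hour, g$period - 1, y)
  ref <- mgcv::gam(y ~ s(hour, bs = "cc", k = 5) + s(per, bs = "cc", k = 10) +
                     ti(hour, per, bs = c("cc", "cc"), k = c(5, 10)),
                   data = data.frame(hour = g$hour, per = g$period - 1, y = y),
                   knots = list(hour = c(0, 24), per = c(0, 26)))
  expect_gt(cor(fit$fitted, fitted(ref)), 0.98)
})

test_that("permutation significance is deterministic and detects a strong signal", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  set.seed(44)
  y <- 2 * cos(2 * pi * g$hour / 24) + rnorm(nrow(g), sd = 0.2)
  fit <- fit_cyclic_gam(g$hour, g$period - 1, y)
  p1 <- significance_by_permutation(fit, n_perm = 199, seed = 3)
  p2 <- significance_by_permutation(fit, n_perm = 199, seed = 3)
  expect_identical(p1, p2)
  expect_equal(p1[["hour"]], 1 / 200)
  expect_warning(significance_by_permutation(fit, n_perm = 50, seed = 3),
                 "coarse")
})
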