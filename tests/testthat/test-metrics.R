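surf <- function(m) structure(m, days = seq_len(nrow(m)),
                              hours = seq_len(ncol(m)) - 1,
                              class = "selection_surface")

test_that("relative selection strength is exp(beta)", {
  expect_equal(rss(0), 1)
  expect_equal(rss(log(1.36)), 1.36)
  expect_equal(rss(-log(2)), 0.5)
})

test_that("preference share counts positive cells and splits medians", {
  all_pos <- surf(matrix(0.2, 10, 4))
  expect_equal(preference_share(all_pos)$share_positive, 1)
  half <- surf(matrix(c(rep(1, 20), rep(-1, 20)), 10, 4))
  ps <- preference_share(half)
  expect_equal(ps$share_positive, 0.5)
  expect_equal(ps$median_rss_positive, exp(1))
  expect_equal(ps$median_rss_negative, exp(-1))
  # exact zeros count as non-preference
  expect_equal(preference_share(surf(matrix(0, 5, 5)))$share_positive, 0)
})

test_that("cumulative surface sums absolute coefficients with a high flag", {
  mods <- c("deciduous", "coniferous", "wetland", "grassland", "arable")
  zero <- setNames(lapply(mods, function(m) surf(matrix(0, 3, 2))), mods)
  expect_true(all(cumulative_surface(zero) == 0))
  vals <- c(1, -1, 0.5, -0.5, 0.25)
  ss <- setNames(lapply(vals, function(v) surf(matrix(v, 3, 2))), mods)
  cum <- cumulative_surface(ss)
  expect_equal(unclass(cum)[1, 1], 3.25)
  # sign-invariance: flipping any habitat's field changes nothing
  ss2 <- ss; ss2$wetland <- surf(matrix(-0.5, 3, 2))
  expect_equal(unclass(cumulative_surface(ss2)), unclass(cum))
  # the display threshold flags points with sum above 3.5
  ss3 <- ss; ss3$deciduous <- surf(matrix(1.3, 3, 2))
  expect_true(all(attr(cumulative_surface(ss3), "high")))
  expect_false(any(attr(cum, "high")))
  ss$arable <- surf(matrix(0, 4, 2))
  expect_error(cumulative_surface(ss), "misaligned")
  expect_error(cumulative_surface(zero[1:3]), "missing surface")
})

test_that("smoothing the cumulative surface preserves flat and harmonic inputs", {
  flat <- structure(matrix(1.89, 365, 24), days = 1:365, hours = 0:23,
                    class = "cumulative_surface")
  fitf <- fit_cumulative_gam(flat)
  expect_equal(as.vector(unclass(fitf$surface)), rep(1.89, 365 * 24),
               tolerance = 1e-6)
  g <- expand.grid(day = 1:365, hour = 0:23)
  harm <- structure(matrix(2 + cos(2 * pi * g$hour / 24), 365, 24),
                    days = 1:365, hours = 0:23, class = "cumulative_surface")
  fith <- fit_cumulative_gam(harm)
  expect_lt(max(abs(unclass(fith$surface) - unclass(harm))), 1e-2)
  # shrinkage keeps a smooth fit within the data range (small tolerance)
  rng <- range(harm)
  expect_gt(min(fith$surface), rng[1] - 0.05)
  expect_lt(max(fith$surface), rng[2] + 0.05)
})

test_that("fold differences use marginal max/min ratios and are scale-invariant", {
  const <- matrix(4, 365, 24)
  f <- fold_differences(const)
  expect_equal(f$diel_fold, 1)
  expect_equal(f$seasonal_fold, 1)
  g <- expand.grid(day = 1:365, hour = 0:23)
  s <- matrix(2 * (1 + 0.5 * cos(2 * pi * g$hour / 24)), 365, 24)
  f2 <- fold_differences(s)
  expect_equal(f2$diel_fold, 1.5 / 0.5, tolerance = 1e-10)
  expect_equal(f2$seasonal_fold, 1, tolerance = 1e-10)
  f3 <- fold_differences(s * 17.3)
  expect_equal(f3$diel_fold, f2$diel_fold)
  expect_error(fold_differences(s - 2), "strictly positive")
})

test_that("repeatability counts unordered cell pairs and bounds correlations", {
  g <- expand.grid(hour = 0:23, period = 1:26)
  mk_gam <- function(y) fit_cyclic_gam(g$hour, g$period - 1, y)
  set.seed(51)
  gams <- list(a = mk_gam(rnorm(624)), b = mk_gam(rnorm(624)),
               c = mk_gam(cos(2 * pi * g$hour / 24)),
               d = mk_gam(sin(2 * pi * (g$period - 1) / 26)),
               e = mk_gam(rnorm(624)), f = mk_gam(rnorm(624)),
               g = mk_gam(rnorm(624)))
  # 10 cells -> C(10,2) = 45 pairs
  r10 <- repeatability(gams, periods = 1:5, hours = 0:1)
  expect_equal(r10$n_pairs, choose(10, 2))
  expect_true(all(r10$correlations >= -1 & r10$correlations <= 1))
  full <- repeatability(gams)
  expect_equal(full$n_pairs, choose(624, 2))
  expect_identical(full$n_cells, 624L)
})

test_that("identical and negated cell vectors give r = 1 and r = -1", {
  # seven pure-diel models with different amplitudes: at hours 0 and 12 the
  # per-cell coefficient vectors are c and -c, so cells sharing an hour
  # correlate at +1 and cells 12 h apart at -1
  g <- expand.grid(hour = 0:23, period = 1:26)
  amps <- c(1, -0.5, 2, 0.3, -1.2, 0.8, 1.5)
  gams <- lapply(amps, function(a)
    fit_cyclic_gam(g$hour, g$period - 1, a * cos(2 * pi * g$hour / 24)))
  names(gams) <- paste0("m", 1:7)
  r <- repeatability(gams, periods = 1:2, hours = c(0, 12))
  expect_equal(r$n_pairs, choose(4, 2))
  expect_equal(sort(round(r$correlations, 3)), c(-1, -1, -1, -1, 1, 1))
  expect_equal(r$proportion_negative, 4 / 6)
})
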