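test_that("temporal cell assignment follows the 14-day x 1-hour rule", {
  cell <- assign_temporal_cell(utc("2021-01-03 00:30:00"))
  expect_identical(c(cell$period, cell$hour), c(1L, 0L))
  cell2 <- assign_temporal_cell(utc("2021-01-15 00:30:00"))
  expect_identical(c(cell2$period, cell2$hour), c(2L, 0L))
  # day 365 would fall in a 27th block; it is absorbed into period 26
  cell3 <- assign_temporal_cell(utc("2021-12-31 23:30:00"))
  expect_identical(c(cell3$period, cell3$hour), c(26L, 23L))
  # leap-year day 366 also absorbed
  cell4 <- assign_temporal_cell(utc("2020-12-31 12:00:00"))
  expect_identical(c(cell4$period, cell4$hour), c(26L, 12L))
})

test_that("partition conserves pairs and covers 624 cells at full coverage", {
  pairs <- synth_pairs_grid(pairs_per_cell = 3L, seed = 2)
  p <- partition_pairs(pairs)
  cells <- unique(p[p$case == 1, c("period", "hour")])
  expect_identical(nrow(cells), 624L)
  expect_identical(sum(table(p$period, p$hour)), nrow(pairs))
  # every stratum in exactly one cell
  per_stratum <- tapply(paste(p$period, p$hour), p$stratum,
                        function(k) length(unique(k)))
  expect_true(all(per_stratum == 1))
  # single-cell input
  one <- partition_pairs(synth_pairs_grid(2L, seed = 3, periods = 1, hours = 0))
  expect_identical(nrow(unique(one[c("period", "hour")])), 1L)
})

test_that("subset standardization samples whole pairs, deterministically", {
  pairs <- partition_pairs(synth_pairs_grid(pairs_per_cell = 25L, seed = 4,
                                            periods = 1:2, hours = 0:1))
  std <- standardize_subsets(pairs, target_pairs = 20L, seed = 9)
  tab <- table(unique(std[c("stratum", "period", "hour")])[, c("period", "hour")])
  expect_true(all(tab == 20L))
  # strata stay intact: every retained stratum has exactly one case and one control
  expect_true(all(table(std$stratum, std$case) == 1))
  expect_true(all(std$stratum %in% pairs$stratum))
  # deterministic given the seed, different under another seed
  std2 <- standardize_subsets(pairs, target_pairs = 20L, seed = 9)
  expect_identical(std, std2)
  std3 <- standardize_subsets(pairs, target_pairs = 20L, seed = 10)
  expect_false(identical(sort(unique(std$stratum)),
                         sort(unique(std3$stratum))))
  # cell at exactly the target is returned unchanged
  exact <- standardize_subsets(pairs, target_pairs = 25L, seed = 9)
  expect_identical(sort(unique(exact$stratum)), sort(unique(pairs$stratum)))
  # shortfall policies
  expect_warning(standardize_subsets(pairs, target_pairs = 30L, seed = 9),
                 "below 30")
  expect_error(standardize_subsets(pairs, target_pairs = 30L, seed = 9,
                                   min_pairs_policy = "error"), "below 30")
})

test_that("the cell grid fits 7 models per populated cell with flags, never aborting", {
  pairs <- partition_pairs(synth_pairs_grid(pairs_per_cell = 40L, seed = 5,
                                            periods = 1:3, hours = 0:2))
  pairs <- standardize_distances(pairs)
  fits <- fit_cell_grid(pairs)
  expect_identical(nrow(fits), 9L * 7L)
  expect_setequal(unique(fits$model), ssf_models)
  # one populated cell -> 7 fits
  one <- standardize_distances(
    partition_pairs(synth_pairs_grid(40L, seed = 6, periods = 5, hours = 12)))
  expect_identical(nrow(fit_cell_grid(one)), 7L)
  # a cell with a constant covariate still yields a flagged row
  one$wetland <- 0
  fits1 <- fit_cell_grid(one)
  wet <- fits1[fits1$model == "wetland", ]
  expect_false(wet$estimable)
  expect_identical(nrow(fits1), 7L)
})

test_that("global distance standardization gives mean 0 and sample sd 1", {
  pairs <- synth_pairs_grid(10L, seed = 7, periods = 1:2, hours = 0:3)
  std <- standardize_distances(pairs)
  for (v in c("dist_road_z", "dist_settlement_z")) {
    expect_equal(mean(std[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(std[[v]]), 1, tolerance = 1e-10)
  }
  # hand-computed example with sample sd (n - 1)
  toy <- data.frame(dist_road = c(0, 10, 20), dist_settlement = c(5, 10, 15))
  z <- standardize_distances(toy)
  expect_equal(z$dist_road_z, c(-1, 0, 1))
  toy$dist_road <- 7
  expect_error(standardize_distances(toy), "zero variance")
})
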