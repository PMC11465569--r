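test_that("the choice kernel reproduces softmax probabilities on a frozen candidate set", {
  u <- c(0.5, -1, 0, 2, 1.2, -0.3)
  p <- exp(u) / sum(exp(u))
  set.seed(61)
  n <- 1e5
  freq <- tabulate(draw_choices(u, n), nbins = length(u)) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < 3 * se + 1e-9))
})

test_that("simulated tracks are deterministic and stay inside the landscape", {
  land <- tiny_landscape()
  spec <- beta_spec()
  cfg <- sim_config(n_individuals = 2, n_days = 3, seed = 5)
  a <- simulate_tracks(land, cfg, spec)
  b <- simulate_tracks(land, cfg, spec)
  expect_identical(a, b)
  expect_false(identical(a, simulate_tracks(
    land, sim_config(n_individuals = 2, n_days = 3, seed = 6), spec)))
  expect_true(all(a$x >= land$origin_x &
                    a$x < land$origin_x + land$n_cols * land$cell_size))
  expect_true(all(a$y >= land$origin_y &
                    a$y < land$origin_y + land$n_rows * land$cell_size))
  expect_identical(nrow(a), 2L * 3L * 24L)
  expect_identical(diff(a$timestamp[1:2]), as.difftime(1, units = "hours"))
})

test_that("neutral selection reproduces kernel availability; positive beta enriches", {
  land <- tiny_landscape()
  # with all beta = 0 the chosen endpoints are a uniform draw from the
  # candidate set, so their habitat frequencies must match availability
  # under the movement kernel; the oracle estimates that availability by
  # brute-force candidate sampling along the same trajectory
  cfg <- sim_config(n_individuals = 7, n_days = 300, seed = 31)
  locs <- simulate_tracks(land, cfg, beta_spec())
  expect_gte(nrow(locs) - cfg$n_individuals, 50000)
  set.seed(99)
  xmax <- land$origin_x + land$n_cols * land$cell_size
  ymax <- land$origin_y + land$n_rows * land$cell_size
  avail_pts <- do.call(rbind, lapply(split(locs, locs$id), function(tr) {
    n <- nrow(tr)
    bear <- atan2(diff(tr$y), diff(tr$x))        # bearing of step i
    # steps i = 2..n-1 (those with a previous bearing), start at fix i
    sx <- tr$x[2:(n - 1)]; sy <- tr$y[2:(n - 1)]
    pb <- bear[1:(n - 2)]
    m <- length(sx)
    px <- rep(NA_real_, m); py <- rep(NA_real_, m)
    todo <- rep(TRUE, m)
    while (any(todo)) {
      k <- sum(todo)
      len <- rgamma(k, cfg$gamma_shape, scale = cfg$gamma_scale)
      ang <- pb[todo] + rvonmises(k, 0, cfg$vm_kappa)
      cx <- sx[todo] + len * cos(ang); cy <- sy[todo] + len * sin(ang)
      ok <- cx >= land$origin_x & cx < xmax & cy >= land$origin_y & cy < ymax
      idx <- which(todo)[ok]
      px[idx] <- cx[ok]; py[idx] <- cy[ok]
      todo[idx] <- FALSE
    }
    data.frame(x = px, y = py)
  }))
  avail <- table(factor(extract_covariates(land, avail_pts$x, avail_pts$y)$habitat,
                        levels = habitat_classes)) / nrow(avail_pts)
  chosen <- locs[ave(seq_len(nrow(locs)), locs$id, FUN = seq_along) > 2, ]
  used <- table(factor(extract_covariates(land, chosen$x, chosen$y)$habitat,
                       levels = habitat_classes)) / nrow(chosen)
  n1 <- nrow(chosen); n2 <- nrow(avail_pts)
  for (h in seq_len(9)) {
    p <- (avail[h] + used[h]) / 2
    se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    # serial dependence of consecutive endpoints inflates the nominal SE
    expect_lt(abs(used[h] - avail[h]), 3 * 2 * se + 0.005)
  }
  # strong preference for deciduous forest shifts use above availability
  cfg2 <- sim_config(n_individuals = 2, n_days = 60, seed = 32)
  locs2 <- simulate_tracks(land, cfg2, beta_spec(deciduous = c(a0 = 2)))
  cov2 <- extract_covariates(land, locs2$x, locs2$y)
  expect_gt(mean(cov2$deciduous), avail[1])
})

test_that("random steps redraw against the boundary and pairs stay matched", {
  land <- tiny_landscape()
  cfg <- sim_config(n_individuals = 2, n_days = 20, seed = 12)
  locs <- simulate_tracks(land, cfg, beta_spec())
  steps <- compute_steps(regularize_bursts(filter_outliers(locs)))
  gk <- fit_gamma(steps$length)
  vk <- fit_vonmises(steps$turn)
  pairs <- build_step_pairs(steps, land, gk, vk, seed = 3)
  expect_true(all(table(pairs$stratum) == 2L))
  expect_true(all(table(pairs$stratum, pairs$case) == 1L))
  expect_true(all(in_bounds <- pairs$x >= land$origin_x &
                    pairs$x < land$origin_x + land$n_cols * land$cell_size))
  # deterministic given the seed
  pairs2 <- build_step_pairs(steps, land, gk, vk, seed = 3)
  expect_identical(pairs, pairs2)
})

test_that("interior random steps match the kernel's analytic mean and heading", {
  # a large landscape with all strata at its centre: boundary redraws never
  # trigger, so the empirical mean length must sit within Monte-Carlo error
  # of shape * scale
  big <- make_landscape(seed = 13, n_rows = 300, n_cols = 300, cell_size = 10)
  centre <- 1500
  n <- 10001L
  steps <- data.frame(
    id = "a", burst_id = 1L, x_start = centre, y_start = centre,
    x_end = centre + 10, y_end = centre,
    t_start = utc("2021-06-01 00:00:00") + 3600 * (seq_len(n) - 1),
    t_end = utc("2021-06-01 01:00:00") + 3600 * (seq_len(n) - 1),
    length = 10, bearing = 0, turn = c(NA, rep(0, n - 1)),
    turn_defined = c(FALSE, rep(TRUE, n - 1)), stratum_id = seq_len(n)
  )
  gk <- structure(list(shape = 2, scale = 150), class = "gamma_fit")
  vk <- structure(list(mu = 0, kappa = 1e6), class = "vonmises_fit")
  pairs <- build_step_pairs(steps, big, gk, vk, seed = 8)
  rnd <- pairs[pairs$case == 0, ]
  rl <- sqrt((rnd$x - centre)^2 + (rnd$y - centre)^2)
  mu <- gk$shape * gk$scale
  sd_mc <- sqrt(gk$shape) * gk$scale / sqrt(length(rl))
  expect_lt(abs(mean(rl) - mu), 3 * sd_mc)
  # near-degenerate von Mises: random bearing equals the previous bearing
  bear <- atan2(rnd$y - centre, rnd$x - centre)
  expect_lt(max(abs(bear)), 1e-2)
})
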