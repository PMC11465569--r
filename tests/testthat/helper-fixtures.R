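# Shared fixtures and independent oracles, all built in code.

# small landscape reused across tests (built once per test run)
tiny_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_landscape(seed = 11, n_rows = 60,
                                                 n_cols = 60, cell_size = 10)
    cache
  }
})

utc <- function(s) as.POSIXct(s, tz = "UTC")

# locations table from vectors
loc_df <- function(ts, x, y, id = "a") {
  data.frame(id = id, timestamp = ts, x = x, y = y)
}

# lightweight full-grid pairs (see synthetic_pairs_grid in the package)
synth_pairs_grid <- function(pairs_per_cell = 30L, seed = 1L,
                             periods = 1:26, hours = 0:23) {
  synthetic_pairs_grid(pairs_per_cell, seed, periods, hours)
}

# conditional log-likelihood of the 1:1 matched design on pair differences
clogit_loglik <- function(beta, d) sum(plogis(beta * d, log.p = TRUE))

# independent oracle: golden-section maximization of the conditional
# likelihood on [-10, 10]
golden_clogit <- function(d, lo = -10, hi = 10, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- clogit_loglik(c1, d); f2 <- clogit_loglik(c2, d)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- clogit_loglik(c2, d)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- clogit_loglik(c1, d)
    }
  }
  (a + b) / 2
}

# simulate matched pairs from the 2-alternative choice kernel with true beta
simulate_choice_pairs <- function(n, beta, rcov = function(n) rnorm(n)) {
  x1 <- rcov(n); x2 <- rcov(n)
  p1 <- 1 / (1 + exp(-beta * (x1 - x2)))
  obs_is_1 <- runif(n) < p1
  list(x_obs = ifelse(obs_is_1, x1, x2), x_rand = ifelse(obs_is_1, x2, x1))
}
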