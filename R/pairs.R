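#' Generate matched random steps and assemble the pairs table
#'
#' For every observed step with a defined previous bearing, draws `K`
#' random steps from the fitted movement kernels (length ~ gamma, turn ~
#' von Mises added to the previous bearing) starting at the same start
#' point, and assembles the long-format pairs table: one row per endpoint,
#' `case = 1` for observed and `case = 0` for random, sharing a `stratum`
#' id and the observed step's end timestamp. Endpoint covariates are
#' extracted from the landscape; strata whose random endpoint could not be
#' placed inside the landscape after 100 redraws are dropped (count
#' attached as the `"n_dropped_outside"` attribute).
#'
#' @param steps steps table from \code{\link{compute_steps}}.
#' @param landscape an \code{\link{ssf_landscape}}.
#' @param gamma_fit,vm_fit fitted kernels (\code{\link{fit_gamma}},
#'   \code{\link{fit_vonmises}}).
#' @param seed integer seed for the random-step draws.
#' @param K random steps per observed step (the reference analysis uses 1).
#' @return Pairs data.frame: `id`, `stratum`, `case`, `t_end`, `x`, `y`,
#'   `habitat`, habitat dummies, `dist_road`, `dist_settlement`.
#' @export
build_step_pairs <- function(steps, landscape, gamma_fit, vm_fit, seed = 1L,
                             K = 1L) {
  stopifnot(K >= 1L)
  rng <- local_rng(seed)
  # previous bearing within each burst; only steps following a step with a
  # defined bearing can receive kernel-drawn random steps
  prev_bearing <- rep(NA_real_, nrow(steps))
  for (b in split(seq_len(nrow(steps)), steps$burst_id)) {
    if (length(b) > 1L)
      prev_bearing[b[-1]] <- steps$bearing[b[-length(b)]]
  }
  use <- which(!is.na(prev_bearing) & steps$turn_defined)
  if (!length(use)) stop("no steps with defined turning angles", call. = FALSE)

  n <- length(use) * K
  len <- stats::rgamma(n, shape = gamma_fit$shape, scale = gamma_fit$scale)
  turn <- rvonmises(n, vm_fit$mu, vm_fit$kappa)
  bear <- rep(prev_bearing[use], each = K) + turn
  rx <- rep(steps$x_start[use], each = K) + len * cos(bear)
  ry <- rep(steps$y_start[use], each = K) + len * sin(bear)
  inside <- in_landscape(landscape, rx, ry)
  tries <- 0L
  while (any(!inside) && tries < 100L) {
    k <- which(!inside)
    len2 <- stats::rgamma(length(k), shape = gamma_fit$shape,
                          scale = gamma_fit$scale)
    turn2 <- rvonmises(length(k), vm_fit$mu, vm_fit$kappa)
    bear2 <- rep(prev_bearing[use], each = K)[k] + turn2
    rx[k] <- rep(steps$x_start[use], each = K)[k] + len2 * cos(bear2)
    ry[k] <- rep(steps$y_start[use], each = K)[k] + len2 * sin(bear2)
    inside <- in_landscape(landscape, rx, ry)
    tries <- tries + 1L
  }
  # strata whose random endpoint never landed inside are dropped
  bad_stratum <- unique(rep(seq_along(use), each = K)[!inside])
  keep <- if (length(bad_stratum)) !(seq_along(use) %in% bad_stratum)
          else rep(TRUE, length(use))
  use <- use[keep]

  obs_cov <- extract_covariates(landscape, steps$x_end[use], steps$y_end[use])
  keep_long <- rep(keep, each = K)
  rnd_cov <- extract_covariates(landscape, rx[keep_long], ry[keep_long])
  obs <- data.frame(id = steps$id[use], stratum = steps$stratum_id[use],
                    case = 1L, t_end = steps$t_end[use],
                    x = steps$x_end[use], y = steps$y_end[use], obs_cov)
  rnd <- data.frame(id = rep(steps$id[use], each = K),
                    stratum = rep(steps$stratum_id[use], each = K),
                    case = 0L, t_end = rep(steps$t_end[use], each = K),
                    x = rx[keep_long], y = ry[keep_long], rnd_cov)
  out <- rbind(obs, rnd)
  out <- out[order(out$stratum, -out$case), ]
  rownames(out) <- NULL
  attr(out, "n_dropped_outside") <- length(bad_stratum)
  out
}

#' Standardize distance covariates globally
#'
#' Z-scores `dist_road` and `dist_settlement` over all endpoints (observed
#' and random pooled, across the whole dataset), using the sample standard
#' deviation (n - 1). Global standardization keeps the distance-model
#' coefficients on one common scale across all temporal cells, which the
#' second-stage smoothing requires.
#'
#' @param pairs pairs table from \code{\link{build_step_pairs}}.
#' @return The pairs table with `dist_road_z` and `dist_settlement_z` added
#'   (mean 0, sd 1).
#' @export
standardize_distances <- function(pairs) {
  for (v in c("dist_road", "dist_settlement")) {
    x <- pairs[[v]]
    if (length(unique(x)) < 2L)
      stop("zero variance in ", v, ": cannot standardize", call. = FALSE)
    pairs[[paste0(v, "_z")]] <- (x - mean(x)) / stats::sd(x)
  }
  pairs
}

# covariate column used by each of the seven models
model_column <- function(model) {
  switch(model,
         dist_road = "dist_road_z",
         dist_settlement = "dist_settlement_z",
         model)
}

#' Write / read the pairs table CSV
#'
#' @param pairs pairs table.
#' @param path CSV path.
#' @export
write_pairs_csv <- function(pairs, path) {
  out <- pairs
  out$t_end <- format(out$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$t_end <- parse_utc(d$t_end)
  d
}
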