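#' Simulation configuration
#'
#' Defaults describe the study design the pipeline targets: hourly fixes
#' over one full calendar year for multiple individuals, a gamma step-length
#' kernel with mean 300 m (shape 2, scale 150 m), mildly persistent headings
#' (von Mises kappa 0.5), and 10 candidate endpoints per move.
#'
#' @param n_individuals number of simulated animals.
#' @param start first fix timestamp (UTC). A non-leap year keeps the
#'   365-day seasonal domain exact.
#' @param n_days days of hourly tracking per individual.
#' @param fix_interval_min fix interval, minutes.
#' @param gamma_shape,gamma_scale step-length kernel (scale in meters).
#' @param vm_kappa turning-angle concentration (>= 0).
#' @param n_candidates candidate endpoints per move (M >= 2).
#' @param seed master seed for the simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5L,
                       start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                       n_days = 365L, fix_interval_min = 60,
                       gamma_shape = 2, gamma_scale = 150,
                       vm_kappa = 0.5, n_candidates = 10L, seed = 1L) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, vm_kappa >= 0,
            n_candidates >= 2L, n_individuals >= 1L, n_days >= 1L,
            fix_interval_min > 0)
  structure(list(n_individuals = as.integer(n_individuals), start = start,
                 n_days = as.integer(n_days),
                 fix_interval_min = fix_interval_min,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 vm_kappa = vm_kappa, n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed)), class = "sim_config")
}

# softmax choice probabilities for candidate utilities
choice_probs <- function(utilities) {
  w <- exp(utilities - max(utilities))
  w / sum(w)
}

#' Draw multinomial choices from candidate utilities
#'
#' The selection kernel of the simulator: candidate i is chosen with
#' probability proportional to `exp(utilities[i])`.
#'
#' @param utilities numeric vector of candidate utilities (sum of beta *
#'   covariate over model terms).
#' @param n number of independent draws.
#' @return Integer indices in `1..length(utilities)`.
#' @export
draw_choices <- function(utilities, n = 1L) {
  sample.int(length(utilities), n, replace = TRUE, prob = choice_probs(utilities))
}

# Per-(day, hour) beta lookup tables for fast utility evaluation:
# class_beta is 9 x 8760 (habitat code x day-hour index), road/settlement
# are length-8760 vectors.
beta_tables <- function(spec) {
  g <- expand.grid(hour = 0:23, day = 1:365)   # dh index = (day-1)*24 + hour + 1
  class_beta <- matrix(0, nrow = 9, ncol = nrow(g))
  for (m in names(.model_class))
    class_beta[.model_class[[m]], ] <- true_beta(spec, m, g$day, g$hour)
  list(class_beta = class_beta,
       road = true_beta(spec, "dist_road", g$day, g$hour),
       settlement = true_beta(spec, "dist_settlement", g$day, g$hour))
}

#' Simulate movement tracks under known time-varying selection
#'
#' Forward model of the step-selection process: at each fix, M candidate
#' endpoints are drawn (length ~ gamma, turn ~ von Mises relative to the
#' previous bearing; the first move uses uniform absolute bearings) and one
#' is selected with probability proportional to
#' `exp(sum_h beta_h(day, hour) x_h)` evaluated at the candidate endpoint.
#' Candidate draws leaving the landscape are redrawn (up to 100 rounds),
#' then reflected off the boundary. Distance covariates enter the utility
#' z-scored over the whole landscape grid.
#'
#' @param landscape an \code{\link{ssf_landscape}}.
#' @param config a \code{\link{sim_config}}.
#' @param spec a \code{\link{beta_spec}} of true selection surfaces.
#' @return A locations data.frame (`id`, `timestamp`, `x`, `y`), hourly per
#'   individual; the number of boundary reflections is attached as the
#'   `"n_reflected"` attribute.
#' @export
simulate_tracks <- function(landscape, config, spec) {
  stopifnot(inherits(landscape, "ssf_landscape"),
            inherits(config, "sim_config"), inherits(spec, "beta_spec"))
  rng <- local_rng(config$seed)
  tb <- beta_tables(spec)
  M <- config$n_candidates
  cs <- landscape$cell_size
  ox <- landscape$origin_x; oy <- landscape$origin_y
  xmax <- ox + landscape$n_cols * cs; ymax <- oy + landscape$n_rows * cs
  hab <- landscape$habitat_grid
  zr <- as.vector(scale(as.vector(landscape$dist_road_grid)))
  zs <- as.vector(scale(as.vector(landscape$dist_settlement_grid)))
  n_rows <- landscape$n_rows; n_cols <- landscape$n_cols

  n_fix <- config$n_days * as.integer(round(24 * 60 / config$fix_interval_min))
  times <- config$start + (seq_len(n_fix) - 1) * config$fix_interval_min * 60
  doy <- as.POSIXlt(times, tz = "UTC")$yday + 1L
  doy[doy > 365L] <- 365L
  hr <- as.POSIXlt(times, tz = "UTC")$hour
  dh <- (doy - 1L) * 24L + hr + 1L

  reflect <- function(v, lo, hi) {
    w <- hi - lo
    v <- (v - lo) %% (2 * w)
    lo + ifelse(v > w, 2 * w - v, v)
  }
  n_reflected <- 0L

  tracks <- vector("list", config$n_individuals)
  for (ind in seq_len(config$n_individuals)) {
    x <- numeric(n_fix); y <- numeric(n_fix)
    x[1] <- stats::runif(1, ox + 0.1 * (xmax - ox), xmax - 0.1 * (xmax - ox))
    y[1] <- stats::runif(1, oy + 0.1 * (ymax - oy), ymax - 0.1 * (ymax - oy))
    prev_bearing <- NA_real_
    for (i in 2:n_fix) {
      len <- stats::rgamma(M, shape = config$gamma_shape,
                           scale = config$gamma_scale)
      bear <- if (is.na(prev_bearing)) {
        stats::runif(M, -pi, pi)
      } else {
        prev_bearing + rvonmises(M, 0, config$vm_kappa)
      }
      cx <- x[i - 1] + len * cos(bear)
      cy <- y[i - 1] + len * sin(bear)
      out <- cx < ox | cx >= xmax | cy < oy | cy >= ymax
      tries <- 0L
      while (any(out) && tries < 100L) {
        k <- sum(out)
        len2 <- stats::rgamma(k, shape = config$gamma_shape,
                              scale = config$gamma_scale)
        bear2 <- if (is.na(prev_bearing)) stats::runif(k, -pi, pi)
                 else prev_bearing + rvonmises(k, 0, config$vm_kappa)
        cx[out] <- x[i - 1] + len2 * cos(bear2)
        cy[out] <- y[i - 1] + len2 * sin(bear2)
        bear[out] <- bear2
        out <- cx < ox | cx >= xmax | cy < oy | cy >= ymax
        tries <- tries + 1L
      }
      if (any(out)) {
        n_reflected <- n_reflected + sum(out)
        cx[out] <- reflect(cx[out], ox, xmax - 1e-9)
        cy[out] <- reflect(cy[out], oy, ymax - 1e-9)
      }
      col <- floor((cx - ox) / cs) + 1L
      row <- floor((cy - oy) / cs) + 1L
      lin <- row + (col - 1L) * n_rows
      u <- tb$class_beta[hab[lin] + 9L * (dh[i] - 1L)] +
        tb$road[dh[i]] * zr[lin] + tb$settlement[dh[i]] * zs[lin]
      pick <- draw_choices(u, 1L)
      x[i] <- cx[pick]; y[i] <- cy[pick]
      prev_bearing <- atan2(y[i] - y[i - 1], x[i] - x[i - 1])
    }
    tracks[[ind]] <- data.frame(id = sprintf("sim%03d", ind),
                                timestamp = times, x = x, y = y)
  }
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  attr(out, "n_reflected") <- n_reflected
  out
}
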