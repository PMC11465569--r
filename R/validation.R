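#' Lightweight matched-pairs generator on the full temporal grid
#'
#' Synthesizes a pairs table that covers every 14-day x 1-hour cell of a
#' calendar year without running the movement simulator: each stratum gets
#' an observed and a random endpoint with habitat codes drawn from slightly
#' different distributions (observed endpoints favour deciduous forest) and
#' exponential raw distances. Intended for structural validation of the
#' grid machinery (cell counts, subsampling, fit bookkeeping) and for
#' examples; it carries no spatial or temporal signal beyond the constant
#' habitat preference.
#'
#' @param pairs_per_cell strata per temporal cell.
#' @param seed integer seed.
#' @param periods,hours the cells to cover (defaults: all 26 periods, all
#'   24 hours).
#' @param p_obs,p_rand probability that an observed / random endpoint falls
#'   in deciduous forest.
#' @return A pairs table with the same layout as
#'   \code{\link{build_step_pairs}}.
#' @export
synthetic_pairs_grid <- function(pairs_per_cell = 30L, seed = 1L,
                                 periods = 1:26, hours = 0:23,
                                 p_obs = 0.35, p_rand = 0.20) {
  rng <- local_rng(seed)
  cells <- expand.grid(period = periods, hour = hours)
  n <- nrow(cells) * pairs_per_cell
  period <- rep(cells$period, each = pairs_per_cell)
  hour <- rep(cells$hour, each = pairs_per_cell)
  day_lo <- (period - 1) * 14 + 1
  day_hi <- pmin(period * 14 + (period == 26) * 1, 365)
  day <- day_lo + floor(stats::runif(n) * (day_hi - day_lo + 1))
  t_end <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") +
    (day - 1) * 86400 + hour * 3600 + 1800
  mk_side <- function(case, p_decid) {
    hab <- ifelse(stats::runif(n) < p_decid, 1L,
                  sample(2:9, n, replace = TRUE))
    d <- data.frame(id = "synthetic", stratum = seq_len(n), case = case,
                    t_end = t_end, x = 0, y = 0, habitat = hab)
    for (m in names(.model_class)) d[[m]] <- as.numeric(hab == .model_class[[m]])
    d$dist_road <- stats::rexp(n, 1 / 400)
    d$dist_settlement <- stats::rexp(n, 1 / 700)
    d
  }
  out <- rbind(mk_side(1L, p_obs), mk_side(0L, p_rand))
  out <- out[order(out$stratum, -out$case), ]
  rownames(out) <- NULL
  out
}

#' End-to-end parameter recovery experiment
#'
#' Simulates tracks under a known pair of time-varying selection surfaces
#' -- a natural habitat (deciduous forest) with pure seasonal variation and
#' an anthropogenic habitat (grassland) with pure diel variation, both with
#' amplitude 1 on the link scale -- runs the full pipeline on the simulated
#' tracks, and compares the recovered smoothed surfaces against the truth:
#' Pearson correlation on the 365 x 24 grid, plus diel and seasonal fold
#' differences of each habitat's `exp(beta)` surface. Successful recovery
#' shows the diel-varying habitat with a dominant diel fold and the
#' seasonally varying habitat with a dominant seasonal fold.
#'
#' @param n_individuals simulated individuals (one year of hourly fixes
#'   each, so also the number of individual-years).
#' @param seed master seed.
#' @param landscape optional `ssf_landscape`; by default a 150 x 150 grid
#'   of 20 m cells (3 km x 3 km) so the mosaic grain stays resolved
#'   relative to the 300 m mean step.
#' @param spec optional `beta_spec` overriding the default truth.
#' @return A list: `spec`, `correlations` (named, per focal model),
#'   `folds` (per focal model, from the exp(beta) surface), `fit` (the
#'   \code{\link{tssf}} object) and `manifest`.
#' @export
recovery_experiment <- function(n_individuals = 20L, seed = 1L,
                                landscape = NULL, spec = NULL) {
  spec <- spec %||% beta_spec(deciduous = c(a0 = 0.3, a_year = 1),
                              grassland = c(a0 = -0.5, a_hour = 1))
  landscape <- landscape %||% make_landscape(seed = child_seed(seed, 99),
                                             n_rows = 150, n_cols = 150,
                                             cell_size = 20,
                                             n_seeds_per_class = 6)
  cfg <- ssf_config(simulate = list(
    config = sim_config(n_individuals = n_individuals, n_days = 365,
                        seed = child_seed(seed, 98)),
    spec = spec, landscape = landscape
  ), seed = seed)
  run <- suppressWarnings(run_ssf_pipeline(cfg))
  focal <- c("deciduous", "grassland")
  correlations <- vapply(focal, function(m) {
    stats::cor(as.vector(unclass(run$fit$surfaces[[m]])),
               as.vector(true_beta_surface(spec, m)))
  }, numeric(1))
  folds <- lapply(stats::setNames(focal, focal), function(m)
    fold_differences(exp(unclass(run$fit$surfaces[[m]]))))
  list(spec = spec, correlations = correlations, folds = folds,
       fit = run$fit, manifest = run$manifest)
}
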