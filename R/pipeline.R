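#' Pipeline configuration
#'
#' Exactly one of `gps_csv` + `landscape_stem` (ingest mode) or
#' `simulate` (a list with a \code{\link{sim_config}}, a
#' \code{\link{beta_spec}} and landscape settings) must be supplied.
#' Defaults mirror the reference analysis: 14-day periods, 1-hour
#' intervals, 863 pairs per cell, k = 10 (year) and k = 5 (hour) cyclic
#' smooths.
#'
#' @param gps_csv path to a GPS CSV (`id, timestamp, x, y`).
#' @param landscape_stem path stem of the ASCII landscape grids
#'   (see \code{\link{read_landscape_ascii}}).
#' @param simulate list with elements `config` (`sim_config`), `spec`
#'   (`beta_spec`) and optional `landscape` (`ssf_landscape`).
#' @param target_pairs,k_year,k_hour analysis settings.
#' @param min_pairs_policy cell shortfall policy
#'   (\code{\link{standardize_subsets}}).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory; when set, all stage tables are
#'   written there as CSV.
#' @return A list of class `ssf_config`.
#' @export
ssf_config <- function(gps_csv = NULL, landscape_stem = NULL, simulate = NULL,
                       target_pairs = 863L, k_year = 10L, k_hour = 5L,
                       min_pairs_policy = "warn_keep_all", seed = 1L,
                       out_dir = NULL) {
  ingest <- !is.null(gps_csv) || !is.null(landscape_stem)
  if (ingest == !is.null(simulate))
    stop("supply exactly one of {gps_csv + landscape_stem, simulate}",
         call. = FALSE)
  if (ingest && (is.null(gps_csv) || is.null(landscape_stem)))
    stop("ingest mode needs both gps_csv and landscape_stem", call. = FALSE)
  structure(list(gps_csv = gps_csv, landscape_stem = landscape_stem,
                 simulate = simulate, target_pairs = as.integer(target_pairs),
                 k_year = as.integer(k_year), k_hour = as.integer(k_hour),
                 min_pairs_policy = min_pairs_policy, seed = as.integer(seed),
                 out_dir = out_dir), class = "ssf_config")
}

#' Validate pipeline input files
#'
#' Checks the GPS CSV schema (columns, timestamp parseability, per-
#' individual monotonicity, finite coordinates) and the alignment of the
#' three landscape grids. Returns a machine-readable report rather than
#' stopping, so callers can itemize every failure at once.
#'
#' @param gps_csv path to the GPS CSV.
#' @param landscape_stem ASCII landscape path stem.
#' @return A list: `ok` (logical) and `failures` (character vector, empty
#'   when valid).
#' @export
validate_inputs <- function(gps_csv, landscape_stem) {
  failures <- character(0)
  d <- tryCatch(utils::read.csv(gps_csv, stringsAsFactors = FALSE),
                error = function(e) NULL)
  if (is.null(d)) {
    failures <- c(failures, paste("cannot read GPS CSV:", gps_csv))
  } else {
    miss <- setdiff(c("id", "timestamp", "x", "y"), names(d))
    if (length(miss))
      failures <- c(failures, paste("GPS CSV missing column(s):",
                                    paste(miss, collapse = ", ")))
    if (!length(miss)) {
      ts <- tryCatch(parse_utc(d$timestamp), error = function(e) NA)
      if (anyNA(ts)) failures <- c(failures, "unparseable timestamps")
      else if (is.unsorted(order(d$id, ts)) &&
               !identical(order(d$id, ts), seq_len(nrow(d))))
        failures <- c(failures, "timestamps not sorted within individual")
      if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
        failures <- c(failures, "non-finite coordinates")
    }
  }
  land <- tryCatch(read_landscape_ascii(landscape_stem),
                   error = function(e) {
                     failures <<- c(failures,
                                    paste("landscape grids:", conditionMessage(e)))
                     NULL
                   })
  if (!is.null(land)) {
    if (!all(land$habitat_grid %in% habitat_classes))
      failures <- c(failures, "habitat grid contains unknown class codes")
    if (min(land$dist_road_grid) < 0 || min(land$dist_settlement_grid) < 0)
      failures <- c(failures, "negative distances in distance grids")
  }
  list(ok = length(failures) == 0L, failures = failures)
}

#' Run the full temporal step-selection pipeline
#'
#' Simulate (or ingest) -> outlier filter -> regularize -> steps -> fit
#' movement kernels -> matched random steps -> endpoint covariates ->
#' global distance standardization -> temporal grid fit with cyclic
#' smoothing (\code{\link{tssf}}) -> Results-level metrics (cumulative
#' selectivity, fold differences, repeatability). Deterministic given the
#' config's master seed; per-stage seeds are derived from it and recorded
#' in the manifest.
#'
#' @param config an \code{\link{ssf_config}}.
#' @return A list of class `ssf_run`: `fit` (the \code{\link{tssf}}
#'   object), `metrics` (preference shares, cumulative fit, folds,
#'   repeatability), `kernels`, `manifest` (stage counts and seeds).
#' @export
run_ssf_pipeline <- function(config) {
  stopifnot(inherits(config, "ssf_config"))
  seeds <- list(simulate = child_seed(config$seed, 1),
                random_steps = child_seed(config$seed, 2),
                subsample = child_seed(config$seed, 3))
  if (!is.null(config$simulate)) {
    land <- config$simulate$landscape %||%
      make_landscape(seed = child_seed(config$seed, 4))
    sc <- config$simulate$config
    sc$seed <- seeds$simulate
    locs <- simulate_tracks(land, sc, config$simulate$spec)
  } else {
    rep <- validate_inputs(config$gps_csv, config$landscape_stem)
    if (!rep$ok) stop("input validation failed: ",
                      paste(rep$failures, collapse = "; "), call. = FALSE)
    locs <- read_gps_csv(config$gps_csv)
    land <- read_landscape_ascii(config$landscape_stem)
  }
  n_raw <- nrow(locs)
  locs <- filter_outliers(locs)
  n_clean <- nrow(locs)
  bursts <- regularize_bursts(locs)
  steps <- compute_steps(bursts)
  if (is.null(steps)) stop("no usable bursts after regularization",
                           call. = FALSE)
  gk <- fit_gamma(steps$length)
  vk <- fit_vonmises(steps$turn)
  pairs <- build_step_pairs(steps, land, gk, vk, seed = seeds$random_steps)
  pairs <- standardize_distances(pairs)
  fit <- tssf(pairs, target_pairs = config$target_pairs,
              k_year = config$k_year, k_hour = config$k_hour,
              seed = seeds$subsample,
              min_pairs_policy = config$min_pairs_policy)
  shares <- lapply(fit$surfaces, preference_share)
  cum <- cumulative_surface(fit$surfaces)
  cum_fit <- fit_cumulative_gam(cum, k_year = config$k_year,
                                k_hour = config$k_hour)
  folds <- tryCatch(fold_differences(cum_fit$surface),
                    error = function(e) list(diel_fold = NA_real_,
                                             seasonal_fold = NA_real_))
  rep_res <- repeatability(fit)
  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    n_fixes_in = n_raw, n_fixes_clean = n_clean,
    n_outliers_removed = n_raw - n_clean,
    n_bursts = length(unique(bursts$burst_id)),
    n_steps = nrow(steps),
    n_pairs = length(unique(pairs$stratum)),
    n_pairs_dropped_outside = attr(pairs, "n_dropped_outside") %||% 0L,
    n_cells = fit$n_cells, n_pairs_used = fit$n_pairs_used,
    n_fits = nrow(fit$fits),
    target_pairs = config$target_pairs,
    r_version = as.character(getRversion())
  )
  out <- structure(list(fit = fit, kernels = list(gamma = gk, vonmises = vk),
                        metrics = list(preference_shares = shares,
                                       cumulative = cum_fit, folds = folds,
                                       repeatability = rep_res),
                        manifest = manifest, config = config,
                        landscape = land),
                   class = "ssf_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fits_csv(run$fit, file.path(out_dir, "fits.csv"))
  write_surfaces_csv(run$fit, file.path(out_dir, "surfaces.csv"))
  metr <- do.call(rbind, lapply(names(run$metrics$preference_shares), function(m) {
    s <- run$metrics$preference_shares[[m]]
    data.frame(model = m, share_positive = s$share_positive,
               median_rss_positive = s$median_rss_positive,
               median_rss_negative = s$median_rss_negative)
  }))
  utils::write.csv(metr, file.path(out_dir, "preference_shares.csv"),
                   row.names = FALSE)
  rp <- run$metrics$repeatability
  utils::write.csv(data.frame(r = rp$correlations),
                   file.path(out_dir, "repeatability_correlations.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.ssf_run <- function(x, ...) {
  m <- x$manifest
  cat("Temporal step-selection pipeline run\n")
  cat(sprintf("  fixes: %d in, %d after outlier filter; %d bursts, %d steps\n",
              m$n_fixes_in, m$n_fixes_clean, m$n_bursts, m$n_steps))
  cat(sprintf("  pairs: %d; cells: %d; cell fits: %d\n",
              m$n_pairs, m$n_cells, m$n_fits))
  cat(sprintf("  folds (cumulative): diel %.2f, seasonal %.2f\n",
              x$metrics$folds$diel_fold, x$metrics$folds$seasonal_fold))
  cat(sprintf("  repeatability: %d pairwise correlations, %.1f%% negative\n",
              x$metrics$repeatability$n_pairs,
              100 * x$metrics$repeatability$proportion_negative))
  invisible(x)
}
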