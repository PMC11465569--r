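#' Relative selection strength
#'
#' `exp(beta)`: the multiplicative factor by which a habitat is selected
#' over the alternatives at equal availability.
#'
#' @param beta selection coefficient(s) on the link scale.
#' @return `exp(beta)`.
#' @export
rss <- function(beta) exp(beta)

#' Preference share of a selection surface
#'
#' The fraction of day-hour grid points with `beta > 0` (preference), with
#' the median relative selection strength computed separately over the
#' preferred (`beta > 0`) and the avoided (`beta <= 0`) cells. Exact zeros
#' count as avoidance.
#'
#' @param surface a `selection_surface` (or any numeric matrix/vector of
#'   beta values over the temporal grid).
#' @return A list: `share_positive`, `median_rss_positive`,
#'   `median_rss_negative`, `n_cells`.
#' @export
preference_share <- function(surface) {
  b <- as.vector(unclass(surface))
  pos <- b > 0
  list(share_positive = mean(pos),
       median_rss_positive = if (any(pos)) stats::median(exp(b[pos])) else NA_real_,
       median_rss_negative = if (any(!pos)) stats::median(exp(b[!pos])) else NA_real_,
       n_cells = length(b))
}

#' Cumulative selectivity surface
#'
#' Pointwise sum of the absolute smoothed selection coefficients across the
#' five habitat-dummy models (the distance models are excluded: their
#' coefficients are on a standardized-distance scale, not comparable to the
#' dummy scale). An index of how strongly the animal discriminates among
#' habitats at each time of day and year.
#'
#' @param surfaces named list of `selection_surface` matrices; the five
#'   habitat models (`deciduous`, `coniferous`, `wetland`, `grassland`,
#'   `arable`) are used.
#' @param models which surfaces to sum (default: the five habitat-dummy
#'   models).
#' @param high_threshold display threshold above which a grid point is
#'   flagged as high selectivity.
#' @return A `cumulative_surface`: the summed matrix with a logical
#'   `"high"` attribute of the same shape.
#' @export
cumulative_surface <- function(surfaces,
                               models = c("deciduous", "coniferous", "wetland",
                                          "grassland", "arable"),
                               high_threshold = 3.5) {
  miss <- setdiff(models, names(surfaces))
  if (length(miss)) stop("missing surface(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dims <- lapply(surfaces[models], dim)
  if (length(unique(dims)) != 1L)
    stop("surfaces are misaligned (differing grids)", call. = FALSE)
  out <- Reduce(`+`, lapply(surfaces[models], function(s) abs(unclass(s))))
  structure(out, high = out > high_threshold,
            days = attr(surfaces[[models[1]]], "days"),
            hours = attr(surfaces[[models[1]]], "hours"),
            class = "cumulative_surface")
}

#' Smooth the cumulative selectivity surface
#'
#' Fits the same cyclic additive model used for the per-habitat
#' coefficients (cyclic day-of-year and hour smooths plus interaction) to
#' the 8,760 cumulative-selectivity grid values.
#'
#' @param cumulative a \code{\link{cumulative_surface}}.
#' @param k_year,k_hour basis dimensions (defaults 10 and 5).
#' @return A list: `model` (`cyclic_gam`) and `surface` (the smoothed
#'   365 x 24 `selection_surface`).
#' @export
fit_cumulative_gam <- function(cumulative, k_year = 10L, k_hour = 5L) {
  days <- attr(cumulative, "days") %||% seq_len(nrow(cumulative))
  hours <- attr(cumulative, "hours") %||% (seq_len(ncol(cumulative)) - 1)
  g <- expand.grid(day = days, hour = hours)
  fit <- fit_cyclic_gam(hour = g$hour, year = day_to_year_coord(g$day),
                        y = as.vector(unclass(cumulative)),
                        k_hour = k_hour, k_year = k_year)
  list(model = fit, surface = predict_surface(fit, days = days, hours = hours))
}

#' Diel and seasonal fold differences of a positive surface
#'
#' Marginal-ratio definition: the diel fold is `max/min` of the hourly
#' means (each hour averaged across days) and the seasonal fold is
#' `max/min` of the daily means (each day averaged across hours). Both are
#' scale-invariant and require a strictly positive surface.
#'
#' @param surface a positive surface (typically the smoothed cumulative
#'   selectivity), days in rows and hours in columns.
#' @return A list: `diel_fold`, `seasonal_fold`.
#' @export
fold_differences <- function(surface) {
  s <- unclass(surface)
  hour_marginal <- colMeans(s)
  day_marginal <- rowMeans(s)
  if (min(hour_marginal) <= 0 || min(day_marginal) <= 0)
    stop("fold differences need a strictly positive surface", call. = FALSE)
  list(diel_fold = max(hour_marginal) / min(hour_marginal),
       seasonal_fold = max(day_marginal) / min(day_marginal))
}

#' Temporal repeatability of habitat selection
#'
#' Evaluates every model's smoothed selection coefficient at each temporal
#' cell (period midpoint day, cell hour), then correlates the resulting
#' per-cell coefficient vectors across every unordered pair of cells. Low
#' or negative correlations indicate that selection in one time window is
#' unrelated (or opposite) to selection in another.
#'
#' @param fit a \code{\link{tssf}} fit (all its models are used), or a
#'   named list of `cyclic_gam` objects.
#' @param periods,hours the cell grid to evaluate (defaults 1..26 and
#'   0..23).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A list of class `repeatability`: `n_cells`, `n_pairs`,
#'   `correlations` (vector over unordered cell pairs),
#'   `proportion_negative`, `n_excluded` (pairs dropped for zero-variance
#'   vectors).
#' @export
repeatability <- function(fit, periods = 1:26, hours = 0:23,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gams <- if (inherits(fit, "tssf")) fit$gams else fit
  g <- expand.grid(period = periods, hour = hours)
  mid_day <- pmin((g$period - 1) * 14 + 7, 365)
  # models x cells matrix of predicted beta
  M <- vapply(gams, function(gm) predict(gm, mid_day, g$hour),
              numeric(nrow(g)))
  M <- t(M)
  n_cells <- ncol(M)
  sds <- apply(M, 2, stats::sd)
  if (method == "spearman") M <- apply(M, 2, rank)
  suppressWarnings(R <- stats::cor(M))
  r <- R[upper.tri(R)]
  n_excluded <- sum(is.na(r))
  r_ok <- r[!is.na(r)]
  structure(list(n_cells = n_cells, n_pairs = length(r),
                 correlations = r_ok,
                 proportion_negative = mean(r_ok < 0),
                 n_excluded = n_excluded, method = method),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Temporal repeatability (%s): %d cells, %d pairwise correlations\n",
              x$method, x$n_cells, x$n_pairs))
  cat(sprintf("  median r = %.3f, proportion negative = %.3f",
              stats::median(x$correlations), x$proportion_negative))
  if (x$n_excluded > 0) cat(sprintf(" (%d pairs excluded)", x$n_excluded))
  cat("\n")
  invisible(x)
}
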