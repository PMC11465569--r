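#' Temporal step-selection fit
#'
#' The package's central model fit. Takes a matched-pairs table (one
#' observed and one random endpoint per stratum, with endpoint covariates),
#' partitions the pairs into 14-day x 1-hour temporal cells, standardizes
#' cell sample sizes by pair-level subsampling, fits one conditional
#' logistic regression per covariate model in every cell, and smooths the
#' resulting selection coefficients over the diel and seasonal cycles with
#' cyclic penalized splines (one additive model per covariate: cyclic
#' hour smooth, cyclic year smooth and their tensor interaction).
#'
#' Cell fits flagged non-estimable or completely separated are excluded
#' from the smoothing stage. With full annual and diel coverage the grid
#' has 26 x 24 = 624 cells and `624 x length(models)` cell fits.
#'
#' @param pairs pairs table from \code{\link{build_step_pairs}} (long
#'   format; `dist_*_z` columns are added by global standardization if
#'   absent).
#' @param target_pairs pairs retained per cell (default 863, i.e. 1,726
#'   locations per cell).
#' @param models covariate models to fit; default all seven
#'   (\code{\link{ssf_models}}).
#' @param k_year,k_hour basis dimensions of the cyclic smooths (defaults
#'   10 and 5).
#' @param seed master seed (drives the per-cell subsampling).
#' @param min_pairs_policy see \code{\link{standardize_subsets}}.
#' @return An object of class `tssf`: `fits` (the per-cell coefficient
#'   table), `gams` (per-model `cyclic_gam`), `surfaces` (per-model 365 x
#'   24 predicted beta surfaces), counts and settings.
#' @seealso \code{\link{predict.tssf}}, \code{\link{summary.tssf}},
#'   \code{\link{plot.tssf}}
#' @export
tssf <- function(pairs, target_pairs = 863L, models = ssf_models,
                 k_year = 10L, k_hour = 5L, seed = 1L,
                 min_pairs_policy = "warn_keep_all") {
  cl <- match.call()
  if (!"dist_road_z" %in% names(pairs)) pairs <- standardize_distances(pairs)
  pairs <- partition_pairs(pairs)
  pairs <- standardize_subsets(pairs, target_pairs = target_pairs,
                               seed = seed,
                               min_pairs_policy = min_pairs_policy)
  fits <- fit_cell_grid(pairs, models = models)
  gams <- list(); surfaces <- list()
  for (m in models) {
    fm <- fits[fits$model == m & fits$estimable & !fits$separation &
                 fits$converged, ]
    gams[[m]] <- fit_cyclic_gam(hour = fm$hour, year = fm$period - 1,
                                y = fm$beta, k_hour = k_hour, k_year = k_year)
    surfaces[[m]] <- predict_surface(gams[[m]])
  }
  structure(list(
    fits = fits, gams = gams, surfaces = surfaces,
    n_cells = nrow(unique(fits[, c("period", "hour")])),
    n_pairs_used = length(unique(pairs$stratum)),
    models = models, target_pairs = target_pairs,
    k_year = k_year, k_hour = k_hour, seed = seed, call = cl
  ), class = "tssf")
}

#' @export
print.tssf <- function(x, ...) {
  cat("Temporal step-selection fit\n")
  cat(sprintf("  %d temporal cells (14-day x 1-hour), %d pairs, %d cell fits\n",
              x$n_cells, x$n_pairs_used, nrow(x$fits)))
  cat("  models:", paste(x$models, collapse = ", "), "\n")
  cat(sprintf("  smoothing: cyclic P-splines, k_year = %d, k_hour = %d\n",
              x$k_year, x$k_hour))
  invisible(x)
}

#' Summarize a temporal step-selection fit
#'
#' One row per covariate model: smoothed intercept (mean selection on the
#' link scale), per-term effective degrees of freedom, and cell-fit
#' bookkeeping (estimable / separated counts). Permutation p-values for the
#' smooth terms can be added with `permutation_p = TRUE`.
#'
#' @param object a `tssf` fit.
#' @param permutation_p compute permutation p-values (slower).
#' @param n_perm,seed permutation settings.
#' @param ... unused.
#' @return A `summary.tssf` data.frame.
#' @export
summary.tssf <- function(object, permutation_p = FALSE, n_perm = 199L,
                         seed = 1L, ...) {
  rows <- lapply(object$models, function(m) {
    g <- object$gams[[m]]
    fm <- object$fits[object$fits$model == m, ]
    r <- data.frame(model = m, intercept = g$coefficients[1],
                    edf_hour = g$edf[["hour"]], edf_year = g$edf[["year"]],
                    edf_interaction = g$edf[["interaction"]],
                    n_cells_used = g$n,
                    n_separated = sum(fm$separation),
                    n_nonestimable = sum(!fm$estimable))
    if (permutation_p) {
      p <- significance_by_permutation(g, n_perm = n_perm,
                                       seed = child_seed(seed, match(m, object$models)))
      r$p_hour <- p[["hour"]]; r$p_year <- p[["year"]]
      r$p_interaction <- p[["interaction"]]
    }
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.tssf", class(out))
  out
}

#' @export
print.summary.tssf <- function(x, digits = 3, ...) {
  cat("Temporal step-selection fit: smoothed selection models\n\n")
  y <- x; class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-cell selection coefficients of a temporal step-selection fit
#'
#' @param object a `tssf` fit.
#' @param ... unused.
#' @return The cell-fit table (period, hour, model, beta, se, flags).
#' @export
coef.tssf <- function(object, ...) object$fits

#' Predict smoothed selection coefficients
#'
#' @param object a `tssf` fit.
#' @param day,hour vectors of day of year (1..365) and hour of day
#'   (`[0, 24)`); recycled to a common length.
#' @param model one of the fitted model ids.
#' @param type `"link"` returns beta, `"rss"` returns exp(beta) (relative
#'   selection strength).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.tssf <- function(object, day, hour, model, type = c("link", "rss"),
                         ...) {
  type <- match.arg(type)
  if (!model %in% names(object$gams))
    stop("model not in fit: ", model, call. = FALSE)
  n <- max(length(day), length(hour))
  day <- rep_len(day, n); hour <- rep_len(hour, n)
  out <- predict(object$gams[[model]], day, hour)
  if (type == "rss") exp(out) else out
}

#' @export
residuals.tssf <- function(object, model = NULL, ...) {
  if (is.null(model)) lapply(object$gams, function(g) g$residuals)
  else object$gams[[model]]$residuals
}

#' @export
fitted.tssf <- function(object, model = NULL, ...) {
  if (is.null(model)) lapply(object$gams, function(g) g$fitted)
  else object$gams[[model]]$fitted
}

#' Heatmap of a smoothed selection surface
#'
#' Day of year on the x axis, hour of day on the y axis, smoothed beta as
#' colour (blue = avoidance, red = preference).
#'
#' @param x a `tssf` fit.
#' @param model model id to plot (default: first fitted model).
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.tssf <- function(x, model = x$models[1], ...) {
  s <- x$surfaces[[model]]
  lim <- max(abs(s))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  graphics::image(x = 1:365, y = 0:23, z = unclass(s), col = pal,
                  zlim = c(-lim, lim), xlab = "day of year",
                  ylab = "hour of day",
                  main = paste("Smoothed selection:", model), ...)
  invisible(x)
}

#' Write the cell-fit and surface tables
#'
#' `write_fits_csv` writes the per-cell coefficient table;
#' `write_surfaces_csv` writes the smoothed surfaces in long format
#' (model, day, hour, beta_hat).
#'
#' @param object a `tssf` fit.
#' @param path CSV path.
#' @export
write_fits_csv <- function(object, path) {
  utils::write.csv(object$fits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fits_csv
#' @export
write_surfaces_csv <- function(object, path) {
  rows <- lapply(names(object$surfaces), function(m) {
    s <- object$surfaces[[m]]
    g <- expand.grid(day = attr(s, "days"), hour = attr(s, "hours"))
    data.frame(model = m, day = g$day, hour = g$hour,
               beta_hat = as.vector(unclass(s)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
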