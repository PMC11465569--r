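#' Assign timestamps to 14-day x 1-hour temporal cells
#'
#' Periods are 14-day blocks counted from 1 January
#' (`period = floor((day_of_year - 1)/14) + 1`, capped at 26 so that days
#' 365-366 are absorbed into the final period); the hour is the integer
#' clock hour (UTC). A step pair is assigned by the observed step's end
#' timestamp, where its covariates are measured.
#'
#' @param timestamp POSIXct vector (UTC).
#' @return data.frame with integer columns `period` (1..26) and `hour`
#'   (0..23).
#' @export
assign_temporal_cell <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday + 1L
  period <- pmin(26L, (doy - 1L) %/% 14L + 1L)
  data.frame(period = period, hour = lt$hour)
}

#' Partition step pairs into temporal cells
#'
#' Adds `period` and `hour` columns (from the observed member's end
#' timestamp) to the pairs table. Every stratum falls in exactly one cell.
#'
#' @param pairs pairs table (long format, `case` 1/0 sharing `stratum`).
#' @return The pairs table with `period` and `hour` columns.
#' @export
partition_pairs <- function(pairs) {
  cell <- assign_temporal_cell(pairs$t_end)
  pairs$period <- cell$period
  pairs$hour <- cell$hour
  pairs
}

#' Standardize cell sample sizes by pair-level subsampling
#'
#' Each temporal cell is reduced to `target_pairs` whole strata by uniform
#' sampling without replacement (pairs are never split: the conditional
#' likelihood needs intact strata). Subsampling is deterministic given the
#' master seed and the cell's (period, hour), independent of iteration
#' order. Cells below the target are handled per `min_pairs_policy`:
#' `"warn_keep_all"` keeps every pair with a warning, `"error"` aborts
#' naming the cell.
#'
#' @param pairs partitioned pairs table.
#' @param target_pairs pairs retained per cell (the reference analysis uses
#'   863, i.e. 1,726 locations).
#' @param seed master seed.
#' @param min_pairs_policy `"warn_keep_all"` or `"error"`.
#' @return The subsampled pairs table.
#' @export
standardize_subsets <- function(pairs, target_pairs = 863L, seed = 1L,
                                min_pairs_policy = c("warn_keep_all", "error")) {
  min_pairs_policy <- match.arg(min_pairs_policy)
  if (!all(c("period", "hour") %in% names(pairs)))
    stop("pairs must be partitioned first (see partition_pairs)", call. = FALSE)
  cell_key <- paste(pairs$period, pairs$hour, sep = ":")
  rows_by_cell <- split(seq_len(nrow(pairs)), cell_key)
  keep_strata <- vector("list", 0L)
  short_cells <- character(0)
  for (key in names(rows_by_cell)) {
    rows <- rows_by_cell[[key]]
    strata <- unique(pairs$stratum[rows])
    if (length(strata) <= target_pairs) {
      if (length(strata) < target_pairs)
        short_cells <- c(short_cells, key)
      keep_strata[[key]] <- strata
    } else {
      ph <- as.integer(strsplit(key, ":")[[1]])
      rng <- local_rng(child_seed(seed, ph[1], ph[2]))
      keep_strata[[key]] <- sort(sample(strata, target_pairs))
    }
  }
  if (length(short_cells)) {
    msg <- paste0(length(short_cells), " cell(s) below ", target_pairs,
                  " pairs (e.g. period:hour ", short_cells[1], ")")
    if (min_pairs_policy == "error") stop(msg, call. = FALSE)
    warning(msg, "; keeping all their pairs", call. = FALSE)
  }
  out <- pairs[pairs$stratum %in% unlist(keep_strata, use.names = FALSE), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the seven conditional logistic models in every temporal cell
#'
#' Runs \code{\link{clogit_pair}} for each model covariate within each
#' populated (period, hour) cell; per-fit failures (non-estimable cells,
#' complete separation) are flagged, never fatal, so the grid always
#' returns `n_cells x 7` rows.
#'
#' @param pairs standardized, partitioned pairs table (must contain the
#'   `dist_*_z` columns from \code{\link{standardize_distances}}).
#' @param models model ids to fit (default all seven).
#' @return A data.frame of subset fits: `period`, `hour`, `model`, `beta`,
#'   `se`, `n_pairs`, `n_informative`, `converged`, `estimable`,
#'   `separation`.
#' @export
fit_cell_grid <- function(pairs, models = ssf_models) {
  stopifnot(all(c("period", "hour") %in% names(pairs)))
  obs <- pairs[pairs$case == 1L, ]
  rnd <- pairs[pairs$case == 0L, ]
  rnd <- rnd[match(obs$stratum, rnd$stratum), ]   # align 1:1 by stratum
  cell_key <- paste(obs$period, obs$hour, sep = ":")
  rows_by_cell <- split(seq_len(nrow(obs)), cell_key)
  res <- vector("list", length(rows_by_cell) * length(models))
  k <- 0L
  for (key in names(rows_by_cell)) {
    rows <- rows_by_cell[[key]]
    ph <- as.integer(strsplit(key, ":")[[1]])
    for (m in models) {
      col <- model_column(m)
      fit <- clogit_pair(obs[[col]][rows], rnd[[col]][rows])
      k <- k + 1L
      res[[k]] <- data.frame(period = ph[1], hour = ph[2], model = m,
                             beta = fit$beta, se = fit$se,
                             n_pairs = fit$n_pairs,
                             n_informative = fit$n_informative,
                             converged = fit$converged,
                             estimable = fit$estimable,
                             separation = fit$separation)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$model, out$period, out$hour), ]
  rownames(out) <- NULL
  out
}
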