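#' Read / write GPS relocation tables
#'
#' The GPS CSV schema is `id, timestamp, x, y` with ISO-8601 UTC timestamps
#' and projected coordinates in meters.
#'
#' @param path CSV file path.
#' @param locations data.frame with columns `id`, `timestamp` (POSIXct, UTC),
#'   `x`, `y`.
#' @return `read_gps_csv` returns the locations data.frame, sorted by id and
#'   timestamp.
#' @export
read_gps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("GPS CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d$timestamp <- tryCatch(parse_utc(d$timestamp), error = function(e) NA)
  if (anyNA(d$timestamp)) stop("unparseable timestamps in ", path, call. = FALSE)
  d <- d[order(d$id, d$timestamp), need]
  rownames(d) <- NULL
  d
}

#' @rdname read_gps_csv
#' @export
write_gps_csv <- function(locations, path) {
  out <- locations[, c("id", "timestamp", "x", "y")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove positional outliers from GPS fixes
#'
#' A fix is an outlier when the step from the previous retained fix implies a
#' speed above `max_step_km` per `max_interval_h` (default: 15 km within
#' 1 h). The later fix of the offending pair is removed and the pair is
#' re-evaluated, so a single spike between two plausible fixes is removed
#' without dragging its neighbours along.
#'
#' @param locations data.frame (`id`, `timestamp`, `x`, `y`), sorted by
#'   timestamp within each individual.
#' @param max_step_km,max_interval_h the speed threshold, as a distance per
#'   time interval.
#' @return The retained fixes; the removed ones are attached as the
#'   `"removed"` attribute.
#' @export
filter_outliers <- function(locations, max_step_km = 15, max_interval_h = 1) {
  if (nrow(locations) == 0L) {
    attr(locations, "removed") <- locations
    return(locations)
  }
  check_sorted(locations)
  speed_limit <- max_step_km * 1000 / (max_interval_h * 3600)  # m/s
  keep <- rep(TRUE, nrow(locations))
  for (ind in unique(locations$id)) {
    idx <- which(locations$id == ind)
    last <- idx[1]
    for (i in idx[-1]) {
      dt <- as.numeric(difftime(locations$timestamp[i],
                                locations$timestamp[last], units = "secs"))
      dist <- sqrt((locations$x[i] - locations$x[last])^2 +
                     (locations$y[i] - locations$y[last])^2)
      if (dt > 0 && dist / dt > speed_limit) keep[i] <- FALSE else last <- i
    }
  }
  out <- locations[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- locations[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  attr(out, "removed") <- removed
  out
}

check_sorted <- function(locations) {
  ord <- order(locations$id, locations$timestamp)
  if (!identical(ord, seq_len(nrow(locations))))
    stop("locations must be sorted by timestamp within individual",
         call. = FALSE)
  invisible(TRUE)
}

#' Regularize fixes into bursts at a target interval
#'
#' Greedy forward scan per individual: starting from an anchor fix, the next
#' fix is kept when its gap from the last kept fix lies within
#' `target_min +/- tol_min` (default 60 +/- 15 min). A gap outside the window
#' closes the current burst and the offending fix anchors a new one. Bursts
#' with fewer than `min_burst` locations are discarded (three are needed for
#' a turning angle).
#'
#' @param locations cleaned, sorted fixes.
#' @param target_min,tol_min target interval and tolerance, minutes.
#' @param min_burst minimum locations per retained burst.
#' @return Retained fixes with a `burst_id` column (unique across
#'   individuals).
#' @export
regularize_bursts <- function(locations, target_min = 60, tol_min = 15,
                              min_burst = 3L) {
  if (nrow(locations) == 0L) {
    locations$burst_id <- integer(0)
    return(locations)
  }
  check_sorted(locations)
  lo <- (target_min - tol_min) * 60; hi <- (target_min + tol_min) * 60
  burst <- integer(nrow(locations))
  next_id <- 1L
  for (ind in unique(locations$id)) {
    idx <- which(locations$id == ind)
    burst[idx[1]] <- next_id
    last <- idx[1]
    for (i in idx[-1]) {
      gap <- as.numeric(difftime(locations$timestamp[i],
                                 locations$timestamp[last], units = "secs"))
      if (gap >= lo && gap <= hi) {
        burst[i] <- burst[last]
      } else {
        next_id <- next_id + 1L
        burst[i] <- next_id
      }
      last <- i
    }
    next_id <- next_id + 1L
  }
  sizes <- table(burst)
  keep <- burst %in% as.integer(names(sizes)[sizes >= min_burst])
  out <- locations[keep, , drop = FALSE]
  out$burst_id <- match(burst[keep], sort(unique(burst[keep])))
  rownames(out) <- NULL
  out
}

#' Compute steps (lengths, bearings, turning angles) from bursts
#'
#' A burst of n locations yields n - 1 steps. The turning angle of a step is
#' the signed difference between its bearing and the previous step's bearing,
#' wrapped to `(-pi, pi]`; the first step of each burst carries no turning
#' angle and serves only as a bearing anchor. A zero-length previous step
#' leaves the turning angle undefined (`NA`, flagged in `turn_defined`).
#'
#' @param bursts output of \code{\link{regularize_bursts}}.
#' @return A steps data.frame: `id`, `burst_id`, `stratum_id`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `t_start`, `t_end`, `length`, `bearing`,
#'   `turn`, `turn_defined`.
#' @export
compute_steps <- function(bursts) {
  pieces <- lapply(split(seq_len(nrow(bursts)), bursts$burst_id), function(idx) {
    b <- bursts[idx, , drop = FALSE]
    n <- nrow(b)
    if (n < 2L) return(NULL)
    dx <- diff(b$x); dy <- diff(b$y)
    len <- sqrt(dx^2 + dy^2)
    bear <- atan2(dy, dx)
    bear[len == 0] <- NA_real_
    turn <- c(NA_real_, wrap_angle(diff(bear)))
    data.frame(
      id = b$id[-n], burst_id = b$burst_id[-n],
      x_start = b$x[-n], y_start = b$y[-n],
      x_end = b$x[-1], y_end = b$y[-1],
      t_start = b$timestamp[-n], t_end = b$timestamp[-1],
      length = len, bearing = bear, turn = turn,
      turn_defined = !is.na(turn)
    )
  })
  steps <- do.call(rbind, pieces)
  if (is.null(steps)) return(NULL)
  rownames(steps) <- NULL
  steps$stratum_id <- seq_len(nrow(steps))
  steps
}
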