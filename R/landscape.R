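#' Habitat class codes
#'
#' The nine habitat classes used throughout the package, in their fixed
#' integer coding (1-9). The first five are the classes modelled with
#' habitat dummies; the remaining four occur in the landscape but carry no
#' selection model of their own.
#'
#' @format A named integer vector of length 9.
#' @export
habitat_classes <- c(
  deciduous_forest = 1L, coniferous_forest = 2L, wetland = 3L,
  grassland = 4L, arable = 5L, anthropogenic = 6L, moorland = 7L,
  bare = 8L, water = 9L
)

#' The seven single-covariate selection models
#'
#' Five habitat-dummy models plus two standardized-distance models
#' (distance to roads, distance to settlements).
#'
#' @export
ssf_models <- c("deciduous", "coniferous", "wetland", "grassland", "arable",
                "dist_road", "dist_settlement")

# habitat class behind each dummy model
.model_class <- c(deciduous = 1L, coniferous = 2L, wetland = 3L,
                  grassland = 4L, arable = 5L)

#' Generate a synthetic categorical landscape with distance grids
#'
#' Builds a patchy habitat mosaic by nearest-seed (Voronoi) assignment of
#' random patch seeds, overlays at least one straight road polyline and at
#' least one settlement cluster, and computes Euclidean distance grids to
#' the nearest road and settlement cell. Grids are stored as matrices
#' indexed `[row, col]` with row 1 at the lower edge (`origin_y`), so y
#' increases with the row index.
#'
#' @param seed integer seed; the whole landscape is deterministic given it.
#' @param n_rows,n_cols grid dimensions (each at least 50).
#' @param cell_size cell edge length in meters.
#' @param n_seeds_per_class number of Voronoi patch seeds per habitat class.
#' @param n_roads number of straight road polylines.
#' @param n_settlements number of settlement cluster centres.
#' @param origin_x,origin_y coordinates of the lower-left corner, meters.
#' @return An object of class `ssf_landscape` with elements `habitat_grid`
#'   (integer matrix of class codes), `dist_road_grid` and
#'   `dist_settlement_grid` (meters, zero exactly on source cells),
#'   `origin_x`, `origin_y`, `cell_size`, `n_rows`, `n_cols`.
#' @export
make_landscape <- function(seed, n_rows = 100L, n_cols = 100L,
                           cell_size = 10, n_seeds_per_class = 4L,
                           n_roads = 2L, n_settlements = 3L,
                           origin_x = 0, origin_y = 0) {
  if (n_rows < 50L || n_cols < 50L)
    stop("landscape dimensions must be at least 50 x 50", call. = FALSE)
  if (n_seeds_per_class < 1L)
    stop("every habitat class needs at least one patch seed", call. = FALSE)
  stopifnot(cell_size > 0)
  rng <- local_rng(seed)

  n_class <- length(habitat_classes)
  n_seed <- n_class * n_seeds_per_class
  seed_row <- sample.int(n_rows, n_seed, replace = TRUE)
  seed_col <- sample.int(n_cols, n_seed, replace = TRUE)
  seed_class <- rep(seq_len(n_class), each = n_seeds_per_class)

  # nearest-seed assignment; each seed owns at least its own cell, so every
  # class is present in the mosaic
  rc <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  best_d2 <- rep(Inf, nrow(rc))
  best_cl <- integer(nrow(rc))
  for (s in seq_len(n_seed)) {
    d2 <- (rc$row - seed_row[s])^2 + (rc$col - seed_col[s])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_cl[upd] <- seed_class[s]
  }
  habitat <- matrix(as.integer(best_cl), n_rows, n_cols)
  for (s in seq_len(n_seed)) habitat[seed_row[s], seed_col[s]] <- seed_class[s]

  # roads: straight polylines across the full extent, rasterized by sampling
  road <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_len(max(1L, n_roads))) {
    if (runif(1) < 0.5) {               # roughly horizontal
      r0 <- runif(1, 1, n_rows); r1 <- runif(1, 1, n_rows)
      tt <- seq(0, 1, length.out = 4L * n_cols)
      rr <- round(r0 + tt * (r1 - r0)); cc <- round(1 + tt * (n_cols - 1))
    } else {                            # roughly vertical
      c0 <- runif(1, 1, n_cols); c1 <- runif(1, 1, n_cols)
      tt <- seq(0, 1, length.out = 4L * n_rows)
      cc <- round(c0 + tt * (c1 - c0)); rr <- round(1 + tt * (n_rows - 1))
    }
    ok <- rr >= 1 & rr <= n_rows & cc >= 1 & cc <= n_cols
    road[cbind(rr[ok], cc[ok])] <- TRUE
  }

  # settlements: small clusters of cells around random centres
  settl <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_len(max(1L, n_settlements))) {
    cr <- sample.int(n_rows, 1); cc <- sample.int(n_cols, 1)
    rr <- pmin(pmax(cr + sample(-2:2, 12, replace = TRUE), 1L), n_rows)
    c2 <- pmin(pmax(cc + sample(-2:2, 12, replace = TRUE), 1L), n_cols)
    settl[cbind(rr, c2)] <- TRUE
    habitat[cbind(rr, c2)] <- habitat_classes[["anthropogenic"]]
  }

  out <- structure(list(
    habitat_grid = habitat,
    dist_road_grid = dist_to_cells(road, cell_size),
    dist_settlement_grid = dist_to_cells(settl, cell_size),
    origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
  ), class = "ssf_landscape")
  out
}

# Euclidean distance (m) from every cell centre to the nearest TRUE cell
# centre; exact brute force over source cells, looped over sources so memory
# stays linear in the grid size.
dist_to_cells <- function(mask, cell_size) {
  n_rows <- nrow(mask); n_cols <- ncol(mask)
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0L) return(matrix(Inf, n_rows, n_cols))
  rows <- matrix(seq_len(n_rows), n_rows, n_cols)
  cols <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  best <- matrix(Inf, n_rows, n_cols)
  for (s in seq_len(nrow(src))) {
    d2 <- (rows - src[s, 1])^2 + (cols - src[s, 2])^2
    best <- pmin(best, d2)
  }
  sqrt(best) * cell_size
}

#' @export
print.ssf_landscape <- function(x, ...) {
  cat("Synthetic landscape:", x$n_rows, "x", x$n_cols, "cells of",
      x$cell_size, "m\n")
  tab <- table(factor(x$habitat_grid, levels = habitat_classes,
                      labels = names(habitat_classes)))
  cat("Habitat shares (%):\n")
  print(round(100 * tab / sum(tab), 1))
  invisible(x)
}

# point -> 1-based (row, col); half-open cells [low, high) on both axes, so
# a point on a shared interior edge belongs to the cell with the larger index
cell_index <- function(landscape, x, y) {
  col <- floor((x - landscape$origin_x) / landscape$cell_size) + 1L
  row <- floor((y - landscape$origin_y) / landscape$cell_size) + 1L
  list(row = as.integer(row), col = as.integer(col))
}

in_landscape <- function(landscape, x, y) {
  idx <- cell_index(landscape, x, y)
  idx$row >= 1L & idx$row <= landscape$n_rows &
    idx$col >= 1L & idx$col <= landscape$n_cols
}

#' Extract endpoint covariates from a landscape
#'
#' Looks up the habitat class and raw road/settlement distances for point
#' coordinates by containing cell. Cells are half-open on both axes: a point
#' on a shared interior edge belongs to the cell with the larger index.
#' Distance standardization is a separate, global step
#' (\code{\link{standardize_distances}}).
#'
#' @param landscape an `ssf_landscape`.
#' @param x,y numeric vectors of projected coordinates (meters).
#' @return A data.frame with `habitat` (integer class code), one 0/1 dummy
#'   column per modelled habitat (`deciduous`, `coniferous`, `wetland`,
#'   `grassland`, `arable`) and raw `dist_road`, `dist_settlement` (meters).
#' @export
extract_covariates <- function(landscape, x, y) {
  if (!all(in_landscape(landscape, x, y)))
    stop("point outside landscape extent", call. = FALSE)
  idx <- cell_index(landscape, x, y)
  lin <- idx$row + (idx$col - 1L) * landscape$n_rows
  hab <- landscape$habitat_grid[lin]
  out <- data.frame(habitat = hab)
  for (m in names(.model_class)) out[[m]] <- as.numeric(hab == .model_class[[m]])
  out$dist_road <- landscape$dist_road_grid[lin]
  out$dist_settlement <- landscape$dist_settlement_grid[lin]
  out
}

#' Write / read a landscape as plain-text ASCII grids
#'
#' Dependency-free text format: a header line
#' `n_rows n_cols origin_x origin_y cell_size`, then `n_rows` lines of
#' space-separated values, top row first. `write_landscape_ascii` writes
#' three files (`<stem>_habitat.asc`, `<stem>_dist_road.asc`,
#' `<stem>_dist_settlement.asc`); `read_landscape_ascii` reassembles them.
#'
#' @param landscape an `ssf_landscape`.
#' @param stem path stem for the three grid files.
#' @return `read_landscape_ascii` returns an `ssf_landscape`.
#' @export
write_landscape_ascii <- function(landscape, stem) {
  grids <- list(habitat = landscape$habitat_grid,
                dist_road = landscape$dist_road_grid,
                dist_settlement = landscape$dist_settlement_grid)
  for (nm in names(grids)) {
    con <- file(paste0(stem, "_", nm, ".asc"), "w")
    cat(landscape$n_rows, landscape$n_cols, landscape$origin_x,
        landscape$origin_y, landscape$cell_size, "\n", file = con)
    g <- grids[[nm]]
    for (r in rev(seq_len(landscape$n_rows)))   # top row first
      cat(format(g[r, ], trim = TRUE), "\n", file = con)
    close(con)
  }
  invisible(paste0(stem, "_", names(grids), ".asc"))
}

#' @rdname write_landscape_ascii
#' @export
read_landscape_ascii <- function(stem) {
  read_one <- function(path) {
    hdr <- scan(path, nmax = 5, quiet = TRUE)
    vals <- scan(path, skip = 1, quiet = TRUE)
    n_rows <- as.integer(hdr[1]); n_cols <- as.integer(hdr[2])
    if (length(vals) != n_rows * n_cols)
      stop("ASCII grid ", path, ": value count does not match header",
           call. = FALSE)
    m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
    list(grid = m[rev(seq_len(n_rows)), , drop = FALSE], hdr = hdr)
  }
  h <- read_one(paste0(stem, "_habitat.asc"))
  r <- read_one(paste0(stem, "_dist_road.asc"))
  s <- read_one(paste0(stem, "_dist_settlement.asc"))
  if (!identical(h$hdr, r$hdr) || !identical(h$hdr, s$hdr))
    stop("ASCII grids are not aligned (headers differ)", call. = FALSE)
  structure(list(
    habitat_grid = matrix(as.integer(h$grid), nrow(h$grid), ncol(h$grid)),
    dist_road_grid = r$grid, dist_settlement_grid = s$grid,
    origin_x = h$hdr[3], origin_y = h$hdr[4], cell_size = h$hdr[5],
    n_rows = as.integer(h$hdr[1]), n_cols = as.integer(h$hdr[2])
  ), class = "ssf_landscape")
}
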