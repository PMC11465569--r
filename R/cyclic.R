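#' Cyclic cubic B-spline basis with difference penalty
#'
#' Uniform cubic B-splines on `k` equally spaced knots over `[0, period)`,
#' made periodic by wrapping: the three overhanging basis functions are
#' folded back onto the first three, so basis rows for `x` and
#' `x + period` are identical and the represented function and its
#' derivatives match at the seam. The smoothness penalty is the cyclic
#' (circulant) second-order difference penalty on the coefficients, whose
#' null space contains exactly the constant function.
#'
#' @param x evaluation points (any reals; reduced modulo `period`).
#' @param period cycle length (24 for hour of day, 26 for the 14-day
#'   period index).
#' @param k basis dimension (number of cyclic knots), at least 3.
#' @return A list: `design` (length(x) x k matrix), `penalty` (k x k),
#'   `period`, `k`.
#' @export
cyclic_basis <- function(x, period, k) {
  if (k < 3L) stop("cyclic basis needs k >= 3", call. = FALSE)
  h <- period / k
  x <- x %% period
  knots <- h * ((-3):(k + 3))
  B <- splines::splineDesign(knots, x, ord = 4)
  Bc <- B[, seq_len(k), drop = FALSE]
  Bc[, 1:3] <- Bc[, 1:3] + B[, k + 1:3, drop = FALSE]
  D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    D[i, i] <- -2
    D[i, if (i == 1L) k else i - 1L] <- 1
    D[i, if (i == k) 1L else i + 1L] <- 1
  }
  list(design = Bc, penalty = crossprod(D), period = period, k = k)
}

# sum-to-zero reparameterization: columns of C span the null space of the
# constraint row c (the column means of the training design)
constraint_null <- function(cvec) {
  qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

#' Fit a cyclic additive model on the temporal grid
#'
#' Penalized least squares for
#' `y = alpha + f_hour(hour) + f_year(year) + f_int(hour, year)` with
#' cyclic P-spline marginals (dimension `k_hour` and `k_year`) and their
#' tensor-product interaction (marginal constraints removed, so each term
#' sums to zero over the training design). Smoothing parameters are chosen
#' by GCV minimization over a fixed log-spaced grid -- deterministic by
#' construction. Effective degrees of freedom per term are the traces of
#' the corresponding hat-matrix blocks.
#'
#' @param hour hour-of-day coordinate (cycle length 24).
#' @param year year-cycle coordinate on the 26-period scale, in `[0, 26)`
#'   (period index minus 1 for cell fits; `(day - 1)/14` clipped for
#'   day-resolution responses).
#' @param y response (selection coefficients, or any grid response).
#' @param k_hour,k_year marginal basis dimensions (defaults 5 and 10).
#' @param lambda_grid candidate smoothing parameters (common log grid for
#'   all three terms).
#' @return An object of class `cyclic_gam` with coefficients, per-term
#'   `edf`, `lambda`, `gcv`, fitted values and everything needed for
#'   prediction.
#' @export
fit_cyclic_gam <- function(hour, year, y, k_hour = 5L, k_year = 10L,
                           lambda_grid = 10^seq(-3, 7, by = 1)) {
  ok <- is.finite(y)
  hour <- hour[ok]; year <- year[ok]; y <- y[ok]
  n <- length(y)
  if (n < 50L) stop("need at least 50 estimable cell values to smooth",
                    call. = FALSE)
  bh <- cyclic_basis(hour, 24, k_hour)
  by <- cyclic_basis(year, 26, k_year)
  Ch <- constraint_null(colMeans(bh$design))
  Cy <- constraint_null(colMeans(by$design))
  Zh <- bh$design %*% Ch
  Zy <- by$design %*% Cy
  Sh <- crossprod(Ch, bh$penalty %*% Ch)
  Sy <- crossprod(Cy, by$penalty %*% Cy)
  ph <- ncol(Zh); py <- ncol(Zy)
  # tensor interaction, h-index slow
  Zi <- Zh[, rep(seq_len(ph), each = py), drop = FALSE] *
    Zy[, rep(seq_len(py), times = ph), drop = FALSE]
  Si <- kronecker(Sh, diag(py)) + kronecker(diag(ph), Sy)

  X <- cbind(`(Intercept)` = 1, Zh, Zy, Zi)
  p <- ncol(X)
  idx <- list(intercept = 1L,
              hour = 1L + seq_len(ph),
              year = 1L + ph + seq_len(py),
              interaction = 1L + ph + py + seq_len(ph * py))
  embed <- function(S, cols) {
    M <- matrix(0, p, p); M[cols, cols] <- S; M
  }
  S1 <- embed(Sh, idx$hour); S2 <- embed(Sy, idx$year)
  S3 <- embed(Si, idx$interaction)

  XtX <- crossprod(X); Xty <- crossprod(X, y)
  best <- NULL
  # grid walked from heaviest to lightest smoothing so that GCV ties
  # (e.g. a response in every penalty null space) resolve to the smoothest
  # fit; improvements below a numerical tolerance do not displace it
  lg <- sort(lambda_grid, decreasing = TRUE)
  grid <- expand.grid(l1 = lg, l2 = lg, l3 = lg)
  gcv_all <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    A <- XtX + grid$l1[g] * S1 + grid$l2[g] * S2 + grid$l3[g] * S3
    AinvXtX <- tryCatch(solve(A, XtX), error = function(e) NULL)
    if (is.null(AinvXtX)) { gcv_all[g] <- Inf; next }
    coef <- solve(A, Xty)
    rss <- sum((y - X %*% coef)^2)
    edf <- sum(diag(AinvXtX))
    gcv_all[g] <- n * rss / (n - edf)^2
    if (is.null(best) ||
        gcv_all[g] < best$gcv - 1e-10 * (1 + abs(best$gcv)))
      best <- list(gcv = gcv_all[g], g = g, coef = coef,
                   AinvXtX = AinvXtX, rss = rss, edf = edf)
  }
  if (is.null(best)) stop("singular penalized system for every lambda",
                          call. = FALSE)
  lam <- as.numeric(grid[best$g, ])
  rng_l <- range(lambda_grid)
  if (any(lam == rng_l[1]) || any(lam == rng_l[2]))
    warning("GCV minimum on the lambda grid boundary", call. = FALSE)
  edf_term <- vapply(idx, function(cols) sum(diag(best$AinvXtX)[cols]),
                     numeric(1))
  fitted <- as.vector(X %*% best$coef)
  structure(list(
    coefficients = as.vector(best$coef), idx = idx,
    Ch = Ch, Cy = Cy, k_hour = k_hour, k_year = k_year,
    lambda = stats::setNames(lam, c("hour", "year", "interaction")),
    edf = edf_term, gcv = best$gcv, gcv_grid = cbind(grid, gcv = gcv_all),
    sigma2 = best$rss / max(1, n - best$edf),
    fitted = fitted, residuals = y - fitted, y = y,
    hour = hour, year = year, n = n
  ), class = "cyclic_gam")
}

# design matrix for new (hour, year) coordinates under the training
# constraint transforms
cyclic_gam_design <- function(object, hour, year) {
  Zh <- cyclic_basis(hour, 24, object$k_hour)$design %*% object$Ch
  Zy <- cyclic_basis(year, 26, object$k_year)$design %*% object$Cy
  ph <- ncol(Zh); py <- ncol(Zy)
  Zi <- Zh[, rep(seq_len(ph), each = py), drop = FALSE] *
    Zy[, rep(seq_len(py), times = ph), drop = FALSE]
  cbind(1, Zh, Zy, Zi)
}

# day of year -> year-cycle coordinate on the 26-period scale
day_to_year_coord <- function(day) {
  pmin((day - 1) / 14, 26 - 1e-9)
}

#' Predict from a cyclic additive model
#'
#' @param object a `cyclic_gam`.
#' @param day day of year 1..365 (converted to the 26-period cycle
#'   coordinate; days 365-366 fall in the final period).
#' @param hour hour of day in `[0, 24)` (24 wraps to 0).
#' @param ... unused.
#' @return Numeric vector of predicted values (recycled over equal-length
#'   `day` and `hour`).
#' @export
predict.cyclic_gam <- function(object, day, hour, ...) {
  stopifnot(length(day) == length(hour))
  X <- cyclic_gam_design(object, hour, day_to_year_coord(day))
  as.vector(X %*% object$coefficients)
}

#' Predict a full day x hour selection surface
#'
#' @param object a fitted `cyclic_gam`.
#' @param days,hours grid margins (defaults: days 1..365, hours 0..23).
#' @return A `length(days) x length(hours)` matrix of predictions, of class
#'   `selection_surface` with `days`/`hours` attributes.
#' @export
predict_surface <- function(object, days = 1:365, hours = 0:23) {
  g <- expand.grid(day = days, hour = hours)
  m <- matrix(predict(object, g$day, g$hour), nrow = length(days))
  structure(m, days = days, hours = hours, class = "selection_surface")
}

#' @export
print.cyclic_gam <- function(x, ...) {
  cat("Cyclic additive model (penalized least squares, GCV-selected lambda)\n")
  cat(sprintf("  n = %d, intercept = %.4f, residual sd = %.4f\n",
              x$n, x$coefficients[1], sqrt(x$sigma2)))
  for (t in c("hour", "year", "interaction"))
    cat(sprintf("  f_%-12s edf = %5.2f  lambda = %g\n", t, x$edf[[t]],
                x$lambda[[t]]))
  invisible(x)
}

#' Permutation significance of the smooth terms
#'
#' Permutes the response over the cells, refits at the smoothing parameters
#' selected for the observed response, and compares each term's explained
#' sum of squares against its permutation null;
#' `p = (1 + #\{perm >= obs\}) / (n_perm + 1)`. An approximate analogue of
#' parametric smooth-term tests, exact under exchangeability of the cell
#' responses.
#'
#' @param object a `cyclic_gam`.
#' @param n_perm number of permutations (at least 99 recommended).
#' @param seed integer seed.
#' @return Named numeric p-values for `hour`, `year`, `interaction`.
#' @export
significance_by_permutation <- function(object, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) warning("fewer than 99 permutations gives coarse p-values",
                            call. = FALSE)
  rng <- local_rng(seed)
  X <- cyclic_gam_design(object, object$hour, object$year)
  p <- ncol(X)
  embedS <- function(S, cols) { M <- matrix(0, p, p); M[cols, cols] <- S; M }
  # reconstruct penalties from the constraint transforms
  Sh <- crossprod(object$Ch,
                  cyclic_basis(0, 24, object$k_hour)$penalty %*% object$Ch)
  Sy <- crossprod(object$Cy,
                  cyclic_basis(0, 26, object$k_year)$penalty %*% object$Cy)
  ph <- ncol(object$Ch); py <- ncol(object$Cy)
  Si <- kronecker(Sh, diag(py)) + kronecker(diag(ph), Sy)
  A <- crossprod(X) + object$lambda[["hour"]] * embedS(Sh, object$idx$hour) +
    object$lambda[["year"]] * embedS(Sy, object$idx$year) +
    object$lambda[["interaction"]] * embedS(Si, object$idx$interaction)
  P <- solve(A, t(X))          # coef = P %*% y
  terms <- c("hour", "year", "interaction")
  term_ss <- function(coef) {
    vapply(terms, function(t) {
      cols <- object$idx[[t]]
      sum((X[, cols, drop = FALSE] %*% coef[cols])^2)
    }, numeric(1))
  }
  obs_ss <- term_ss(P %*% object$y)
  exceed <- stats::setNames(numeric(3), terms)
  for (b in seq_len(n_perm)) {
    ss <- term_ss(P %*% sample(object$y))
    exceed <- exceed + (ss >= obs_ss)
  }
  (1 + exceed) / (n_perm + 1)
}
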