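#' Gamma step-length kernel: maximum-likelihood fit
#'
#' Newton iteration on the shape parameter using the digamma equation
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))`, with
#' `scale = mean(x) / shape`, so the MLE identity `shape * scale == mean(x)`
#' holds exactly. Zero lengths are dropped (count reported), as the gamma
#' density is supported on the positive reals.
#'
#' @param step_lengths positive step lengths (meters); at least 10 after
#'   dropping zeros.
#' @return A list of class `gamma_fit`: `shape`, `scale`, `n`, `n_zero_dropped`.
#' @export
fit_gamma <- function(step_lengths) {
  x <- step_lengths[!is.na(step_lengths)]
  n_zero <- sum(x <= 0)
  x <- x[x > 0]
  if (length(x) < 10L) stop("need at least 10 positive step lengths",
                            call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate sample: all step lengths equal",
                               call. = FALSE)
  m <- mean(x)
  s <- log(m) - mean(log(x))          # s > 0 by Jensen unless degenerate
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # standard start
  for (it in 1:100) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    shape_new <- shape - step
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-12 * shape) { shape <- shape_new; break }
    shape <- shape_new
  }
  structure(list(shape = shape, scale = m / shape, n = length(x),
                 n_zero_dropped = n_zero), class = "gamma_fit")
}

#' Von Mises turning-angle kernel: maximum-likelihood fit
#'
#' The mean direction `mu` is the circular mean; the concentration `kappa`
#' solves `A1(kappa) = I1(kappa)/I0(kappa) = Rbar` (the mean resultant
#' length) by bracketed root-finding. `kappa = 0` when `Rbar` is below the
#' numerical floor (no directional signal); `kappa` is capped when `Rbar`
#' is numerically 1.
#'
#' @param turning_angles angles in radians; at least 10 non-missing values.
#' @param kappa_cap upper bound on the fitted concentration.
#' @return A list of class `vonmises_fit`: `mu` (in `(-pi, pi]`), `kappa`, `n`.
#' @export
fit_vonmises <- function(turning_angles, kappa_cap = 1e6) {
  a <- turning_angles[!is.na(turning_angles)]
  if (length(a) < 10L) stop("need at least 10 turning angles", call. = FALSE)
  C <- mean(cos(a)); S <- mean(sin(a))
  rbar <- sqrt(C^2 + S^2)
  mu <- wrap_angle(atan2(S, C))
  # A1(k) = I1(k)/I0(k); asymptotic expansion where besselI underflows
  a1 <- function(k) {
    if (k > 1e5) return(1 - 1 / (2 * k) - 1 / (8 * k^2))
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  kappa <- if (rbar < 1e-8) {
    0
  } else if (a1(kappa_cap) <= rbar) {
    kappa_cap
  } else {
    stats::uniroot(function(k) a1(k) - rbar, c(1e-10, kappa_cap),
                   tol = 1e-10)$root
  }
  structure(list(mu = mu, kappa = kappa, n = length(a)),
            class = "vonmises_fit")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; exact, vectorized by batch rejection.
#' `kappa = 0` reduces to the uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(ok)
    if (nk > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  wrap_angle(out + mu)
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma step-length kernel: shape = %.4f, scale = %.2f m (mean %.2f m, n = %d)\n",
              x$shape, x$scale, x$shape * x$scale, x$n))
  invisible(x)
}

#' @export
print.vonmises_fit <- function(x, ...) {
  cat(sprintf("Von Mises turning-angle kernel: mu = %.4f rad, kappa = %.4f (n = %d)\n",
              x$mu, x$kappa, x$n))
  invisible(x)
}
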