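#' Specify true, cyclically time-varying selection coefficients
#'
#' Defines, per model covariate, a harmonic selection surface
#' \deqn{\beta(d, t) = a_0 + a_{hour}\cos(2\pi t/24 - \phi_{hour})
#'   + a_{year}\cos(2\pi d/365 - \phi_{year})
#'   + a_{int}\cos(2\pi t/24)\cos(2\pi d/365)}
#' with day of year \eqn{d \in [1, 365]} and hour \eqn{t \in [0, 24)}.
#' The surface is periodic in both arguments, so it is exactly the kind of
#' signal the cyclic smoothers downstream are designed to recover.
#'
#' @param ... named coefficient vectors, one per model in
#'   \code{\link{ssf_models}}. Each is a numeric vector with any of the
#'   elements `a0`, `a_hour`, `phi_hour`, `a_year`, `phi_year`, `a_int`
#'   (missing elements default to 0). Unnamed models default to a zero
#'   surface.
#' @return An object of class `beta_spec`: a list of full 6-coefficient
#'   vectors keyed by model id.
#' @examples
#' spec <- beta_spec(deciduous = c(a0 = 0.5, a_hour = 1),
#'                   grassland = c(a_year = 1, phi_year = pi))
#' true_beta(spec, "deciduous", day = 180, hour = 0)
#' @export
beta_spec <- function(...) {
  given <- list(...)
  bad <- setdiff(names(given), ssf_models)
  if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  full <- c(a0 = 0, a_hour = 0, phi_hour = 0, a_year = 0, phi_year = 0,
            a_int = 0)
  out <- lapply(ssf_models, function(m) {
    v <- full
    g <- given[[m]]
    if (!is.null(g)) {
      bad <- setdiff(names(g), names(full))
      if (length(bad)) stop("unknown coefficient(s) for ", m, ": ",
                            paste(bad, collapse = ", "), call. = FALSE)
      v[names(g)] <- g
    }
    v
  })
  names(out) <- ssf_models
  structure(out, class = "beta_spec")
}

#' Evaluate a true selection surface
#'
#' @param spec a \code{\link{beta_spec}}.
#' @param model one of \code{\link{ssf_models}}.
#' @param day day of year, in `[1, 365]` (vectorized).
#' @param hour hour of day, in `[0, 24)` (vectorized).
#' @return Numeric vector of beta values.
#' @export
true_beta <- function(spec, model, day, hour) {
  stopifnot(inherits(spec, "beta_spec"))
  if (!model %in% names(spec)) stop("unknown model id: ", model, call. = FALSE)
  stopifnot(all(day >= 1 & day <= 365), all(hour >= 0 & hour < 24))
  v <- spec[[model]]
  wh <- 2 * pi * hour / 24
  wy <- 2 * pi * day / 365
  v[["a0"]] + v[["a_hour"]] * cos(wh - v[["phi_hour"]]) +
    v[["a_year"]] * cos(wy - v[["phi_year"]]) +
    v[["a_int"]] * cos(wh) * cos(wy)
}

#' True selection surface on the standard 365-day x 24-hour grid
#'
#' @inheritParams true_beta
#' @return A 365 x 24 matrix; rows are days 1..365, columns hours 0..23.
#' @export
true_beta_surface <- function(spec, model) {
  g <- expand.grid(day = 1:365, hour = 0:23)
  matrix(true_beta(spec, model, g$day, g$hour), nrow = 365)
}

#' @export
print.beta_spec <- function(x, ...) {
  cat("True selection coefficient surfaces (harmonic in hour and day):\n")
  nz <- names(x)[vapply(x, function(v) any(v[c(1, 2, 4, 6)] != 0), logical(1))]
  if (!length(nz)) cat("  all models: zero surface\n")
  for (m in nz) {
    v <- x[[m]]
    cat(sprintf("  %-16s a0=%.2f a_hour=%.2f a_year=%.2f a_int=%.2f\n",
                m, v[["a0"]], v[["a_hour"]], v[["a_year"]], v[["a_int"]]))
  }
  invisible(x)
}
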