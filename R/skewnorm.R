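#' Skew-normal parameter set (canonical parameterization)
#'
#' The skew-normal distribution SN(mu, omega, lambda) generalizes the
#' Gaussian with a location `mu`, a scale `omega > 0` and a real skewness
#' `lambda` (`lambda = 0` recovers N(mu, omega^2)). Assay score samples are
#' modeled with this family because functional-score distributions are
#' typically asymmetric.
#'
#' @param location Location parameter, in assay-score units.
#' @param scale Positive scale parameter, in assay-score units.
#' @param skew Dimensionless skewness parameter.
#' @return An object of class `sn_params`.
#' @examples
#' sn_params(0, 1, 2)
#' @export
sn_params <- function(location, scale, skew) {
  assert_scalar_number(location, "location")
  assert_scalar_number(scale, "scale")
  assert_scalar_number(skew, "skew")
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  structure(list(location = location, scale = scale, skew = skew),
            class = "sn_params")
}

#' @export
print.sn_params <- function(x, ...) {
  cat(sprintf("SN(location = %.4g, scale = %.4g, skew = %.4g)\n",
              x$location, x$scale, x$skew))
  invisible(x)
}

#' Alternate (stochastic-representation) skew-normal parameters
#'
#' The alternate parameterization (location, Delta, Gamma) corresponds to the
#' constructive representation `X = location + Delta * T + sqrt(Gamma) * U`,
#' with `T` a standard normal truncated below zero and `U` standard normal.
#' It is the natural coordinate system for the EM parameter updates. The two
#' parameterizations are related by `Delta = omega * lambda / sqrt(1 + lambda^2)`
#' and `Gamma = omega^2 * (1 - lambda^2 / (1 + lambda^2))`, so that
#' `Delta^2 + Gamma = omega^2`.
#'
#' @param location Location parameter.
#' @param delta Skewness-carrying coefficient (assay-score units); its sign is
#'   the sign of the canonical skew.
#' @param gamma Strictly positive residual variance (squared score units).
#' @return An object of class `sn_alt_params`.
#' @export
sn_alt_params <- function(location, delta, gamma) {
  assert_scalar_number(location, "location")
  assert_scalar_number(delta, "delta")
  assert_scalar_number(gamma, "gamma")
  if (gamma < 0) stop("'gamma' must be nonnegative", call. = FALSE)
  if (gamma == 0) stop("'gamma' = 0 is a degenerate (half-normal) boundary; not supported",
                       call. = FALSE)
  structure(list(location = location, delta = delta, gamma = gamma),
            class = "sn_alt_params")
}

#' Convert between canonical and alternate skew-normal parameterizations
#'
#' @param params An `sn_params` (for `canonical_to_alternate`) or
#'   `sn_alt_params` (for `alternate_to_canonical`) object.
#' @return The parameter set in the other parameterization. The maps are
#'   mutually inverse and preserve the sign of the skew.
#' @examples
#' alternate_to_canonical(canonical_to_alternate(sn_params(2.5, 0.7, -1.3)))
#' @export
canonical_to_alternate <- function(params) {
  stopifnot(inherits(params, "sn_params"))
  delta_unit <- params$skew / sqrt(1 + params$skew^2)
  sn_alt_params(location = params$location,
                delta = params$scale * delta_unit,
                gamma = params$scale^2 * (1 - delta_unit^2))
}

#' @rdname canonical_to_alternate
#' @export
alternate_to_canonical <- function(params) {
  stopifnot(inherits(params, "sn_alt_params"))
  sn_params(location = params$location,
            scale = sqrt(params$delta^2 + params$gamma),
            skew = params$delta / sqrt(params$gamma))
}

## Internal flat representation c(mu, delta, gamma) used by the EM hot path.
alt_vec <- function(params) {
  if (inherits(params, "sn_params")) params <- canonical_to_alternate(params)
  c(params$location, params$delta, params$gamma)
}

alt_vec_to_canonical <- function(v) {
  sn_params(v[1], sqrt(v[2]^2 + v[3]), v[2] / sqrt(v[3]))
}

sn_logpdf_alt <- function(x, v) {
  omega <- sqrt(v[2]^2 + v[3])
  lambda <- v[2] / sqrt(v[3])
  z <- (x - v[1]) / omega
  log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(lambda * z, log.p = TRUE)
}

#' Skew-normal density, log-density and distribution function
#'
#' `sn_pdf` evaluates `(2/omega) * phi(z) * Phi(lambda * z)` with
#' `z = (x - mu)/omega`; `sn_logpdf` is its numerically safe logarithm
#' (needed deep in the distribution tails during EM); `sn_cdf` evaluates the
#' distribution function via Owen's T function,
#' `F(x) = Phi(z) - 2 * T(z, lambda)`, with the T integral computed by
#' adaptive quadrature.
#'
#' @param x Numeric vector of quantiles.
#' @param params An `sn_params` object.
#' @return `sn_pdf`: nonnegative densities; `sn_cdf`: probabilities in
#'   `[0, 1]`, nondecreasing in `x`.
#' @examples
#' sn_pdf(0, sn_params(0, 1, 0))   # standard normal density at 0
#' sn_cdf(0, sn_params(0, 1, 0))   # 0.5
#' @export
sn_pdf <- function(x, params) {
  exp(sn_logpdf(x, params))
}

#' @rdname sn_pdf
#' @export
sn_logpdf <- function(x, params) {
  stopifnot(inherits(params, "sn_params"))
  z <- (x - params$location) / params$scale
  log(2) - log(params$scale) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(params$skew * z, log.p = TRUE)
}

# Owen's T function T(h, a) by adaptive quadrature; vectorized over h.
owen_t <- function(h, a) {
  if (a == 0) return(numeric(length(h)))
  vapply(h, function(hh) {
    if (!is.finite(hh)) return(0)
    stats::integrate(function(u) exp(-0.5 * hh^2 * (1 + u^2)) / (1 + u^2),
                     lower = 0, upper = a,
                     rel.tol = 1e-10, abs.tol = 1e-13)$value / (2 * pi)
  }, numeric(1))
}

#' @rdname sn_pdf
#' @export
sn_cdf <- function(x, params) {
  stopifnot(inherits(params, "sn_params"))
  z <- (x - params$location) / params$scale
  p <- stats::pnorm(z) - 2 * owen_t(z, params$skew)
  pmin(pmax(p, 0), 1)
}

#' Draw skew-normal variates
#'
#' Sampling uses the constructive representation
#' `X = mu + Delta * |Z1| + sqrt(Gamma) * Z2` with independent standard
#' normals `Z1, Z2`, so a fixed `seed` yields byte-identical output.
#'
#' @param params An `sn_params` object.
#' @param n Number of draws (positive integer).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Numeric vector of length `n`.
#' @export
sn_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "sn_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  v <- alt_vec(params)
  with_seed(seed, {
    t0 <- abs(stats::rnorm(n))
    u <- stats::rnorm(n)
    v[1] + v[2] * t0 + sqrt(v[3]) * u
  })
}
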