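# Skew-normal distribution in the centred parameterisation (mean, SD, shape).
#
# The centred parameters (mu, sigma, alpha) are what a data analyst reports;
# the direct parameters (xi, w, alpha) are what the density is written in:
#   f(x) = (2/w) phi(z) Phi(alpha * z),  z = (x - xi)/w.
# The two are linked through mu_z = sqrt(2/pi) * alpha / sqrt(1 + alpha^2):
#   w = sigma / sqrt(1 - mu_z^2),  xi = mu - w * mu_z,
# so that the distribution has mean mu and variance sigma^2 exactly.
# alpha = 0 degenerates to the normal distribution.

.check_sn <- function(mean, sd, alpha) {
  if (!is.numeric(mean) || !is.numeric(sd) || !is.numeric(alpha))
    stop("skew-normal parameters must be numeric", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(!is.finite(alpha)))
    stop("skew-normal parameters must be finite", call. = FALSE)
  if (any(sd <= 0))
    stop("'sd' must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

#' Convert centred skew-normal parameters to direct parameters
#'
#' Maps the centred parameterisation (population mean, SD and shape) to the
#' direct parameterisation (location `xi`, scale `w`, shape `alpha`) in which
#' the skew-normal density is written. The mapping uses
#' `mu_z = sqrt(2/pi) * alpha / sqrt(1 + alpha^2)`, `w = sd / sqrt(1 - mu_z^2)`
#' and `xi = mean - w * mu_z`, which guarantees that the distribution with the
#' returned direct parameters has mean `mean` and variance `sd^2`.
#'
#' @param mean Population mean (outcome units).
#' @param sd Population standard deviation (outcome units, > 0).
#' @param alpha Shape (skewness) parameter; `alpha = 0` gives the normal
#'   distribution, positive values skew to the right.
#' @return A list with components `xi` (location), `w` (scale), `alpha`
#'   (shape) and `mu_z` (mean of the standardised skew-normal kernel).
#' @seealso [sn_centred()] for the inverse mapping.
#' @examples
#' sn_direct(0, 1, 1)
#' sn_direct(5, 2, -3)$xi # above the mean for left-skewed distributions
#' @export
sn_direct <- function(mean, sd, alpha) {
  .check_sn(mean, sd, alpha)
  mu_z <- sqrt(2 / pi) * alpha / sqrt(1 + alpha^2)
  w <- sd / sqrt(1 - mu_z^2)
  xi <- mean - w * mu_z
  list(xi = xi, w = w, alpha = alpha, mu_z = mu_z)
}

#' Convert direct skew-normal parameters to centred parameters
#'
#' Inverse of [sn_direct()]: given location `xi`, scale `w` and shape `alpha`,
#' returns the population mean and SD of the corresponding skew-normal
#' distribution.
#'
#' @param xi Location parameter (outcome units).
#' @param w Scale parameter (outcome units, > 0).
#' @param alpha Shape parameter.
#' @return A list with components `mean`, `sd`, `alpha` and `mu_z`.
#' @export
sn_centred <- function(xi, w, alpha) {
  if (any(!is.finite(xi)) || any(!is.finite(w)) || any(!is.finite(alpha)))
    stop("direct parameters must be finite", call. = FALSE)
  if (any(w <= 0)) stop("'w' must be strictly positive", call. = FALSE)
  mu_z <- sqrt(2 / pi) * alpha / sqrt(1 + alpha^2)
  list(mean = xi + w * mu_z, sd = w * sqrt(1 - mu_z^2),
       alpha = alpha, mu_z = mu_z)
}

#' Owen's T function
#'
#' Computes Owen's T function
#' `T(h, a) = (1 / 2 pi) * integral_0^a exp(-h^2 (1 + x^2) / 2) / (1 + x^2) dx`,
#' the auxiliary bivariate-normal integral through which the skew-normal CDF
#' has the closed form `Phi(z) - 2 T(z, alpha)`. Arguments with `|a| > 1` are
#' reduced to `|a| <= 1` via the standard identity
#' `T(h, a) = (Phi(h) + Phi(ah))/2 - Phi(h) Phi(ah) - T(ah, 1/a)` before the
#' defining integral is evaluated by adaptive quadrature.
#'
#' @param h Numeric vector.
#' @param a Numeric scalar or vector of the same length as `h`.
#' @return Numeric vector of the same length as `h`.
#' @export
owens_t <- function(h, a) {
  if (!is.numeric(h) || !is.numeric(a))
    stop("'h' and 'a' must be numeric", call. = FALSE)
  if (length(a) == 1L) a <- rep_len(a, length(h))
  if (length(a) != length(h))
    stop("'a' must have length 1 or length(h)", call. = FALSE)
  vapply(seq_along(h), function(i) .owens_t1(h[i], a[i]), numeric(1))
}

.owens_t1 <- function(h, a) {
  if (is.nan(h) || is.nan(a)) return(NaN)
  if (a == 0 || is.infinite(h)) return(0)
  if (a < 0) return(-.owens_t1(h, -a))
  h <- abs(h) # T(-h, a) = T(h, a)
  if (is.infinite(a)) return(0.5 * pnorm(-h))
  if (a > 1) {
    ah <- a * h
    return(0.5 * (pnorm(h) + pnorm(ah)) - pnorm(h) * pnorm(ah) -
             .owens_t1(ah, 1 / a))
  }
  if (h == 0) return(atan(a) / (2 * pi))
  val <- integrate(function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2),
                   0, a, rel.tol = 1e-12, abs.tol = 1e-15)
  val$value / (2 * pi)
}

#' Skew-normal density
#'
#' Density of the skew-normal distribution in the centred parameterisation:
#' `(2/w) * phi((x - xi)/w) * Phi(alpha * (x - xi)/w)` with `(xi, w)` derived
#' from `(mean, sd, alpha)` by [sn_direct()].
#'
#' @param x Vector of quantiles (outcome units).
#' @inheritParams sn_direct
#' @param log Logical; return the log density?
#' @return Density values (units 1/outcome).
#' @export
dskewnorm <- function(x, mean = 0, sd = 1, alpha = 0, log = FALSE) {
  dp <- sn_direct(mean, sd, alpha)
  z <- (x - dp$xi) / dp$w
  logd <- base::log(2) - base::log(dp$w) + dnorm(z, log = TRUE) +
    pnorm(alpha * z, log.p = TRUE)
  if (log) logd else exp(logd)
}

#' Skew-normal cumulative distribution function
#'
#' `P(X <= q)` for a skew-normal outcome with the given centred parameters,
#' evaluated through Owen's T function as `Phi(z) - 2 T(z, alpha)` with
#' `z = (q - xi)/w`. A direct adaptive-quadrature evaluation of the density
#' integral is available as `method = "quadrature"` and is used automatically
#' should the Owen's T path fail.
#'
#' @param q Vector of quantiles (outcome units).
#' @inheritParams sn_direct
#' @param method `"owen"` (default, closed form via Owen's T) or
#'   `"quadrature"` (adaptive quadrature of the density, absolute tolerance
#'   1e-10).
#' @return Probabilities in `[0, 1]`.
#' @export
pskewnorm <- function(q, mean = 0, sd = 1, alpha = 0,
                      method = c("owen", "quadrature")) {
  method <- match.arg(method)
  dp <- sn_direct(mean, sd, alpha)
  z <- (q - dp$xi) / dp$w
  if (method == "owen") {
    p <- tryCatch(pnorm(z) - 2 * owens_t(z, alpha),
                  error = function(e) NULL)
    if (!is.null(p)) return(pmin(pmax(p, 0), 1))
  }
  # quadrature fallback: integrate the density from the far left tail
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    lo <- dp$xi - 15 * dp$w
    if (qi <= lo) return(0)
    res <- tryCatch(
      integrate(dskewnorm, lo, qi, mean = mean, sd = sd, alpha = alpha,
                rel.tol = 1e-12, abs.tol = 1e-10),
      error = function(e)
        stop("quadrature evaluation of the skew-normal CDF failed at q = ",
             qi, " (mean = ", mean, ", sd = ", sd, ", alpha = ", alpha,
             "): ", conditionMessage(e), call. = FALSE))
    min(max(res$value, 0), 1)
  }, numeric(1))
}

#' Skew-normal quantile function
#'
#' Numerical inverse of [pskewnorm()] by root bracketing.
#'
#' @param p Vector of probabilities in (0, 1).
#' @inheritParams sn_direct
#' @return Quantiles (outcome units).
#' @export
qskewnorm <- function(p, mean = 0, sd = 1, alpha = 0) {
  .check_sn(mean, sd, alpha)
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  vapply(p, function(pi) {
    uniroot(function(x) pskewnorm(x, mean, sd, alpha) - pi,
            lower = mean - 15 * sd, upper = mean + 15 * sd,
            extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate skew-normal draws
#'
#' Random variates via the convolution representation
#' `Z = delta |U0| + sqrt(1 - delta^2) U1` with `delta = alpha/sqrt(1+alpha^2)`
#' and independent standard normals `U0, U1`; `X = xi + w Z`.
#'
#' @param n Number of draws.
#' @inheritParams sn_direct
#' @return Numeric vector of length `n`.
#' @export
rskewnorm <- function(n, mean = 0, sd = 1, alpha = 0) {
  dp <- sn_direct(mean, sd, alpha)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  dp$xi + dp$w * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

#' Derivative of the tail proportion with respect to the mean
#'
#' The distributional proportion below a fixed cut-point `x0`, seen as a
#' function of the population mean with SD and shape held fixed, has
#' derivative `-(2/w) * phi((x0 - xi)/w) * Phi(alpha (x0 - xi)/w)`, i.e. minus
#' the skew-normal density at the cut-point. This is the building block of
#' every delta-method standard error in the package: raising the mean shifts
#' the distribution rightwards, so the proportion below a fixed cut falls,
#' and the derivative is always `<= 0` with magnitude equal to the density.
#'
#' @param x0 Cut-point (outcome units).
#' @inheritParams sn_direct
#' @return Derivative of `P(X <= x0)` with respect to `mean` (units
#'   1/outcome); non-positive.
#' @export
skewnorm_dp_dmean <- function(x0, mean = 0, sd = 1, alpha = 0) {
  -dskewnorm(x0, mean = mean, sd = sd, alpha = alpha)
}

# Moment skewness gamma1 implied by shape alpha; bounded by ~0.9952717.
.sn_skewness_from_alpha <- function(alpha) {
  mu_z <- sqrt(2 / pi) * alpha / sqrt(1 + alpha^2)
  (4 - pi) / 2 * mu_z^3 / (1 - mu_z^2)^1.5
}

# Invert gamma1 -> alpha (method of moments). |gamma1| at/over the attainable
# bound maps to +/- alpha_cap with an attribute flagging the truncation.
.sn_alpha_from_skewness <- function(gamma1, alpha_cap = 50) {
  bound <- (4 - pi) / 2 * (2 / pi)^1.5 / (1 - 2 / pi)^1.5 # ~0.99527, alpha -> Inf limit
  capped <- abs(gamma1) >= bound
  g <- sign(gamma1) * pmin(abs(gamma1), bound * (1 - 1e-10))
  t <- sign(g) * (2 * abs(g) / (4 - pi))^(1 / 3)
  mu_z <- t / sqrt(1 + t^2)
  delta <- mu_z / sqrt(2 / pi)
  delta <- pmin(pmax(delta, -1 + 1e-12), 1 - 1e-12)
  alpha <- delta / sqrt(1 - delta^2)
  alpha <- sign(alpha) * pmin(abs(alpha), alpha_cap)
  alpha[gamma1 == 0] <- 0
  structure(alpha, capped = capped)
}

# Sample moment skewness m3 / m2^(3/2).
.sample_skewness <- function(x) {
  x <- x - base::mean(x)
  m2 <- base::mean(x^2)
  base::mean(x^3) / m2^1.5
}
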