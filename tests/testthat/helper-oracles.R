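# Independent oracles used across the suite. These recompute quantities from
# first principles (the printed parameter conversions and the defining
# density integral) without calling the package's Owen's-T/CDF code paths.

# Direct parameters from the centred ones, written out from the defining
# relations mu_z^2 = (2/pi) alpha^2/(1+alpha^2), w^2 = sd^2/(1-mu_z^2),
# xi = mean - w mu_z.
oracle_direct <- function(mean, sd, alpha) {
  mu_z2 <- (2 / pi) * alpha^2 / (1 + alpha^2)
  mu_z <- sign(alpha) * sqrt(mu_z2)
  w <- sqrt(sd^2 / (1 - mu_z2))
  list(xi = mean - w * mu_z, w = w, mu_z = mu_z)
}

# Brute-force quadrature of the tail-probability integral: the skew-normal
# density (2/w) phi((t-xi)/w) Phi(alpha (t-xi)/w) integrated from far below.
oracle_sn_cdf <- function(x0, mean, sd, alpha, abs_tol = 1e-10) {
  dp <- oracle_direct(mean, sd, alpha)
  f <- function(t) {
    z <- (t - dp$xi) / dp$w
    2 / dp$w * dnorm(z) * pnorm(alpha * z)
  }
  lo <- dp$xi - 14 * dp$w
  if (x0 <= lo) return(0)
  stats::integrate(f, lo, x0, rel.tol = 1e-12, abs.tol = abs_tol,
                   subdivisions = 500L)$value
}

# Tail probability by quadrature with a purely relative error criterion:
# integrating the (positive) density over the requested tail avoids the
# cancellation that limits CDF-difference accuracy near 0 and 1, so finite
# differences of this oracle stay meaningful for very small tails.
oracle_sn_prob <- function(x0, mean, sd, alpha, lower = TRUE) {
  dp <- oracle_direct(mean, sd, alpha)
  f <- function(t) {
    z <- (t - dp$xi) / dp$w
    2 / dp$w * dnorm(z) * pnorm(alpha * z)
  }
  if (lower)
    stats::integrate(f, dp$xi - 14 * dp$w, x0, rel.tol = 1e-12,
                     abs.tol = 0, subdivisions = 1000L)$value
  else
    stats::integrate(f, x0, dp$xi + 14 * dp$w, rel.tol = 1e-12,
                     abs.tol = 0, subdivisions = 1000L)$value
}

# Published per-group summaries of the birthweight example used by several
# tests.
bw_groups <- function() {
  list(ref = group_summary(983, 3452, 435, "non-smoker"),
       exp = group_summary(494, 3267, 441, "smoker"))
}

# A minimal synthetic sim_metrics object for exercising summarize_grid
# without running replicates.
fake_metrics <- function(rel_bias, rel_se_bias, coverage, n = 100,
                         skewness = 0.1, family = "lognormal",
                         method = "normal", seed = 1) {
  sc <- suppressWarnings(sim_scenario(family, skewness, n, 0.2,
                                      replicates = 10, seed = seed,
                                      method = method))
  structure(
    data.frame(estimand = c("d", "rr", "or"),
               truth = c(0.1, 2, 2.2),
               mean_estimate = c(0.1, 2, 2.2) * (1 + rel_bias),
               sd_estimate = 0.01, mean_se = 0.01 * (1 + rel_se_bias),
               rel_bias = rel_bias, rel_se_bias = rel_se_bias,
               coverage = coverage),
    class = c("sim_metrics", "data.frame"),
    scenario = sc, truths = list(), n_failed = 0L, n_used = 10L)
}
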