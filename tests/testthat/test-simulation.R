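# Simulation framework: generators, analytic truths, scenario runs, grids.

test_that("scenario construction validates and warns on out-of-design values", {
  sc <- sim_scenario("lognormal", 0.2, 100, 0.2, seed = 1)
  expect_s3_class(sc, "sim_scenario")
  expect_identical(sc$replicates, 20000L)
  expect_error(sim_scenario("lognormal", 0.2, 100, 0.2), "seed")
  expect_error(sim_scenario("lognormal", -0.1, 100, 0.2, seed = 1),
               "positive")
  expect_warning(sim_scenario("lognormal", 2, 100, 0.2, seed = 1),
                 "design range")
  expect_warning(sim_scenario("skew_normal", 5, 1000, 0.2, seed = 1),
                 "design range")
})

test_that("generators are seed-deterministic and match their families", {
  x1 <- sim_generate(500, "lognormal", list(meanlog = 0, sdlog = 0.5),
                     seed = 42)
  x2 <- sim_generate(500, "lognormal", list(meanlog = 0, sdlog = 0.5),
                     seed = 42)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0))

  # low log-SD lognormal is nearly normal: closed-form skewness
  # (exp(s^2) + 2) sqrt(exp(s^2) - 1) = 0.060 at s = 0.02
  set.seed(43)
  x <- sim_generate(2e5, "lognormal", list(meanlog = 0, sdlog = 0.02))
  s2 <- exp(0.02^2)
  gamma_true <- (s2 + 2) * sqrt(s2 - 1)
  expect_equal(gamma_true, 0.060, tolerance = 1e-3)
  xc <- x - mean(x)
  expect_equal(mean(xc^3) / mean(xc^2)^1.5, gamma_true, tolerance = 0.15)

  # high log-SD: mean/median ratio equals exp(sdlog^2/2)
  set.seed(44)
  x <- sim_generate(4e5, "lognormal", list(meanlog = 0, sdlog = 1))
  expect_equal(mean(x) / median(x), exp(0.5), tolerance = 0.03)

  # skew-normal family at alpha = 0 is indistinguishable from normal
  set.seed(45)
  x <- sim_generate(1e4, "skew_normal", list(mean = 0, sd = 1, alpha = 0))
  ks <- suppressWarnings(stats::ks.test(x, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("analytic truths come from the generating CDFs", {
  # equal groups: null effects (effect size at the design floor of zero)
  sc <- suppressWarnings(sim_scenario("skew_normal", 3, 100, 0,
                                      replicates = 10, seed = 1))
  tv <- sim_true_values(sc)
  expect_equal(tv$d, 0, tolerance = 1e-12)
  expect_equal(tv$rr, 1, tolerance = 1e-12)
  expect_equal(tv$or, 1, tolerance = 1e-12)

  # lognormal truths match a direct plnorm computation
  sc <- sim_scenario("lognormal", 0.5, 100, 0.3, cutpoint_prob = 0.1,
                     replicates = 10, seed = 1)
  tv <- sim_true_values(sc)
  x0 <- qlnorm(0.1, 0, 0.5)
  expect_equal(tv$cutpoint, x0, tolerance = 1e-10)
  expect_equal(tv$p_ref, 0.1, tolerance = 1e-10)
  m1 <- exp(0.5^2 / 2); sd1 <- sqrt((exp(0.25) - 1) * exp(0.25))
  mlog2 <- log(m1 + 0.3 * sd1) - 0.5^2 / 2
  expect_equal(tv$p_exp, plnorm(x0, mlog2, 0.5), tolerance = 1e-10)
  expect_equal(tv$rr, tv$p_exp / tv$p_ref, tolerance = 1e-12)

  # skew-normal truth at alpha = 0 equals the normal truth
  sc0 <- sim_scenario("skew_normal", 0, 100, 0.3, cutpoint_prob = 0.1,
                      replicates = 10, seed = 1)
  tv0 <- sim_true_values(sc0)
  expect_equal(tv0$cutpoint, qnorm(0.1), tolerance = 1e-8)
  expect_equal(tv0$p_exp, pnorm(qnorm(0.1), 0.3, 1), tolerance = 1e-8)

  # upper-tail scenarios report the upper-tail probabilities
  scu <- sim_scenario("lognormal", 0.5, 100, 0.3, cutpoint_prob = 0.1,
                      tail = "above", replicates = 10, seed = 1)
  tvu <- sim_true_values(scu)
  expect_equal(tvu$p_ref, 0.1, tolerance = 1e-10)
  expect_gt(tvu$p_exp, tvu$p_ref) # shifting the mean up fills the upper tail
})

test_that("scenario runs are deterministic and approximately calibrated", {
  sc <- sim_scenario("skew_normal", 0, 100, 0.3, replicates = 300, seed = 7)
  m1 <- run_scenario(sc)
  m2 <- run_scenario(sc)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_identical(attr(m1, "n_failed"), 0L)
  expect_setequal(m1$estimand, c("d", "rr", "or"))
  expect_true(all(m1$coverage >= 0 & m1$coverage <= 1))
  expect_true(all(m1$sd_estimate > 0))
  # normal data + normal method: near-nominal coverage, small bias
  # (loose bounds: 300 replicates -> MC SD of coverage ~ 0.013)
  expect_true(all(m1$coverage > 0.90 & m1$coverage < 0.99))
  d_row <- m1[m1$estimand == "d", ]
  expect_lt(abs(d_row$mean_estimate - d_row$truth), 4 * d_row$sd_estimate /
              sqrt(attr(m1, "n_used")))
})

test_that("zero effect size yields a mean difference near zero", {
  sc <- suppressWarnings(sim_scenario("lognormal", 0.3, 100, 0,
                                      replicates = 300, seed = 8))
  m <- run_scenario(sc)
  d_row <- m[m$estimand == "d", ]
  expect_equal(d_row$truth, 0, tolerance = 1e-12)
  # rel_bias falls back to the absolute scale when the truth is zero
  expect_lt(abs(d_row$rel_bias), 4 * d_row$sd_estimate / sqrt(300))
})

test_that("scenarios with pervasive estimator failures abort", {
  # cut-point ~ 14 SD into the tail: every replicate hits the degenerate-tail
  # guard, so the >1% failure rule must trigger
  sc <- sim_scenario("skew_normal", 0, 50, 0.2, cutpoint_prob = 1e-45,
                     replicates = 5, seed = 9)
  expect_error(run_scenario(sc), "replicates")
})

test_that("grid summaries reproduce brute-force quantile computations", {
  vals <- c(0.1, 0.2, 0.3, 0.4)
  metrics <- lapply(seq_along(vals), function(i)
    fake_metrics(rel_bias = rep(vals[i], 3), rel_se_bias = rep(vals[i], 3),
                 coverage = rep(0.90 + 0.02 * i, 3), seed = i))
  s7 <- summarize_grid(metrics, quantile_type = 7)
  s6 <- summarize_grid(metrics, quantile_type = 6)
  s1 <- summarize_grid(metrics, quantile_type = 1)
  d7 <- s7[s7$estimand == "d", ]
  expect_identical(d7$n_scenarios, 4L)
  # hand-computed order-statistic interpolations for {0.1, 0.2, 0.3, 0.4}:
  # type 7: h = (n-1)p + 1 = 3.25 -> 0.3 + 0.25 * 0.1 = 0.325
  # type 6: h = (n+1)p = 3.75     -> 0.3 + 0.75 * 0.1 = 0.375
  # type 1: inverse ECDF          -> x_(3) = 0.3
  expect_equal(d7$q3_abs_rel_bias, 0.325)
  expect_equal(s6[s6$estimand == "d", ]$q3_abs_rel_bias, 0.375)
  expect_equal(s1[s1$estimand == "d", ]$q3_abs_rel_bias, 0.3)
  cov <- 0.90 + 0.02 * seq_along(vals)
  expect_equal(d7$coverage_iqr,
               diff(quantile(cov, c(0.25, 0.75), type = 7, names = FALSE)))

  # single-scenario cell: Q3 equals the value, IQR degenerates to zero
  s_one <- summarize_grid(metrics[[2]])
  expect_equal(s_one[s_one$estimand == "rr", ]$q3_abs_rel_bias, 0.2)
  expect_equal(s_one$coverage_iqr, rep(0, 3))

  # all-zero biases summarise to zero
  z <- summarize_grid(lapply(1:3, function(i)
    fake_metrics(rep(0, 3), rep(0, 3), rep(0.95, 3), seed = i)))
  expect_equal(z$q3_abs_rel_bias, rep(0, 3))
  expect_equal(z$q3_abs_rel_se_bias, rep(0, 3))
})
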