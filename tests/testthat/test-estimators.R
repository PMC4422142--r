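# Distributional proportions, comparisons and confidence intervals.

test_that("pooled SD is the df-weighted combination", {
  g <- function(n, s) group_summary(n, 0, s, paste0("g", n, s))
  expect_equal(pooled_sd(g(10, 2), g(50, 2)), 2, tolerance = 1e-14)
  expect_equal(pooled_sd(g(2, 1), g(2, 3)), sqrt(5), tolerance = 1e-14)
  bw <- bw_groups()
  expect_equal(pooled_sd(bw$ref, bw$exp),
               sqrt((982 * 435^2 + 493 * 441^2) / 1475), tolerance = 1e-14)
  expect_equal(round(pooled_sd(bw$ref, bw$exp), 1), 437.0)
})

test_that("group_summary and pooled_model validate their inputs", {
  expect_error(group_summary(1, 0, 1), ">= 2")
  expect_error(group_summary(10.5, 0, 1), "integer")
  expect_error(group_summary(10, 0, 0), "positive")
  g1 <- group_summary(10, 0, 1, "a")
  expect_error(pooled_model(g1, g1), "distinct labels")
  g2 <- group_summary(10, 1, 1, "b")
  expect_error(pooled_model(g1, g2, sd_pooled = -1), "positive")
  # the normal method forces alpha to zero
  expect_identical(pooled_model(g1, g2, alpha = 3, method = "normal")$alpha, 0)
})

test_that("distributional proportions reproduce the closed-form normal case", {
  bw <- bw_groups()
  m <- pooled_model(bw$ref, bw$exp)
  thr <- threshold_spec(2500, "below")
  sdp <- m$sd_pooled
  p1 <- distributional_proportion(m, "reference", thr)
  p2 <- distributional_proportion(m, "exposed", thr)
  # closed-form normal CDF with the pooled SD
  expect_equal(p1$p, pnorm((2500 - 3452) / sdp), tolerance = 1e-12)
  expect_equal(p2$p, pnorm((2500 - 3267) / sdp), tolerance = 1e-12)
  expect_equal(round(p1$p, 4), 0.0147)
  expect_equal(round(p2$p, 4), 0.0396)
  # se^2 = (sd^2/n) p'(mean)^2 reduces to phi(z)^2/n for the normal method
  expect_equal(p1$se, dnorm((2500 - 3452) / sdp) / sqrt(983),
               tolerance = 1e-12)

  # symmetry at the mean; either tail gives 1/2
  g <- group_summary(100, 0, 1, "g"); h <- group_summary(50, 2, 1, "h")
  mm <- pooled_model(g, h, sd_pooled = 1)
  expect_equal(distributional_proportion(mm, "reference",
                                         threshold_spec(0, "below"))$p, 0.5)
  expect_equal(distributional_proportion(mm, "reference",
                                         threshold_spec(0, "above"))$p, 0.5)
  # closed-form SE phi(0)/sqrt(n) at the mean
  expect_equal(distributional_proportion(mm, "reference",
                                         threshold_spec(0, "below"))$se,
               dnorm(0) / 10, tolerance = 1e-12)
})

test_that("SE shrinks as 1/sqrt(n) and degenerate tails are refused", {
  thr <- threshold_spec(-1, "below")
  se_at <- function(n) {
    g <- group_summary(n, 0, 1, "a"); h <- group_summary(n, 0.5, 1, "b")
    distributional_proportion(pooled_model(g, h, sd_pooled = 1),
                              "reference", thr)$se
  }
  expect_equal(se_at(100) / se_at(400), 2, tolerance = 1e-12)
  g <- group_summary(50, 0, 1, "a"); h <- group_summary(50, 0.5, 1, "b")
  m <- pooled_model(g, h, sd_pooled = 1)
  expect_error(
    distributional_proportion(m, "reference", threshold_spec(-11, "below")),
    "degenerate tail")
})

test_that("Monte-Carlo SD of the estimate matches the delta-method SE", {
  # mean 0, sd 1, n = 100, cut at the mean: se = phi(0)/10
  set.seed(101)
  p_hat <- replicate(20000, {
    x <- rnorm(100)
    pnorm((0 - mean(x)) / 1) # sd treated as known, as the delta method does
  })
  expect_equal(sd(p_hat), dnorm(0) / 10, tolerance = 0.03)
})

test_that("two-group comparison reproduces the published birthweight example", {
  bw <- bw_groups()
  cmp <- compare_groups(pooled_model(bw$ref, bw$exp),
                        threshold_spec(2500, "below"))
  expect_equal(round(cmp$d, 3), 0.025)
  expect_equal(round(cmp$se_d, 3), 0.004)
  expect_equal(round(cmp$ci_d, 3), c(0.017, 0.033))
  # log-scale ratio SEs, printed as 0.13 for both ratios
  expect_equal(round(cmp$se_log_rr, 2), 0.13)
  expect_equal(round(cmp$se_log_or, 2), 0.13)
  expect_identical(cmp$direction, "smoker - non-smoker")
})

test_that("comparison has closed-form values in the toy normal case", {
  # reference mean 1, exposed mean 0, sd 1, cut at 0, lower tail
  ref <- group_summary(100, 1, 1, "ref"); exp_ <- group_summary(100, 0, 1, "exp")
  cmp <- compare_groups(pooled_model(ref, exp_, sd_pooled = 1),
                        threshold_spec(0, "below"))
  expect_equal(cmp$p_reference$p, pnorm(-1), tolerance = 1e-12)
  expect_equal(cmp$p_exposed$p, 0.5, tolerance = 1e-12)
  expect_equal(cmp$d, 0.5 - pnorm(-1), tolerance = 1e-12)
  expect_equal(round(cmp$d, 4), 0.3413)
  expect_equal(round(cmp$rr, 3), round(0.5 / pnorm(-1), 3))
  expect_equal(round(cmp$rr, 3), 3.151)
})

test_that("identical groups give null effects and swapping reverses them", {
  a <- group_summary(120, 5, 2, "a"); b <- group_summary(80, 5, 2, "b")
  thr <- threshold_spec(3.3, "below")
  cmp <- compare_groups(pooled_model(a, b, alpha = 2, method = "skew_normal"),
                        thr)
  expect_identical(cmp$d, 0)
  expect_identical(cmp$rr, 1)
  expect_identical(cmp$or, 1)

  a <- group_summary(120, 5, 2, "a"); b <- group_summary(80, 6, 2.4, "b")
  for (alpha in c(0, 3)) {
    method <- if (alpha == 0) "normal" else "skew_normal"
    fwd <- compare_groups(pooled_model(a, b, alpha = alpha, method = method), thr)
    rev <- compare_groups(pooled_model(b, a, alpha = alpha, method = method), thr)
    expect_equal(rev$d, -fwd$d, tolerance = 1e-14)
    expect_equal(rev$rr, 1 / fwd$rr, tolerance = 1e-12)
    expect_equal(rev$or, 1 / fwd$or, tolerance = 1e-12)
    expect_equal(rev$se_log_rr, fwd$se_log_rr, tolerance = 1e-12)
    expect_equal(rev$se_log_or, fwd$se_log_or, tolerance = 1e-12)
    expect_equal(rev$se_d, fwd$se_d, tolerance = 1e-14)
    # directions agree across the three estimands
    expect_identical(fwd$d > 0, fwd$rr > 1)
    expect_identical(fwd$d > 0, fwd$or > 1)
  }
})

test_that("skew-normal path at alpha = 0 equals the normal path", {
  set.seed(11)
  for (i in 1:25) {
    a <- group_summary(50 + i, runif(1, -5, 5), runif(1, 0.5, 3), "a")
    b <- group_summary(80, runif(1, -5, 5), runif(1, 0.5, 3), "b")
    thr <- threshold_spec(runif(1, -4, 4), sample(c("below", "above"), 1))
    n <- tryCatch(compare_groups(pooled_model(a, b, method = "normal"), thr),
                  error = function(e) NULL)
    if (is.null(n)) next # cut-point drawn too deep in a tail
    s <- compare_groups(pooled_model(a, b, alpha = 0, method = "skew_normal"),
                        thr)
    for (f in c("d", "se_d", "rr", "se_log_rr", "or", "se_log_or"))
      expect_equal(s[[f]], n[[f]], tolerance = 1e-10)
  }
})

test_that("tail mapping is exact under the negate transform", {
  # negating data and cut-point flips the tail but leaves every distributional
  # estimate unchanged (proportion preservation for the fitted model)
  a <- group_summary(60, 3, 1.2, "a"); b <- group_summary(90, 3.8, 1.1, "b")
  thr <- threshold_spec(2.5, "below")
  neg <- transform_spec("negate")
  a2 <- group_summary(60, -3, 1.2, "a"); b2 <- group_summary(90, -3.8, 1.1, "b")
  cmp1 <- compare_groups(pooled_model(a, b), thr)
  cmp2 <- compare_groups(pooled_model(a2, b2, sd_pooled = pooled_sd(a, b)),
                         map_threshold(thr, neg))
  expect_equal(cmp2$d, cmp1$d, tolerance = 1e-12)
  expect_equal(cmp2$rr, cmp1$rr, tolerance = 1e-12)
  expect_equal(cmp2$or, cmp1$or, tolerance = 1e-12)
  expect_equal(cmp2$se_d, cmp1$se_d, tolerance = 1e-12)
})

test_that("distributional confidence intervals behave on both scales", {
  ci <- dci(0.025, 0.004, 0.95, "identity")
  expect_equal(ci, 0.025 + c(-1, 1) * qnorm(0.975) * 0.004, tolerance = 1e-12)
  expect_equal(round(ci, 3), c(0.017, 0.033))
  # log-scale interval for a ratio of 1 always contains 1
  ci_log <- dci(1, 0.3, 0.95, "log")
  expect_lt(ci_log[1], 1); expect_gt(ci_log[2], 1)
  # width grows without bound as level -> 1
  expect_gt(diff(dci(0, 1, 1 - 1e-12)), diff(dci(0, 1, 0.999)))
  expect_error(dci(0, 1, 1.2), "level")
  expect_error(dci(0, -1, 0.95), "positive")
})
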