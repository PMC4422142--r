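# Simulation framework: robustness of the normal distributional method to
# skewness and validation of the skew-normal method. Data are generated from
# a lognormal family (skewed upper tail, indexed by the log-SD) or a
# skew-normal family (indexed by the shape alpha), the chosen estimator is
# applied to every replicate, and bias of estimates, bias of standard errors
# and coverage of the 95% DCI are aggregated.

.sim_design_ranges <- list(
  lognormal = c(0.02, 1), skew_normal = c(-20, 20),
  n_per_group = c(20, 500), effect_size = c(0.01, 0.5))

#' Define a simulation scenario
#'
#' @param family `"lognormal"` (skewness indexed by the log-scale SD,
#'   0.02-1 in the study design; the mean/median ratio `exp(sdlog^2/2)`
#'   gauges the skewness) or `"skew_normal"` (skewness indexed by the shape
#'   alpha, -20 to 20).
#' @param skewness Log-SD (lognormal) or shape alpha (skew-normal).
#' @param n_per_group Observations per group (design range 20-500).
#' @param effect_size Standardised mean difference between the groups:
#'   difference in raw-scale means over the reference group's SD (design
#'   range 0.01-0.5). `effect_scale = "se"` instead reads it as a multiple
#'   of the reference mean's standard error.
#' @param cutpoint_prob Reference group's true lower-tail probability at the
#'   cut-point; the cut-point is placed at the corresponding quantile of the
#'   reference distribution so that cut-points are comparable across
#'   skewness levels. Default 0.1.
#' @param tail Tail of interest, `"below"` (default) or `"above"`.
#' @param replicates Number of simulated datasets (default 20000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param method Estimator applied to each replicate: `"normal"` or
#'   `"skew_normal"` (joint MLE of the shared scale and shape per replicate).
#' @param effect_scale `"sd"` (default) or `"se"`.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(family = c("lognormal", "skew_normal"), skewness,
                         n_per_group, effect_size, cutpoint_prob = 0.1,
                         tail = c("below", "above"), replicates = 20000,
                         seed, method = c("normal", "skew_normal"),
                         effect_scale = c("sd", "se")) {
  family <- match.arg(family)
  tail <- match.arg(tail)
  method <- match.arg(method)
  effect_scale <- match.arg(effect_scale)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer 'seed' is mandatory", call. = FALSE)
  stopifnot(is.numeric(skewness), length(skewness) == 1L,
            is.numeric(n_per_group), n_per_group >= 2,
            is.numeric(effect_size), length(effect_size) == 1L,
            is.numeric(cutpoint_prob), cutpoint_prob > 0, cutpoint_prob < 1,
            is.numeric(replicates), replicates >= 1)
  if (family == "lognormal" && skewness <= 0)
    stop("lognormal skewness (log-SD) must be positive", call. = FALSE)
  rng <- .sim_design_ranges[[family]]
  if (skewness < rng[1] || skewness > rng[2])
    warning("skewness ", skewness, " lies outside the study design range [",
            rng[1], ", ", rng[2], "]", call. = FALSE)
  if (n_per_group < 20 || n_per_group > 500)
    warning("n_per_group ", n_per_group,
            " lies outside the study design range [20, 500]", call. = FALSE)
  if (effect_size < 0.01 || effect_size > 0.5)
    warning("effect_size ", effect_size,
            " lies outside the study design range [0.01, 0.5]", call. = FALSE)
  structure(list(family = family, skewness = skewness,
                 n_per_group = as.integer(n_per_group),
                 effect_size = effect_size, cutpoint_prob = cutpoint_prob,
                 tail = tail, replicates = as.integer(replicates),
                 seed = as.integer(seed), method = method,
                 effect_scale = effect_scale),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: %s (skewness %g), n = %d/group, effect %g %s, cut at ref p = %g (%s), %d replicates, %s method, seed %d\n",
    x$family, x$skewness, x$n_per_group, x$effect_size, x$effect_scale,
    x$cutpoint_prob, x$tail, x$replicates, sub("_", "-", x$method), x$seed))
  invisible(x)
}

# Generating-distribution parameters for both groups. The reference
# lognormal has meanlog 0; the exposed group's raw-scale mean is shifted by
# effect * SD(reference) and mapped back to a meanlog with the shared sdlog,
# so both groups stay lognormal. Skew-normal groups share SD 1 and the shape.
.sim_group_params <- function(scenario) {
  eff <- scenario$effect_size
  if (scenario$effect_scale == "se") eff <- eff / sqrt(scenario$n_per_group)
  if (scenario$family == "lognormal") {
    s <- scenario$skewness
    m1 <- exp(s^2 / 2)                     # mean of lognormal(0, s)
    sd1 <- sqrt((exp(s^2) - 1) * exp(s^2))
    m2 <- m1 + eff * sd1
    list(ref = list(meanlog = 0, sdlog = s),
         exp = list(meanlog = log(m2) - s^2 / 2, sdlog = s))
  } else {
    list(ref = list(mean = 0, sd = 1, alpha = scenario$skewness),
         exp = list(mean = eff, sd = 1, alpha = scenario$skewness))
  }
}

.sim_cutpoint <- function(scenario) {
  pars <- .sim_group_params(scenario)$ref
  p <- scenario$cutpoint_prob
  if (scenario$tail == "above") p <- 1 - p
  if (scenario$family == "lognormal")
    qlnorm(p, pars$meanlog, pars$sdlog)
  else
    qskewnorm(p, pars$mean, pars$sd, pars$alpha)
}

#' Generate one sample from a scenario family
#'
#' @param n Number of draws.
#' @param family `"lognormal"` or `"skew_normal"`.
#' @param params Parameter list: `meanlog`/`sdlog` for lognormal,
#'   `mean`/`sd`/`alpha` for skew-normal.
#' @param seed Optional seed set before drawing (omit inside replicate
#'   loops that manage the RNG stream themselves).
#' @return Numeric vector of `n` draws.
#' @export
sim_generate <- function(n, family = c("lognormal", "skew_normal"), params,
                         seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  if (family == "lognormal") rlnorm(n, params$meanlog, params$sdlog)
  else rskewnorm(n, params$mean, params$sd, params$alpha)
}

#' True comparison values of a scenario
#'
#' Exact tail probabilities of both generating distributions at the
#' scenario's cut-point, combined into the true difference in proportions,
#' risk ratio and odds ratio. These analytic truths are what coverage is
#' scored against.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with `p_ref`, `p_exp`, `d`, `rr`, `or` and `cutpoint`.
#' @export
sim_true_values <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  x0 <- .sim_cutpoint(scenario)
  pars <- .sim_group_params(scenario)
  tailp <- function(p) {
    pr <- if (scenario$family == "lognormal")
      plnorm(x0, p$meanlog, p$sdlog)
    else pskewnorm(x0, p$mean, p$sd, p$alpha)
    if (scenario$tail == "below") pr else 1 - pr
  }
  p1 <- tailp(pars$ref)
  p2 <- tailp(pars$exp)
  list(p_ref = p1, p_exp = p2, d = p2 - p1, rr = p2 / p1,
       or = (p2 / (1 - p2)) / (p1 / (1 - p1)), cutpoint = x0)
}

#' Run a simulation scenario
#'
#' For each replicate: draw both groups, apply the chosen distributional
#' method (normal: sample means and df-pooled SD; skew-normal: joint MLE of
#' the shared scale and shape), and score the estimates, standard errors and
#' 95% DCIs of d, rr and or against the scenario's analytic truths.
#' Replicates whose estimator fails (degenerate tail, non-convergence) are
#' counted; the run aborts if more than 1% fail.
#'
#' @param scenario A [sim_scenario()].
#' @param level Confidence level of the DCIs (default 0.95).
#' @return An object of class `"sim_metrics"`: a data frame with one row per
#'   estimand (`d`, `rr`, `or`) and columns `truth`, `mean_estimate`,
#'   `sd_estimate`, `mean_se`, `rel_bias` (mean relative difference between
#'   estimate and truth), `rel_se_bias` (relative difference between the
#'   mean SE and the SD of the estimates) and `coverage`; the scenario,
#'   truths and failure count are attached as attributes.
#' @export
run_scenario <- function(scenario, level = 0.95) {
  stopifnot(inherits(scenario, "sim_scenario"))
  truths <- sim_true_values(scenario)
  pars <- .sim_group_params(scenario)
  thr <- threshold_spec(truths$cutpoint, scenario$tail)
  n <- scenario$n_per_group
  R <- scenario$replicates
  z <- qnorm((1 + level) / 2)

  est <- matrix(NA_real_, R, 3, dimnames = list(NULL, c("d", "rr", "or")))
  ses <- matrix(NA_real_, R, 3) # se_d, se_log_rr, se_log_or
  hit <- matrix(NA, R, 3)
  failed <- 0L

  set.seed(scenario$seed)
  for (r in seq_len(R)) {
    x1 <- sim_generate(n, scenario$family, pars$ref)
    x2 <- sim_generate(n, scenario$family, pars$exp)
    cmp <- tryCatch({
      model <- if (scenario$method == "normal")
        build_pooled_model(x1, x2, method = "normal")
      else
        build_pooled_model(x1, x2, method = "skew_normal")
      compare_groups(model, thr, level = level)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(cmp)) { failed <- failed + 1L; next }
    est[r, ] <- c(cmp$d, cmp$rr, cmp$or)
    ses[r, ] <- c(cmp$se_d, cmp$se_log_rr, cmp$se_log_or)
    hit[r, ] <- c(
      abs(cmp$d - truths$d) <= z * cmp$se_d,
      abs(log(cmp$rr) - log(truths$rr)) <= z * cmp$se_log_rr,
      abs(log(cmp$or) - log(truths$or)) <= z * cmp$se_log_or)
  }
  if (failed > 0.01 * R)
    stop(sprintf("scenario failed: %d of %d replicates (%.1f%%) errored",
                 failed, R, 100 * failed / R), call. = FALSE)

  ok <- !is.na(est[, 1])
  truth_vec <- c(d = truths$d, rr = truths$rr, or = truths$or)
  # SEs for rr/or are on the log scale; compare them with the SD of the log
  # estimates, mirroring how the DCIs are built.
  obs <- cbind(est[ok, 1], log(est[ok, 2]), log(est[ok, 3]))
  mean_est <- colMeans(est[ok, , drop = FALSE])
  sd_obs <- apply(obs, 2, sd)
  mean_se <- colMeans(ses[ok, , drop = FALSE])
  rel_bias <- vapply(1:3, function(j) {
    if (truth_vec[j] == 0) return(base::mean(est[ok, j])) # absolute, truth 0
    base::mean((est[ok, j] - truth_vec[j]) / truth_vec[j])
  }, numeric(1))
  out <- data.frame(
    estimand = c("d", "rr", "or"),
    truth = as.numeric(truth_vec),
    mean_estimate = as.numeric(mean_est),
    sd_estimate = as.numeric(sd_obs),
    mean_se = as.numeric(mean_se),
    rel_bias = rel_bias,
    rel_se_bias = as.numeric((mean_se - sd_obs) / sd_obs),
    coverage = as.numeric(colMeans(hit[ok, , drop = FALSE])),
    row.names = NULL)
  structure(out, class = c("sim_metrics", "data.frame"),
            scenario = scenario, truths = truths,
            n_failed = failed, n_used = sum(ok))
}

#' Summarise a grid of scenarios
#'
#' Aggregates [run_scenario()] results the way the study's summary tables
#' do: per (sample size, skewness, method, estimand) cell, the 3rd quartile
#' of |relative bias of the estimates|, the 3rd quartile of |relative SE
#' bias| and the interquartile range of coverage, the within-cell variation
#' coming from the effect-size and cut-point grid.
#'
#' @param metrics A list of `"sim_metrics"` objects.
#' @param quantile_type Quantile rule passed to [stats::quantile()]
#'   (default 7, linear interpolation; 1 gives the nearest-order-statistic
#'   rule).
#' @return A data frame with one row per cell and columns
#'   `family`, `method`, `n_per_group`, `skewness`, `estimand`,
#'   `n_scenarios`, `q3_abs_rel_bias`, `q3_abs_rel_se_bias`,
#'   `coverage_q1`, `coverage_q3`, `coverage_iqr`.
#' @export
summarize_grid <- function(metrics, quantile_type = 7) {
  if (inherits(metrics, "sim_metrics")) metrics <- list(metrics)
  stopifnot(length(metrics) >= 1,
            all(vapply(metrics, inherits, logical(1), "sim_metrics")))
  rows <- do.call(rbind, lapply(metrics, function(m) {
    sc <- attr(m, "scenario")
    data.frame(family = sc$family, method = sc$method,
               n_per_group = sc$n_per_group, skewness = sc$skewness,
               estimand = m$estimand, rel_bias = m$rel_bias,
               rel_se_bias = m$rel_se_bias, coverage = m$coverage)
  }))
  q <- function(x, p) as.numeric(quantile(x, p, type = quantile_type,
                                          names = FALSE))
  cells <- split(rows, interaction(rows$family, rows$method,
                                   rows$n_per_group, rows$skewness,
                                   rows$estimand, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(cell) {
    data.frame(
      family = cell$family[1], method = cell$method[1],
      n_per_group = cell$n_per_group[1], skewness = cell$skewness[1],
      estimand = cell$estimand[1], n_scenarios = nrow(cell),
      q3_abs_rel_bias = q(abs(cell$rel_bias), 0.75),
      q3_abs_rel_se_bias = q(abs(cell$rel_se_bias), 0.75),
      coverage_q1 = q(cell$coverage, 0.25),
      coverage_q3 = q(cell$coverage, 0.75),
      coverage_iqr = q(cell$coverage, 0.75) - q(cell$coverage, 0.25))
  }))
  rownames(out) <- NULL
  out[order(out$family, out$method, out$n_per_group, out$skewness,
            out$estimand), , drop = FALSE]
}
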