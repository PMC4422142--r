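# Distributional estimators: proportions beyond a cut-point and their
# comparison (difference, risk ratio, odds ratio) with delta-method SEs.

#' Per-group summary statistics
#'
#' Container for one group's sample size, mean and SD on the analysis scale.
#' This is all the distributional method needs: the worked examples in the
#' package run entirely from published summary statistics.
#'
#' @param n Sample size (integer >= 2).
#' @param mean Sample mean (outcome units).
#' @param sd Sample standard deviation (outcome units, > 0).
#' @param label Group name.
#' @return An object of class `"group_summary"`.
#' @export
group_summary <- function(n, mean, sd, label = "group") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      n != round(n))
    stop("'n' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("'mean' must be a single finite number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("'sd' must be a single positive number", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 label = as.character(label)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %g, sd = %g\n", x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Cut-point specification
#'
#' A clinical cut-point together with the tail of interest: `"below"` reports
#' the proportion with outcome under the cut-point (e.g. birthweight
#' < 2500 g), `"above"` the complementary tail (e.g. SBP over 160 mmHg).
#'
#' @param x0 Cut-point (outcome units).
#' @param tail `"below"` or `"above"`.
#' @return An object of class `"threshold_spec"`.
#' @export
threshold_spec <- function(x0, tail = c("below", "above")) {
  tail <- match.arg(tail)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("'x0' must be a single finite number", call. = FALSE)
  structure(list(x0 = x0, tail = tail), class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold: %s %g\n", x$tail, x$x0))
  invisible(x)
}

#' Pooled standard deviation of two groups
#'
#' Degrees-of-freedom weighted pooling under an equal-variance assumption:
#' `sqrt(((n1 - 1) sd1^2 + (n2 - 1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return Pooled SD (outcome units).
#' @export
pooled_sd <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  df <- g1$n + g2$n - 2L
  if (df <= 0) stop("total sample size must exceed 2", call. = FALSE)
  sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df)
}

#' Two-group pooled distributional model
#'
#' Combines a reference and an exposed group under the assumption of equal
#' variance and (for the skew-normal method) equal skewness: both groups
#' share the pooled SD and a single shape `alpha`, and differ only in their
#' means. With `alpha = 0` this is the normal distributional method.
#'
#' @param reference,exposed [group_summary()] objects; the comparison is
#'   reported as exposed minus (or over) reference.
#' @param alpha Shared shape parameter; ignored (forced to 0) when
#'   `method = "normal"`.
#' @param method `"normal"` or `"skew_normal"`.
#' @param sd_pooled Shared SD; defaults to [pooled_sd()] of the two groups.
#'   Supply the jointly estimated SD when the shape was fitted from raw data.
#' @return An object of class `"pooled_model"`.
#' @export
pooled_model <- function(reference, exposed, alpha = 0,
                         method = c("normal", "skew_normal"),
                         sd_pooled = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(reference, "group_summary"),
            inherits(exposed, "group_summary"))
  if (identical(reference$label, exposed$label))
    stop("the two groups must have distinct labels", call. = FALSE)
  if (method == "normal") alpha <- 0
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite number", call. = FALSE)
  if (is.null(sd_pooled)) sd_pooled <- pooled_sd(reference, exposed)
  if (!is.numeric(sd_pooled) || sd_pooled <= 0 || !is.finite(sd_pooled))
    stop("'sd_pooled' must be positive and finite", call. = FALSE)
  structure(list(reference = reference, exposed = exposed,
                 sd_pooled = sd_pooled, alpha = alpha, method = method),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("pooled %s model (sd = %g, alpha = %g)\n",
              sub("_", "-", x$method), x$sd_pooled, x$alpha))
  print(x$reference)
  print(x$exposed)
  invisible(x)
}

#' Distributional estimate of a tail proportion
#'
#' Estimates the proportion of a group beyond the cut-point from the fitted
#' distribution (mean, pooled SD, shared shape) rather than by counting, with
#' the delta-method standard error `se^2 = (sd^2 / n) * p'(mean)^2` where
#' `p'` is [skewnorm_dp_dmean()]. The SE therefore reflects the sampling
#' variability of the group mean, which is what gives distributional
#' proportions the precision of the comparison of means.
#'
#' @param model A [pooled_model()].
#' @param group `"reference"`, `"exposed"`, or a [group_summary()].
#' @param threshold A [threshold_spec()].
#' @return An object of class `"proportion_estimate"`: list with `p`, `se`,
#'   `var`, `group`, `n`.
#' @export
distributional_proportion <- function(model, group, threshold) {
  stopifnot(inherits(model, "pooled_model"),
            inherits(threshold, "threshold_spec"))
  if (is.character(group)) group <- model[[match.arg(group, c("reference", "exposed"))]]
  stopifnot(inherits(group, "group_summary"))
  s <- model$sd_pooled
  z <- (threshold$x0 - group$mean) / s
  if (abs(z) > 10)
    stop("degenerate tail: the cut-point ", threshold$x0, " lies ",
         sprintf("%.1f", abs(z)), " pooled SDs from the mean of group '",
         group$label, "'; the distributional proportion is numerically 0 ",
         "or 1 and dichotomisation at this cut-point is not informative",
         call. = FALSE)
  p_below <- pskewnorm(threshold$x0, group$mean, s, model$alpha)
  p <- if (threshold$tail == "below") p_below else 1 - p_below
  dp <- skewnorm_dp_dmean(threshold$x0, group$mean, s, model$alpha)
  v <- (s^2 / group$n) * dp^2
  structure(list(p = p, se = sqrt(v), var = v,
                 group = group$label, n = group$n),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%s: p = %.4f (se %.4f)\n", x$group, x$p, x$se))
  invisible(x)
}

#' Distributional confidence interval
#'
#' Symmetric normal-quantile interval on the stated scale; `scale = "log"`
#' builds the interval for `log(point)` and back-transforms, which is how the
#' risk-ratio and odds-ratio intervals are constructed.
#'
#' @param point Point estimate.
#' @param se Standard error (on the `scale` scale).
#' @param level Confidence level in (0, 1).
#' @param scale `"identity"` or `"log"`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
dci <- function(point, se, level = 0.95, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(se) || any(se <= 0))
    stop("'se' must be positive", call. = FALSE)
  z <- qnorm((1 + level) / 2)
  if (scale == "identity") c(point - z * se, point + z * se)
  else exp(c(log(point) - z * se, log(point) + z * se))
}

#' Compare two groups' tail proportions distributionally
#'
#' Computes the distributional difference in proportions, risk ratio and odds
#' ratio between the exposed and reference groups of a [pooled_model()], with
#' delta-method standard errors and distributional confidence intervals
#' (DCIs). Writing `var_i` for the delta-method variance of group i's
#' proportion:
#' \itemize{
#'   \item `se(d)^2 = var_ref + var_exp`
#'   \item `se(log rr)^2 = var_ref / p_ref^2 + var_exp / p_exp^2`
#'   \item `se(log or)^2 = var_ref / (p_ref (1 - p_ref))^2 +
#'     var_exp / (p_exp (1 - p_exp))^2`
#' }
#' Ratio intervals are symmetric on the log scale and exponentiated. The
#' method is a large-sample approximation; standard normal quantiles are
#' used throughout.
#'
#' @param model A [pooled_model()].
#' @param threshold A [threshold_spec()].
#' @param level Confidence level, default 0.95.
#' @return An object of class `"dich_comparison"`.
#' @export
compare_groups <- function(model, threshold, level = 0.95) {
  stopifnot(inherits(model, "pooled_model"))
  ref <- distributional_proportion(model, "reference", threshold)
  exp_ <- distributional_proportion(model, "exposed", threshold)
  d <- exp_$p - ref$p
  se_d <- sqrt(ref$var + exp_$var)
  rr <- exp_$p / ref$p
  se_log_rr <- sqrt(ref$var / ref$p^2 + exp_$var / exp_$p^2)
  or <- (exp_$p / (1 - exp_$p)) / (ref$p / (1 - ref$p))
  se_log_or <- sqrt(ref$var / (ref$p * (1 - ref$p))^2 +
                      exp_$var / (exp_$p * (1 - exp_$p))^2)
  structure(list(
    d = d, se_d = se_d, ci_d = dci(d, se_d, level),
    rr = rr, se_log_rr = se_log_rr, ci_rr = dci(rr, se_log_rr, level, "log"),
    or = or, se_log_or = se_log_or, ci_or = dci(or, se_log_or, level, "log"),
    p_reference = ref, p_exposed = exp_,
    direction = sprintf("%s - %s", exp_$group, ref$group),
    threshold = threshold, method = model$method,
    alpha = model$alpha, sd_pooled = model$sd_pooled, level = level),
    class = "dich_comparison")
}

#' @export
print.dich_comparison <- function(x, digits = 3, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("Distributional comparison of proportions (%s method)\n",
              sub("_", "-", x$method)))
  cat(sprintf("  proportion %s %g, %s\n",
              x$threshold$tail, x$threshold$x0, x$direction))
  cat(sprintf("  p(%s) = %s (se %s), p(%s) = %s (se %s)\n",
              x$p_reference$group, fmt(x$p_reference$p), fmt(x$p_reference$se),
              x$p_exposed$group, fmt(x$p_exposed$p), fmt(x$p_exposed$se)))
  lvl <- sprintf("%g%% DCI", 100 * x$level)
  cat(sprintf("  difference  %s (%s) %s [%s, %s]\n", fmt(x$d), fmt(x$se_d),
              lvl, fmt(x$ci_d[1]), fmt(x$ci_d[2])))
  cat(sprintf("  risk ratio  %s (log-se %s) %s [%s, %s]\n", fmt(x$rr),
              fmt(x$se_log_rr), lvl, fmt(x$ci_rr[1]), fmt(x$ci_rr[2])))
  cat(sprintf("  odds ratio  %s (log-se %s) %s [%s, %s]\n", fmt(x$or),
              fmt(x$se_log_or), lvl, fmt(x$ci_or[1]), fmt(x$ci_or[2])))
  invisible(x)
}
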