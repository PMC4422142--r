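# Monotone transformations of outcomes with automatic mapping of the
# cut-point and tail direction. A proportion defined by a threshold is
# unchanged by a continuous strictly monotone transform: increasing
# transforms preserve the tail, decreasing transforms flip it (a lower-tail
# proportion on the original scale is an upper-tail proportion on, say, the
# inverse scale).

#' Monotone transformation specification
#'
#' Registered transforms:
#' \describe{
#'   \item{`identity`}{increasing, any values.}
#'   \item{`log`, `sqrt`, `square`}{increasing, positive values only
#'     (`square` is restricted to positive inputs so it is monotone).}
#'   \item{`inverse`}{`1/x`, positive values, decreasing.}
#'   \item{`negate`}{`-x`, decreasing.}
#'   \item{`reflect_log`}{`log(c - x)`, values strictly below the reflection
#'     point `c`, decreasing. Used for left-skewed outcomes bounded above,
#'     e.g. gestational age with the domain convention `c = 45` weeks.}
#' }
#'
#' @param name Transform name (see above).
#' @param c Reflection point, required for `reflect_log` (outcome units).
#' @return An object of class `"transform_spec"` with fields `name`,
#'   `direction` (`"increasing"`/`"decreasing"`), `fun`, `inv` and `c`.
#' @export
transform_spec <- function(name = c("identity", "log", "sqrt", "square",
                                    "inverse", "negate", "reflect_log"),
                           c = NULL) {
  name <- match.arg(name)
  if (name == "reflect_log") {
    if (is.null(c) || !is.numeric(c) || length(c) != 1L || !is.finite(c))
      stop("'reflect_log' requires a finite reflection point 'c'",
           call. = FALSE)
  } else if (!is.null(c)) {
    stop("'c' is only meaningful for the 'reflect_log' transform",
         call. = FALSE)
  }
  def <- switch(name,
    identity    = list(fun = function(x) x, inv = function(y) y,
                       direction = "increasing", domain = "any"),
    log         = list(fun = base::log, inv = base::exp,
                       direction = "increasing", domain = "positive"),
    sqrt        = list(fun = base::sqrt, inv = function(y) y^2,
                       direction = "increasing", domain = "positive"),
    square      = list(fun = function(x) x^2, inv = base::sqrt,
                       direction = "increasing", domain = "positive"),
    inverse     = list(fun = function(x) 1 / x, inv = function(y) 1 / y,
                       direction = "decreasing", domain = "positive"),
    negate      = list(fun = function(x) -x, inv = function(y) -y,
                       direction = "decreasing", domain = "any"),
    reflect_log = list(fun = function(x) base::log(c - x),
                       inv = function(y) c - base::exp(y),
                       direction = "decreasing", domain = "below_c"))
  structure(list(name = name, direction = def$direction, fun = def$fun,
                 inv = def$inv, domain = def$domain, c = c),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  extra <- if (x$name == "reflect_log") sprintf(" (c = %g)", x$c) else ""
  cat(sprintf("transform: %s%s, %s\n", x$name, extra, x$direction))
  invisible(x)
}

.check_transform_domain <- function(values, spec, what = "values") {
  bad <- switch(spec$domain,
                any = logical(length(values)),
                positive = values <= 0,
                below_c = values >= spec$c)
  bad <- bad | !is.finite(values)
  if (any(bad)) {
    offenders <- unique(values[bad])
    shown <- paste(utils::head(format(offenders, trim = TRUE), 5L),
                   collapse = ", ")
    req <- switch(spec$domain, any = "finite",
                  positive = "positive",
                  below_c = sprintf("strictly below c = %g", spec$c))
    stop(sprintf("the '%s' transform requires %s %s; offending value(s): %s",
                 spec$name, req, what, shown), call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply a monotone transform to outcome values
#'
#' @param values Numeric vector on the original scale.
#' @param spec A [transform_spec()].
#' @return Transformed values; order preserved for increasing transforms,
#'   reversed for decreasing ones.
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  .check_transform_domain(values, spec)
  spec$fun(values)
}

#' Map a cut-point through a monotone transform
#'
#' The transformed cut-point is the transform of the original one; the tail
#' direction is preserved by increasing transforms and flipped by decreasing
#' ones (e.g. obesity BMI > 30 becomes inverse-BMI < 1/30).
#'
#' @param threshold A [threshold_spec()] on the original scale.
#' @param spec A [transform_spec()].
#' @return A [threshold_spec()] on the transformed scale.
#' @export
map_threshold <- function(threshold, spec) {
  stopifnot(inherits(threshold, "threshold_spec"),
            inherits(spec, "transform_spec"))
  .check_transform_domain(threshold$x0, spec, what = "cut-point")
  tail <- threshold$tail
  if (spec$direction == "decreasing")
    tail <- if (tail == "below") "above" else "below"
  threshold_spec(spec$fun(threshold$x0), tail)
}

#' Check that a transform preserves the empirical tail proportion
#'
#' Counts observations strictly beyond the cut-point on the original scale
#' and strictly beyond the mapped cut-point on the transformed scale; for a
#' strictly monotone transform the two counts must be identical (values
#' exactly at the cut-point are outside the tail under the strict-inequality
#' convention on both scales). A mismatch signals a transform or tail-mapping
#' bug and raises an error.
#'
#' @param values Numeric vector on the original scale.
#' @param threshold A [threshold_spec()] on the original scale.
#' @param spec A [transform_spec()].
#' @return A list with `count_original`, `count_transformed`, `n`,
#'   `proportion` and the mapped threshold.
#' @export
preserve_proportion_check <- function(values, threshold, spec) {
  stopifnot(inherits(threshold, "threshold_spec"))
  .check_transform_domain(values, spec)
  beyond <- function(x, thr)
    if (thr$tail == "below") sum(x < thr$x0) else sum(x > thr$x0)
  mapped <- map_threshold(threshold, spec)
  n_orig <- beyond(values, threshold)
  n_trans <- beyond(spec$fun(values), mapped)
  if (n_orig != n_trans)
    stop(sprintf(
      "proportion not preserved under '%s': %d observation(s) beyond the original cut-point but %d beyond the mapped one",
      spec$name, n_orig, n_trans), call. = FALSE)
  list(count_original = n_orig, count_transformed = n_trans,
       n = length(values), proportion = n_orig / length(values),
       mapped_threshold = mapped)
}
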