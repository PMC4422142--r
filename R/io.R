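# File I/O, report rendering and the command-line interface.

#' Read raw two-group data from a CSV file
#'
#' Expects an RFC-4180 CSV with a group column and a numeric value column.
#' Rows with missing values are dropped and counted; exactly two groups must
#' remain.
#'
#' @param path Path to the CSV file.
#' @param group_col,value_col Column names (defaults `"group"`, `"value"`).
#' @return A named list of two numeric vectors (names = group labels), with
#'   attribute `"n_dropped"`.
#' @export
read_raw <- function(path, group_col = "group", value_col = "value") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c(group_col, value_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  vals <- df[[value_col]]
  if (!is.numeric(vals))
    stop("column '", value_col, "' must be numeric", call. = FALSE)
  keep <- is.finite(vals) & !is.na(df[[group_col]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " row(s) with missing values dropped", call. = FALSE)
  df <- df[keep, , drop = FALSE]
  groups <- split(df[[value_col]], df[[group_col]])
  if (length(groups) != 2L)
    stop("exactly two groups are required, found ", length(groups), ": ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("empty group after dropping missing values", call. = FALSE)
  structure(groups, n_dropped = n_dropped)
}

#' Build pooled-model inputs from per-group summary records
#'
#' The worked examples of the distributional method run entirely in summary
#' mode: per-group n, mean and SD (on the analysis scale), plus optionally a
#' shared shape parameter for the skew-normal method.
#'
#' @param records A data frame with columns `n`, `mean`, `sd` and optionally
#'   `label`, one row per group (reference first), or a list of two such
#'   records.
#' @param alpha Optional shared shape; defaults to 0 (normal method).
#' @return A [pooled_model()].
#' @export
read_summary <- function(records, alpha = 0) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (!is.data.frame(records) || nrow(records) != 2L)
    stop("'records' must describe exactly two groups", call. = FALSE)
  for (col in c("n", "mean", "sd"))
    if (!col %in% names(records))
      stop("summary records need column '", col, "'", call. = FALSE)
  labels <- if ("label" %in% names(records)) as.character(records$label)
            else c("reference", "exposed")
  g1 <- group_summary(records$n[1], records$mean[1], records$sd[1], labels[1])
  g2 <- group_summary(records$n[2], records$mean[2], records$sd[2], labels[2])
  method <- if (alpha == 0) "normal" else "skew_normal"
  pooled_model(g1, g2, alpha = alpha, method = method)
}

#' Render an analysis report
#'
#' Produces a deterministic machine-readable record (JSON) and a
#' human-readable text block for a completed comparison. The JSON payload
#' has a fixed field order, no timestamps, and carries the method, shape,
#' threshold (original and mapped), transform and package version alongside
#' every estimate, SE and interval.
#'
#' @param comparison A `"dich_comparison"` from [compare_groups()].
#' @param transform Optional [transform_spec()] used before analysis.
#' @param threshold_original Optional [threshold_spec()] on the original
#'   scale (before transformation).
#' @param file Optional path; when given the JSON record is written there.
#' @return Invisibly, a list with `record` (the report as a list), `json`
#'   (JSON string) and `text` (character vector of report lines).
#' @export
render_report <- function(comparison, transform = NULL,
                          threshold_original = NULL, file = NULL) {
  stopifnot(inherits(comparison, "dich_comparison"))
  x <- comparison
  record <- list(
    method = x$method,
    alpha = x$alpha,
    sd_pooled = x$sd_pooled,
    transform = if (is.null(transform)) "identity" else transform$name,
    threshold_original = if (is.null(threshold_original))
      list(x0 = x$threshold$x0, tail = x$threshold$tail)
    else list(x0 = threshold_original$x0, tail = threshold_original$tail),
    threshold_analysis = list(x0 = x$threshold$x0, tail = x$threshold$tail),
    direction = x$direction,
    level = x$level,
    groups = list(
      reference = list(label = x$p_reference$group, n = x$p_reference$n,
                       p = x$p_reference$p, se = x$p_reference$se),
      exposed = list(label = x$p_exposed$group, n = x$p_exposed$n,
                     p = x$p_exposed$p, se = x$p_exposed$se)),
    difference = list(estimate = x$d, se = x$se_d, ci = x$ci_d),
    risk_ratio = list(estimate = x$rr, se_log = x$se_log_rr, ci = x$ci_rr),
    odds_ratio = list(estimate = x$or, se_log = x$se_log_or, ci = x$ci_or),
    software = list(package = "dichodist",
                    version = as.character(packageVersion("dichodist"))))
  json <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(file)) writeLines(json, file)
  text <- utils::capture.output(print(x))
  invisible(list(record = record, json = as.character(json), text = text))
}

# ---------------------------------------------------------------------------
# Command-line interface. Subcommands: compare, fit, simulate, transforms.
# Thin wrapper intended for Rscript (see inst/scripts/dichodist.R); returns
# an exit status: 0 success, 2 validation error, 3 numerical failure.

.cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

.cli_summary_model <- function(flags) {
  parse_group <- function(s) {
    v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    if (length(v) != 3 || any(!is.finite(v)))
      stop("group summaries must be 'n,mean,sd'", call. = FALSE)
    v
  }
  g1 <- parse_group(flags$group1)
  g2 <- parse_group(flags$group2)
  labels <- if (!is.null(flags$labels))
    strsplit(flags$labels, ",", fixed = TRUE)[[1]]
  else c("reference", "exposed")
  alpha <- if (is.null(flags$alpha)) 0 else as.numeric(flags$alpha)
  read_summary(data.frame(n = c(g1[1], g2[1]), mean = c(g1[2], g2[2]),
                          sd = c(g1[3], g2[3]), label = labels),
               alpha = alpha)
}

.cli_compare <- function(flags) {
  if (is.null(flags$cutpoint)) stop("--cutpoint is required", call. = FALSE)
  tail <- if (is.null(flags$tail)) "below" else flags$tail
  thr <- threshold_spec(as.numeric(flags$cutpoint), tail)
  level <- if (is.null(flags$level)) 0.95 else as.numeric(flags$level)
  tspec <- NULL
  thr_orig <- NULL

  if (!is.null(flags$group1)) {
    model <- .cli_summary_model(flags)
  } else if (!is.null(flags$data)) {
    groups <- read_raw(flags$data,
                       group_col = if (is.null(flags[["group-col"]])) "group"
                                   else flags[["group-col"]],
                       value_col = if (is.null(flags[["value-col"]])) "value"
                                   else flags[["value-col"]])
    x1 <- groups[[1]]
    x2 <- groups[[2]]
    if (!is.null(flags$transform) && flags$transform != "identity") {
      tspec <- transform_spec(flags$transform,
                              c = if (is.null(flags[["transform-c"]])) NULL
                                  else as.numeric(flags[["transform-c"]]))
      thr_orig <- thr
      preserve_proportion_check(c(x1, x2), thr, tspec)
      x1 <- apply_transform(x1, tspec)
      x2 <- apply_transform(x2, tspec)
      thr <- map_threshold(thr, tspec)
      message("threshold mapped by '", tspec$name, "' transform to ",
              thr$tail, " ", format(thr$x0))
    }
    method <- if (is.null(flags$method)) "auto" else flags$method
    model <- build_pooled_model(x1, x2, method = method,
                                labels = names(groups))
  } else {
    stop("either --group1/--group2 (summary mode) or --data is required",
         call. = FALSE)
  }
  cmp <- compare_groups(model, thr, level = level)
  rep <- render_report(cmp, transform = tspec,
                       threshold_original = thr_orig,
                       file = flags$json)
  cat(rep$text, sep = "\n")
  0L
}

.cli_fit <- function(flags) {
  if (is.null(flags$data)) stop("--data is required", call. = FALSE)
  vcol <- if (is.null(flags[["value-col"]])) "value" else flags[["value-col"]]
  df <- read.csv(flags$data, stringsAsFactors = FALSE)
  if (!vcol %in% names(df))
    stop("column '", vcol, "' not found", call. = FALSE)
  fit <- fit_skew_normal(df[[vcol]])
  print(fit)
  guard <- method_guard(fit, n = fit$n_used,
                        n_min = if (is.null(flags[["n-min"]])) 50
                                else as.numeric(flags[["n-min"]]))
  cat("recommended method:", guard$method, "\n")
  0L
}

.cli_read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs; ",
           "use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

.cli_simulate <- function(flags) {
  if (is.null(flags$config)) stop("--config is required", call. = FALSE)
  cfg <- .cli_read_config(flags$config)
  if (!is.null(cfg$family)) cfg <- list(cfg) # single scenario at top level
  seed_override <- if (is.null(flags$seed)) NULL else as.integer(flags$seed)
  metrics <- lapply(cfg, function(sc) {
    if (!is.null(seed_override)) sc$seed <- seed_override
    run_scenario(do.call(sim_scenario, sc))
  })
  tidy <- do.call(rbind, lapply(metrics, function(m) {
    sc <- attr(m, "scenario")
    cbind(data.frame(family = sc$family, method = sc$method,
                     skewness = sc$skewness, n_per_group = sc$n_per_group,
                     effect_size = sc$effect_size,
                     cutpoint_prob = sc$cutpoint_prob,
                     replicates = sc$replicates, seed = sc$seed),
          as.data.frame(m))
  }))
  if (!is.null(flags$out)) {
    write.csv(tidy, flags$out, row.names = FALSE)
    message("results written to ", flags$out)
  } else {
    print(tidy)
  }
  if (isTRUE(flags$summary) || is.character(flags$summary)) {
    summ <- summarize_grid(metrics)
    if (is.character(flags$summary)) {
      write.csv(summ, flags$summary, row.names = FALSE)
      message("summary written to ", flags$summary)
    } else print(summ)
  }
  0L
}

.cli_transforms <- function(flags) {
  info <- data.frame(
    name = c("identity", "log", "sqrt", "square", "inverse", "negate",
             "reflect_log"),
    direction = c("increasing", "increasing", "increasing", "increasing",
                  "decreasing", "decreasing", "decreasing"),
    domain = c("any", "x > 0", "x > 0", "x > 0", "x > 0", "any", "x < c"))
  print(info, row.names = FALSE)
  0L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `compare` (summary or raw-CSV mode, with
#' optional transform), `fit` (skew-normal fit plus method recommendation),
#' `simulate` (scenario grids from a JSON/YAML config) and `transforms`
#' (list registered transforms). Designed to be called from the
#' `inst/scripts/dichodist.R` wrapper; results go to stdout/files, log
#' messages to stderr.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 success, 2 validation error,
#'   3 numerical failure.
#' @export
dich_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dichodist <compare|fit|simulate|transforms> [flags]",
    "  compare --group1 n,mean,sd --group2 n,mean,sd [--labels a,b]",
    "          [--alpha a] --cutpoint x0 [--tail below|above]",
    "          [--level 0.95] [--json out.json]",
    "  compare --data file.csv [--group-col g] [--value-col v]",
    "          [--method auto|normal|skew_normal]",
    "          [--transform name] [--transform-c c] --cutpoint x0 ...",
    "  fit --data file.csv [--value-col v] [--n-min 50]",
    "  simulate --config scenarios.json [--seed s] [--out results.csv]",
    "           [--summary [summary.csv]]",
    "  transforms", sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- tryCatch({
    flags <- .cli_parse_flags(args[-1])
    switch(cmd,
           compare = .cli_compare(flags),
           fit = .cli_fit(flags),
           simulate = .cli_simulate(flags),
           transforms = .cli_transforms(flags),
           { message("unknown subcommand: ", cmd, "\n", usage); 2L })
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("quadrature|converge|degenerate|numerical",
              conditionMessage(e))) 3L else 2L
  })
  invisible(as.integer(status))
}
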