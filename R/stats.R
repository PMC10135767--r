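#' Build a group sample
#'
#' A labelled vector of one transient feature (seconds or dimensionless)
#' for one experimental condition.  A warning is raised when fewer than
#' `min_events` values are supplied, mirroring the assay's collection rule
#' of at least 15 typical calcium signaling events per group.
#'
#' @param condition condition label (e.g. ligand µg/mL, shear dyn/cm²,
#'   treatment).
#' @param values numeric vector of finite feature values.
#' @param min_events collection-rule threshold for the warning (default 15).
#' @return A list of class `group_sample`: `condition`, `values`, `n`.
#' @export
group_sample <- function(condition, values, min_events = 15) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop_caflow("`values` must be finite", "caflow_parameter_error")
  }
  if (length(values) < min_events) {
    warning(sprintf("group '%s' has %d events; fewer than the %d-event collection rule",
                    condition, length(values), min_events), call. = FALSE)
  }
  structure(list(condition = as.character(condition), values = values,
                 n = length(values)),
            class = "group_sample")
}

#' @noRd
as_group_sample <- function(x, label = "group") {
  if (inherits(x, "group_sample")) return(x)
  suppressWarnings(group_sample(label, x))
}

#' Two-group comparison (Student's t-test)
#'
#' Two-sample t-test between two groups, pooled-variance Student form by
#' default (`var_equal = TRUE`), Welch available.  Two degenerate groups
#' (zero variance in both) with equal means are reported as `p = 1` with a
#' flag instead of an error.
#'
#' @param a,b [group_sample()] objects (or bare numeric vectors).
#' @param var_equal pooled-variance Student form when `TRUE` (default).
#' @return A list of class `stat_result`: `test`, `statistic`, `p_value`,
#'   `stars`, `df`, `groups`, `degenerate`.
#' @export
compare_two <- function(a, b, var_equal = TRUE) {
  a <- as_group_sample(a, "a"); b <- as_group_sample(b, "b")
  if (a$n < 2 || b$n < 2) {
    stop_caflow("both groups need n >= 2", "caflow_parameter_error")
  }
  degenerate <- stats::var(a$values) == 0 && stats::var(b$values) == 0
  if (degenerate) {
    same <- mean(a$values) == mean(b$values)
    res <- list(test = if (var_equal) "Student t" else "Welch t",
                statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df = a$n + b$n - 2,
                groups = c(a$condition, b$condition),
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(a$values, b$values, var.equal = var_equal)
    res <- list(test = if (var_equal) "Student t" else "Welch t",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter),
                groups = c(a$condition, b$condition), degenerate = FALSE)
  }
  res$stars <- p_stars(res$p_value)
  structure(res, class = "stat_result")
}

#' Multi-group comparison (one-way ANOVA + Tukey's HSD)
#'
#' One-way analysis of variance across three or more groups, followed by
#' Tukey's honestly-significant-difference test (studentized-range
#' distribution) for all pairwise comparisons.
#'
#' @param groups list of [group_sample()] objects (>= 3).
#' @param alpha significance level used for the Tukey confidence level.
#' @return A list of class `stat_result`: `test`, `statistic` (F),
#'   `p_value` (omnibus), `stars`, `df`, `pairwise` (data.frame: `group_1`,
#'   `group_2`, `mean_diff`, `p_adj`, `stars`).
#' @export
compare_many <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop_caflow("`compare_many` needs at least 3 groups", "caflow_parameter_error")
  }
  groups <- lapply(groups, as_group_sample)
  small <- vapply(groups, function(g) g$n < 2, logical(1))
  if (any(small)) {
    stop_caflow(sprintf("group(s) with n < 2: %s",
                        paste(vapply(groups[small], `[[`, character(1), "condition"),
                              collapse = ", ")),
                "caflow_parameter_error")
  }
  labs <- vapply(groups, `[[`, character(1), "condition")
  if (anyDuplicated(labs)) {
    stop_caflow("condition labels must be unique", "caflow_parameter_error")
  }
  df <- data.frame(
    value = unlist(lapply(groups, `[[`, "values")),
    condition = factor(rep(labs, vapply(groups, `[[`, numeric(1), "n")),
                       levels = labs))
  fit <- stats::aov(value ~ condition, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$condition
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group_1 = pairs[, 1], group_2 = pairs[, 2],
                         mean_diff = unname(tk[, "diff"]),
                         p_adj = unname(tk[, "p adj"]))
  pairwise$stars <- p_stars(pairwise$p_adj)
  structure(list(test = "one-way ANOVA + Tukey HSD",
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 stars = p_stars(an[["Pr(>F)"]][1]),
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 pairwise = pairwise),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.3g (%s)\n",
              x$test, x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Boxplot five-number summary with mean and SEM
#'
#' The five horizontal lines of the assay's boxplots (maximum, upper
#' quartile, median, lower quartile, minimum) plus mean and standard error
#' of the mean.  Quartiles use linear interpolation between order
#' statistics (the `stats::quantile()` type-7 rule); this convention is
#' fixed and documented because boxplot quartile rules vary between tools.
#'
#' @param group a [group_sample()] (or bare numeric vector), `n >= 1`.
#' @return A one-row data.frame: `condition`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`, `sem`, `degenerate` (`TRUE` when `n = 1`, where
#'   the SEM is reported as 0 by convention).
#' @export
summarize_group <- function(group) {
  g <- as_group_sample(group)
  if (g$n < 1) stop_caflow("empty group", "caflow_parameter_error")
  q <- stats::quantile(g$values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  sem <- if (g$n > 1) stats::sd(g$values) / sqrt(g$n) else 0
  data.frame(condition = g$condition, n = g$n,
             min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             mean = mean(g$values), sem = sem, degenerate = g$n == 1)
}

#' Feature-wise group statistics for a features table
#'
#' Applies [compare_two()] (2 conditions) or [compare_many()] (3 or more)
#' and [summarize_group()] to each requested feature of a per-cell features
#' table, using activated cells only (the transient characteristics are
#' defined only for activated cells).
#'
#' @param features data.frame from [quantify_traces()] (needs a `condition`
#'   column).
#' @param features_to_test character vector among `"T_D_s"`, `"T_P_s"`,
#'   `"I_P"`.
#' @param var_equal,alpha passed to the tests.
#' @param min_events collection-rule threshold for the per-group warning.
#' @return A list: `tests` (data.frame: `feature`, `test`, `statistic`,
#'   `p_value`, `stars`), `pairwise` (Tukey table per feature, when
#'   applicable), `summaries` (five-number + mean/SEM per feature and
#'   condition).
#' @export
group_statistics <- function(features, features_to_test = c("T_D_s", "T_P_s", "I_P"),
                             var_equal = TRUE, alpha = 0.05, min_events = 15) {
  if (!"condition" %in% names(features)) {
    stop_caflow("`features` must have a condition column", "caflow_parameter_error")
  }
  act <- features[features$activated & !features$qc_fail, , drop = FALSE]
  conds <- unique(features$condition)
  tests <- list(); pairwise <- list(); summaries <- list()
  for (feat in features_to_test) {
    gs <- lapply(conds, function(cc) {
      v <- act[[feat]][act$condition == cc]
      suppressWarnings(group_sample(cc, v[is.finite(v)], min_events = min_events))
    })
    ns <- vapply(gs, `[[`, numeric(1), "n")
    if (any(ns < min_events)) {
      warning(sprintf("feature %s: group(s) below the %d-event collection rule: %s",
                      feat, min_events,
                      paste(conds[ns < min_events], collapse = ", ")),
              call. = FALSE)
    }
    summaries[[feat]] <- do.call(rbind, lapply(gs, summarize_group))
    summaries[[feat]]$feature <- feat
    res <- if (length(conds) == 2L) {
      compare_two(gs[[1]], gs[[2]], var_equal = var_equal)
    } else {
      compare_many(gs, alpha = alpha)
    }
    tests[[feat]] <- data.frame(feature = feat, test = res$test,
                                statistic = res$statistic,
                                p_value = res$p_value, stars = res$stars)
    if (!is.null(res$pairwise)) {
      pw <- res$pairwise; pw$feature <- feat
      pairwise[[feat]] <- pw
    }
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       pairwise = if (length(pairwise)) do.call(rbind, c(pairwise, list(make.row.names = FALSE))) else NULL,
       summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))))
}
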