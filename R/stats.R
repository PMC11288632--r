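#' Grouped samples for a statistical comparison
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 1
#'   observation).
#' @param metric_name,units Optional labels carried into reports.
#' @return A list of class `grouped_samples`.
#' @export
grouped_samples <- function(groups, metric_name = NA_character_,
                            units = NA_character_) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 1L))
    stop("every group needs at least one observation")
  if (!all(vapply(groups, is.numeric, logical(1))))
    stop("groups must be numeric")
  structure(list(groups = lapply(groups, as.numeric),
                 metric_name = metric_name, units = units),
            class = "grouped_samples")
}

as_grouped <- function(x) {
  if (inherits(x, "grouped_samples")) return(x)
  if (is.list(x)) return(grouped_samples(x))
  stop("expected grouped_samples or a named list")
}

#' Normality gate: parametric or nonparametric branch
#'
#' Runs a Shapiro-Wilk test on every group; the comparison is parametric only
#' if every group passes at `alpha`. Groups too small for the test (n < 3) or
#' with zero variance force the nonparametric branch.
#'
#' @param groups A [grouped_samples()] or named list.
#' @param alpha Gate significance level, default 0.05.
#' @return `"parametric"` or `"nonparametric"`, with attribute `p_values`
#'   (per-group Shapiro-Wilk p, `NA` where untestable).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  g <- as_grouped(groups)$groups
  p <- vapply(g, function(x) {
    if (length(x) < 3L || length(x) > 5000L || stats::var(x) == 0)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  branch <- if (anyNA(p) || any(p <= alpha)) "nonparametric" else "parametric"
  structure(branch, p_values = p)
}

new_test_result <- function(test_name, statistic, p_value, gate = NA,
                            alpha = 0.05, note = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), normality_gate_used = gate,
                 alpha = alpha, note = note),
            class = "meioquant_test")
}

#' @export
print.meioquant_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n", x$test_name,
              x$statistic, x$p_value, significance_stars(x$p_value)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Significance stars
#'
#' Star coding used in figure legends: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Normality-gated group comparison
#'
#' Dispatches the comparison the way the analysis workflow prescribes: the
#' Shapiro-Wilk gate chooses between the parametric and nonparametric
#' families, then the group count chooses the test — Welch's t-test (two
#' groups) or Welch's ANOVA (three or more) when parametric, Mann-Whitney or
#' Kruskal-Wallis when not. A zero-variance group in the parametric branch
#' falls back to the nonparametric branch with a warning. The Mann-Whitney
#' test is exact (two-sided p = min(1, 2 x one-sided), by enumeration) when
#' both groups have n <= 8 and there are no ties, otherwise the tie-corrected
#' normal approximation with continuity correction is used; Kruskal-Wallis
#' uses the tie-corrected chi-square approximation.
#'
#' @param groups A [grouped_samples()] or named list of numeric vectors.
#' @param gate Optional: force `"parametric"` or `"nonparametric"` instead of
#'   running the Shapiro-Wilk gate.
#' @param alpha Gate level (default 0.05).
#' @return A `meioquant_test` result.
#' @export
compare_groups <- function(groups, gate = NULL, alpha = 0.05) {
  gs <- as_grouped(groups)
  g <- gs$groups
  k <- length(g)
  if (is.null(gate)) gate <- normality_gate(gs, alpha)
  branch <- as.character(gate)
  if (branch == "parametric" &&
      any(vapply(g, stats::var, numeric(1)) == 0)) {
    warning("zero-variance group: falling back to nonparametric comparison")
    branch <- "nonparametric"
  }
  vals <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)))
  if (branch == "parametric") {
    if (k == 2L) {
      ht <- stats::t.test(g[[1]], g[[2]], var.equal = FALSE)
      res <- new_test_result("Welch's t-test", ht$statistic, ht$p.value,
                             gate = branch, alpha = alpha)
    } else {
      ht <- stats::oneway.test(vals ~ fac, var.equal = FALSE)
      res <- new_test_result("Welch's ANOVA", ht$statistic, ht$p.value,
                             gate = branch, alpha = alpha)
    }
  } else {
    if (k == 2L) {
      exact <- length(g[[1]]) <= 8L && length(g[[2]]) <= 8L &&
        !any(duplicated(vals))
      ht <- suppressWarnings(
        stats::wilcox.test(g[[1]], g[[2]], exact = exact, correct = TRUE))
      res <- new_test_result(
        paste0("Mann-Whitney", if (exact) " (exact)" else " (normal approx.)"),
        ht$statistic, ht$p.value, gate = branch, alpha = alpha)
    } else {
      ht <- stats::kruskal.test(vals, fac)
      res <- new_test_result("Kruskal-Wallis", ht$statistic, ht$p.value,
                             gate = branch, alpha = alpha)
    }
  }
  res
}

#' Brown-Forsythe test for equality of variances
#'
#' One-way ANOVA on the absolute deviations from group medians. Constant
#' (zero-spread) groups yield statistic 0 and p = 1.
#'
#' @param groups A [grouped_samples()] or named list (>= 2 groups, each
#'   n >= 2).
#' @return A `meioquant_test` result.
#' @export
brown_forsythe <- function(groups) {
  g <- as_grouped(groups)$groups
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  dev <- unlist(lapply(g, function(x) abs(x - stats::median(x))),
                use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)))
  if (all(dev == 0))
    return(new_test_result("Brown-Forsythe", 0, 1))
  fit <- stats::anova(stats::lm(dev ~ fac))
  new_test_result("Brown-Forsythe", fit$`F value`[1], fit$`Pr(>F)`[1])
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p by the probability-mass method (sum of hypergeometric
#' probabilities not exceeding the observed table's); the one-sided p for
#' enrichment of the top-left cell is reported alongside.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return A `meioquant_test` result with extra elements `p_one_sided` and
#'   `table`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("input error: need a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("input error: counts must be non-negative integers")
  if (sum(tab) == 0L) stop("input error: empty table")
  two <- stats::fisher.test(tab, alternative = "two.sided")
  one <- stats::fisher.test(tab, alternative = "greater")
  res <- new_test_result("Fisher's exact", two$estimate %||% NA_real_,
                         two$p.value)
  res$p_one_sided <- one$p.value
  res$table <- tab
  res
}

#' Tabular report for a set of group comparisons
#'
#' Runs [compare_groups()] (and optionally [brown_forsythe()]) on each metric
#' and assembles a plain data frame suitable for writing as TSV.
#'
#' @param metrics Named list; each element a named list of group samples.
#' @param brown_forsythe_too Also report the Brown-Forsythe test per metric.
#' @return Data frame: metric, test, statistic, p_value, stars, gate.
#' @export
stats_report <- function(metrics, brown_forsythe_too = FALSE) {
  rows <- lapply(names(metrics), function(m) {
    res <- compare_groups(metrics[[m]])
    out <- data.frame(metric = m, test = res$test_name,
                      statistic = res$statistic, p_value = res$p_value,
                      stars = significance_stars(res$p_value),
                      gate = as.character(res$normality_gate_used))
    if (brown_forsythe_too) {
      bf <- brown_forsythe(metrics[[m]])
      out <- rbind(out, data.frame(metric = m, test = bf$test_name,
                                   statistic = bf$statistic,
                                   p_value = bf$p_value,
                                   stars = significance_stars(bf$p_value),
                                   gate = NA_character_))
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
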