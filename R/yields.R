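# Per-lane sequence-yield arithmetic and significance testing.

#' Construct a yield table
#'
#' Per-lane sequence yields grouped by library condition (e.g. number of
#' initially biased sequences).
#'
#' @param group group labels (character or factor).
#' @param experiment experiment labels within group.
#' @param yield sequence yields (non-negative integers).
#' @return A data.frame of class `"yield_table"`.
#' @export
yield_table <- function(group, experiment, yield) {
  if (any(yield < 0) || any(yield != floor(yield))) {
    stop("yields must be non-negative integers", call. = FALSE)
  }
  structure(data.frame(group = as.character(group),
                       experiment = as.character(experiment),
                       yield = as.numeric(yield),
                       stringsAsFactors = FALSE),
            class = c("yield_table", "data.frame"))
}

#' Read a yield table from TSV
#'
#' Expects columns `group`, `experiment`, `yield`.
#'
#' @param path TSV file.
#' @return A [yield_table()].
#' @export
read_yield_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("group", "experiment", "yield") %in% names(d))) {
    stop("yield table needs columns group, experiment, yield", call. = FALSE)
  }
  yield_table(d$group, d$experiment, d$yield)
}

#' Example per-lane yield tables
#'
#' Two bundled example tables of per-lane sequence yields:
#' `"ibs_groups"` — nine lanes in three groups with 0, 1 or 2 initially
#' biased sequences (IBS), for group-mean and percent-of-baseline
#' arithmetic and ANOVA; `"scs_vs_bareback"` — five paired lanes (2-IBS
#' and 4-IBS libraries) processed with both standard real-time analysis
#' (SCS) and deferred cluster calling (bareback), with the counts of
#' reads containing an expected barcode under each processing route.
#'
#' @param which `"ibs_groups"` or `"scs_vs_bareback"`.
#' @return `"ibs_groups"`: a [yield_table()]. `"scs_vs_bareback"`: a
#'   data.frame with columns `library`, `lane`, `scs_yield`,
#'   `bareback_yield`, `scs_barcoded`, `bareback_barcoded`.
#' @export
#' @examples
#' example_yield_table("ibs_groups")
example_yield_table <- function(which = c("ibs_groups", "scs_vs_bareback")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".tsv"), package = "lowdiv",
                      mustWork = TRUE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (which == "ibs_groups") yield_table(d$group, d$experiment, d$yield) else d
}

#' Group means and percent-of-baseline for a yield table
#'
#' For each group: the arithmetic mean yield, half-up rounded to the
#' nearest integer, and the group mean as a percentage of the baseline
#' group's mean, half-up rounded to the nearest integer — the arithmetic
#' conventionally printed in per-lane yield tables.
#'
#' @param table a [yield_table()].
#' @param baseline_group label of the baseline group (its percentage
#'   is 100).
#' @return A data.frame with columns `group`, `n`, `mean_yield`
#'   (rounded integer), `pct_of_baseline` (rounded integer), ordered with
#'   the baseline first.
#' @export
#' @examples
#' tab <- example_yield_table("ibs_groups")
#' yield_report(tab, baseline_group = "0 IBS")
yield_report <- function(table, baseline_group) {
  stopifnot(inherits(table, "yield_table"))
  if (!baseline_group %in% table$group) {
    stop(sprintf("baseline group '%s' not present", baseline_group), call. = FALSE)
  }
  groups <- unique(table$group)
  groups <- c(baseline_group, setdiff(groups, baseline_group))
  means <- vapply(groups, function(g) {
    y <- table$yield[table$group == g]
    if (length(y) == 0L) stop(sprintf("group '%s' is empty", g), call. = FALSE)
    mean(y)
  }, numeric(1))
  if (means[[1L]] == 0) stop("baseline group mean is zero", call. = FALSE)
  data.frame(group = groups,
             n = vapply(groups, function(g) sum(table$group == g), integer(1)),
             mean_yield = round_half_up(means),
             pct_of_baseline = round_half_up(100 * means / means[[1L]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent increase between paired yields
#'
#' `100 * (to - from) / from`, half-up rounded to one decimal — the
#' per-lane gain of deferred cluster calling over standard processing.
#'
#' @param from,to numeric vectors of yields (recycled pairwise).
#' @return Percent increases, one decimal.
#' @export
#' @examples
#' percent_increase(12291694, 21125492)  # 71.9
percent_increase <- function(from, to) {
  if (any(from <= 0)) stop("'from' yields must be positive", call. = FALSE)
  round_half_up(100 * (to - from) / from, 1)
}

#' Percentage of reads containing an expected barcode
#'
#' `100 * barcoded / total`, half-up rounded to one decimal.
#'
#' @param barcoded,total read counts.
#' @return Percentages, one decimal.
#' @export
#' @examples
#' barcode_percentage(11647935, 12291694)  # 94.8
barcode_percentage <- function(barcoded, total) {
  if (any(total <= 0)) stop("'total' must be positive", call. = FALSE)
  round_half_up(100 * barcoded / total, 1)
}

#' One-way ANOVA with Bonferroni post-hoc tests on yield groups
#'
#' Fixed-effects one-way analysis of variance of per-lane yields across
#' groups, followed by pairwise two-sided t tests using the pooled
#' within-group variance, Bonferroni-adjusted (p values multiplied by the
#' number of comparisons and capped at 1). Assumes approximately normal
#' yields with uniform between-group variability.
#'
#' @param table a [yield_table()] with at least 2 groups of at least 2
#'   observations each.
#' @return A list of class `"yield_anova"`: `F` statistic, `df` (between,
#'   within), `p_value`, `pairwise` (matrix of Bonferroni-adjusted p
#'   values), and the underlying `aov` fit.
#' @export
#' @examples
#' anova_yields(example_yield_table("ibs_groups"))
anova_yields <- function(table) {
  stopifnot(inherits(table, "yield_table"))
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g) < 2L)) stop("every group needs at least two observations",
                                  call. = FALSE)
  within_var <- vapply(levels(g), function(lv) stats::var(table$yield[g == lv]),
                       numeric(1))
  if (all(within_var == 0)) {
    stop("degenerate table: zero within-group variance everywhere", call. = FALSE)
  }
  fit <- aov(yield ~ group, data = data.frame(yield = table$yield, group = g))
  tab <- anova(fit)
  pw <- pairwise.t.test(table$yield, g, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)
  structure(
    list(F = tab[["F value"]][1L],
         df = c(between = tab[["Df"]][1L], within = tab[["Df"]][2L]),
         p_value = tab[["Pr(>F)"]][1L],
         pairwise = pw$p.value,
         fit = fit),
    class = "yield_anova"
  )
}

#' @export
print.yield_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p_value))
  cat("Bonferroni-adjusted pairwise p values:\n")
  print(signif(x$pairwise, 4))
  invisible(x)
}
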