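# Relative methylation levels. The denominator is the full locus count of
# the analysed set ("total markers"), so uninformative loci depress the
# other class percentages; the four class percentages always sum to 100.

#' Per-sample relative methylation levels
#'
#' Each class percentage is `100 * (class count) / (number of loci analysed)`.
#' The denominator is the total marker count of the analysed set (all loci,
#' or the given subset), not the count of informative loci, so the
#' methylation levels are relative and the four classes sum to 100.
#'
#' @param states character state matrix, loci x samples.
#' @param subset optional locus subset: character locus ids, or a logical or
#'   integer row index. Must be non-empty.
#' @return Data frame with one row per sample: `sample`, `hemi_pct`,
#'   `full_pct`, `non_pct`, `uninf_pct`, `methylated_pct`
#'   (`hemi_pct + full_pct`) and `denominator`.
#' @export
relative_levels <- function(states, subset = NULL) {
  states <- validate_state_matrix(states)
  if (!is.null(subset)) {
    if (is.character(subset)) {
      missing <- setdiff(subset, rownames(states))
      if (length(missing) > 0)
        msap_stop("unknown locus in subset: '%s'", missing[1])
    }
    states <- states[subset, , drop = FALSE]
  }
  if (nrow(states) == 0) msap_stop("empty locus subset")
  n <- nrow(states)
  pct <- function(tok) 100 * colSums(states == tok) / n
  hemi <- pct("HEMI"); full <- pct("FULL")
  data.frame(sample = colnames(states),
             hemi_pct = hemi, full_pct = full,
             non_pct = pct("NON"), uninf_pct = pct("UNINF"),
             methylated_pct = hemi + full,
             denominator = n, row.names = NULL)
}

#' Summarise level profiles across samples
#'
#' Per class: mean, min and max across samples together with the samples
#' attaining the extremes (ties broken by first occurrence).
#'
#' @param profiles data frame from [relative_levels()] (>= 1 row).
#' @return Data frame with one row per metric: `metric`, `mean`, `min`,
#'   `max`, `min_sample`, `max_sample`.
#' @export
summarize_levels <- function(profiles) {
  if (nrow(profiles) < 1) msap_stop("need at least one profile")
  metrics <- c("hemi_pct", "full_pct", "non_pct", "uninf_pct",
               "methylated_pct")
  rows <- lapply(metrics, function(m) {
    v <- profiles[[m]]
    data.frame(metric = m, mean = mean(v), min = min(v), max = max(v),
               min_sample = profiles$sample[which.min(v)],
               max_sample = profiles$sample[which.max(v)])
  })
  do.call(rbind, rows)
}

#' Combine per-class average levels into overall methylation summaries
#'
#' Given the across-sample average relative full- and hemi-methylation
#' levels, returns the total methylation level (their sum) and the average
#' relative methylation level (their mean), both on the 0-100 scale.
#'
#' @param full_pct,hemi_pct average relative levels in percent.
#' @return Data frame with `total_methylated_pct` and `mean_class_pct`.
#' @export
methylation_level_summary <- function(full_pct, hemi_pct) {
  data.frame(total_methylated_pct = full_pct + hemi_pct,
             mean_class_pct = (full_pct + hemi_pct) / 2)
}

# Two-sample t statistic with a defined degenerate branch: identical
# constant groups give t = 0, p = 1 (stats::t.test refuses constant data).
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    msap_stop("each group needs >= 2 values for a t-test (got %d and %d)",
              length(x), length(y))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
    return(list(t = sign(d) * Inf, p = 0, df = length(x) + length(y) - 2))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Compare a methylation level metric between two sample groups
#'
#' Two-sided two-sample t-test on the per-sample metric values. The default
#' is the classical equal-variance (Student) test; set `var_equal = FALSE`
#' for Welch. Both groups need at least two samples.
#'
#' @param profiles data frame from [relative_levels()].
#' @param groups named character vector mapping sample label -> group label;
#'   must define exactly two groups over the profiled samples
#'   (see [default_groups()]).
#' @param metric one of `"hemi_pct"`, `"full_pct"`, `"non_pct"`,
#'   `"methylated_pct"`, `"uninf_pct"`.
#' @param var_equal pool variances (default TRUE)?
#' @param alpha significance threshold; significance is also flagged at
#'   `alpha/5` (0.01 for the default 0.05).
#' @return List of class `group_comparison` with `metric`, `group_a`,
#'   `group_b`, `samples_a`, `samples_b`, `mean_a`, `mean_b`, `t_statistic`,
#'   `p_value`, `significant`, `significant_strict`.
#' @export
compare_groups <- function(profiles, groups, metric, var_equal = TRUE,
                           alpha = 0.05) {
  metrics <- c("hemi_pct", "full_pct", "non_pct", "methylated_pct",
               "uninf_pct")
  if (!metric %in% metrics)
    msap_stop("unknown metric '%s'", metric)
  missing <- setdiff(profiles$sample, names(groups))
  if (length(missing) > 0)
    msap_stop("sample '%s' has no group assignment", missing[1])
  g <- groups[profiles$sample]
  labels <- sort(unique(g))
  if (length(labels) != 2)
    msap_stop("need exactly two groups, got %d", length(labels))
  va <- profiles[[metric]][g == labels[1]]
  vb <- profiles[[metric]][g == labels[2]]
  res <- two_sample_t(va, vb, var_equal = var_equal)
  structure(list(metric = metric,
                 group_a = labels[1], group_b = labels[2],
                 samples_a = profiles$sample[g == labels[1]],
                 samples_b = profiles$sample[g == labels[2]],
                 mean_a = mean(va), mean_b = mean(vb),
                 t_statistic = res$t, p_value = res$p,
                 significant = res$p < alpha,
                 significant_strict = res$p < alpha / 5),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (mean %.3f) vs %s (mean %.3f): t = %.3f, p = %.4g%s\n",
              x$metric, x$group_a, x$mean_a, x$group_b, x$mean_b,
              x$t_statistic, x$p_value,
              if (x$significant_strict) " **" else if (x$significant) " *"
              else ""))
  invisible(x)
}
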