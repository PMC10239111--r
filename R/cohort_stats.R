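#' Quantile-based birth cohorts
#'
#' Splits samples into `n_cohorts` approximately equal strata using the
#' empirical cumulative distribution of birth year, at year granularity: all
#' samples sharing a birth year land in the same cohort (a year is never
#' split), so cohort sizes can differ by at most the largest single-year
#' count. Cohort `c` collects years whose CDF value falls in
#' `((c-1)/C, c/C]`.
#'
#' @param birth_years per-sample integer birth years (no missing values).
#' @param n_cohorts number of cohorts (default 5).
#' @return object of class `birth_cohorts`: per-sample cohort index `1..C`
#'   and the per-cohort year boundaries.
#' @export
assign_birth_cohorts <- function(birth_years, n_cohorts = 5L) {
  if (anyNA(birth_years)) stop("birth years must be non-missing")
  n_cohorts <- as.integer(n_cohorts)
  if (n_cohorts < 1L) stop("`n_cohorts` must be at least 1")
  if (length(unique(birth_years)) < n_cohorts) {
    stop("fewer distinct birth years (", length(unique(birth_years)),
         ") than cohorts (", n_cohorts, ")")
  }
  cdf <- stats::ecdf(birth_years)
  idx <- pmin(pmax(ceiling(cdf(birth_years) * n_cohorts), 1L), n_cohorts)
  bounds <- do.call(rbind, lapply(seq_len(n_cohorts), function(ci) {
    yrs <- birth_years[idx == ci]
    # heavy ties can leave a quantile stratum empty; reported as n = 0
    data.frame(cohort = ci,
               year_min = if (length(yrs)) min(yrs) else NA_integer_,
               year_max = if (length(yrs)) max(yrs) else NA_integer_,
               n = length(yrs))
  }))
  structure(list(cohort = idx, boundaries = bounds, n_cohorts = n_cohorts),
            class = "birth_cohorts")
}

#' @export
print.birth_cohorts <- function(x, ...) {
  cat("birth_cohorts:", x$n_cohorts, "cohorts over", length(x$cohort),
      "samples\n")
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (mean(x) - mean(y)) / s_pooled`, with
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#' Uses the pooled-SD (Cohen) form, not the small-sample Hedges correction.
#'
#' @param x,y numeric samples, each of size at least 2.
#' @return the effect size `d`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 observations")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop("zero pooled SD: effect size undefined")
  (mean(x) - mean(y)) / sp
}

#' Two-sided Z-test for a difference of estimates
#'
#' `Z = (est1 - est2) / sqrt(se1^2 + se2^2)`, `p = 2 * pnorm(-|Z|)`. Used to
#' compare LD score regression intercepts, attenuation ratios, or group
#' means between methods or cohorts.
#'
#' @param est1,se1 first estimate and its standard error (`se1 > 0`).
#' @param est2,se2 second estimate and its standard error (`se2 > 0`).
#' @return list with elements `z` and `p`.
#' @export
z_test_difference <- function(est1, se1, est2, se2) {
  if (any(c(se1, se2) <= 0)) stop("standard errors must be positive")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (at least 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1L) stop("`n_tests` must be at least 1")
  alpha / n_tests
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output preserves the input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values, same length and order as `pvals`.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# Truncate (toward zero) to one decimal, the printed convention for
# relative-change percentages (e.g. 31.37 -> 31.3).
.trunc1 <- function(x) trunc(x * 10) / 10

#' Cross-method assignment count summary
#'
#' Per-group sample counts under two assignment methods, the unclassified
#' counts and percentages, and the per-group relative change
#' `100 * (n2 - n1) / n1` (method 1 is the baseline), truncated to one
#' decimal as conventionally printed.
#'
#' @param a_baseline,a_alt two `ancestry_assignment` objects over the same
#'   samples (e.g. coarse-blended baseline vs panel method), or two
#'   data.frames with `sample_id` and `label` columns.
#' @return list with `counts` (data.frame: label, n_baseline, n_alt,
#'   rel_change_pct), `unclassified` (n and pct per method) and `total`.
#' @export
summarize_assignments <- function(a_baseline, a_alt) {
  lab <- function(a) {
    if (inherits(a, "ancestry_assignment")) a$assignments else a
  }
  t1 <- lab(a_baseline); t2 <- lab(a_alt)
  if (!setequal(t1$sample_id, t2$sample_id)) {
    stop("the two assignments cover different sample sets")
  }
  labs <- sort(unique(c(t1$label, t2$label)))
  n1 <- vapply(labs, function(l) sum(t1$label == l), integer(1))
  n2 <- vapply(labs, function(l) sum(t2$label == l), integer(1))
  rel <- ifelse(n1 > 0, .trunc1(100 * (n2 - n1) / n1), NA_real_)
  counts <- data.frame(label = labs, n_baseline = n1, n_alt = n2,
                       rel_change_pct = rel, row.names = NULL,
                       stringsAsFactors = FALSE)
  total <- nrow(t1)
  u1 <- sum(t1$label == "Unclassified"); u2 <- sum(t2$label == "Unclassified")
  list(counts = counts,
       unclassified = data.frame(
         method = c("baseline", "alt"), n = c(u1, u2),
         pct = 100 * c(u1, u2) / total, stringsAsFactors = FALSE),
       total = total)
}

#' Regress between-cohort trait change on ancestry-proportion change
#'
#' Ordinary least squares of the per-cohort-pair difference in trait means
#' on the per-cohort-pair difference in mean ancestry proportion, pooled
#' across within-group cohort pairs.
#'
#' @param d_trait per-pair trait mean differences (at least 3 pairs).
#' @param d_prop per-pair proportion mean differences, same length.
#' @return list with `slope`, `se`, `p` (two-sided) and the `lm` fit.
#' @export
regress_change_on_change <- function(d_trait, d_prop) {
  if (length(d_trait) != length(d_prop)) stop("inputs must have equal length")
  if (length(d_trait) < 3L) stop("at least 3 cohort pairs are required")
  if (stats::var(d_prop) == 0) stop("zero variance in the proportion changes")
  fit <- stats::lm(d_trait ~ d_prop)
  co <- summary(fit)$coefficients
  list(slope = co["d_prop", "Estimate"], se = co["d_prop", "Std. Error"],
       p = co["d_prop", "Pr(>|t|)"], fit = fit)
}

#' Pairwise cohort comparisons of a per-sample quantity
#'
#' For every group and every pair of cohorts, compares the group's values
#' between the two cohorts: difference in means, Cohen's d, a two-sided
#' Z-test on the means (SE taken as `sd / sqrt(n)` per cell), and
#' Benjamini-Hochberg q-values across all comparisons.
#'
#' @param values per-sample numeric values (e.g. an ancestry proportion or
#'   a trait).
#' @param groups per-sample group labels.
#' @param cohorts per-sample cohort indices.
#' @param alpha significance level for the `significant` flag after FDR
#'   (default 0.05).
#' @return data.frame: group, cohort_a, cohort_b, mean_a, mean_b, diff, d,
#'   z, p, q, significant.
#' @export
compare_across_cohorts <- function(values, groups, cohorts, alpha = 0.05) {
  stopifnot(length(values) == length(groups),
            length(values) == length(cohorts))
  rows <- list()
  for (grp in sort(unique(groups))) {
    cs <- sort(unique(cohorts[groups == grp]))
    if (length(cs) < 2L) next
    for (i in seq_len(length(cs) - 1L)) for (j in (i + 1L):length(cs)) {
      xa <- values[groups == grp & cohorts == cs[i]]
      xb <- values[groups == grp & cohorts == cs[j]]
      if (length(xa) < 2L || length(xb) < 2L) next
      zt <- z_test_difference(mean(xa), stats::sd(xa) / sqrt(length(xa)),
                              mean(xb), stats::sd(xb) / sqrt(length(xb)))
      d <- tryCatch(cohens_d(xa, xb), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, cohort_a = cs[i], cohort_b = cs[j],
        mean_a = mean(xa), mean_b = mean(xb), diff = mean(xa) - mean(xb),
        d = d, z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- fdr_adjust(out$p)
  out$significant <- out$q < alpha
  out
}
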