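#' Published MVP superpopulation sample sizes
#'
#' The published Million Veteran Program (release 4) per-superpopulation
#' sample sizes under the two assignment strategies: the coarse blended
#' self-identified-label method (HARE) and the high-resolution 1kGP + HGDP
#' reference-panel random-forest method. Groups the coarse method cannot
#' resolve (Central/South Asian, Middle Eastern) are `NA` in its column.
#' Used for count-summary arithmetic on real published data.
#'
#' @return data.frame with columns label, panel, coarse.
#' @export
mvp_assignment_counts <- function() {
  utils::read.delim(system.file("extdata", "mvp_assignment_counts.tsv",
                                package = "strataforge"),
                    stringsAsFactors = FALSE)
}

#' Count summary from a published count table
#'
#' The same derived quantities as [summarize_assignments()], computed from a
#' table of per-group counts rather than per-sample assignments: per-group
#' relative change `100 * (n_alt - n_baseline) / n_baseline` (truncated to
#' one printed decimal), unclassified percentages, and column totals.
#'
#' @param counts data.frame with columns `label` and two count columns.
#' @param baseline,alt names of the baseline and comparison count columns.
#' @return list with `counts` (label, n_baseline, n_alt, rel_change_pct),
#'   `unclassified` (n, pct per method) and `total` per method.
#' @export
summarize_count_table <- function(counts, baseline = "coarse", alt = "panel") {
  stopifnot(all(c("label", baseline, alt) %in% names(counts)))
  n1 <- counts[[baseline]]
  n2 <- counts[[alt]]
  rel <- ifelse(!is.na(n1) & n1 > 0, .trunc1(100 * (n2 - n1) / n1), NA_real_)
  tot1 <- sum(n1, na.rm = TRUE)
  tot2 <- sum(n2, na.rm = TRUE)
  u <- counts$label == "Unclassified"
  list(counts = data.frame(label = counts$label, n_baseline = n1, n_alt = n2,
                           rel_change_pct = rel, stringsAsFactors = FALSE),
       unclassified = data.frame(
         method = c("baseline", "alt"),
         n = c(n1[u], n2[u]),
         pct = c(100 * n1[u] / tot1, 100 * n2[u] / tot2),
         stringsAsFactors = FALSE),
       total = c(baseline = tot1, alt = tot2))
}
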