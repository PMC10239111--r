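#' LD score regression
#'
#' Fits `E[chi2_j] = intercept + (N h2 / M) * l_j` by two-step weighted least
#' squares: provisional weights `1 / max(l_j, 1)`, refined to
#' `1 / (2 * fitted_j^2 * max(l_j, 1))` using the provisional fit (the
#' heteroskedasticity weighting conventional for this regression). The
#' intercept captures confounding such as residual population
#' stratification; the slope gives the heritability estimate
#' `h2 = slope * M / N`. Standard errors come from a delete-a-block
#' jackknife over contiguous variant blocks.
#'
#' @param s a `gwas_sumstats` (or its `stats` data.frame).
#' @param l an `ld_scores` object (or a data.frame with `id` and `ldscore`),
#'   matched to the sumstats by variant ID.
#' @param n_blocks jackknife blocks (default 200); reduced to `floor(M/10)`
#'   with a warning when the variant count `M` is below `2 * n_blocks`.
#' @return object of class `ldsc_fit` with intercept, slope, h2, mean chi2,
#'   attenuation ratio, their jackknife SEs, and block metadata. The
#'   attenuation ratio is `NA` (with `ar_defined = FALSE`) when mean chi2
#'   does not exceed 1; h2 is reported even outside `[0, 1]`, flagged via
#'   `h2_out_of_range`.
#' @export
ldsc_regression <- function(s, l, n_blocks = 200L) {
  st <- if (inherits(s, "gwas_sumstats")) s$stats else s
  sc <- if (inherits(l, "ld_scores")) l$scores else l
  idx <- match(st$id, sc$id)
  if (anyNA(idx)) stop(sum(is.na(idx)), " sumstats variant(s) missing LD scores")
  ell <- sc$ldscore[idx]
  chi2 <- st$chisq
  M <- length(chi2)
  N <- stats::median(st$n)
  if (stats::var(ell) == 0) stop("zero variance in LD scores")
  if (n_blocks > M) stop("`n_blocks` exceeds the number of variants")
  if (M < 2L * n_blocks) {
    n_blocks <- max(2L, as.integer(floor(M / 10)))
    warning("few variants; jackknife blocks reduced to ", n_blocks)
  }
  w1 <- 1 / pmax(ell, 1)
  fit1 <- .wls(ell, chi2, w1)
  fitted <- pmax(fit1[1] + fit1[2] * ell, 0.1)
  w <- 1 / (2 * fitted^2 * pmax(ell, 1))
  block <- as.integer(cut(seq_len(M), breaks = n_blocks, labels = FALSE))
  # running WLS sums per block: full-fit and delete-a-block fits by subtraction
  sums <- function(sel) c(sum(w[sel]), sum(w[sel] * ell[sel]),
                          sum(w[sel] * ell[sel]^2), sum(w[sel] * chi2[sel]),
                          sum(w[sel] * ell[sel] * chi2[sel]),
                          sum(chi2[sel]), sum(sel))
  tot <- sums(rep(TRUE, M))
  bs <- vapply(seq_len(n_blocks), function(b) sums(block == b), numeric(7))
  est_from <- function(v) {
    # v = (sw, swx, swxx, swy, swxy, sy, n)
    det <- v[1] * v[3] - v[2]^2
    slope <- (v[1] * v[5] - v[2] * v[4]) / det
    int <- (v[4] - slope * v[2]) / v[1]
    mean_chi2 <- v[6] / v[7]
    h2 <- slope * M / N
    ar <- if (mean_chi2 > 1) (int - 1) / (mean_chi2 - 1) else NA_real_
    c(intercept = int, slope = slope, h2 = h2, mean_chi2 = mean_chi2, ar = ar)
  }
  full <- est_from(tot)
  jk <- vapply(seq_len(n_blocks), function(b) est_from(tot - bs[, b]),
               numeric(5))
  jk_se <- function(theta) {
    th <- theta[is.finite(theta)]
    B <- length(th)
    if (B < 2L) return(NA_real_)
    sqrt((B - 1) / B * sum((th - mean(th))^2))
  }
  ses <- apply(jk, 1L, jk_se)
  structure(
    list(intercept = unname(full["intercept"]), intercept_se = ses[1],
         slope = unname(full["slope"]), slope_se = ses[2],
         h2 = unname(full["h2"]), h2_se = ses[3],
         mean_chi2 = unname(full["mean_chi2"]),
         attenuation_ratio = unname(full["ar"]), ar_se = ses[5],
         ar_defined = is.finite(full["ar"]),
         h2_out_of_range = full["h2"] < 0 || full["h2"] > 1,
         n_blocks = n_blocks, M = M, N = N),
    class = "ldsc_fit"
  )
}

# Closed-form weighted least squares of y on (1, x).
.wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  c(intercept = (swy - slope * swx) / sw, slope = slope)
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("ldsc_fit (M =", x$M, ", N =", x$N, ",", x$n_blocks, "jackknife blocks)\n")
  cat(sprintf("  intercept = %.4f (%.4f)\n", x$intercept, x$intercept_se))
  cat(sprintf("  h2        = %.4f (%.4f)%s\n", x$h2, x$h2_se,
              if (isTRUE(x$h2_out_of_range)) "  [outside 0..1]" else ""))
  cat(sprintf("  mean chi2 = %.4f\n", x$mean_chi2))
  if (isTRUE(x$ar_defined)) {
    cat(sprintf("  attenuation ratio = %.4f (%.4f)\n", x$attenuation_ratio,
                x$ar_se))
  } else {
    cat("  attenuation ratio: not defined (mean chi2 <= 1)\n")
  }
  invisible(x)
}

#' @export
coef.ldsc_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.ldsc_fit <- function(object, ...) {
  data.frame(intercept = object$intercept, intercept_se = object$intercept_se,
             h2 = object$h2, h2_se = object$h2_se,
             mean_chi2 = object$mean_chi2,
             attenuation_ratio = object$attenuation_ratio,
             ar_se = object$ar_se, n_blocks = object$n_blocks,
             M = object$M, N = object$N)
}

#' Attenuation ratio
#'
#' `(intercept - 1) / (mean_chi2 - 1)`: the fraction of test-statistic
#' inflation not attributable to polygenicity. Not defined when the mean
#' chi-square does not exceed 1; returned as `NA` in that case, matching the
#' reporting convention of LD score regression software.
#'
#' @param intercept LD score regression intercept.
#' @param mean_chi2 mean association chi-square.
#' @return the ratio, or `NA` when `mean_chi2 <= 1`.
#' @export
attenuation_ratio <- function(intercept, mean_chi2) {
  if (mean_chi2 <= 1) return(NA_real_)
  (intercept - 1) / (mean_chi2 - 1)
}

#' Convert a list of LDSC fits to a table
#'
#' @param fits named list of `ldsc_fit` objects; names become the `cell`
#'   column (conventionally `"group.cohort"`).
#' @return data.frame, one row per fit.
#' @export
ldsc_fit_table <- function(fits) {
  stopifnot(length(fits) > 0L)
  out <- do.call(rbind, lapply(fits, summary))
  cbind(cell = names(fits), out, row.names = NULL)
}

#' Compare LDSC fits between two assignment methods
#'
#' Per (group x cohort) cell, two-sided Z-tests on the difference in
#' intercepts and (where defined) in attenuation ratios, with
#' Benjamini-Hochberg adjustment across cells per metric, plus the mean
#' intercept reduction (method 1 minus method 2) with its standard error
#' across cells.
#'
#' @param fits1,fits2 named lists of `ldsc_fit` objects with identical names
#'   (cells), e.g. from the coarse-blended and panel pipelines.
#' @return list with `table` (per-cell comparison rows) and
#'   `mean_intercept_reduction` (estimate, se).
#' @export
compare_methods <- function(fits1, fits2) {
  if (!setequal(names(fits1), names(fits2)) || is.null(names(fits1))) {
    stop("`fits1` and `fits2` must be named lists over the same cells")
  }
  cells <- names(fits1)
  rows <- lapply(cells, function(cl) {
    f1 <- fits1[[cl]]; f2 <- fits2[[cl]]
    zi <- z_test_difference(f1$intercept, f1$intercept_se,
                            f2$intercept, f2$intercept_se)
    ar_ok <- isTRUE(f1$ar_defined) && isTRUE(f2$ar_defined) &&
      is.finite(f1$ar_se) && is.finite(f2$ar_se) &&
      f1$ar_se > 0 && f2$ar_se > 0
    za <- if (ar_ok) {
      z_test_difference(f1$attenuation_ratio, f1$ar_se,
                        f2$attenuation_ratio, f2$ar_se)
    } else list(z = NA_real_, p = NA_real_)
    data.frame(cell = cl,
               intercept1 = f1$intercept, intercept2 = f2$intercept,
               intercept_diff = f1$intercept - f2$intercept,
               z_intercept = zi$z, p_intercept = zi$p,
               ar1 = f1$attenuation_ratio, ar2 = f2$attenuation_ratio,
               z_ar = za$z, p_ar = za$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_intercept <- fdr_adjust(tab$p_intercept)
  tab$q_ar <- NA_real_
  ok <- !is.na(tab$p_ar)
  if (any(ok)) tab$q_ar[ok] <- fdr_adjust(tab$p_ar[ok])
  red <- tab$intercept_diff
  list(table = tab,
       mean_intercept_reduction = c(
         estimate = mean(red),
         se = if (length(red) > 1L) stats::sd(red) / sqrt(length(red)) else NA_real_))
}
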