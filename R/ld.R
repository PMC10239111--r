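# Standardize dosage columns to zero mean / unit SD after mean imputation.
# Zero-variance columns become all-zero (they carry no LD information).
.std_cols <- function(X) {
  X <- .impute_mean(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  Xs <- sweep(X, 2L, mu, "-")
  pos <- sd > 0
  Xs[, pos] <- sweep(Xs[, pos, drop = FALSE], 2L, sd[pos], "/")
  Xs[, !pos] <- 0
  Xs
}

#' Greedy LD pruning
#'
#' Left-to-right scan over variants in position order: a variant is dropped
#' when its squared Pearson correlation with any previously *retained*
#' variant within `window_kb` upstream exceeds `r2_max`. The result is
#' deterministic given the input variant order.
#'
#' @param g a [genotype_matrix()].
#' @param r2_max squared-correlation threshold (default 0.01).
#' @param window_kb window size in kilobases (default 1500).
#' @return integer indices of the retained variants.
#' @export
ld_prune <- function(g, r2_max = 0.01, window_kb = 1500) {
  stopifnot(inherits(g, "genotype_matrix"))
  pos <- g$variants$pos
  J <- length(pos)
  if (J <= 1L) return(seq_len(J))
  Xs <- .std_cols(g$dosages)
  n <- nrow(Xs)
  win <- window_kb * 1000
  keep <- logical(J)
  chunk <- 512L
  for (s in seq(1L, J, by = chunk)) {
    e <- min(s + chunk - 1L, J)
    # first variant with pos >= pos[s] - win (positions are integers)
    lo <- findInterval(pos[s] - win - 0.5, pos) + 1L
    ctx <- lo:e
    R2 <- (crossprod(Xs[, ctx, drop = FALSE], Xs[, s:e, drop = FALSE]) /
             (n - 1))^2
    for (j in s:e) {
      jc <- j - s + 1L
      prev <- ctx[keep[ctx] & pos[ctx] >= pos[j] - win & ctx < j]
      keep[j] <- !length(prev) || max(R2[match(prev, ctx), jc]) <= r2_max
    }
  }
  which(keep)
}

#' LD scores with finite-sample adjustment
#'
#' For each variant `j`, `l_j` is the sum of adjusted squared correlations
#' `r2_adj = r2 - (1 - r2) / (n - 2)` with every variant within `window_kb`
#' (including itself, whose adjusted term is exactly 1). The adjustment makes
#' cross terms unbiased for zero under no LD. Scores are computed in-sample
#' on the supplied genotypes, normally the same group used for the
#' association scan.
#'
#' @param g a [genotype_matrix()] with at least 3 samples.
#' @param window_kb window size in kilobases (default 1000, the conventional
#'   ~1 cM scale).
#' @return object of class `ld_scores`: data.frame (id, pos, ldscore) plus
#'   window/n metadata.
#' @export
compute_ld_scores <- function(g, window_kb = 1000) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  if (n < 3L) stop("LD-score adjustment requires at least 3 samples")
  pos <- g$variants$pos
  J <- length(pos)
  Xs <- .std_cols(g$dosages)
  win <- window_kb * 1000
  ell <- numeric(J)
  chunk <- 512L
  for (s in seq(1L, J, by = chunk)) {
    e <- min(s + chunk - 1L, J)
    lo <- findInterval(pos[s] - win - 0.5, pos) + 1L
    hi <- findInterval(pos[e] + win, pos)
    ctx <- lo:hi
    R2 <- (crossprod(Xs[, ctx, drop = FALSE], Xs[, s:e, drop = FALSE]) /
             (n - 1))^2
    R2a <- R2 - (1 - R2) / (n - 2)
    inwin <- outer(pos[ctx], pos[s:e], function(a, b) abs(a - b) <= win)
    ell[s:e] <- colSums(R2a * inwin)
    # force the self term to exactly 1 (zero-variance columns have r = 0)
    self <- cbind(match(s:e, ctx), seq_len(e - s + 1L))
    ell[s:e] <- ell[s:e] - (R2a[self] - 1)
  }
  structure(list(scores = data.frame(id = g$variants$id, pos = pos,
                                     ldscore = ell, stringsAsFactors = FALSE),
                 window_kb = window_kb, n = n),
            class = "ld_scores")
}

#' @export
print.ld_scores <- function(x, ...) {
  cat("ld_scores:", nrow(x$scores), "variants; window", x$window_kb,
      "kb; LD reference n =", x$n, "\n")
  cat(sprintf("  mean l = %.3f (range %.3f..%.3f)\n", mean(x$scores$ldscore),
              min(x$scores$ldscore), max(x$scores$ldscore)))
  invisible(x)
}
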