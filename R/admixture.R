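#' Supervised admixture-proportion estimation by EM
#'
#' Estimates, for every sample independently, the simplex vector `q` of
#' ancestry proportions against *fixed* reference-population allele
#' frequencies `p_kj` by maximizing the binomial log-likelihood
#' `l(q) = sum_j [ g_j log(sum_k q_k p_kj) + (2 - g_j) log(1 - sum_k q_k p_kj) ]`
#' with the classic responsibility-weighted EM update
#' `q_k <- (1 / 2J) sum_j [ g_j r1_jk + (2 - g_j) r0_jk ]`, where `r1` and
#' `r0` are the posterior responsibilities of population `k` for the alt and
#' ref alleles. The update never decreases the log-likelihood. Iteration
#' starts at the uniform vector and stops when the per-sample log-likelihood
#' gain falls below `tol` (or at `max_iter`, with a warning flag). Missing
#' genotypes are dropped from a sample's likelihood.
#'
#' @param g a [genotype_matrix()].
#' @param ref_freqs variants x K matrix of reference allele frequencies;
#'   row names, when present, are matched against variant IDs (only shared
#'   variants are used). Frequencies are clipped to `[1e-6, 1 - 1e-6]`.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 2000); `0` returns the
#'   uniform initialization.
#' @return object of class `admixture_proportions`: `q` (samples x K),
#'   `loglik`, `iterations`, `converged` per sample, and the total
#'   log-likelihood trace across iterations.
#' @export
estimate_proportions <- function(g, ref_freqs, tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(g, "genotype_matrix"))
  ref_freqs <- as.matrix(ref_freqs)
  if (!is.null(rownames(ref_freqs))) {
    shared <- intersect(g$variants$id, rownames(ref_freqs))
    if (!length(shared)) stop("no variants shared between genotypes and `ref_freqs`")
    G <- g$dosages[, match(shared, g$variants$id), drop = FALSE]
    P <- ref_freqs[shared, , drop = FALSE]
  } else {
    if (nrow(ref_freqs) != ncol(g$dosages)) {
      stop("`ref_freqs` rows must match the genotype variants (or carry row names)")
    }
    G <- g$dosages
    P <- ref_freqs
  }
  K <- ncol(P)
  if (is.null(colnames(P))) colnames(P) <- paste0("POP", seq_len(K))
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  n <- nrow(G)
  W <- !is.na(G)              # per-entry observation indicator
  G0 <- ifelse(W, G, 0)
  Jn <- rowSums(W)            # non-missing variants per sample
  if (any(Jn == 0L)) stop("sample(s) with no observed genotypes")
  Q <- matrix(1 / K, n, K, dimnames = list(g$sample_ids, colnames(P)))
  loglik_of <- function(Q) {
    D1 <- Q %*% t(P)
    D0 <- Q %*% t(1 - P)
    rowSums(W * (G0 * log(D1) + (2 - G0) * log(D0)))
  }
  ll <- loglik_of(Q)
  trace <- sum(ll)
  iters <- 0L
  converged <- rep(max_iter == 0L, n)  # max_iter = 0: report initialization
  if (max_iter > 0L) {
    active <- rep(TRUE, n)
    converged <- rep(FALSE, n)
    for (it in seq_len(max_iter)) {
      ai <- which(active)
      Qa <- Q[ai, , drop = FALSE]
      D1 <- Qa %*% t(P)
      D0 <- Qa %*% t(1 - P)
      A1 <- W[ai, , drop = FALSE] * G0[ai, , drop = FALSE] / D1
      A0 <- W[ai, , drop = FALSE] * (2 - G0[ai, , drop = FALSE]) / D0
      Qn <- (Qa * (A1 %*% P + A0 %*% (1 - P))) / (2 * Jn[ai])
      Qn <- Qn / rowSums(Qn)  # guard roundoff; update sums to 1 analytically
      Q[ai, ] <- Qn
      ll_new <- ll
      ll_new[ai] <- rowSums(W[ai, , drop = FALSE] *
                              (G0[ai, , drop = FALSE] * log(Qn %*% t(P)) +
                               (2 - G0[ai, , drop = FALSE]) * log(Qn %*% t(1 - P))))
      done <- (ll_new[ai] - ll[ai]) < tol
      converged[ai[done]] <- TRUE
      active[ai[done]] <- FALSE
      ll <- ll_new
      trace <- c(trace, sum(ll))
      iters <- it
      if (!any(active)) break
    }
    if (any(!converged)) {
      warning(sum(!converged), " sample(s) did not converge in ", max_iter,
              " iterations")
    }
  }
  structure(list(q = Q, loglik = ll, iterations = iters,
                 converged = converged, loglik_trace = trace),
            class = "admixture_proportions")
}

#' @export
print.admixture_proportions <- function(x, ...) {
  cat("admixture_proportions:", nrow(x$q), "samples x", ncol(x$q),
      "reference populations;", x$iterations, "EM iterations\n")
  cat("  mean q:", paste(sprintf("%s=%.3f", colnames(x$q), colMeans(x$q)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Per-group mean ancestry proportions
#'
#' Means and SDs of the estimated proportions over the samples in each group
#' (optionally crossed with a cohort factor). Cells smaller than `min_cell`
#' are reported as suppressed (`NA` values, `suppressed = TRUE`), mirroring
#' the privacy floor common in large biobank reporting.
#'
#' @param q an `admixture_proportions` (or a samples x K matrix).
#' @param groups per-sample group labels.
#' @param cohorts optional per-sample cohort labels.
#' @param min_cell minimum reportable cell size (default 11).
#' @return data.frame with one row per (group, cohort, reference population):
#'   n, mean, sd, suppressed.
#' @export
group_mean_proportions <- function(q, groups, cohorts = NULL, min_cell = 11L) {
  Q <- if (inherits(q, "admixture_proportions")) q$q else as.matrix(q)
  if (length(groups) != nrow(Q)) stop("`groups` must have one label per sample")
  if (anyNA(groups)) stop("unknown (NA) group label")
  if (is.null(cohorts)) cohorts <- rep(1L, nrow(Q))
  cells <- unique(data.frame(group = groups, cohort = cohorts,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$group, cells$cohort), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- groups == cells$group[i] & cohorts == cells$cohort[i]
    n <- sum(sel)
    supp <- n < min_cell
    data.frame(group = cells$group[i], cohort = cells$cohort[i],
               pop = colnames(Q), n = n,
               mean = if (supp) NA_real_ else colMeans(Q[sel, , drop = FALSE]),
               sd = if (supp) NA_real_ else apply(Q[sel, , drop = FALSE], 2L, stats::sd),
               suppressed = supp, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Write an admixture-proportion table
#'
#' @param q an `admixture_proportions`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(q, path) {
  stopifnot(inherits(q, "admixture_proportions"))
  tab <- data.frame(sample_id = rownames(q$q),
                    as.data.frame(q$q, check.names = FALSE),
                    loglik = q$loglik, converged = q$converged,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
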