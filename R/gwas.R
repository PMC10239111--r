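#' Within-group covariate principal components
#'
#' Fresh PCA restricted to one group's members, on (typically LD-pruned)
#' variants, standardized by the group's own allele frequencies. Returns
#' scores for those members only; these are the per-group, per-method
#' covariate PCs of the association scan.
#'
#' @param g a [genotype_matrix()].
#' @param members sample selector (indices or sample IDs).
#' @param n_pcs number of PCs (default 10); the group must have at least
#'   `n_pcs + 2` members.
#' @param pruned optional variant indices to restrict to.
#' @return members x n_pcs score matrix (rownames = sample IDs).
#' @export
within_group_pcs <- function(g, members, n_pcs = 10L, pruned = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(members)) members <- match(members, g$sample_ids)
  if (anyNA(members)) stop("unknown sample IDs in `members`")
  if (length(members) < n_pcs + 2L) {
    stop("group of ", length(members), " is too small for ", n_pcs, " PCs")
  }
  vi <- if (is.null(pruned)) seq_len(nrow(g$variants)) else pruned
  X <- g$dosages[members, vi, drop = FALSE]
  rownames(X) <- g$sample_ids[members]
  .pca_scores(X, n_pcs)
}

#' Per-variant association scan with fixed covariates
#'
#' Ordinary least squares of the trait on each variant's alt-allele dosage
#' plus an intercept and the supplied covariates (conventionally age, sex
#' and 10 within-group PCs). Uses complete cases over trait and covariates;
#' missing genotypes are mean-imputed per variant; variants monomorphic in
#' the analysis sample are skipped and counted. The per-variant fit is
#' computed by residualizing trait and dosages on the covariates
#' (Frisch-Waugh-Lovell), which reproduces the full OLS coefficient, SE and
#' Wald test exactly.
#'
#' @param g a [genotype_matrix()].
#' @param trait per-sample numeric trait (aligned with `g` samples), or a
#'   data.frame from [simulate_phenotype()] (its `trait` column is used).
#' @param covariates data.frame or matrix of covariates aligned with the
#'   samples; `NULL` for an intercept-only model.
#' @return object of class `gwas_sumstats`: data.frame (id, chrom, pos, a1,
#'   a2, beta, se, p, chisq, n) with attributes `n_used`, `n_skipped`.
#' @export
run_gwas <- function(g, trait, covariates = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(trait)) trait <- trait$trait
  n_all <- nrow(g$dosages)
  if (length(trait) != n_all) stop("`trait` must align with the samples")
  C <- if (is.null(covariates)) {
    matrix(nrow = n_all, ncol = 0)
  } else as.matrix(covariates)
  cc <- stats::complete.cases(trait, C)
  if (sum(cc) < 50L) stop("fewer than 50 complete cases")
  y <- trait[cc]
  Cm <- cbind(`(Intercept)` = 1, C[cc, , drop = FALSE])
  qrC <- qr(Cm)
  if (qrC$rank < ncol(Cm)) {
    drop_cols <- colnames(Cm)[-seq_len(qrC$rank)]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(setdiff(colnames(Cm), colnames(Cm)[qrC$pivot[seq_len(qrC$rank)]]),
               collapse = ", "))
  }
  X <- .impute_mean(g$dosages[cc, , drop = FALSE])
  mono <- apply(X, 2L, stats::sd) == 0
  n <- length(y)
  df <- n - ncol(Cm) - 1L
  yr <- qr.resid(qrC, y)
  Xr <- qr.resid(qrC, X[, !mono, drop = FALSE])
  sxx <- colSums(Xr^2)
  sxy <- colSums(Xr * yr)
  syy <- sum(yr^2)
  beta <- sxy / sxx
  rss <- syy - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  v <- g$variants[!mono, , drop = FALSE]
  out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                    a1 = v$alt, a2 = v$ref,
                    beta = beta, se = se, p = p, chisq = tval^2, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(mono)) {
    message("run_gwas: skipped ", sum(mono), " monomorphic variant(s)")
  }
  structure(list(stats = out, n_used = n, n_skipped = sum(mono)),
            class = "gwas_sumstats")
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat("gwas_sumstats:", nrow(x$stats), "variants, N =", x$n_used,
      "(", x$n_skipped, "monomorphic skipped )\n")
  cat(sprintf("  mean chi^2 = %.3f; min p = %.3g\n", mean(x$stats$chisq),
              min(x$stats$p)))
  invisible(x)
}

#' Write / read association summary statistics
#'
#' Tab-delimited with columns SNP, CHR, POS, A1, A2, BETA, SE, P, CHISQ, N —
#' the layout expected by the LD score regression step and by standard
#' sumstats tooling.
#'
#' @param s a `gwas_sumstats`.
#' @param path TSV path.
#' @return `path` (writer) or a `gwas_sumstats` (reader).
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "gwas_sumstats"))
  tab <- s$stats
  names(tab) <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "P",
                  "CHISQ", "N")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "P", "CHISQ", "N")
  if (!all(need %in% names(tab))) {
    stop("malformed sumstats file (expected columns ",
         paste(need, collapse = ", "), "): ", path)
  }
  out <- data.frame(id = tab$SNP, chrom = as.character(tab$CHR), pos = tab$POS,
                    a1 = tab$A1, a2 = tab$A2, beta = tab$BETA, se = tab$SE,
                    p = tab$P, chisq = tab$CHISQ, n = tab$N,
                    stringsAsFactors = FALSE)
  structure(list(stats = out, n_used = stats::median(tab$N), n_skipped = NA),
            class = "gwas_sumstats")
}
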