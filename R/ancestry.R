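#' Reference-panel PCA model
#'
#' Fits a principal components model on the (optionally LD-pruned) reference
#' panel: dosages are mean-imputed, centered by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))` with `p_hat` the panel allele frequency,
#' then decomposed by SVD. Variants that are monomorphic in the panel are
#' excluded with a log entry. The sign of each PC is fixed so that its
#' largest-magnitude loading is positive, making runs comparable.
#'
#' @param panel a `reference_panel`, or a [genotype_matrix()].
#' @param n_pcs number of components to keep (default 20).
#' @param pruned optional integer indices of the variants to use (e.g. from
#'   [ld_prune()]); default all.
#' @return an object of class `pc_model` with the variant subset, centering
#'   and scale vectors, orthonormal loadings, per-PC explained variance, and
#'   the reference scores.
#' @export
fit_reference_pca <- function(panel, n_pcs = 20, pruned = NULL) {
  g <- if (inherits(panel, "reference_panel")) panel$genotypes else panel
  stopifnot(inherits(g, "genotype_matrix"))
  vi <- if (is.null(pruned)) seq_len(nrow(g$variants)) else pruned
  X <- .impute_mean(g$dosages[, vi, drop = FALSE])
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    message("fit_reference_pca: excluded ", sum(!poly),
            " monomorphic variant(s)")
    vi <- vi[poly]
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  n_pcs <- min(n_pcs, nrow(X) - 1L, ncol(X))
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  sv <- svd(Xs, nu = n_pcs, nv = n_pcs)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  for (k in seq_len(n_pcs)) {  # largest-|loading| positive sign convention
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- g$sample_ids
  structure(
    list(variant_ids = g$variants$id[vi],
         alleles = g$variants[vi, c("ref", "alt")],
         center = center, scale = scale, loadings = loadings,
         explained_variance = sv$d[seq_len(n_pcs)]^2 / (nrow(X) - 1),
         total_variance = sum(Xs^2) / (nrow(X) - 1),
         scores = scores, n_pcs = n_pcs),
    class = "pc_model"
  )
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", x$n_pcs, "PCs on", length(x$variant_ids), "variants\n")
  ev <- x$explained_variance / x$total_variance
  cat("  variance explained (top 5):",
      paste(sprintf("%.1f%%", 100 * utils::head(ev, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Project samples onto a fitted PC model
#'
#' Standardizes the samples with the *model's* panel-derived centering and
#' scale (no refitting) and multiplies by the loadings. Missing dosages are
#' treated as the panel mean (standardized zero). Errors if the model's
#' variants are absent or have mismatched alleles.
#'
#' @param model a `pc_model` from [fit_reference_pca()].
#' @param g a [genotype_matrix()] containing the model's variants.
#' @return samples x n_pcs score matrix.
#' @export
project_samples <- function(model, g) {
  stopifnot(inherits(model, "pc_model"), inherits(g, "genotype_matrix"))
  idx <- match(model$variant_ids, g$variants$id)
  if (anyNA(idx)) {
    miss <- model$variant_ids[is.na(idx)]
    stop("samples are missing ", length(miss), " model variant(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...")
  }
  al <- g$variants[idx, c("ref", "alt")]
  bad <- al$ref != model$alleles$ref | al$alt != model$alleles$alt
  if (any(bad)) {
    stop("allele mismatch between model and samples at ",
         paste(utils::head(model$variant_ids[bad], 5), collapse = ", "))
  }
  X <- g$dosages[, idx, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  Xs[is.na(Xs)] <- 0
  scores <- Xs %*% model$loadings
  rownames(scores) <- g$sample_ids
  scores
}

# Shared assembly + thresholding for the two assignment paths. A sample is
# Unclassified when its maximum class probability is <= prob_min (strict
# "greater than" rule) or, later, when flagged as a PC-space outlier.
.threshold_assignment <- function(prob, prob_min, method) {
  if (is.null(rownames(prob))) {
    rownames(prob) <- sprintf("sample%04d", seq_len(nrow(prob)))
  }
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  maxp <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
  lab[maxp <= prob_min] <- "Unclassified"
  structure(
    list(assignments = data.frame(sample_id = rownames(prob), label = lab,
                                  max_prob = maxp, outlier = FALSE,
                                  stringsAsFactors = FALSE),
         prob = prob, method = method, prob_min = prob_min),
    class = "ancestry_assignment"
  )
}

#' @export
print.ancestry_assignment <- function(x, ...) {
  cat("ancestry_assignment [", x$method, "]: ", nrow(x$assignments),
      " samples\n", sep = "")
  print(table(x$assignments$label))
  invisible(x)
}

#' @export
summary.ancestry_assignment <- function(object, ...) {
  tab <- table(object$assignments$label)
  data.frame(label = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / nrow(object$assignments),
             row.names = NULL)
}

#' Random-forest ancestry classification from PC scores
#'
#' Trains a random forest (default 500 trees, sqrt-of-features per split, no
#' depth limit) on the reference scores and labels, then predicts class
#' probabilities for the cohort samples. Samples whose maximum class
#' probability is not strictly greater than `prob_min` are `Unclassified`.
#'
#' @param ref_scores reference samples x PCs matrix (e.g. `model$scores`).
#' @param ref_labels reference population labels, one per reference sample;
#'   every class needs at least 2 members.
#' @param sample_scores cohort samples x PCs matrix from [project_samples()];
#'   must have the same number of PCs as `ref_scores`.
#' @param prob_min probability threshold (default 0.5, strict).
#' @param seed RNG seed fixing tree randomness.
#' @param ntree number of trees (default 500).
#' @return an object of class `ancestry_assignment` (method `"panel"`):
#'   per-sample label (or `Unclassified`), class probabilities, outlier flag.
#' @export
classify_ancestry <- function(ref_scores, ref_labels, sample_scores,
                              prob_min = 0.5, seed = 1L, ntree = 500L) {
  if (ncol(ref_scores) != ncol(sample_scores)) {
    stop("reference and sample scores must use the same number of PCs")
  }
  cls <- table(ref_labels)
  if (any(cls < 2L)) {
    stop("reference class(es) with < 2 members: ",
         paste(names(cls)[cls < 2L], collapse = ", "))
  }
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = as.data.frame(ref_scores), y = factor(ref_labels),
    ntree = ntree, mtry = max(1L, floor(sqrt(ncol(ref_scores)))))
  prob <- stats::predict(rf, as.data.frame(sample_scores), type = "prob")
  rownames(prob) <- rownames(sample_scores)
  .threshold_assignment(prob, prob_min, method = "panel")
}

# Internal PCA used for within-group score computation: standardizes by the
# group's own allele frequencies (2p, sqrt(2p(1-p))), monomorphic variants
# dropped, Gram-side eigendecomposition when variants outnumber samples.
.pca_scores <- function(X, n_pcs) {
  X <- .impute_mean(X)
  p <- colMeans(X) / 2
  poly <- p > 1e-9 & p < 1 - 1e-9
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Xs <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  n <- nrow(Xs)
  n_pcs <- min(n_pcs, n - 1L, ncol(Xs))
  if (ncol(Xs) > 1.5 * n) {
    ei <- eigen(tcrossprod(Xs), symmetric = TRUE)
    d <- sqrt(pmax(ei$values[seq_len(n_pcs)], 0))
    scores <- ei$vectors[, seq_len(n_pcs), drop = FALSE] %*% diag(d, n_pcs)
  } else {
    sv <- svd(Xs, nu = n_pcs, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  }
  # deterministic sign: largest-|score| coordinate positive
  for (k in seq_len(n_pcs)) {
    if (scores[which.max(abs(scores[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(X)
  scores
}

#' Refine assignments by within-group PC-space outlier removal
#'
#' Within each assigned group a fresh PCA (top `n_pcs`) is computed on that
#' group's members only; a member is flagged when, on any dimension, its
#' score is more than `n_mads` median absolute deviations from the group
#' median (unscaled MAD, no normal-consistency factor). Flagged members
#' become `Unclassified`. Dimensions with MAD 0 are skipped; groups smaller
#' than 3 are skipped with a warning. Applied as a single pass.
#'
#' @param a an `ancestry_assignment`.
#' @param g the [genotype_matrix()] of the assigned samples (typically the
#'   LD-pruned cohort genotypes).
#' @param n_pcs PCs per group (default 20).
#' @param n_mads flagging threshold (default 6).
#' @return the refined `ancestry_assignment` with updated outlier flags.
#' @export
refine_outliers <- function(a, g, n_pcs = 20, n_mads = 6) {
  stopifnot(inherits(a, "ancestry_assignment"), inherits(g, "genotype_matrix"))
  ids <- a$assignments$sample_id
  idx <- match(ids, g$sample_ids)
  if (anyNA(idx)) stop("assignment and genotype sample sets differ")
  for (grp in setdiff(unique(a$assignments$label), "Unclassified")) {
    mem <- which(a$assignments$label == grp)
    if (length(mem) < 3L) {
      warning("refine_outliers: group ", grp, " has < 3 members; skipped")
      next
    }
    sc <- .pca_scores(g$dosages[idx[mem], , drop = FALSE], n_pcs)
    flag <- rep(FALSE, length(mem))
    for (k in seq_len(ncol(sc))) {
      med <- stats::median(sc[, k])
      mad0 <- stats::median(abs(sc[, k] - med))
      if (mad0 > 0) flag <- flag | abs(sc[, k] - med) > n_mads * mad0
    }
    a$assignments$outlier[mem[flag]] <- TRUE
    a$assignments$label[mem[flag]] <- "Unclassified"
  }
  a
}

#' Coarse-label blended assignment (self-identified-label baseline)
#'
#' Emulates assignment schemes that harmonize a coarse self-identified label
#' with genetic ancestry. A random forest is trained to predict the *coarse*
#' label from the samples' genetic PC scores, using the samples whose coarse
#' label is non-missing. A sample's final label is then its coarse label,
#' when that agrees with the genetic prediction; the predicted label, when
#' the coarse label is missing and the prediction confidence exceeds
#' `prob_min`; and `Unclassified` otherwise (label/genetics discordance, or
#' missing label with low confidence). For labeled samples the genetic
#' prediction uses the forest's out-of-bag votes, so the forest cannot
#' simply reproduce a sample's own (possibly wrong) label.
#'
#' @param sample_scores cohort samples x PCs matrix.
#' @param coarse_labels per-sample coarse labels (`NA` = missing); at least
#'   90 percent must be non-missing.
#' @param prob_min confidence threshold for imputing missing labels
#'   (default 0.5, strict).
#' @param seed RNG seed.
#' @param ntree number of trees (default 500).
#' @return an `ancestry_assignment` (method `"coarse-blended"`).
#' @export
coarse_blended_assignment <- function(sample_scores, coarse_labels,
                                      prob_min = 0.5, seed = 1L,
                                      ntree = 500L) {
  ok <- !is.na(coarse_labels)
  if (!any(ok)) stop("all coarse labels are missing")
  if (mean(ok) < 0.9) {
    stop("coarse labels must be present for at least 90% of samples (",
         sprintf("%.1f%%", 100 * mean(ok)), " present)")
  }
  set.seed(seed)
  classes <- unique(coarse_labels[ok])
  if (length(classes) == 1L) {
    # degenerate single-class cohort: the genetic prediction is that class
    prob <- matrix(1, nrow(sample_scores), 1L,
                   dimnames = list(rownames(sample_scores), classes))
  } else {
    rf <- randomForest::randomForest(
      x = as.data.frame(sample_scores[ok, , drop = FALSE]),
      y = factor(coarse_labels[ok]),
      ntree = ntree, mtry = max(1L, floor(sqrt(ncol(sample_scores)))))
    # labeled samples get their out-of-bag votes so the forest cannot
    # simply memorize a sample's own (possibly wrong) label; unlabeled
    # samples get ordinary predictions
    prob <- matrix(0, nrow(sample_scores), ncol(rf$votes),
                   dimnames = list(rownames(sample_scores),
                                   colnames(rf$votes)))
    prob[ok, ] <- rf$votes
    if (any(!ok)) {
      prob[!ok, ] <- stats::predict(
        rf, as.data.frame(sample_scores[!ok, , drop = FALSE]), type = "prob")
    }
  }
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  maxp <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
  lab <- rep("Unclassified", nrow(prob))
  agree <- ok & coarse_labels == pred
  lab[agree] <- coarse_labels[agree]
  impute <- !ok & maxp > prob_min
  lab[impute] <- pred[impute]
  structure(
    list(assignments = data.frame(sample_id = rownames(prob), label = lab,
                                  max_prob = maxp, outlier = FALSE,
                                  stringsAsFactors = FALSE),
         prob = prob, method = "coarse-blended", prob_min = prob_min),
    class = "ancestry_assignment"
  )
}

#' Write an assignment table
#'
#' @param a an `ancestry_assignment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(a, path) {
  stopifnot(inherits(a, "ancestry_assignment"))
  tab <- cbind(a$assignments[, c("sample_id", "label", "max_prob", "outlier")],
               method = a$method,
               as.data.frame(a$prob, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
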