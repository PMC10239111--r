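# Replicated simulation studies quantifying the package's operating
# characteristics: null calibration of the LD score regression intercept,
# detection of stratification induced by merging diverged populations under
# a coarse label, and parameter recovery (admixture proportions,
# heritability, classifier accuracy). These are the experiments reported in
# the package documentation; each returns raw per-replicate results.

# Random LD-block sizes covering n_variants: mostly singletons with a tail
# of strong blocks, giving the right-skewed LD-score distribution real
# genomes show (and good leverage for the LD score regression).
.random_blocks <- function(n_variants, max_block = 20L, p_single = 0.7) {
  n_draw <- n_variants  # upper bound on the number of blocks
  sizes <- ifelse(stats::runif(n_draw) < p_single, 1L,
                  sample(2:max_block, n_draw, replace = TRUE))
  sizes <- sizes[cumsum(sizes) <= n_variants]
  rem <- n_variants - sum(sizes)
  if (rem > 0L) sizes <- c(sizes, rem)
  sizes
}

#' Null calibration of the LDSC intercept
#'
#' Simulates replicate single-population cohorts with no heritability and no
#' stratification (`h2 = 0`, no mean shifts, no population structure), runs
#' the full scan (QC, LD pruning, 10 within-group covariate PCs, per-variant
#' OLS, in-sample LD scores) and fits the LD score regression. Genotypes
#' carry block LD so that LD scores vary and the intercept is identified;
#' under the null the intercept should be 1.
#'
#' @param n_reps replicates (default 20).
#' @param n samples per replicate (default 2000).
#' @param n_variants variants per replicate (default 5000).
#' @param max_block largest LD-block size (default 20).
#' @param seed base RNG seed; replicate r uses `seed + r` offsets.
#' @return data.frame with one row per replicate: intercept, intercept_se,
#'   mean_chi2.
#' @export
sim_study_null_calibration <- function(n_reps = 20L, n = 2000L,
                                       n_variants = 5000L, max_block = 20L,
                                       seed = 1L) {
  res <- lapply(seq_len(n_reps), function(r) {
    s <- seed + 1000L * r
    set.seed(s)
    model <- population_model(n_variants, fst = 0,
                              blocks = .random_blocks(n_variants, max_block),
                              block_cor = 0.9, seed = s)
    panel <- simulate_reference_panel(model, n_per_pop = 30L, seed = s + 1L)
    spec <- cohort_spec(n_per_cohort = n,
                        admixture_priors = matrix(1, 1L, 1L),
                        birth_year_ranges = matrix(c(1940L, 1999L), 1L))
    cohort <- simulate_cohort(panel, spec, seed = s + 2L)
    pheno <- simulate_phenotype(cohort$genotypes, cohort$truth,
                                phenotype_spec(h2 = 0, n_causal = 0L),
                                metadata = cohort$metadata, seed = s + 3L)
    fit <- .scan_and_fit(cohort$genotypes, pheno, cohort$metadata,
                         ldsc_window_kb = 100)
    data.frame(rep = r, intercept = fit$intercept,
               intercept_se = fit$intercept_se, mean_chi2 = fit$mean_chi2)
  })
  do.call(rbind, res)
}

# QC -> prune -> within-group covariate PCs -> GWAS -> LD scores -> LDSC,
# for one analysis group. `members` defaults to all samples; `ld_ref`
# optionally supplies an external genotype matrix for the LD scores
# (default: in-sample from the analysis group).
.scan_and_fit <- function(g, pheno, metadata, members = NULL, n_pcs = 10L,
                          ldsc_window_kb = 1000, n_blocks = 200L,
                          ld_ref = NULL) {
  if (!is.null(members)) {
    g <- subset_genotypes(g, samples = members)
    pheno <- pheno[members, , drop = FALSE]
    metadata <- metadata[members, , drop = FALSE]
  }
  g <- suppressMessages(qc_filter(g))
  pruned <- ld_prune(g)
  pcs <- within_group_pcs(g, seq_along(g$sample_ids), n_pcs = n_pcs,
                          pruned = pruned)
  covars <- cbind(age = metadata$age, sex = metadata$sex, pcs)
  scan <- suppressMessages(run_gwas(g, pheno, covariates = covars))
  gl <- if (is.null(ld_ref)) g else {
    subset_genotypes(ld_ref, variants = match(g$variants$id,
                                              ld_ref$variants$id))
  }
  ell <- compute_ld_scores(gl, window_kb = ldsc_window_kb)
  suppressWarnings(ldsc_regression(scan, ell, n_blocks = n_blocks))
}

#' Stratification detection: merged vs fine ancestry groups
#'
#' The headline mechanism: two continental groups at between-group FST
#' `fst_between`, each a collection of `n_subpops` related populations
#' (within-group FST `fst_within`) with population-specific trait mean
#' shifts, are merged under one coarse label. The between-group trait gap is
#' exactly `trait_gap` SD; population shifts within each group jitter around
#' the group mean with SD `shift_jitter_sd` (centered, so the gap is
#' preserved). With `2 * n_subpops` populations the merged group's
#' structure has more axes than the 10 covariate PCs can absorb, while the
#' fine (single-group) analysis is fully corrected — the situation coarse
#' labels create when they merge genetically heterogeneous groups.
#'
#' Per replicate, the scan + LD score regression is run once on the merged
#' group and once on the fine group, each with its own 10 covariate PCs.
#' LD scores come from an external homogeneous reference cohort drawn from
#' one population, so that admixture LD in the merged group cannot leak the
#' stratification signal into the regression slope.
#'
#' @param n_reps replicates (default 10).
#' @param n_per_subpop samples per population (default 125).
#' @param n_subpops populations per continental group (default 10).
#' @param n_variants variants (default 5000).
#' @param fst_between between-group divergence (default 0.05).
#' @param fst_within within-group population divergence (default 0.02).
#' @param trait_gap between-group trait mean gap in SD units (default 0.5).
#' @param shift_jitter_sd SD of population-level trait-mean jitter within a
#'   group (default 0.25, conservative relative to observed between-population
#'   trait-mean differences within continents).
#' @param h2 trait heritability (default 0.2).
#' @param n_ld_ref external LD-reference samples (default 1000).
#' @param seed base RNG seed.
#' @return data.frame per replicate: intercept_merged, intercept_fine,
#'   merged_higher.
#' @export
sim_study_confounding <- function(n_reps = 10L, n_per_subpop = 125L,
                                  n_subpops = 10L, n_variants = 5000L,
                                  fst_between = 0.05, fst_within = 0.02,
                                  trait_gap = 0.5, shift_jitter_sd = 0.25,
                                  h2 = 0.2, n_ld_ref = 1000L, seed = 1L) {
  K <- 2L * n_subpops
  pops <- c(paste0("A", seq_len(n_subpops)), paste0("B", seq_len(n_subpops)))
  grp <- rep(c("A", "B"), each = n_subpops)
  res <- lapply(seq_len(n_reps), function(r) {
    s <- seed + 1000L * r
    set.seed(s)
    model <- population_model(
      n_variants, fst = stats::setNames(rep(fst_within, K), pops),
      blocks = .random_blocks(n_variants), block_cor = 0.9,
      groups = grp, group_fst = c(A = fst_between, B = fst_between),
      seed = s)
    panel <- simulate_reference_panel(model, n_per_pop = 20L, seed = s + 1L)
    # each population contributes one cohort slot of mostly-pure samples
    priors <- matrix(1 / (K - 1), K, K)
    diag(priors) <- 19
    spec <- cohort_spec(
      n_per_cohort = rep(n_per_subpop, K),
      admixture_priors = priors,
      birth_year_ranges = matrix(rep(c(1940L, 1999L), each = K), ncol = 2L),
      coarse_label_map = stats::setNames(rep("MERGED", K), pops),
      pops = pops)
    cohort <- simulate_cohort(panel, spec, seed = s + 2L)
    # population-specific shifts: +/- gap/2 by group, centered jitter within
    jitA <- stats::rnorm(n_subpops, 0, shift_jitter_sd)
    jitB <- stats::rnorm(n_subpops, 0, shift_jitter_sd)
    shift <- c(trait_gap / 2 + jitA - mean(jitA),
               -trait_gap / 2 + jitB - mean(jitB))
    pheno <- simulate_phenotype(
      cohort$genotypes, cohort$truth,
      phenotype_spec(h2 = h2, n_causal = 500L, strat_shift = shift),
      metadata = cohort$metadata, seed = s + 3L)
    # external homogeneous LD reference from the first population
    ldprior <- matrix(1e-3, 1L, K)
    ldprior[1L] <- 1e3
    ldspec <- cohort_spec(n_ld_ref, ldprior,
                          matrix(c(1940L, 1999L), 1L), pops = pops)
    ldref <- simulate_cohort(panel, ldspec, seed = s + 4L)$genotypes
    qa <- rowSums(cohort$truth[, grp == "A", drop = FALSE])
    merged_fit <- .scan_and_fit(cohort$genotypes, pheno, cohort$metadata,
                                ld_ref = ldref, ldsc_window_kb = 100)
    fine_fit <- .scan_and_fit(cohort$genotypes, pheno, cohort$metadata,
                              members = which(qa > 0.5), ld_ref = ldref,
                              ldsc_window_kb = 100)
    data.frame(rep = r, intercept_merged = merged_fit$intercept,
               intercept_fine = fine_fit$intercept,
               merged_higher = merged_fit$intercept > fine_fit$intercept)
  })
  do.call(rbind, res)
}

#' Admixture-proportion recovery of the supervised EM
#'
#' Fully admixed samples (uniform Dirichlet over K reference populations)
#' are estimated against the panel's realized reference frequencies; returns
#' the root-mean-square error against the generating proportions.
#'
#' @param n samples (default 500).
#' @param n_variants variants (default 5000).
#' @param K reference populations (default 5).
#' @param fst per-population divergence (default 0.1).
#' @param seed RNG seed.
#' @return list with `rmse` and the per-sample estimates/truth.
#' @export
sim_study_em_recovery <- function(n = 500L, n_variants = 5000L, K = 5L,
                                  fst = 0.1, seed = 1L) {
  model <- population_model(n_variants, fst = rep(fst, K), seed = seed)
  panel <- simulate_reference_panel(model, n_per_pop = 20L, seed = seed + 1L)
  spec <- cohort_spec(n_per_cohort = n,
                      admixture_priors = matrix(1, 1L, K),
                      birth_year_ranges = matrix(c(1940L, 1999L), 1L))
  cohort <- simulate_cohort(panel, spec, seed = seed + 2L)
  freqs <- panel$freqs
  rownames(freqs) <- panel$genotypes$variants$id
  est <- estimate_proportions(cohort$genotypes, freqs)
  rmse <- sqrt(mean((est$q - cohort$truth)^2))
  list(rmse = rmse, estimated = est$q, truth = cohort$truth)
}

#' Heritability recovery through LD score regression
#'
#' Single homogeneous population with block-LD variants (so LD scores vary
#' across the genome), a polygenic trait of heritability `h2`, and the full
#' scan; returns the per-replicate LDSC heritability estimates.
#'
#' @param n_reps replicates (default 20).
#' @param n samples (default 2000).
#' @param n_variants variants (default 5000).
#' @param h2 simulated heritability (default 0.5).
#' @param n_causal causal variants (default 500).
#' @param max_block largest LD-block size (default 20).
#' @param seed base RNG seed.
#' @return data.frame per replicate: h2_hat, intercept, mean_chi2.
#' @export
sim_study_h2_recovery <- function(n_reps = 20L, n = 2000L, n_variants = 5000L,
                                  h2 = 0.5, n_causal = 500L, max_block = 20L,
                                  seed = 1L) {
  res <- lapply(seq_len(n_reps), function(r) {
    s <- seed + 1000L * r
    set.seed(s)
    model <- population_model(n_variants, fst = 0,
                              blocks = .random_blocks(n_variants, max_block),
                              block_cor = 0.9, seed = s)
    panel <- simulate_reference_panel(model, n_per_pop = 30L, seed = s + 1L)
    spec <- cohort_spec(n_per_cohort = n,
                        admixture_priors = matrix(1, 1L, 1L),
                        birth_year_ranges = matrix(c(1940L, 1999L), 1L))
    cohort <- simulate_cohort(panel, spec, seed = s + 2L)
    pheno <- simulate_phenotype(cohort$genotypes, cohort$truth,
                                phenotype_spec(h2 = h2, n_causal = n_causal),
                                metadata = cohort$metadata, seed = s + 3L)
    fit <- .scan_and_fit(cohort$genotypes, pheno, cohort$metadata,
                         ldsc_window_kb = 100)
    data.frame(rep = r, h2_hat = fit$h2, intercept = fit$intercept,
               mean_chi2 = fit$mean_chi2)
  })
  do.call(rbind, res)
}

#' Classifier accuracy on a separated synthetic panel
#'
#' Reference-panel self-classification: PCA on the LD-pruned panel, then the
#' random-forest classifier applied back to the panel's own scores. On
#' well-separated populations (FST 0.1) accuracy should be essentially
#' perfect.
#'
#' @param K populations (default 3).
#' @param n_per_pop individuals per population (default 100).
#' @param n_variants variants (default 2000).
#' @param fst divergence (default 0.1).
#' @param n_pcs PCs (default 20).
#' @param seed RNG seed.
#' @return list with `accuracy` (fraction correct) and the assignment.
#' @export
sim_study_classifier_accuracy <- function(K = 3L, n_per_pop = 100L,
                                          n_variants = 2000L, fst = 0.1,
                                          n_pcs = 20L, seed = 1L) {
  model <- population_model(n_variants, fst = rep(fst, K), seed = seed)
  panel <- simulate_reference_panel(model, n_per_pop = n_per_pop,
                                    seed = seed + 1L)
  # the generator's variants are unlinked, so no pruning step is needed;
  # pruning a small *structured* panel at r2 = 0.01 would strip exactly
  # the differentiated variants the PCA needs
  pcm <- fit_reference_pca(panel, n_pcs = n_pcs)
  a <- classify_ancestry(pcm$scores, panel$labels, pcm$scores,
                         seed = seed + 2L)
  list(accuracy = mean(a$assignments$label == panel$labels), assignment = a)
}
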