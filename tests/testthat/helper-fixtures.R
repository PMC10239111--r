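# Small in-code fixtures shared across test files.

# Tiny two-population panel + admixed cohort, sized for fast unit tests.
tiny_study <- function(n_variants = 400, fst = c(A = 0.1, B = 0.1),
                       n_per_pop = 40, n_per_cohort = c(60, 60),
                       priors = rbind(c(10, 1), c(1, 10)),
                       coarse_map = NULL, label_noise = 0,
                       label_missing = 0, seed = 101) {
  model <- population_model(n_variants, fst = fst, seed = seed)
  panel <- simulate_reference_panel(model, n_per_pop, seed = seed + 1)
  spec <- cohort_spec(
    n_per_cohort = n_per_cohort, admixture_priors = priors,
    birth_year_ranges = matrix(rep(c(1930L, 1999L), each = length(n_per_cohort)),
                               ncol = 2L),
    coarse_label_map = coarse_map, label_noise = label_noise,
    label_missing = label_missing, pops = model$pops)
  cohort <- simulate_cohort(panel, spec, seed = seed + 2)
  list(model = model, panel = panel, spec = spec, cohort = cohort)
}

# Hand-rolled genotype matrix from a plain matrix.
gm_from <- function(mat, chrom = "1", spacing = 10000L) {
  J <- ncol(mat)
  genotype_matrix(
    mat,
    sample_ids = paste0("s", seq_len(nrow(mat))),
    variants = data.frame(id = paste0("v", seq_len(J)), chrom = chrom,
                          pos = seq_len(J) * spacing, ref = "A", alt = "G",
                          stringsAsFactors = FALSE))
}

# Hudson-style FST estimator (ratio of averages) between two populations,
# used as an independent moment check on the Balding-Nichols generator.
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2; n1 <- nrow(g1)
  p2 <- colMeans(g2) / 2; n2 <- nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Brute-force Benjamini-Hochberg step-up, an independent oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
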