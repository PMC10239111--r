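# Build a synthetic sumstats/ld-scores pair from explicit vectors.
fake_fit_inputs <- function(chi2, ell, n = 1000L) {
  M <- length(chi2)
  s <- structure(list(stats = data.frame(
    id = paste0("v", seq_len(M)), chrom = "1", pos = seq_len(M) * 1000,
    a1 = "G", a2 = "A", beta = sqrt(chi2 / n), se = sqrt(1 / n),
    p = pchisq(chi2, 1, lower.tail = FALSE), chisq = chi2, n = n,
    stringsAsFactors = FALSE), n_used = n, n_skipped = 0L),
    class = "gwas_sumstats")
  l <- structure(list(scores = data.frame(id = paste0("v", seq_len(M)),
                                          pos = seq_len(M) * 1000,
                                          ldscore = ell),
                      window_kb = 1000, n = n), class = "ld_scores")
  list(s = s, l = l)
}

test_that("exact linear chi2 recovers intercept and slope to 1e-8", {
  set.seed(31)
  ell <- runif(2000, 1, 60)
  chi2 <- 1.1 + 0.002 * ell
  fi <- fake_fit_inputs(chi2, ell)
  fit <- ldsc_regression(fi$s, fi$l, n_blocks = 100)
  expect_equal(fit$intercept, 1.1, tolerance = 1e-8)
  expect_equal(fit$slope, 0.002, tolerance = 1e-8)
  expect_equal(fit$h2, 0.002 * 2000 / 1000, tolerance = 1e-8)
  # noiseless fit: jackknife SE collapses to ~0
  expect_lt(fit$intercept_se, 1e-8)
})

test_that("jackknife SE is positive for noisy chi2 and fit flags behave", {
  set.seed(37)
  ell <- runif(3000, 1, 30)
  chi2 <- rchisq(3000, 1) * (1 + 0.05 * ell / 10)
  fi <- fake_fit_inputs(chi2, ell)
  fit <- ldsc_regression(fi$s, fi$l, n_blocks = 150)
  expect_gt(fit$intercept_se, 0)
  expect_gt(fit$h2_se, 0)
  expect_error(ldsc_regression(fi$s, fake_fit_inputs(chi2, rep(2, 3000))$l),
               "zero variance")
  expect_warning(ldsc_regression(fake_fit_inputs(chi2[1:300], ell[1:300])$s,
                                 fake_fit_inputs(chi2[1:300], ell[1:300])$l,
                                 n_blocks = 200),
                 "reduced")
})

test_that("attenuation ratio arithmetic and undefined case", {
  expect_equal(attenuation_ratio(1.05, 1.25), 0.2)
  expect_equal(attenuation_ratio(1.0, 1.7), 0)
  expect_equal(attenuation_ratio(1.3, 1.3), 1)
  expect_true(is.na(attenuation_ratio(1.1, 0.99)))
})

test_that("intercept is invariant to allele relabeling", {
  set.seed(41)
  st <- tiny_study(n_variants = 400, n_per_cohort = c(150, 150),
                   priors = rbind(c(5, 5), c(5, 5)), seed = 113)
  g <- st$cohort$genotypes
  ph <- simulate_phenotype(g, st$cohort$truth, phenotype_spec(0.3, 50),
                           metadata = st$cohort$metadata, seed = 117)
  scan <- suppressMessages(run_gwas(g, ph, NULL))
  ell <- compute_ld_scores(g)
  f1 <- suppressWarnings(ldsc_regression(scan, ell, n_blocks = 40))
  # relabel: flip dosages of half the variants; chi2 and r2 are unchanged
  g2 <- g
  flip <- seq(1, 400, by = 2)
  g2$dosages[, flip] <- 2 - g2$dosages[, flip]
  tmp <- g2$variants$ref[flip]
  g2$variants$ref[flip] <- g2$variants$alt[flip]
  g2$variants$alt[flip] <- tmp
  scan2 <- suppressMessages(run_gwas(g2, ph, NULL))
  ell2 <- compute_ld_scores(g2)
  f2 <- suppressWarnings(ldsc_regression(scan2, ell2, n_blocks = 40))
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-10)
})

test_that("compare_methods: identical fits give p = 1 and zero mean reduction", {
  set.seed(43)
  ell <- runif(1000, 1, 20)
  chi2 <- rchisq(1000, 1) + 0.01 * ell
  fi <- fake_fit_inputs(chi2, ell)
  fit <- suppressWarnings(ldsc_regression(fi$s, fi$l, n_blocks = 50))
  fits <- list(EUR.1 = fit, EUR.2 = fit)
  cm <- compare_methods(fits, fits)
  expect_true(all(cm$table$p_intercept == 1))
  expect_equal(unname(cm$mean_intercept_reduction["estimate"]), 0)
  expect_error(compare_methods(fits, fits[1]), "same cells")
})

test_that("Z-test on published-style intercept pairs matches hand arithmetic", {
  zt <- z_test_difference(1.10, 0.010, 1.05, 0.010)
  expect_equal(zt$z, 0.05 / sqrt(2e-4), tolerance = 1e-12)
  expect_equal(zt$p, 4.07e-4, tolerance = 1e-2)
})

test_that("ldsc_fit_table flattens fits with their cells", {
  set.seed(47)
  ell <- runif(600, 1, 20)
  fi <- fake_fit_inputs(rchisq(600, 1) + 0.02 * ell, ell)
  fit <- suppressWarnings(ldsc_regression(fi$s, fi$l, n_blocks = 30))
  tab <- ldsc_fit_table(list(A.1 = fit, B.1 = fit))
  expect_equal(tab$cell, c("A.1", "B.1"))
  expect_equal(tab$intercept[1], fit$intercept)
})

test_that("intercept responds monotonically to stratification and PCs reduce it", {
  # two merged populations, trait gap swept over three levels; small sizes
  # keep the directional check fast (10 replicates per level)
  levels <- c(0, 0.5, 1.5)
  int_nopc <- matrix(NA_real_, 10, length(levels))
  int_pc <- chi2_lab <- chi2_nopc <- numeric(10)
  for (r in 1:10) {
    s <- 3300 + 97 * r
    set.seed(s)
    model <- population_model(
      2000, fst = c(A = 0.05, B = 0.05),
      blocks = strataforge:::.random_blocks(2000), block_cor = 0.9, seed = s)
    panel <- simulate_reference_panel(model, 10, seed = s + 1)
    spec <- cohort_spec(c(300, 300), rbind(c(19, 1), c(1, 19)),
                        rbind(c(1940L, 1999L), c(1940L, 1999L)),
                        pops = model$pops)
    co <- simulate_cohort(panel, spec, seed = s + 2)
    g <- suppressMessages(qc_filter(co$genotypes))
    ell <- compute_ld_scores(g, window_kb = 100)
    meta <- co$metadata
    base_cov <- cbind(age = meta$age, sex = meta$sex)
    for (li in seq_along(levels)) {
      ph <- simulate_phenotype(
        g, co$truth,
        phenotype_spec(0, 0, strat_shift = c(levels[li] / 2, -levels[li] / 2)),
        metadata = meta, seed = s + 3)
      scan <- suppressMessages(run_gwas(g, ph, base_cov))
      int_nopc[r, li] <- suppressWarnings(
        ldsc_regression(scan, ell, 100))$intercept
      if (levels[li] == 0.5) {
        chi2_nopc[r] <- mean(scan$stats$chisq)
        pcs <- within_group_pcs(g, seq_along(g$sample_ids), 10)
        scan_pc <- suppressMessages(run_gwas(g, ph, cbind(base_cov, pcs)))
        int_pc[r] <- suppressWarnings(
          ldsc_regression(scan_pc, ell, 100))$intercept
        lab <- as.integer(co$truth[, 1] > 0.5)
        scan_lab <- suppressMessages(run_gwas(g, ph, cbind(base_cov, pop = lab)))
        chi2_lab[r] <- mean(scan_lab$stats$chisq)
      }
    }
  }
  means <- colMeans(int_nopc)
  expect_true(all(diff(means) >= 0))           # monotone confounding response
  expect_gt(means[2], means[1] + 0.2)          # and materially so
  expect_lt(mean(int_pc), means[2])            # PCs reduce the intercept
  expect_lt(mean(chi2_lab), mean(chi2_nopc))   # true label removes inflation
  expect_lt(abs(mean(chi2_lab) - 1), 0.1)
})
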