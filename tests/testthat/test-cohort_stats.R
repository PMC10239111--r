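test_that("birth cohorts split exact quantiles and never split a year", {
  yrs10 <- rep(1:10, each = 3)
  bc <- assign_birth_cohorts(yrs10, n_cohorts = 5)
  expect_equal(bc$cohort, rep(1:5, each = 6))
  expect_equal(bc$boundaries$year_min, c(1, 3, 5, 7, 9))
  expect_equal(bc$boundaries$year_max, c(2, 4, 6, 8, 10))
  # a mass of ties lands wholly in one cohort
  yrs <- c(rep(1950L, 80), 1951:1970)
  bc2 <- assign_birth_cohorts(yrs, n_cohorts = 4)
  expect_equal(length(unique(bc2$cohort[yrs == 1950L])), 1L)
  expect_error(assign_birth_cohorts(c(1950L, 1950L, 1951L), 3), "distinct")
  bc3 <- assign_birth_cohorts(yrs, n_cohorts = 1)
  expect_true(all(bc3$cohort == 1L))
})

test_that("cohort-size imbalance is bounded by the largest single-year count", {
  for (s in 1:8) {
    set.seed(s)
    yrs <- sample(1904:1999, 3000, replace = TRUE,
                  prob = dexp(seq(0, 3, length.out = 96)))
    bc <- assign_birth_cohorts(yrs, n_cohorts = 5)
    sizes <- tabulate(bc$cohort, 5)
    # year-granular boundaries: each cohort can gain/lose at most one whole
    # boundary year on each side, so the spread is bounded by two year-bins
    expect_lte(max(sizes) - min(sizes), 2 * max(table(yrs)))
    expect_lte(max(abs(sizes - length(yrs) / 5)), max(table(yrs)))
  }
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  x <- rnorm(20); y <- rnorm(25, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("Z-test reproduces the published intercept comparisons", {
  # EUR 1954-1963: printed intercepts 1.12 (0.017) vs 1.07 (0.016)
  zt <- z_test_difference(1.12, 0.017, 1.07, 0.016)
  expect_equal(zt$z, 2.1418, tolerance = 1e-4)
  expect_equal(zt$p, 0.032, tolerance = 0.01)
  # identical estimates; scaling property
  expect_equal(z_test_difference(1, 0.1, 1, 0.1)$p, 1)
  expect_equal(z_test_difference(1.3, 0.2, 1.1, 0.2)$z,
               2 * z_test_difference(1.3, 0.4, 1.1, 0.4)$z)
  expect_error(z_test_difference(1, 0, 1, 0.1), "positive")
})

test_that("Bonferroni threshold reproduces the 250-test design threshold", {
  expect_equal(bonferroni_threshold(0.05, 5 * 5 * 10), 2.0e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 250),
               bonferroni_threshold(0.05, 5 * 5 * 10))
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("BH q-values equal the brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.123), 0.123)
  for (s in 1:5) {
    set.seed(s)
    p <- runif(40)^2
    q <- fdr_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("assignment count summaries reproduce published arithmetic", {
  t1 <- data.frame(sample_id = as.character(1:40),
                   label = rep(c("EAS", "EUR"), c(10, 30)))
  t2 <- data.frame(sample_id = as.character(1:40),
                   label = rep(c("EAS", "EUR", "Unclassified"), c(13, 26, 1)))
  s <- summarize_assignments(t1, t2)
  expect_equal(s$counts$rel_change_pct[s$counts$label == "EAS"], 30.0)
  # 100 * (26 - 30) / 30 = -13.33, truncated toward zero
  expect_equal(s$counts$rel_change_pct[s$counts$label == "EUR"], -13.3)
  s2 <- summarize_assignments(t1, t1)
  expect_true(all(s2$counts$rel_change_pct == 0))
  expect_error(summarize_assignments(t1, t2[1:10, ]), "different")

  # published counts: 31.3% East Asian increase, 1.52% unclassified, totals
  pub <- summarize_count_table(mvp_assignment_counts())
  expect_equal(pub$counts$rel_change_pct[pub$counts$label == "East Asian"],
               31.3)
  expect_equal(round(pub$unclassified$pct[1], 2), 1.52)
  expect_equal(unname(pub$total), c(658582, 658582))
})

test_that("change-on-change regression recovers exact and null slopes", {
  dp <- c(0.01, -0.02, 0.03, 0.015, -0.01)
  r <- suppressWarnings(regress_change_on_change(2 * dp, dp))  # exact fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)
  # permutation null: slope centered at zero across shuffles
  set.seed(99)
  dtr <- rnorm(12)
  dpr <- rnorm(12, sd = 0.02)
  slopes <- replicate(200, regress_change_on_change(dtr, sample(dpr))$slope)
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(200) * 3 + 1e-9)
  expect_error(regress_change_on_change(c(1, 2), c(1, 2)), "3 cohort pairs")
  expect_error(regress_change_on_change(dtr, rep(1, 12)), "zero variance")
})

test_that("simulated admixture drift is recovered by the change regression", {
  # trait shift proportional to admixture drift across cohorts
  st <- tiny_study(n_per_cohort = c(400, 400, 400),
                   priors = rbind(c(8, 2), c(6, 4), c(4, 6)),
                   n_variants = 60, seed = 83)
  ph <- simulate_phenotype(st$cohort$genotypes, st$cohort$truth,
                           phenotype_spec(h2 = 0, n_causal = 0,
                                          strat_shift = c(3, 0)),
                           metadata = st$cohort$metadata, seed = 87)
  cm <- st$cohort$metadata
  pairs <- utils::combn(1:3, 2)
  d_tr <- d_q <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- cm$cohort == pairs[1, k]; b <- cm$cohort == pairs[2, k]
    d_tr[k] <- mean(ph$trait[a]) - mean(ph$trait[b])
    d_q[k] <- mean(st$cohort$truth[a, 1]) - mean(st$cohort$truth[b, 1])
  }
  r <- regress_change_on_change(d_tr, d_q)
  expect_lt(abs(r$slope - 3), 2 * r$se + 0.5)
})

test_that("cohort-pair comparison table has coherent effect directions", {
  st <- tiny_study(n_per_cohort = c(300, 300),
                   priors = rbind(c(8, 2), c(2, 8)), n_variants = 40,
                   seed = 91)
  q1 <- st$cohort$truth[, 1]
  cm <- st$cohort$metadata
  tab <- compare_across_cohorts(q1, groups = rep("ALL", nrow(cm)),
                                cohorts = cm$cohort)
  expect_equal(nrow(tab), 1L)
  expect_equal(sign(tab$d), sign(tab$diff))
  expect_lt(tab$p, 1e-10)  # designed drift is large
  expect_true(all(tab$q >= tab$p))
})
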