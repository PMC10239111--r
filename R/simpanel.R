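#' Population divergence model for genotype simulation
#'
#' Describes `K` ancestral populations that diverged from a common ancestral
#' allele-frequency spectrum under the Balding-Nichols model: population `k`
#' draws its allele frequency at variant `j` from
#' `Beta(p_j (1 - F_k) / F_k, (1 - p_j)(1 - F_k) / F_k)`, so that
#' `Var(p_kj) = F_k p_j (1 - p_j)`. All variants live on one synthetic
#' chromosome with strictly increasing positions.
#'
#' An optional block-LD mode groups consecutive variants into blocks that
#' share an allele frequency and are generated as correlated copies of a
#' block seed variant (pairwise correlation about `block_cor^2`). The default
#' (`blocks = NULL`) is fully unlinked variants, in which case any LD in an
#' admixed cohort arises from population structure alone.
#'
#' Hierarchical (two-level) structure is supported: when `groups` and
#' `group_fst` are given, each continental group first drifts from the
#' ancestral frequencies with its own `group_fst`, and every population then
#' drifts from its group's frequencies with its `fst` entry. This emulates
#' panels in which continental groups each contain many related populations.
#'
#' @param n_variants number of biallelic variants to simulate.
#' @param fst numeric vector of per-population differentiation values, each in
#'   `[0, 1)`; its length sets the number of populations `K`. Names, if
#'   present, are used as population labels (default `POP1..POPK`). With a
#'   hierarchy, this is the within-group drift.
#' @param groups optional character vector (length `K`) assigning each
#'   population to a continental group.
#' @param group_fst optional named numeric vector of per-group drift from the
#'   common ancestor, each in `[0, 1)`; required with `groups`.
#' @param ancestral_freqs optional vector of ancestral allele frequencies,
#'   strictly inside (0.05, 0.95). Drawn uniformly on that interval when `NULL`.
#' @param spacing_bp distance between adjacent variant positions (default 1 kb).
#' @param blocks optional integer vector of LD-block sizes summing to
#'   `n_variants`; `NULL` means unlinked.
#' @param block_cor correlation between a block member and its block seed,
#'   in `[0, 1)`; only used when `blocks` is given.
#' @param seed RNG seed used when `ancestral_freqs` must be drawn.
#' @return an object of class `population_model`.
#' @export
population_model <- function(n_variants, fst, ancestral_freqs = NULL,
                             spacing_bp = 1000L, blocks = NULL,
                             block_cor = 0.9, groups = NULL,
                             group_fst = NULL, seed = 1L) {
  if (any(fst < 0 | fst >= 1)) {
    stop("all `fst` values must lie in [0, 1)")
  }
  if (!is.null(groups)) {
    if (length(groups) != length(fst)) {
      stop("`groups` must assign every population")
    }
    if (is.null(group_fst) || !all(unique(groups) %in% names(group_fst))) {
      stop("`group_fst` must name every group in `groups`")
    }
    if (any(group_fst < 0 | group_fst >= 1)) {
      stop("all `group_fst` values must lie in [0, 1)")
    }
  }
  n_variants <- as.integer(n_variants)
  if (is.null(ancestral_freqs)) {
    set.seed(seed)
    ancestral_freqs <- stats::runif(n_variants, 0.05 + 1e-9, 0.95 - 1e-9)
  }
  if (length(ancestral_freqs) != n_variants) {
    stop("`ancestral_freqs` must have length `n_variants`")
  }
  if (any(ancestral_freqs <= 0.05 | ancestral_freqs >= 0.95)) {
    stop("`ancestral_freqs` must lie strictly inside (0.05, 0.95)")
  }
  if (!is.null(blocks)) {
    blocks <- as.integer(blocks)
    if (any(blocks < 1L) || sum(blocks) != n_variants) {
      stop("`blocks` must be positive integers summing to `n_variants`")
    }
    if (block_cor < 0 || block_cor >= 1) stop("`block_cor` must be in [0, 1)")
  }
  pops <- names(fst)
  if (is.null(pops)) pops <- paste0("POP", seq_along(fst))
  positions <- as.integer(seq_len(n_variants)) * as.integer(spacing_bp)
  structure(
    list(
      n_pops = length(fst), fst = unname(fst), pops = pops,
      ancestral_freqs = ancestral_freqs, positions = positions,
      blocks = blocks, block_cor = block_cor,
      groups = groups, group_fst = group_fst
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("population_model:", x$n_pops, "populations,",
      length(x$ancestral_freqs), "variants\n")
  cat("  FST:", paste(sprintf("%s=%.3g", x$pops, x$fst), collapse = ", "), "\n")
  if (!is.null(x$blocks)) {
    cat("  block LD: ", length(x$blocks), " blocks, member-seed cor ",
        x$block_cor, "\n", sep = "")
  } else {
    cat("  unlinked variants\n")
  }
  invisible(x)
}

# Draw population-specific frequencies p_kj under Balding-Nichols.
# For F = 0 the Beta degenerates to a point mass at the ancestral frequency.
.bn_pop_freqs <- function(p, fst_k) {
  if (fst_k == 0) return(p)
  a <- p * (1 - fst_k) / fst_k
  b <- (1 - p) * (1 - fst_k) / fst_k
  stats::rbeta(length(p), a, b)
}

# Per-block shared frequencies: every member of a block uses the seed's
# frequency so that within-block copying preserves the marginal distribution.
.blockify_freqs <- function(freqs, blocks) {
  if (is.null(blocks)) return(freqs)
  seed_idx <- rep(cumsum(c(1L, utils::head(blocks, -1L))), times = blocks)
  if (is.matrix(freqs)) freqs[seed_idx, , drop = FALSE] else freqs[seed_idx]
}

# Binomial(2, p) genotypes for an n x J matrix of per-entry frequencies,
# with optional within-block correlation: each non-seed member copies the
# seed genotype with probability block_cor and redraws otherwise.
.draw_genotypes <- function(prob, blocks = NULL, block_cor = 0) {
  n <- nrow(prob); J <- ncol(prob)
  g <- matrix(stats::rbinom(n * J, 2L, prob), n, J)
  if (!is.null(blocks) && block_cor > 0) {
    start <- cumsum(c(1L, utils::head(blocks, -1L)))
    for (b in seq_along(blocks)) {
      if (blocks[b] == 1L) next
      s <- start[b]
      for (j in (s + 1L):(s + blocks[b] - 1L)) {
        keep <- stats::runif(n) < block_cor
        g[keep, j] <- g[keep, s]
      }
    }
  }
  g
}

#' Simulate a labeled ancestry reference panel
#'
#' Draws per-population allele frequencies under the Balding-Nichols model of
#' the supplied [population_model()] and genotypes `n_per_pop` individuals per
#' population as `Binomial(2, p_kj)` alt-allele dosages. The returned panel
#' carries the true population labels and the realized frequencies `p_kj`,
#' which downstream supervised admixture estimation can use as its reference.
#'
#' @param model a [population_model()].
#' @param n_per_pop individuals per population (at least 2).
#' @param seed RNG seed; identical seeds give byte-identical panels.
#' @return an object of class `reference_panel` with elements `genotypes`
#'   (a [genotype_matrix()]), `labels`, `freqs` (variants x populations) and
#'   `pops`.
#' @export
simulate_reference_panel <- function(model, n_per_pop, seed) {
  stopifnot(inherits(model, "population_model"))
  n_per_pop <- as.integer(n_per_pop)
  if (n_per_pop < 2L) stop("`n_per_pop` must be at least 2")
  set.seed(seed)
  J <- length(model$ancestral_freqs)
  K <- model$n_pops
  if (is.null(model$groups)) {
    freqs <- vapply(seq_len(K),
                    function(k) .bn_pop_freqs(model$ancestral_freqs,
                                              model$fst[k]),
                    numeric(J))
  } else {
    # two-level drift: ancestor -> continental group -> population
    gfreqs <- vapply(unique(model$groups), function(g)
      pmin(pmax(.bn_pop_freqs(model$ancestral_freqs, model$group_fst[g]),
                0.01), 0.99),
      numeric(J))
    freqs <- vapply(seq_len(K), function(k)
      .bn_pop_freqs(gfreqs[, model$groups[k]], model$fst[k]),
      numeric(J))
  }
  colnames(freqs) <- model$pops
  freqs <- .blockify_freqs(freqs, model$blocks)
  g <- matrix(NA_integer_, nrow = K * n_per_pop, ncol = J)
  labels <- rep(model$pops, each = n_per_pop)
  for (k in seq_len(K)) {
    rows <- ((k - 1L) * n_per_pop + 1L):(k * n_per_pop)
    prob <- matrix(freqs[, k], nrow = n_per_pop, ncol = J, byrow = TRUE)
    g[rows, ] <- .draw_genotypes(prob, model$blocks, model$block_cor)
  }
  ids <- sprintf("REF%04d", seq_len(nrow(g)))
  gm <- genotype_matrix(g, sample_ids = ids,
                        variants = .synthetic_variants(model))
  structure(list(genotypes = gm, labels = labels, freqs = freqs,
                 pops = model$pops, model = model),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", length(x$labels), "individuals,",
      ncol(x$genotypes$dosages), "variants\n")
  print(table(x$labels))
  invisible(x)
}

.synthetic_variants <- function(model) {
  J <- length(model$ancestral_freqs)
  data.frame(
    id = sprintf("var%05d", seq_len(J)),
    chrom = "1",
    pos = model$positions,
    ref = "A",
    alt = "G",
    stringsAsFactors = FALSE
  )
}

#' Cohort design for the admixed longitudinal simulation
#'
#' Encodes how each birth cohort of the simulated study population is drawn:
#' per-cohort sample sizes, per-cohort Dirichlet concentration vectors over
#' the K reference populations (so admixture can drift across cohorts), the
#' mapping from fine population to the coarse self-identified label recorded
#' in metadata (coarse labels may merge genetically distinct populations),
#' a label-noise rate, a missing-label rate, and birth-year ranges.
#'
#' @param n_per_cohort integer vector, samples per birth cohort.
#' @param admixture_priors matrix (cohorts x K) of strictly positive Dirichlet
#'   concentrations.
#' @param birth_year_ranges matrix (cohorts x 2) of inclusive year bounds.
#' @param coarse_label_map named character vector mapping every fine
#'   population name to a coarse label; defaults to the identity map.
#' @param label_noise probability that a recorded coarse label is replaced by
#'   a random *other* coarse label.
#' @param label_missing probability that the coarse label is missing (`NA`).
#' @param reference_year year used to compute age as `reference_year -
#'   birth_year` (default 2011, the study-enrolment era).
#' @param pops population names (columns of `admixture_priors`).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cohort, admixture_priors, birth_year_ranges,
                        coarse_label_map = NULL, label_noise = 0,
                        label_missing = 0, reference_year = 2011L,
                        pops = NULL) {
  admixture_priors <- as.matrix(admixture_priors)
  C <- length(n_per_cohort)
  if (nrow(admixture_priors) != C) {
    stop("`admixture_priors` must have one row per cohort")
  }
  if (any(admixture_priors <= 0)) {
    stop("Dirichlet concentrations must be strictly positive")
  }
  birth_year_ranges <- as.matrix(birth_year_ranges)
  if (nrow(birth_year_ranges) != C || ncol(birth_year_ranges) != 2L) {
    stop("`birth_year_ranges` must be a cohorts x 2 matrix")
  }
  if (is.null(pops)) pops <- colnames(admixture_priors)
  if (is.null(pops)) pops <- paste0("POP", seq_len(ncol(admixture_priors)))
  if (is.null(coarse_label_map)) {
    coarse_label_map <- stats::setNames(pops, pops)
  }
  if (!all(pops %in% names(coarse_label_map))) {
    stop("`coarse_label_map` must cover every population: ",
         paste(setdiff(pops, names(coarse_label_map)), collapse = ", "))
  }
  structure(
    list(n_per_cohort = as.integer(n_per_cohort),
         admixture_priors = admixture_priors,
         birth_year_ranges = birth_year_ranges,
         coarse_label_map = coarse_label_map,
         label_noise = label_noise, label_missing = label_missing,
         reference_year = as.integer(reference_year), pops = pops),
    class = "cohort_spec"
  )
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate an admixed longitudinal cohort
#'
#' Each sample draws an admixture vector `q` from its birth cohort's
#' Dirichlet prior and genotypes `Binomial(2, sum_k q_k p_kj)` against the
#' realized reference-panel frequencies. Metadata records birth year (uniform
#' within the cohort's range), sex (0/1, balanced), age relative to the
#' spec's reference year, and a coarse self-identified label derived from the
#' dominant ancestry component through `coarse_label_map`, with optional
#' label noise and missingness.
#'
#' @param panel a `reference_panel` from [simulate_reference_panel()].
#' @param spec a [cohort_spec()]; must use the panel's K populations.
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `metadata`
#'   (data.frame: sample_id, cohort, birth_year, age, sex, coarse_label),
#'   and `truth` (samples x K matrix of true admixture proportions).
#' @export
simulate_cohort <- function(panel, spec, seed) {
  stopifnot(inherits(panel, "reference_panel"), inherits(spec, "cohort_spec"))
  if (ncol(spec$admixture_priors) != ncol(panel$freqs)) {
    stop("panel and cohort spec disagree on the number of populations")
  }
  if (any(spec$n_per_cohort < 1L)) stop("every cohort must be non-empty")
  set.seed(seed)
  C <- length(spec$n_per_cohort)
  n <- sum(spec$n_per_cohort)
  J <- nrow(panel$freqs)
  model <- panel$model
  q <- matrix(NA_real_, n, ncol(panel$freqs),
              dimnames = list(NULL, spec$pops))
  cohort <- rep(seq_len(C), times = spec$n_per_cohort)
  birth_year <- integer(n)
  g <- matrix(NA_integer_, n, J)
  offset <- 0L
  for (ci in seq_len(C)) {
    nc <- spec$n_per_cohort[ci]
    rows <- offset + seq_len(nc)
    q[rows, ] <- .rdirichlet(nc, spec$admixture_priors[ci, ])
    birth_year[rows] <- sample(
      seq(spec$birth_year_ranges[ci, 1], spec$birth_year_ranges[ci, 2]),
      nc, replace = TRUE)
    prob <- q[rows, , drop = FALSE] %*% t(panel$freqs)
    g[rows, ] <- .draw_genotypes(prob, model$blocks, model$block_cor)
    offset <- offset + nc
  }
  ids <- sprintf("S%05d", seq_len(n))
  rownames(q) <- ids
  fine <- spec$pops[max.col(q, ties.method = "first")]
  coarse <- unname(spec$coarse_label_map[fine])
  coarse_levels <- unique(unname(spec$coarse_label_map))
  if (spec$label_noise > 0 && length(coarse_levels) > 1L) {
    flip <- stats::runif(n) < spec$label_noise
    for (i in which(flip)) {
      coarse[i] <- sample(setdiff(coarse_levels, coarse[i]), 1L)
    }
  }
  if (spec$label_missing > 0) {
    coarse[stats::runif(n) < spec$label_missing] <- NA_character_
  }
  meta <- data.frame(
    sample_id = ids,
    cohort = cohort,
    birth_year = birth_year,
    age = spec$reference_year - birth_year,
    sex = stats::rbinom(n, 1L, 0.5),
    coarse_label = coarse,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(g, sample_ids = ids,
                        variants = .synthetic_variants(model))
  list(genotypes = gm, metadata = meta, truth = q)
}

#' Trait architecture for the simulated phenotype
#'
#' @param h2 target SNP-heritability in `[0, 1]` of the causal component.
#' @param n_causal number of causal variants.
#' @param strat_shift numeric vector of per-population additive mean shifts
#'   (trait units): the confound. All zeros gives an unconfounded trait.
#' @param sex_effect,age_effect fixed covariate coefficients (trait units).
#' @return an object of class `phenotype_spec`. Genetic and residual variance
#'   sum to 1 before shifts, so `strat_shift` is on the trait-SD scale.
#' @export
phenotype_spec <- function(h2, n_causal, strat_shift = 0,
                           sex_effect = 0, age_effect = 0) {
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]")
  structure(list(h2 = h2, n_causal = as.integer(n_causal),
                 strat_shift = strat_shift, sex_effect = sex_effect,
                 age_effect = age_effect),
            class = "phenotype_spec")
}

#' Simulate a confounded polygenic quantitative trait
#'
#' The trait is the sum of (i) a polygenic component built from `n_causal`
#' standardized dosages with Gaussian effects, rescaled so its realized
#' variance is exactly `h2`; (ii) Gaussian noise with variance `1 - h2`;
#' (iii) fixed age and sex covariate effects; and (iv) the stratification
#' confound `sum_k q_k * strat_shift_k`. With `strat_shift = 0` the trait
#' carries no ancestry signal beyond the causal variants themselves.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth samples x K true admixture matrix (from [simulate_cohort()]).
#' @param spec a [phenotype_spec()].
#' @param metadata data.frame with `age` and `sex` columns (from
#'   [simulate_cohort()]); optional when both covariate effects are zero.
#' @param seed RNG seed.
#' @return data.frame (sample_id, trait, age, sex) with attributes
#'   `genetic_component`, `confound` and `causal_idx` for variance
#'   decomposition checks.
#' @export
simulate_phenotype <- function(genotypes, truth, spec, metadata = NULL,
                               seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(spec, "phenotype_spec"))
  G <- genotypes$dosages
  n <- nrow(G); J <- ncol(G)
  if (spec$n_causal > J) stop("`n_causal` exceeds the number of variants")
  set.seed(seed)
  if (is.null(metadata)) {
    metadata <- data.frame(age = rep(0, n), sex = rep(0L, n))
  }
  genetic <- rep(0, n)
  causal <- integer(0)
  if (spec$h2 > 0 && spec$n_causal > 0L) {
    causal <- sort(sample.int(J, spec$n_causal))
    Xc <- .impute_mean(G[, causal, drop = FALSE])
    Xc <- scale(Xc)
    Xc[is.nan(Xc)] <- 0  # monomorphic-in-sample causal variants contribute 0
    genetic <- drop(Xc %*% stats::rnorm(spec$n_causal))
    sg <- stats::sd(genetic)
    if (sg > 0) genetic <- genetic * sqrt(spec$h2) / sg
  }
  noise <- stats::rnorm(n, sd = sqrt(max(0, 1 - spec$h2)))
  shift <- rep(spec$strat_shift, length.out = ncol(truth))
  confound <- drop(truth %*% shift)
  trait <- genetic + noise + confound +
    spec$age_effect * metadata$age + spec$sex_effect * metadata$sex
  out <- data.frame(sample_id = genotypes$sample_ids, trait = trait,
                    age = metadata$age, sex = metadata$sex,
                    stringsAsFactors = FALSE)
  attr(out, "genetic_component") <- genetic
  attr(out, "confound") <- confound
  attr(out, "causal_idx") <- causal
  out
}
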