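---
title: "Ancestry assignment strategies and residual stratification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry assignment strategies and residual stratification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(strataforge)
```

## The question the package addresses

Large biobank GWAS are run within ancestry strata. How those strata are
defined matters: a coarse stratum that merges genetically distinct
populations (for example, a census-style "Asian" group containing both East
Asian and Central/South Asian participants) is more heterogeneous than a
stratum defined against a high-resolution genetic reference panel, and the
extra heterogeneity can leak into the association statistics as residual
population stratification. strataforge implements both assignment
strategies and the machinery to measure the consequence — the LD score
regression (LDSC) intercept and attenuation ratio of a quantitative-trait
GWAS — on synthetic cohorts with known ground truth.

## The generative model

### Genotypes

Populations diverge from a common ancestral allele-frequency spectrum under
the Balding–Nichols model: population $k$ draws its frequency at variant
$j$ from

$$p_{kj} \sim \mathrm{Beta}\!\left(p_j \tfrac{1-F_k}{F_k},\;
(1-p_j)\tfrac{1-F_k}{F_k}\right),
\qquad \mathrm{Var}(p_{kj}) = F_k\, p_j (1-p_j),$$

so $F_k$ is the FST-scale drift of population $k$. Ancestral frequencies
are uniform on (0.05, 0.95). A two-level mode adds continental hierarchy:
group frequencies drift from the ancestor with `group_fst`, and populations
drift from their group with `fst` — the structure of reference panels in
which six continental groups contain dozens of related populations. An
admixed individual with proportions $q$ draws genotypes
$\mathrm{Binomial}(2, \sum_k q_k p_{kj})$; $q$ itself is Dirichlet with
per-birth-cohort concentrations, which is how cohort-varying admixture is
encoded.

Variants sit on one synthetic chromosome at 1 kb spacing and are unlinked
by default: in an admixed cohort all LD is then structure-driven. An
optional block-LD mode groups consecutive variants into blocks sharing an
allele frequency, each member copying the block seed genotype with
probability $\phi$ (pairwise $r^2 \approx \phi^4$, seed–member
$r^2 \approx \phi^2$; the default $\phi = 0.9$ gives $r^2 \approx 0.66$ and
$0.81$). Block LD exists because LD score regression is only identified
when LD scores vary: with fully unlinked variants the in-sample LD score is
$1$ plus sampling noise of order $\sqrt{2W}/n \approx 0.03$, and the
intercept estimate is essentially unconstrained (per-replicate spread above
0.5 in our pilots). The studies below therefore simulate genomes whose
block sizes are mostly singletons (70%) with a tail of blocks up to 20
variants — a wide, long-tailed LD-score distribution (mean about 8, SD
about 4.3, range roughly 1–17) of the kind that gives the regression its
leverage. With block sizes uniform on 1..12 instead, the narrower LD-score
spread roughly doubles the per-replicate spread of the intercept. No
recombination map, phasing or sequencing error is modeled;
what passing tests show is that the analysis machinery behaves correctly
under this stylized LD, not that it reproduces any real genome's LD.

### Phenotype

The trait is
$g + \varepsilon + \sum_k q_k s_k + \beta_{\mathrm{age}}\,\mathrm{age} +
\beta_{\mathrm{sex}}\,\mathrm{sex}$, where the polygenic component $g$ sums
`n_causal` standardized dosages with Gaussian effects rescaled so
$\mathrm{Var}(g) = h^2$ exactly, $\varepsilon$ is Gaussian with variance
$1 - h^2$, and $s$ is the per-population mean shift — the stratification
confound, in trait-SD units because genetic plus residual variance is 1.
`strat_shift = 0` gives an unconfounded trait by construction.

## The two assignment strategies

**Reference-panel method.** Genotypes are QC'd (MAF $\ge$ 1%, variant
missingness $\le$ 5%, then sample missingness $\le$ 3%; variant-first order,
logged), LD-pruned by a greedy left-to-right scan ($r^2 \le 0.01$ within
1500 kb), and the panel is decomposed by SVD after centering at $2\hat p$
and scaling by $\sqrt{2\hat p(1-\hat p)}$. Cohort samples are projected
onto the top 20 loadings with the panel's centering (never refit), and a
random forest (500 trees, $\sqrt{p}$ features per split) trained on the
panel scores assigns labels; a sample is `Unclassified` unless its maximum
class probability strictly exceeds 0.5. Assigned groups are refined once:
within each group a fresh PCA is computed and any member more than 6
(unscaled) median absolute deviations from the group median on any of the
top 20 axes becomes `Unclassified`. We read the MAD rule per-dimension and
without the 1.4826 normal-consistency factor — the stricter, simpler
interpretation — and apply a single pass rather than iterating.

**Coarse-blended baseline.** Emulating assignment schemes that harmonize
self-identified labels with genetics, a random forest learns to predict the
*coarse* label from the samples' own PC scores (using samples whose label
is present). The final label is the coarse label when it agrees with the
genetic prediction, the predicted label when the coarse label is missing
and confidence exceeds 0.5, and `Unclassified` otherwise. Training on the
cohort's own labels (rather than on the reference panel) mirrors how such
classifiers are actually built; the reference panel plays no role in this
baseline. For labeled samples the genetic prediction uses the forest's
*out-of-bag* votes: in-bag predictions memorize each sample's own label,
and a mislabeled sample would always "agree" with itself, so discordance
could never be detected.

One practical caveat surfaced by the tests: at reference-panel sample sizes
of a few hundred, pruning at $r^2 = 0.01$ is close to the null sampling
level of $r^2$ ($\approx 1/n$) and can discard most variants — and in a
*structured* panel it preferentially discards the differentiated variants,
whose mutual structure-LD exceeds the threshold, flattening the PCA. The
pipeline therefore prunes on the large cohort, as the source procedure
does, and uses those variants for the panel PCA.

## Admixture proportions

Per sample, the simplex vector $q$ maximizes the supervised binomial
likelihood
$\ell(q) = \sum_j \big[g_j \log \pi_j + (2-g_j)\log(1-\pi_j)\big]$ with
$\pi_j = \sum_k q_k p_{kj}$ against *fixed* reference frequencies (clipped
to $[10^{-6}, 1-10^{-6}]$), via the EM update

$$q_k \leftarrow \frac{1}{2J}\sum_j\left[
g_j \frac{q_k p_{kj}}{\pi_j} + (2-g_j)\frac{q_k (1-p_{kj})}{1-\pi_j}
\right],$$

starting from the uniform vector and stopping when the per-sample
log-likelihood gain drops below `tol` ($10^{-6}$) or at `max_iter` (2000,
returned with a warning flag). The update is the standard
responsibility-weighted form and never decreases the likelihood; the test
suite asserts monotonicity and checks the optimum against a grid search
over the simplex. Missing genotypes drop out of the sample's likelihood.
Samples are independent, so the batch implementation vectorizes across
them with an active set for converged samples.

## Cohort statistics

Birth cohorts come from the empirical CDF of birth year at year
granularity: cohort $c$ collects the years whose CDF value falls in
$((c-1)/C,\, c/C]$, so a calendar year is never split and cohort sizes can
differ by up to a year-bin (heavy ties can even empty a stratum, which is
reported rather than repaired). Comparisons use Cohen's $d$ with the pooled
SD, two-sided Z-tests
$Z = (\hat\theta_1 - \hat\theta_2)/\sqrt{SE_1^2 + SE_2^2}$, Bonferroni
thresholds $\alpha/m$, and Benjamini–Hochberg q-values (via
`stats::p.adjust`; the tests carry an independent brute-force step-up
oracle). For ancestry-proportion means the Z-test SE is the per-cell
$\mathrm{SD}/\sqrt{n}$ — the source does not state its choice, and this is
the standard one. Group-by-cohort proportion cells with fewer than 11
samples are suppressed, mirroring biobank privacy floors. Relative changes
in group counts are printed truncated (not rounded) to one decimal,
matching the convention of the published table they reproduce.

## GWAS and LD score regression

The association scan is per-variant OLS of the trait on dosage plus
intercept, age, sex and 10 within-group PCs, computed by
Frisch–Waugh–Lovell residualization (exactly equal to the full OLS fit,
which the tests verify against `lm` and explicit normal equations at
$10^{-10}$). Dosages are kept on the allele-count scale; $\chi^2 =
(\hat\beta/SE)^2$ is scale-invariant so the LDSC stage is unaffected.
Covariate PCs are recomputed per group and per assignment method.

LD scores use the finite-sample-adjusted estimator
$\tilde r^2 = r^2 - (1-r^2)/(n-2)$ summed over a window (self term exactly
1). The regression $E[\chi^2_j] = 1 + (N h^2 / M)\,\ell_j$ is fitted by
two-step weighted least squares with the conventional weights
($1/\max(\ell_j, 1)$, refined by $1/(2\hat\chi^4_j \max(\ell_j,1))$);
standard errors come from a delete-a-block jackknife over 200 contiguous
variant blocks (reduced to $M/10$ with a warning when $M$ is small). The
attenuation ratio is $(\mathrm{intercept}-1)/(\bar\chi^2-1)$, reported as
missing when $\bar\chi^2 \le 1$ — we adopt the proportion-of-inflation
definition; the alternative intercept-to-mean-$\chi^2$ ratio reading is
inconsistent with how attenuation ratios are used and reported in the LDSC
literature.

Two numerical findings shaped the simulation-study design (both
reproducible with the package's own functions):

* **Window scale.** The conventional ~1 Mb LDSC window presumes real
  genomes' LD range. The synthetic genome's LD spans at most 12 kb, so the
  replicated studies use a 100 kb window: it covers all true LD while
  adding an order of magnitude fewer pure-noise $\tilde r^2$ cross terms.
  The window stays configurable everywhere.
* **LD reference.** In an admixed analysis group, in-sample LD scores pick
  up genome-wide admixture LD on exactly the differentiated variants whose
  $\chi^2$ the confound inflates; the regression then routes the
  stratification signal into the slope (we observed merged-group
  intercepts pushed *below* the fine-group's). The confounding study
  therefore computes LD scores on an external homogeneous reference cohort
  drawn from one population — the analogue of LDSC's external reference
  panel — while the pipeline default remains in-sample, which is adequate
  for homogeneous groups.

## The replicated studies and why they are designed as they are

`sim_study_null_calibration` (20 replicates, $n = 2000$, $M = 5000$,
$h^2 = 0$, no stratification, block-LD genome, single population) checks
that the intercept is 1 under the null. `sim_study_h2_recovery` (20
replicates, $h^2 = 0.5$, 500 causal variants) checks the slope-derived
$\hat h^2$; a pilot grid showed the weighted estimator is unbiased to
within a few hundredths at these sizes with per-replicate SD about 0.13.
`sim_study_em_recovery` ($n = 500$, 5000 variants, $K = 5$ at FST 0.1,
uniform-Dirichlet admixture) measures RMSE of $\hat q$ against the
generating proportions. `sim_study_classifier_accuracy` checks panel
self-classification at FST 0.1.

`sim_study_confounding` deserves the longest explanation. The naive design
— merge two single populations at FST 0.05 with a 0.5 SD trait gap and scan
with 10 PCs — has *no* detectable signal: a one-dimensional confound whose
axis is the dominant eigenvector is absorbed essentially completely by the
PCs (we measured merged-group intercepts of 3–9 without PCs collapsing to
$1.00 \pm 0.1$ with them, direction a coin flip). That is not the situation
coarse labels create in real cohorts: there, each merged stratum is itself
a collection of populations, and the heterogeneity has more axes than the
10 fitted PCs. The study therefore simulates two continental groups at
between-group FST 0.05, each containing 10 populations at within-group FST
0.02, with population-specific trait shifts: group means at $\pm 0.25$ (the
0.5 SD between-group gap) plus population jitter of SD 0.25, centered
within each group so the gap is exact. Population-level trait-mean
differences of a quarter SD are conservative relative to, say, documented
height differences between European populations. Under this design 10 PCs
absorb roughly three quarters of the confound variance and the merged
group's scan retains visible inflation (mean $\chi^2 \approx 1.1$–$1.3$),
while the fine single-group analysis — whose structure fits inside 10 PCs —
is corrected; the study asserts only the *direction* of the intercept
difference across replicates.

## Pipeline, sizes and reproducibility

`run_pipeline()` drives the full factorial experiment (simulate, QC,
both assignment methods, admixture proportions, birth cohorts, per-cell
GWAS + LDSC, cross-method comparison) from one configuration with a single
master seed; every stage's seed derives from it, reruns are byte-identical,
and a manifest (config, package version, seeds, cell list) is written
beside the tables. The shipped demonstration configuration uses 3
populations, 2 cohorts and 2000 variants so a full run takes well under a
minute; the replicated studies above use $n = 2000$ and $M = 5000$, chosen
as the smallest sizes at which the LDSC machinery is stable enough for
calibrated inference. Every simulation parameter named in this vignette is
an argument with the stated default, not a constant.

## Known limitations

* The synthetic LD (exchangeable blocks) has no decay structure, no
  MAF–LD coupling, and no long-range LD; conclusions about LDSC behavior
  under realistic LD architectures are out of reach of these tests.
* Kinship is not modeled or estimated; the pipeline assumes unrelated
  samples (an unrelated-set list can be applied upstream).
* The coarse-label baseline emulates the *decision logic* of
  self-identified-label harmonization, not any particular cohort's
  questionnaire or trained classifier.
* Attenuation-ratio comparisons are underpowered at desk scale: jackknife
  SEs on the ratio are large when mean $\chi^2$ is near 1, and the
  comparison table reports them as missing in that regime.
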