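#' Default pipeline configuration
#'
#' A small end-to-end demonstration configuration: 3 populations, 2 birth
#' cohorts, both assignment methods, with a coarse label merging two of the
#' populations. All stochastic stages derive their seeds from the single
#' top-level `seed`. Any element can be overridden via `...` (top-level
#' names) before validation.
#'
#' @param seed master seed.
#' @param ... top-level overrides (e.g. `panel = list(...)`).
#' @return a configuration list suitable for [run_pipeline()].
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    panel = list(n_variants = 2000L, fst = c(A = 0.08, B = 0.08, C = 0.08),
                 n_per_pop = 60L),
    cohort = list(
      n_per_cohort = c(700L, 700L),
      # sparse Dirichlet: individuals cluster near population corners, the
      # second (younger) cohort is more balanced and more admixed
      admixture_priors = rbind(c(0.3, 0.12, 0.12), c(0.25, 0.18, 0.18)),
      birth_year_ranges = rbind(c(1930L, 1959L), c(1960L, 1999L)),
      # the coarse labels cannot resolve population C, which is lumped
      # with B -- the merge the panel method is meant to undo
      coarse_label_map = c(A = "A", B = "B", C = "B"),
      label_noise = 0.02, label_missing = 0.02),
    phenotype = list(h2 = 0.3, n_causal = 200L, strat_shift = c(0.3, -0.3, 0),
                     sex_effect = 0.5, age_effect = 0.01),
    qc = list(maf_min = 0.01, snp_missing_max = 0.05,
              sample_missing_max = 0.03),
    assign = list(n_pcs = 10L, prob_min = 0.5, n_mads = 6, ntree = 300L,
                  prune_r2 = 0.01, prune_window_kb = 1500),
    admixture = list(tol = 1e-4, max_iter = 1000L),
    gwas = list(n_pcs = 10L, min_group_n = 100L),
    ldsc = list(window_kb = 1000, n_blocks = 100L),
    cohorts = list(n_cohorts = 2L),
    min_cell = 11L,
    write_genotypes = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full comparison pipeline
#'
#' Orchestrates the whole experiment from one configuration: simulate the
#' reference panel, admixed cohort and trait; QC; LD-prune; assign ancestry
#' by both the reference-panel method (PCA projection + random forest +
#' outlier refinement) and the coarse-blended baseline; estimate admixture
#' proportions; build birth cohorts; per (method x group x cohort) cell run
#' the covariate-PC association scan and LD score regression; and compare
#' methods. Writes all result tables plus a run manifest to `out_dir`.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (assignments,
#'   proportions, cohort labels, LDSC fits, comparison table).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- function(...) message("[strataforge] ", sprintf(...))

  logf("stage simulate: K=%d, %d variants", length(cfg$panel$fst),
       cfg$panel$n_variants)
  model <- population_model(cfg$panel$n_variants, fst = unlist(cfg$panel$fst),
                            seed = cfg$seed + 1L)
  panel <- simulate_reference_panel(model, cfg$panel$n_per_pop,
                                    seed = cfg$seed + 2L)
  spec <- cohort_spec(
    n_per_cohort = cfg$cohort$n_per_cohort,
    admixture_priors = .as_matrix(cfg$cohort$admixture_priors),
    birth_year_ranges = .as_matrix(cfg$cohort$birth_year_ranges),
    coarse_label_map = unlist(cfg$cohort$coarse_label_map),
    label_noise = cfg$cohort$label_noise,
    label_missing = cfg$cohort$label_missing,
    pops = model$pops)
  cohort <- simulate_cohort(panel, spec, seed = cfg$seed + 3L)
  pheno <- simulate_phenotype(
    cohort$genotypes, cohort$truth,
    phenotype_spec(cfg$phenotype$h2, cfg$phenotype$n_causal,
                   unlist(cfg$phenotype$strat_shift),
                   cfg$phenotype$sex_effect, cfg$phenotype$age_effect),
    metadata = cohort$metadata, seed = cfg$seed + 4L)

  logf("stage qc")
  g <- qc_filter(cohort$genotypes, cfg$qc$maf_min, cfg$qc$snp_missing_max,
                 cfg$qc$sample_missing_max)
  keep <- match(g$sample_ids, cohort$metadata$sample_id)
  meta <- cohort$metadata[keep, , drop = FALSE]
  ph <- pheno[keep, , drop = FALSE]

  logf("stage assign")
  pruned <- ld_prune(g, cfg$assign$prune_r2, cfg$assign$prune_window_kb)
  panel_keep <- heterozygosity_keep(panel$genotypes)
  panel_g <- subset_genotypes(panel$genotypes, samples = which(panel_keep),
                              variants = match(g$variants$id[pruned],
                                               panel$genotypes$variants$id))
  pcm <- fit_reference_pca(panel_g, n_pcs = cfg$assign$n_pcs)
  scores <- project_samples(pcm, g)
  a_panel <- classify_ancestry(pcm$scores, panel$labels[panel_keep], scores,
                               prob_min = cfg$assign$prob_min,
                               seed = cfg$seed + 5L,
                               ntree = cfg$assign$ntree)
  a_panel <- refine_outliers(a_panel, subset_genotypes(g, variants = pruned),
                             n_pcs = cfg$assign$n_pcs,
                             n_mads = cfg$assign$n_mads)
  a_coarse <- coarse_blended_assignment(scores, meta$coarse_label,
                                        prob_min = cfg$assign$prob_min,
                                        seed = cfg$seed + 6L,
                                        ntree = cfg$assign$ntree)
  write_assignment(a_panel, file.path(out_dir, "assignments_panel.tsv"))
  write_assignment(a_coarse, file.path(out_dir, "assignments_coarse.tsv"))

  logf("stage admixture")
  freqs <- panel$freqs
  rownames(freqs) <- panel$genotypes$variants$id
  q <- estimate_proportions(subset_genotypes(g, variants = pruned), freqs,
                            tol = cfg$admixture$tol,
                            max_iter = cfg$admixture$max_iter)
  write_proportions(q, file.path(out_dir, "admixture_proportions.tsv"))

  logf("stage cohorts")
  bc <- assign_birth_cohorts(meta$birth_year, cfg$cohorts$n_cohorts)
  utils::write.table(bc$boundaries, file.path(out_dir, "cohort_boundaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prop_tab <- group_mean_proportions(q, groups = a_coarse$assignments$label,
                                     cohorts = bc$cohort,
                                     min_cell = cfg$min_cell)
  utils::write.table(prop_tab, file.path(out_dir, "group_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  logf("stage gwas+ldsc")
  methods <- list(panel = a_panel, coarse = a_coarse)
  fits <- list(panel = list(), coarse = list())
  for (m in names(methods)) {
    labs <- methods[[m]]$assignments$label
    for (grp in setdiff(sort(unique(labs)), "Unclassified")) {
      for (ci in seq_len(cfg$cohorts$n_cohorts)) {
        mem <- which(labs == grp & bc$cohort == ci)
        if (length(mem) < cfg$gwas$min_group_n) next
        cell <- paste(grp, ci, sep = ".")
        fit <- tryCatch({
          pcs <- within_group_pcs(g, mem, n_pcs = cfg$gwas$n_pcs,
                                  pruned = pruned)
          gg <- subset_genotypes(g, samples = mem)
          covars <- cbind(age = meta$age[mem], sex = meta$sex[mem], pcs)
          scan <- run_gwas(gg, ph$trait[mem], covariates = covars)
          write_sumstats(scan, file.path(out_dir,
                                         sprintf("sumstats_%s_%s.tsv", m, cell)))
          ell <- compute_ld_scores(gg, window_kb = cfg$ldsc$window_kb)
          suppressWarnings(ldsc_regression(scan, ell,
                                           n_blocks = cfg$ldsc$n_blocks))
        }, error = function(e) {
          stop("stage gwas+ldsc failed for method ", m, ", cell ", cell,
               ": ", conditionMessage(e))
        })
        fits[[m]][[cell]] <- fit
      }
    }
    if (length(fits[[m]])) {
      utils::write.table(ldsc_fit_table(fits[[m]]),
                         file.path(out_dir, sprintf("ldsc_fits_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  logf("stage compare")
  shared <- intersect(names(fits$coarse), names(fits$panel))
  comparison <- NULL
  if (length(shared) > 0L) {
    comparison <- compare_methods(fits$coarse[shared], fits$panel[shared])
    utils::write.table(comparison$table,
                       file.path(out_dir, "method_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summ <- summarize_assignments(a_coarse, a_panel)
  utils::write.table(summ$counts, file.path(out_dir, "assignment_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$write_genotypes)) {
    write_genotypes(g, file.path(out_dir, "cohort.vcf"), format = "vcf")
    write_genotypes(panel$genotypes, file.path(out_dir, "panel.vcf"),
                    format = "vcf")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.config_for_yaml(cfg), cfg_path)
  manifest <- list(
    package = "strataforge",
    version = as.character(utils::packageVersion("strataforge")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    cells = lapply(fits, names))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  logf("done: %d panel cells, %d coarse cells", length(fits$panel),
       length(fits$coarse))
  invisible(list(config = cfg, assignments = methods, proportions = q,
                 cohorts = bc, fits = fits, comparison = comparison,
                 counts = summ))
}

.as_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, unlist))  # YAML list-of-rows
}

# Matrices serialize poorly through YAML; emit them as lists of rows.
.config_for_yaml <- function(x) {
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) unname(x[i, ])))
  if (is.list(x)) return(lapply(x, .config_for_yaml))
  x
}

.validate_config <- function(cfg) {
  need <- c("seed", "panel", "cohort", "phenotype", "qc", "assign",
            "admixture", "gwas", "ldsc", "cohorts")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("config must carry an explicit numeric seed")
  defaults <- default_config(seed = cfg$seed)
  for (sec in setdiff(need, "seed")) {
    fill <- setdiff(names(defaults[[sec]]), names(cfg[[sec]]))
    cfg[[sec]][fill] <- defaults[[sec]][fill]
  }
  if (is.null(cfg$min_cell)) cfg$min_cell <- defaults$min_cell
  cfg
}

#' Render a plain-text report from a pipeline result bundle
#'
#' Reads the tables written by [run_pipeline()] from `out_dir` and renders
#' assignment counts, the per-cell intercept comparison, and the
#' group-proportion listing as aligned text. Cells below the privacy floor
#' are rendered as `"<11"`.
#'
#' @param out_dir the pipeline output directory.
#' @param min_cell suppression floor used in rendering (default 11).
#' @return the report lines, invisibly; the report is also printed.
#' @export
report_bundle <- function(out_dir, min_cell = 11L) {
  need <- c("assignment_counts.tsv", "ldsc_fits_panel.tsv",
            "group_proportions.tsv")
  have <- file.exists(file.path(out_dir, need))
  if (!any(have)) stop("empty bundle: no result tables in ", out_dir)
  if (!all(have)) {
    stop("incomplete bundle; missing: ",
         paste(need[!have], collapse = ", "))
  }
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  cnt <- utils::read.delim(file.path(out_dir, "assignment_counts.tsv"))
  add("== Assignment counts (baseline vs panel) ==")
  for (i in seq_len(nrow(cnt))) {
    add("  %-14s %8s %8s  %s%%", cnt$label[i],
        .suppress(cnt$n_baseline[i], min_cell),
        .suppress(cnt$n_alt[i], min_cell),
        ifelse(is.na(cnt$rel_change_pct[i]), "NA",
               format(cnt$rel_change_pct[i])))
  }
  for (m in c("coarse", "panel")) {
    f <- file.path(out_dir, sprintf("ldsc_fits_%s.tsv", m))
    if (!file.exists(f)) next
    fit <- utils::read.delim(f)
    add("== LDSC fits [%s] ==", m)
    for (i in seq_len(nrow(fit))) {
      add("  %-12s intercept %.3f (%.3f)  mean chi2 %.3f", fit$cell[i],
          fit$intercept[i], fit$intercept_se[i], fit$mean_chi2[i])
    }
  }
  pr <- utils::read.delim(file.path(out_dir, "group_proportions.tsv"))
  add("== Mean ancestry proportions by group x cohort ==")
  for (i in seq_len(nrow(pr))) {
    if (isTRUE(pr$suppressed[i])) {
      add("  %-10s cohort %s %-6s n=%s", pr$group[i], pr$cohort[i], pr$pop[i],
          paste0("<", min_cell))
    } else {
      add("  %-10s cohort %s %-6s n=%d mean %.3f sd %.3f", pr$group[i],
          pr$cohort[i], pr$pop[i], pr$n[i], pr$mean[i], pr$sd[i])
    }
  }
  cmp <- file.path(out_dir, "method_comparison.tsv")
  if (file.exists(cmp)) {
    cm <- utils::read.delim(cmp)
    add("== Method comparison (intercepts) ==")
    for (i in seq_len(nrow(cm))) {
      add("  %-12s %.3f vs %.3f  p=%.3g q=%.3g", cm$cell[i], cm$intercept1[i],
          cm$intercept2[i], cm$p_intercept[i], cm$q_intercept[i])
    }
  }
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}

.suppress <- function(n, min_cell) {
  if (is.na(n)) "NA" else if (n > 0 && n < min_cell) paste0("<", min_cell)
  else format(n)
}
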