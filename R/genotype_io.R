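#' Genotype matrix container
#'
#' Samples x variants alt-allele dosages in `{0, 1, 2, NA}` together with the
#' variant records (id, chromosome, 1-based position, ref, alt alleles).
#'
#' @param dosages numeric/integer matrix, samples in rows.
#' @param sample_ids unique character sample identifiers.
#' @param variants data.frame with columns id, chrom, pos, ref, alt; positions
#'   must be non-decreasing within a chromosome.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  if (length(sample_ids) != nrow(dosages)) {
    stop("`sample_ids` length must match the number of dosage rows")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("`variants` must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("`variants` rows must match the number of dosage columns")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  cat("genotype_matrix:", nrow(d), "samples x", ncol(d), "variants\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing: %.2f%%; chrom(s): %s\n", 100 * miss,
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param samples row selector (indices, logical, or sample IDs).
#' @param variants column selector (indices, logical, or variant IDs).
#' @return the subsetted [genotype_matrix()].
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(g$sample_ids) else samples
  if (is.character(si)) si <- match(si, g$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  genotype_matrix(g$dosages[si, vi, drop = FALSE],
                  g$sample_ids[si],
                  g$variants[vi, , drop = FALSE])
}

# Per-variant mean imputation of missing dosages; returns a plain matrix.
.impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2L]]
  X[is.na(X)] <- 0  # all-missing columns
  X
}

.gt_to_dosage <- function(gt) {
  # strip any trailing FORMAT subfields, accept phased or unphased separators
  gt <- sub(":.*$", "", gt)
  a <- substr(gt, 1L, 1L)
  b <- substr(gt, 3L, 3L)
  d <- (a == "1") + (b == "1")
  d[a == "." | b == "."] <- NA_integer_
  as.integer(d)
}

#' Read genotypes from VCF or a dosage table
#'
#' VCF parsing keeps biallelic records only; multiallelic records (comma in
#' ALT) are skipped with a logged count. The dosage-table format is the
#' tab-delimited layout written by [write_genotypes()]: one row per variant
#' with columns id, chrom, pos, ref, alt followed by one column per sample.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") .read_vcf(path) else .read_dosage_table(path)
}

.read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)) || nrow(fix) == 0L) stop("empty VCF: ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("read_genotypes: skipped ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- apply(gt, 2L, .gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L)  # single variant
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), sample_ids = colnames(gt), variants = variants)
}

.read_dosage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty dosage table: ", path)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("malformed dosage table (expected columns ",
         paste(need, collapse = ", "), "): ", path)
  }
  samp <- setdiff(names(tab), need)
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  genotype_matrix(dos, sample_ids = samp,
                  variants = tab[, need])
}

#' Write genotypes as VCF 4.2 or a dosage table
#'
#' The VCF writer emits unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`) with
#' 1-based positions; the dosage writer emits the tab-delimited layout read
#' back by [read_genotypes()].
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "dosage")) {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "dosage") {
    tab <- cbind(g$variants[, c("id", "chrom", "pos", "ref", "alt")],
                 as.data.frame(t(g$dosages), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_codes <- c("0/0", "0/1", "1/1")
  D <- g$dosages
  gt <- matrix("./.", nrow(D), ncol(D))
  ok <- !is.na(D)
  gt[ok] <- gt_codes[D[ok] + 1L]
  body <- apply(gt, 2L, paste, collapse = "\t")  # per-variant sample fields
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=strataforge",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(g$sample_ids, collapse = "\t")),
    paste(g$variants$chrom, g$variants$pos, g$variants$id, g$variants$ref,
          g$variants$alt, ".", ".", ".", "GT", body, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Quality-control filter on variants then samples
#'
#' Removes variants with minor allele frequency below `maf_min` (MAF computed
#' on non-missing alleles only) or missing rate above `snp_missing_max`, then
#' removes samples whose missing rate over the retained variants exceeds
#' `sample_missing_max`. The variant-first order is fixed and logged. The
#' filter is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param snp_missing_max maximum per-variant missing rate (default 0.05).
#' @param sample_missing_max maximum per-sample missing rate (default 0.03).
#' @return the filtered [genotype_matrix()], with an attribute `qc_log`
#'   recording the removal counts.
#' @export
qc_filter <- function(g, maf_min = 0.01, snp_missing_max = 0.05,
                      sample_missing_max = 0.03) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(maf_min, snp_missing_max, sample_missing_max)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  D <- g$dosages
  p <- colMeans(D, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  vmiss <- colMeans(is.na(D))
  keep_v <- maf >= maf_min & vmiss <= snp_missing_max
  if (!any(keep_v)) {
    stop("qc_filter removed all ", ncol(D), " variants (maf < ", maf_min,
         " or missingness > ", snp_missing_max, ")")
  }
  D2 <- D[, keep_v, drop = FALSE]
  smiss <- rowMeans(is.na(D2))
  keep_s <- smiss <= sample_missing_max
  out <- subset_genotypes(g, samples = which(keep_s), variants = which(keep_v))
  log <- list(order = "variants-then-samples",
              variants_removed = sum(!keep_v),
              samples_removed = sum(!keep_s))
  message(sprintf(
    "qc_filter [variants-then-samples]: removed %d/%d variants, %d/%d samples",
    log$variants_removed, ncol(D), log$samples_removed, nrow(D)))
  attr(out, "qc_log") <- log
  out
}

#' Flag heterozygosity outliers in a reference panel
#'
#' Per-sample heterozygosity rate (fraction of non-missing genotypes equal
#' to 1) outside `n_sd` standard deviations of the panel mean marks a sample
#' for removal, mirroring common reference-panel curation.
#'
#' @param g a [genotype_matrix()].
#' @param n_sd threshold in standard deviations (default 3).
#' @return logical vector, `TRUE` for samples to keep.
#' @export
heterozygosity_keep <- function(g, n_sd = 3) {
  stopifnot(inherits(g, "genotype_matrix"))
  het <- rowMeans(g$dosages == 1L, na.rm = TRUE)
  s <- stats::sd(het)
  if (is.na(s) || s == 0) return(rep(TRUE, length(het)))
  abs(het - mean(het)) <= n_sd * s
}
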