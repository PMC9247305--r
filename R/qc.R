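#' Remove duplicated genotype samples
#'
#' Duplicates are samples carrying the same canonical identifier (repeat
#' genotyping, or records submitted by two partners).  Within each
#' duplicate set the sample with the highest call rate is kept; exact call
#' rate ties are broken in favour of the first occurrence and logged.
#'
#' @param gm A `genotype_matrix`.
#' @return List with `genotypes` (deduplicated) and `report`
#'   (`n_input`, `n_removed`, `n_retained`, `ties`: ids whose tie was
#'   broken by order).
#' @export
deduplicate <- function(gm) {
  ids <- gm$samples$id
  cr <- sample_call_rate(gm)
  keep <- rep(TRUE, length(ids))
  ties <- character(0)
  for (dup_id in unique(ids[duplicated(ids)])) {
    idx <- which(ids == dup_id)
    best <- idx[which.max(cr[idx])]   # which.max -> first occurrence on tie
    if (sum(cr[idx] == cr[best]) > 1L) ties <- c(ties, dup_id)
    keep[setdiff(idx, best)] <- FALSE
  }
  list(genotypes = subset_genotypes(gm, samples = which(keep)),
       report = list(n_input = length(ids), n_removed = sum(!keep),
                     n_retained = sum(keep), ties = ties))
}

#' Genotype quality control
#'
#' Standard chip-data filters, applied in a fixed order: (1) samples with
#' a call rate below `sample_cr_min` are removed; (2) SNPs with a call
#' rate (computed on the remaining samples) below `snp_cr_min` are
#' removed; (3) SNPs with a minor allele frequency below `maf_min`
#' (computed on the remaining samples, missing calls excluded) are
#' removed.  All three thresholds are strict (`<`): a marker sitting
#' exactly on a threshold is retained.
#'
#' @param gm A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param snp_cr_min Minimum per-SNP call rate (default 0.90).
#' @param sample_cr_min Minimum per-sample call rate (default 0.90).
#' @return List with `genotypes` (filtered) and `report`, a data frame of
#'   per-stage counts (`stage`, `removed`, `retained`).
#' @export
qc_filter <- function(gm, maf_min = 0.01, snp_cr_min = 0.90,
                      sample_cr_min = 0.90) {
  report <- data.frame(stage = character(), unit = character(),
                       removed = integer(), retained = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, unit, removed, retained)
    rbind(report, data.frame(stage = stage, unit = unit,
                             removed = removed, retained = retained,
                             stringsAsFactors = FALSE))

  cr <- sample_call_rate(gm)
  keep_s <- cr >= sample_cr_min
  report <- note("sample_call_rate", "sample", sum(!keep_s), sum(keep_s))
  if (!any(keep_s)) stop("qc_filter: no samples left after sample call-rate filter")
  gm <- subset_genotypes(gm, samples = which(keep_s))

  cr <- snp_call_rate(gm)
  keep_m <- cr >= snp_cr_min
  report <- note("snp_call_rate", "snp", sum(!keep_m), sum(keep_m))
  if (!any(keep_m)) stop("qc_filter: no SNPs left after SNP call-rate filter")
  gm <- subset_genotypes(gm, snps = which(keep_m))

  maf <- snp_maf(gm)
  keep_m <- !is.na(maf) & maf >= maf_min
  report <- note("maf", "snp", sum(!keep_m), sum(keep_m))
  if (!any(keep_m)) stop("qc_filter: no SNPs left after MAF filter")
  gm <- subset_genotypes(gm, snps = which(keep_m))

  list(genotypes = gm, report = report)
}

#' Merge per-country genotype datasets
#'
#' Restricts all datasets to their common SNP set, reconciles allele
#' labels (a SNP whose `a1`/`a2` labels are swapped relative to the first
#' dataset is recoded by flipping calls; irreconcilable labels drop the
#' SNP with a log entry), concatenates the samples and re-applies
#' [qc_filter()] on the merged matrix.
#'
#' @param gms List of `genotype_matrix` objects.
#' @param requalify Re-run QC on the merged matrix (default `TRUE`).
#' @param ... Passed to [qc_filter()].
#' @return List with `genotypes`, `report` (the merged-QC report or
#'   `NULL`), and `dropped_snps` (irreconcilable allele labels).
#' @export
merge_datasets <- function(gms, requalify = TRUE, ...) {
  stopifnot(length(gms) >= 1L)
  if (length(gms) == 1L)
    return(list(genotypes = gms[[1L]], report = NULL,
                dropped_snps = character(0)))
  common <- Reduce(intersect, lapply(gms, function(g) g$map$snp))
  if (!length(common)) stop("merge_datasets: no SNPs shared by all datasets")
  ref <- subset_genotypes(gms[[1L]], snps = common)
  dropped <- character(0)
  parts <- list(ref)
  for (k in 2:length(gms)) {
    g <- subset_genotypes(gms[[k]], snps = common)
    same <- g$map$a1 == ref$map$a1 & g$map$a2 == ref$map$a2
    swap <- g$map$a1 == ref$map$a2 & g$map$a2 == ref$map$a1
    bad <- !(same | swap)
    if (any(swap)) {
      g$calls[, swap] <- 2L - g$calls[, swap]
      if (!is.null(g$phase))
        g$phase <- lapply(g$phase, function(h) {
          h[, swap] <- 1L - h[, swap]; h })
      g$map$a1[swap] <- ref$map$a1[swap]
      g$map$a2[swap] <- ref$map$a2[swap]
    }
    if (any(bad)) dropped <- union(dropped, common[bad])
    parts[[k]] <- g
  }
  if (length(dropped)) {
    keep <- setdiff(common, dropped)
    parts <- lapply(parts, subset_genotypes, snps = keep)
  }
  phase_ok <- all(vapply(parts, function(g) !is.null(g$phase), TRUE))
  merged <- genotype_matrix(
    do.call(rbind, lapply(parts, `[[`, "calls")),
    parts[[1L]]$map,
    do.call(rbind, lapply(parts, function(g)
      g$samples[, c("id", "breed", "country", "sex", "birth_year")])),
    phase = if (phase_ok)
      list(h1 = do.call(rbind, lapply(parts, function(g) g$phase$h1)),
           h2 = do.call(rbind, lapply(parts, function(g) g$phase$h2))))
  if (requalify) {
    qc <- qc_filter(merged, ...)
    list(genotypes = qc$genotypes, report = qc$report, dropped_snps = dropped)
  } else {
    list(genotypes = merged, report = NULL, dropped_snps = dropped)
  }
}
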