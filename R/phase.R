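#' Consistency of the gametic phase between two populations
#'
#' For every SNP pair (same chromosome, distance at most 1 Mb) shared by
#' two populations and polymorphic in both, the signed square root of
#' \eqn{r^2} (the sign being that of D) is computed in each population;
#' the profile reports, for nine distance classes, the Pearson
#' correlation of these signed values across populations.  A correlation
#' near 1 means the same allele combinations ride on the same haplotypes
#' in both populations — the condition for SNP effects to transfer in
#' across-population genomic evaluation.
#'
#' Before signing, allele orientation is harmonized: population B is
#' recoded to population A's allele labels wherever the labels are
#' swapped, and both are then oriented to the pooled major allele so the
#' sign of D refers to the same reference allele in both files.
#'
#' @param gm_a,gm_b `genotype_matrix` objects sharing a SNP namespace.
#' @param classes Data frame of distance classes (`lo_kb`, `hi_kb`,
#'   `class`); default [phase_distance_classes()].
#' @param max_dist Maximum pair distance in bp (default 1 Mb).
#' @param use_phase Use stored haplotypes where available (default).
#' @param min_pairs Classes with fewer shared pairs than this get an `NA`
#'   correlation and are flagged (default 3).
#' @return Data frame `class`, `lo_kb`, `hi_kb`, `correlation`,
#'   `n_pairs`, `defined`.
#' @export
phase_consistency <- function(gm_a, gm_b, classes = phase_distance_classes(),
                              max_dist = 1e6,
                              use_phase = !is.null(gm_a$phase) &&
                                !is.null(gm_b$phase),
                              min_pairs = 3L) {
  shared <- intersect(gm_a$map$snp, gm_b$map$snp)
  if (!length(shared)) stop("phase_consistency: no shared SNPs")
  A <- subset_genotypes(gm_a, snps = shared)
  B <- subset_genotypes(gm_b, snps = shared)

  # harmonize B's allele labels to A's
  swap <- B$map$a1 == A$map$a2 & B$map$a2 == A$map$a1
  if (any(swap)) {
    B$calls[, swap] <- 2L - B$calls[, swap]
    if (!is.null(B$phase))
      B$phase <- lapply(B$phase, function(h) { h[, swap] <- 1L - h[, swap]; h })
    B$map$a1[swap] <- A$map$a1[swap]
    B$map$a2[swap] <- A$map$a2[swap]
  }
  bad <- B$map$a1 != A$map$a1 | B$map$a2 != A$map$a2
  if (any(bad)) {
    keep <- which(!bad)
    A <- subset_genotypes(A, snps = keep)
    B <- subset_genotypes(B, snps = keep)
  }

  # orient both files to the pooled major allele
  p_pool <- (colSums(A$calls, na.rm = TRUE) + colSums(B$calls, na.rm = TRUE)) /
    (2 * (colSums(!is.na(A$calls)) + colSums(!is.na(B$calls))))
  flip <- !is.na(p_pool) & p_pool < 0.5
  for (nm in c("A", "B")) {
    G <- get(nm)
    G$calls[, flip] <- 2L - G$calls[, flip]
    if (!is.null(G$phase))
      G$phase <- lapply(G$phase, function(h) { h[, flip] <- 1L - h[, flip]; h })
    tmp <- G$map$a1[flip]; G$map$a1[flip] <- G$map$a2[flip]; G$map$a2[flip] <- tmp
    assign(nm, G)
  }

  pa <- ld_pairs_within(A, max_dist = max_dist, use_phase = use_phase)
  pb <- ld_pairs_within(B, max_dist = max_dist, use_phase = use_phase)
  key_a <- paste(pa$i, pa$j)
  key_b <- paste(pb$i, pb$j)
  m <- match(key_a, key_b)
  ok <- !is.na(m) & !is.na(pa$signed_r) & !is.na(pb$signed_r[m])
  d_kb <- pa$distance_bp[ok] / 1000
  ra <- pa$signed_r[ok]
  rb <- pb$signed_r[m[ok]]

  out <- classes
  out$correlation <- NA_real_
  out$n_pairs <- 0L
  for (k in seq_len(nrow(classes))) {
    sel <- d_kb > classes$lo_kb[k] & d_kb <= classes$hi_kb[k]
    out$n_pairs[k] <- sum(sel)
    if (sum(sel) >= min_pairs &&
        stats::sd(ra[sel]) > 0 && stats::sd(rb[sel]) > 0)
      out$correlation[k] <- stats::cor(ra[sel], rb[sel])
  }
  out$defined <- !is.na(out$correlation)
  out
}
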