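#' VanRaden genomic relationship matrix
#'
#' Method-1 genomic relationships: with \eqn{Z} the matrix of calls minus
#' twice the allele frequency (missing calls imputed to \eqn{2p_j}, i.e.
#' zero after centering), \eqn{G = ZZ' / (2\sum_j p_j(1-p_j))}.
#' Frequencies are computed from the analysed sample set; monomorphic
#' SNPs are excluded (they contribute no variance).
#'
#' @param gm A QC-passed (optionally pruned) `genotype_matrix`.
#' @return List with `G` (n x n symmetric, dimnames = animal ids), `p`
#'   (centering frequencies of the SNPs used) and `snps` (SNP ids used).
#' @export
grm <- function(gm) {
  p <- allele_freq(gm)
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("grm: all SNPs are monomorphic")
  calls <- gm$calls[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(calls, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(gm$samples$id, gm$samples$id)
  list(G = G, p = p, snps = gm$map$snp[keep])
}

#' Principal component analysis of a genomic relationship matrix
#'
#' Eigendecomposition of G; individual coordinates are the eigenvectors
#' scaled by the square root of their eigenvalues, and each component's
#' share of variance is its eigenvalue over the trace.  The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making coordinates reproducible across runs and platforms.
#'
#' @param g A [grm()] result or a symmetric numeric matrix.
#' @param n_components Number of leading components to return (default 10).
#' @return List with `coords` (n x k matrix), `variance_pct` (percent of
#'   total variance per returned component) and `eigenvalues` (all of
#'   them, sorted decreasing).
#' @export
pca_grm <- function(g, n_components = 10L) {
  G <- if (is.list(g)) g$G else g
  if (any(!is.finite(G))) stop("pca_grm: non-finite entries in G")
  n_components <- min(n_components, nrow(G))
  eg <- eigen(G, symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  lam <- pmax(vals[seq_len(n_components)], 0)
  coords <- sweep(vecs, 2L, sqrt(lam), `*`)
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords,
       variance_pct = 100 * vals[seq_len(n_components)] / sum(vals),
       eigenvalues = vals)
}

#' Genomic inbreeding from homozygosity excess
#'
#' Per animal, over its L non-missing (pruned) SNPs:
#' \deqn{F = (O_{hom} - E_{hom}) / (L - E_{hom})}
#' where \eqn{O_{hom}} is the observed homozygous count and
#' \eqn{E_{hom} = \sum_j (1 - 2 p_j (1 - p_j))} the Hardy-Weinberg
#' expectation at the sample allele frequencies (plug-in estimator,
#' no small-sample correction).  The GRM diagonal minus one is reported
#' alongside as a secondary estimator.
#'
#' @param gm A pruned `genotype_matrix`.
#' @param min_snps Animals with fewer non-missing SNPs than this are
#'   flagged `low_confidence` (default 100).
#' @return Data frame `id`, `F_het`, `F_grm`, `n_snps`, `low_confidence`.
#' @export
genomic_inbreeding <- function(gm, min_snps = 100L) {
  p <- allele_freq(gm)
  keep <- !is.na(p) & p > 0 & p < 1
  calls <- gm$calls[, keep, drop = FALSE]
  p <- p[keep]
  het_exp <- 2 * p * (1 - p)
  obs <- !is.na(calls)
  L <- rowSums(obs)
  O_hom <- rowSums(calls != 1L, na.rm = TRUE)
  E_hom <- obs %*% (1 - het_exp)
  F_het <- as.numeric((O_hom - E_hom) / (L - E_hom))
  g <- grm(subset_genotypes(gm, snps = which(keep)))
  data.frame(id = gm$samples$id, F_het = F_het,
             F_grm = diag(g$G) - 1, n_snps = L,
             low_confidence = L < min_snps,
             stringsAsFactors = FALSE)
}
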