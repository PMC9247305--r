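#' LD pruning by variance inflation factor
#'
#' Mirrors the classical `--indep` pruning of chip data: a sliding window
#' of `window_snps` SNPs advances by `step` SNPs along each chromosome;
#' within a window, the SNP with the largest variance inflation factor
#' (VIF, from the regression of the SNP on the other SNPs of the window)
#' is removed repeatedly until every remaining VIF is at most `vif_max`.
#' The retained set is deterministic: ties on VIF remove the SNP that
#' comes later on the map, and removals persist across windows.
#'
#' @param gm A QC-passed `genotype_matrix`.
#' @param window_snps Window size in SNPs (default 50).
#' @param step Window advance in SNPs (default 5).
#' @param vif_max Maximum tolerated VIF (default 2.0).
#' @return Integer vector of retained SNP column indices (sorted).
#' @export
ld_prune <- function(gm, window_snps = 50L, step = 5L, vif_max = 2.0) {
  stopifnot(window_snps >= 2L, step >= 1L, vif_max > 1)
  m <- ncol(gm$calls)
  removed <- rep(FALSE, m)
  # standardized, mean-imputed calls
  X <- apply(gm$calls, 2L, function(g) {
    mu <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu
    g - mu
  })
  sdx <- sqrt(colMeans(X^2))
  for (chrom in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == chrom)
    # monomorphic columns can't inflate anything; skip them
    poly <- idx[sdx[idx] > 0]
    if (length(poly) < 2L) next
    starts <- seq(1L, max(1L, length(poly) - 1L), by = step)
    for (s in starts) {
      win <- poly[s:min(s + window_snps - 1L, length(poly))]
      win <- win[!removed[win]]
      repeat {
        if (length(win) < 2L) break
        R <- stats::cor(X[, win, drop = FALSE])
        vif <- diag(solve_ridge(R))
        worst <- max(vif)
        if (worst <= vif_max) break
        # remove the later SNP among those attaining the worst VIF
        # (relative tolerance: perfect duplicates give two huge VIFs that
        # differ only in the last floating-point digits)
        drop_i <- max(which(vif >= worst * (1 - 1e-6)))
        removed[win[drop_i]] <- TRUE
        win <- win[-drop_i]
      }
    }
  }
  which(!removed & sdx > 0)
}

# inverse of a correlation matrix, ridge-stabilized so that perfectly
# collinear SNPs show up as huge (finite) VIFs instead of erroring
solve_ridge <- function(R, eps = 1e-8) {
  out <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)))
    out <- solve(R + diag(eps, nrow(R)))
  out
}
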