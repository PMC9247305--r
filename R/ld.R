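#' Two-locus haplotype frequency
#'
#' Estimates the frequency of the haplotype carrying the `a1` allele at
#' both loci.  With phased data (`use_phase = TRUE`) this is a direct
#' haplotype count.  From unphased genotypes the maximum-likelihood
#' estimate is obtained with the standard two-locus EM algorithm: only the
#' double heterozygotes are phase-ambiguous, and their expected split
#' between coupling (AB/ab) and repulsion (Ab/aB) is iterated from the
#' linkage-equilibrium start \eqn{p_{AB} = p_A p_B} until the estimate
#' moves by less than `tol`.
#'
#' Individuals missing a call at either locus are excluded; allele
#' frequencies are computed on the same complete-case set so that
#' \eqn{D = p_{AB} - p_A p_B} is internally consistent.
#'
#' @param gm A `genotype_matrix`.
#' @param i,j SNP column indices (or SNP ids).
#' @param use_phase Count haplotypes directly from `gm$phase` (default
#'   when phase is available).
#' @param tol EM convergence tolerance on `p_AB` (default 1e-10).
#' @param max_iter EM iteration cap (default 1000).
#' @return List with `p_AB`, `p_A`, `p_B`, `n` (individuals used),
#'   `iterations`, and `defined` (`FALSE` when a locus is monomorphic in
#'   the complete-case set, in which case `p_AB` is `NA`).
#' @export
haplotype_freq <- function(gm, i, j, use_phase = !is.null(gm$phase),
                           tol = 1e-10, max_iter = 1000L) {
  if (is.character(i)) i <- match(i, gm$map$snp)
  if (is.character(j)) j <- match(j, gm$map$snp)
  if (use_phase && is.null(gm$phase))
    stop("use_phase = TRUE but the genotype matrix carries no phase")
  if (use_phase) {
    h1 <- gm$phase$h1; h2 <- gm$phase$h2
    ok <- !is.na(h1[, i]) & !is.na(h1[, j]) & !is.na(h2[, i]) & !is.na(h2[, j])
    a <- c(h1[ok, i], h2[ok, i]); b <- c(h1[ok, j], h2[ok, j])
    n <- sum(ok)
    if (n < 2L) return(undefined_pair(n))
    p_A <- mean(a); p_B <- mean(b)
    if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
      return(undefined_pair(n, p_A, p_B))
    return(list(p_AB = mean(a == 1L & b == 1L), p_A = p_A, p_B = p_B,
                n = n, iterations = 0L, defined = TRUE))
  }
  g1 <- gm$calls[, i]; g2 <- gm$calls[, j]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2L) return(undefined_pair(n))
  p_A <- mean(g1) / 2; p_B <- mean(g2) / 2
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
    return(undefined_pair(n, p_A, p_B))
  # unambiguous AB haplotypes + the double-heterozygote split
  n_AB_known <- sum(2L * (g1 == 2L & g2 == 2L)) +
    sum(g1 == 2L & g2 == 1L) + sum(g1 == 1L & g2 == 2L)
  n_dh <- sum(g1 == 1L & g2 == 1L)
  p_AB <- p_A * p_B
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_Ab <- p_A - p_AB; p_aB <- p_B - p_AB; p_ab <- 1 - p_A - p_B + p_AB
    coup <- p_AB * p_ab; rep_ <- p_Ab * p_aB
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    p_new <- (n_AB_known + n_dh * w) / (2 * n)
    done <- abs(p_new - p_AB) < tol || iter >= max_iter || n_dh == 0L
    p_AB <- p_new
    if (done) break
  }
  list(p_AB = p_AB, p_A = p_A, p_B = p_B, n = n, iterations = iter,
       defined = TRUE)
}

undefined_pair <- function(n, p_A = NA_real_, p_B = NA_real_) {
  list(p_AB = NA_real_, p_A = p_A, p_B = p_B, n = n, iterations = 0L,
       defined = FALSE)
}

#' Pairwise linkage disequilibrium statistics
#'
#' Computes, for two SNPs on the same chromosome, the haplotype frequency
#' \eqn{p_{AB}}, the disequilibrium \eqn{D = p_{AB} - p_A p_B}, the
#' squared correlation \eqn{r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))} and the
#' signed square root \eqn{sign(D)\sqrt{r^2}} used for gametic-phase
#' comparisons, together with the inter-marker distance in base pairs.
#'
#' @inheritParams haplotype_freq
#' @return One-row data frame: `snp_i`, `snp_j`, `distance_bp`, `p_A`,
#'   `p_B`, `p_AB`, `D`, `r2`, `signed_r`, `n`.  `r2`/`signed_r` are `NA`
#'   when a locus is monomorphic.
#' @export
ld_pair <- function(gm, i, j, use_phase = !is.null(gm$phase)) {
  if (is.character(i)) i <- match(i, gm$map$snp)
  if (is.character(j)) j <- match(j, gm$map$snp)
  if (gm$map$chrom[i] != gm$map$chrom[j])
    stop("ld_pair: SNPs lie on different chromosomes")
  hf <- haplotype_freq(gm, i, j, use_phase = use_phase)
  d <- abs(gm$map$bp[i] - gm$map$bp[j])
  if (!hf$defined)
    return(data.frame(snp_i = gm$map$snp[i], snp_j = gm$map$snp[j],
                      distance_bp = d, p_A = hf$p_A, p_B = hf$p_B,
                      p_AB = NA_real_, D = NA_real_, r2 = NA_real_,
                      signed_r = NA_real_, n = hf$n,
                      stringsAsFactors = FALSE))
  D <- hf$p_AB - hf$p_A * hf$p_B
  denom <- hf$p_A * (1 - hf$p_A) * hf$p_B * (1 - hf$p_B)
  r2 <- min(D * D / denom, 1)
  data.frame(snp_i = gm$map$snp[i], snp_j = gm$map$snp[j],
             distance_bp = d, p_A = hf$p_A, p_B = hf$p_B, p_AB = hf$p_AB,
             D = D, r2 = r2, signed_r = sign(D) * sqrt(r2), n = hf$n,
             stringsAsFactors = FALSE)
}

#' All within-chromosome LD pairs up to a maximum distance
#'
#' Workhorse shared by [ld_decay()] and [phase_consistency()].  With
#' phased data the full pairwise table is computed by matrix
#' cross-products over the haplotypes; from unphased genotypes each pair
#' goes through the two-locus EM (slower, but exact for the model).
#'
#' @inheritParams haplotype_freq
#' @param max_dist Maximum inter-SNP distance in bp (default 1e6).
#' @return Data frame `i`, `j` (column indices with `i < j`), `chrom`,
#'   `distance_bp`, `r2`, `signed_r`; pairs involving a monomorphic SNP
#'   have `NA` statistics.
#' @export
ld_pairs_within <- function(gm, max_dist = 1e6,
                            use_phase = !is.null(gm$phase)) {
  out <- list()
  for (chrom in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == chrom)
    if (length(idx) < 2L) next
    bp <- gm$map$bp[idx]
    pr <- which(outer(bp, bp, function(a, b) {
      d <- b - a; d > 0 & d <= max_dist
    }), arr.ind = TRUE)
    pr <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]
    if (!nrow(pr)) next
    if (use_phase) {
      H <- rbind(gm$phase$h1[, idx, drop = FALSE],
                 gm$phase$h2[, idx, drop = FALSE])
      p <- colMeans(H)
      v <- p * (1 - p)
      PAB <- crossprod(H) / nrow(H)
      D <- PAB - outer(p, p)
      denom <- outer(v, v)
      sr <- D / sqrt(denom)           # signed r
      sr[denom == 0] <- NA_real_
      srv <- sr[pr]
      r2v <- pmin(srv * srv, 1)
      srv <- sign(srv) * sqrt(r2v)
    } else {
      srv <- r2v <- numeric(nrow(pr))
      for (k in seq_len(nrow(pr))) {
        st <- ld_pair(gm, idx[pr[k, 1L]], idx[pr[k, 2L]], use_phase = FALSE)
        r2v[k] <- st$r2; srv[k] <- st$signed_r
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      i = idx[pr[, 1L]], j = idx[pr[, 2L]], chrom = chrom,
      distance_bp = bp[pr[, 2L]] - bp[pr[, 1L]],
      r2 = r2v, signed_r = srv)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), chrom = character(),
                      distance_bp = numeric(), r2 = numeric(),
                      signed_r = numeric()))
  do.call(rbind, out)
}

#' LD decay curve
#'
#' Bins all within-chromosome SNP pairs up to `max_dist` into `n_bins`
#' equal-width distance classes (by default 50 classes of 20 kb over
#' (0, 1 Mb]) and reports the mean \eqn{r^2} per class.  Each class is
#' labelled by the median distance of the pairs it contains; empty
#' classes are labelled by their midpoint and flagged.
#'
#' @inheritParams ld_pairs_within
#' @param n_bins Number of distance classes (default 50).
#' @return List with `curve` (data frame `bin`, `lo_bp`, `hi_bp`,
#'   `label_bp`, `mean_r2`, `n_pairs`, `empty`), `n_pairs` (pairs used)
#'   and `n_undefined` (pairs skipped for monomorphism).
#' @export
ld_decay <- function(gm, max_dist = 1e6, n_bins = 50L,
                     use_phase = !is.null(gm$phase)) {
  pairs <- ld_pairs_within(gm, max_dist = max_dist, use_phase = use_phase)
  undef <- is.na(pairs$r2)
  pairs <- pairs[!undef, , drop = FALSE]
  width <- max_dist / n_bins
  lo <- (seq_len(n_bins) - 1L) * width
  hi <- lo + width
  bin <- ceiling(pairs$distance_bp / width)
  bin[bin < 1L] <- 1L
  curve <- data.frame(bin = seq_len(n_bins), lo_bp = lo, hi_bp = hi,
                      label_bp = NA_real_, mean_r2 = NA_real_,
                      n_pairs = 0L, empty = TRUE)
  if (nrow(pairs)) {
    agg_n <- tapply(pairs$r2, bin, length)
    agg_m <- tapply(pairs$r2, bin, mean)
    agg_d <- tapply(pairs$distance_bp, bin, stats::median)
    at <- as.integer(names(agg_n))
    curve$n_pairs[at] <- as.integer(agg_n)
    curve$mean_r2[at] <- as.numeric(agg_m)
    curve$label_bp[at] <- as.numeric(agg_d)
    curve$empty[at] <- FALSE
  }
  curve$label_bp[curve$empty] <- (lo[curve$empty] + hi[curve$empty]) / 2
  list(curve = curve, n_pairs = sum(curve$n_pairs), n_undefined = sum(undef))
}

#' The nine standard distance classes for gametic-phase profiles (kb)
#' @return Data frame `class`, `lo_kb`, `hi_kb`.
#' @export
phase_distance_classes <- function() {
  lo <- c(0, 1, 10, 20, 40, 60, 100, 200, 500)
  hi <- c(1, 10, 20, 40, 60, 100, 200, 500, 1000)
  data.frame(class = sprintf("(%g,%g]", lo, hi), lo_kb = lo, hi_kb = hi,
             stringsAsFactors = FALSE)
}
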