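#' Balding-Nichols population allele frequencies
#'
#' Draws ancestral allele frequencies uniformly on [0.05, 0.95] and, for
#' each population p with divergence F, per-SNP frequencies from
#' \deqn{Beta(p_j (1-F)/F,\; (1-p_j)(1-F)/F)} — the Balding-Nichols
#' model, whose mean is the ancestral frequency and whose variance is
#' \eqn{p_j(1-p_j) F}.  Frequencies are clipped to [0.01, 0.99].
#'
#' @param spec A `population_spec`.
#' @return List with `ancestral` (length-m vector), `populations`
#'   (populations x m matrix, rownames are population labels) and `map`
#'   (the marker map).
#' @export
draw_population_frequencies <- function(spec) {
  spec <- validate_population_spec(spec)
  map <- spec_marker_map(spec)
  m <- nrow(map)
  fst <- resolve_fst(spec)
  pops <- names(fst)
  ancestral <- with_stream(spec$seed, 1L, stats::runif(m, 0.05, 0.95))
  freqs <- matrix(NA_real_, length(pops), m, dimnames = list(pops, map$snp))
  for (i in seq_along(pops)) {
    F <- fst[i]
    shape_scale <- (1 - F) / F
    freqs[i, ] <- with_stream(spec$seed, 100L + i, stats::rbeta(
      m, ancestral * shape_scale, (1 - ancestral) * shape_scale))
  }
  freqs <- pmin(pmax(freqs, 0.01), 0.99)
  list(ancestral = ancestral, populations = freqs, map = map)
}

#' Founder haplotypes as mosaics of ancestral templates
#'
#' Per population, `n_ancestral_haplotypes` template haplotypes are drawn
#' site-independently from that population's allele frequencies; each
#' founder haplotype then copies from one template at a time, switching
#' to a uniformly chosen template between adjacent SNPs with probability
#' \eqn{1 - \exp(-\lambda d)} where d is the inter-SNP distance in bp.
#' The finite template pool plus the distance-dependent switching is what
#' gives founders pairwise \eqn{r^2} that decays with physical distance.
#'
#' @param spec A `population_spec`.
#' @param pop_freqs Result of [draw_population_frequencies()].
#' @return Named list (per population) of 0/1 haplotype matrices with
#'   `2 * n_founders` rows; attribute `templates` holds the template
#'   pools.  With a single template the founders are identical and every
#'   locus is monomorphic: the matrix carries attribute
#'   `monomorphic = TRUE`.
#' @export
simulate_founder_haplotypes <- function(spec, pop_freqs) {
  spec <- validate_population_spec(spec)
  map <- pop_freqs$map
  m <- nrow(map)
  n_hap <- 2L * spec$n_founders
  n_tpl <- spec$n_ancestral_haplotypes
  gaps <- diff(map$bp)
  gaps[diff(map$chrom) != 0] <- Inf      # chromosomes switch independently
  p_switch <- 1 - exp(-spec$mosaic_switch_rate * gaps)
  p_switch[!is.finite(gaps)] <- 1
  pops <- rownames(pop_freqs$populations)
  out <- vector("list", length(pops))
  names(out) <- pops
  for (k in seq_along(pops)) {
    out[[k]] <- with_stream(spec$seed, 200L + k, {
      tpl <- matrix(stats::rbinom(n_tpl * m, 1L,
                                  rep(pop_freqs$populations[k, ], each = n_tpl)),
                    n_tpl, m)
      H <- matrix(0L, n_hap, m)
      for (h in seq_len(n_hap)) {
        switches <- c(TRUE, stats::runif(m - 1L) < p_switch)
        seg <- cumsum(switches)
        tid <- sample.int(n_tpl, max(seg), replace = TRUE)[seg]
        H[h, ] <- tpl[cbind(tid, seq_len(m))]
      }
      attr(H, "templates") <- tpl
      if (n_tpl == 1L) attr(H, "monomorphic") <- TRUE
      H
    })
  }
  out
}
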