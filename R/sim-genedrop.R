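#' Gene dropping: transmit haplotypes down a pedigree
#'
#' Founders of each population receive the supplied founder haplotypes in
#' order; every non-founder receives one recombined gamete from each
#' parent.  Recombination follows the Haldane model: the number of
#' crossovers per chromosome is Poisson with mean `recomb_rate *
#' chrom_length_bp`, crossover positions are uniform, and the gamete
#' alternates between the parent's two haplotypes across crossovers
#' (starting haplotype chosen at random).  Phase is retained: `h1` is the
#' paternal, `h2` the maternal haplotype.
#'
#' @param spec A `population_spec`.
#' @param registry Master pedigree as produced by [simulate_pedigree()]
#'   (columns `id`, `sire`, `dam`, `population`), parents before
#'   offspring; a cycle is a structural error.
#' @param founder_haps Named list (population label -> `2 * n_founders` x
#'   m 0/1 matrix) from [simulate_founder_haplotypes()].
#' @param map Marker map (defaults to [spec_marker_map()]).
#' @return List with `h1`, `h2` (n x m 0/1 matrices, rownames = animal
#'   ids) and `map`.
#' @export
gene_drop <- function(spec, registry, founder_haps,
                      map = spec_marker_map(spec)) {
  spec <- validate_population_spec(spec)
  with_stream(spec$seed, 4L, gene_drop_impl(spec, registry, founder_haps, map))
}

gene_drop_impl <- function(spec, registry, founder_haps, map) {
  ord <- pedigree_order(registry)      # errors on cycles
  registry <- registry[ord, , drop = FALSE]
  n <- nrow(registry)
  m <- nrow(map)
  ids <- registry$id
  sire <- match(registry$sire, ids)
  dam <- match(registry$dam, ids)
  h1 <- matrix(0L, n, m, dimnames = list(ids, map$snp))
  h2 <- matrix(0L, n, m, dimnames = list(ids, map$snp))

  # chromosome bookkeeping for gamete formation
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_bp <- lapply(chrom_idx, function(ix) map$bp[ix])
  mean_xo <- spec$recomb_rate * spec$chrom_length_bp

  gamete <- function(a, b) {
    g <- integer(m)
    for (ci in seq_along(chroms)) {
      ix <- chrom_idx[[ci]]
      k <- stats::rpois(1L, mean_xo)
      start <- stats::runif(1) < 0.5
      if (k == 0L) {
        g[ix] <- if (start) a[ix] else b[ix]
      } else {
        xo <- sort(stats::runif(k, 0, spec$chrom_length_bp))
        seg <- findInterval(chrom_bp[[ci]], xo)
        use_a <- (seg %% 2L == 0L) == start   # alternate across crossovers
        g[ix] <- ifelse(use_a, a[ix], b[ix])
      }
    }
    g
  }

  fcount <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (is.na(sire[i]) && is.na(dam[i])) {
      pop <- registry$population[i]
      used <- get0(pop, envir = fcount, ifnotfound = 0L)
      H <- founder_haps[[pop]]
      if (is.null(H))
        stop("gene_drop: no founder haplotypes for population ", pop)
      if (2L * used + 2L > nrow(H))
        stop("gene_drop: founder pool of ", pop, " exhausted")
      h1[i, ] <- H[2L * used + 1L, ]
      h2[i, ] <- H[2L * used + 2L, ]
      assign(pop, used + 1L, envir = fcount)
    } else if (!is.na(sire[i]) && !is.na(dam[i])) {
      h1[i, ] <- gamete(h1[sire[i], ], h2[sire[i], ])
      h2[i, ] <- gamete(h1[dam[i], ], h2[dam[i], ])
    } else {
      # one known parent: the unknown side contributes a fresh founder gamete
      pop <- registry$population[i]
      H <- founder_haps[[pop]]
      ghost <- H[sample.int(nrow(H), 1L), ]
      if (!is.na(sire[i])) {
        h1[i, ] <- gamete(h1[sire[i], ], h2[sire[i], ])
        h2[i, ] <- ghost
      } else {
        h1[i, ] <- ghost
        h2[i, ] <- gamete(h1[dam[i], ], h2[dam[i], ])
      }
    }
  }
  list(h1 = h1, h2 = h2, map = map)
}

#' Count Mendelian violations in gene-dropped haplotypes
#'
#' Under gene dropping the paternal haplotype of every offspring must,
#' at each SNP, carry an allele present in the sire (and likewise the
#' maternal haplotype for the dam).  Returns the number of
#' (animal, SNP, side) entries violating this — zero for a correct
#' transmission model.
#'
#' @param drop A [gene_drop()] result.
#' @param registry The pedigree used for the drop.
#' @return Integer count of violations.
#' @export
mendelian_violations <- function(drop, registry) {
  ids <- rownames(drop$h1)
  sire <- match(registry$sire, ids)
  dam <- match(registry$dam, ids)
  self <- match(registry$id, ids)
  bad <- 0L
  for (i in seq_along(self)) {
    if (!is.na(sire[i])) {
      ok <- drop$h1[self[i], ] == drop$h1[sire[i], ] |
        drop$h1[self[i], ] == drop$h2[sire[i], ]
      bad <- bad + sum(!ok)
    }
    if (!is.na(dam[i])) {
      ok <- drop$h2[self[i], ] == drop$h1[dam[i], ] |
        drop$h2[self[i], ] == drop$h2[dam[i], ]
      bad <- bad + sum(!ok)
    }
  }
  bad
}
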