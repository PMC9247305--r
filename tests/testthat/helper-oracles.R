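# Independent oracles and small generators shared across the suite.

# Numerator relationship matrix by the tabular recursion (Wright/Emik-Terrill):
# A[i,i] = 1 + 0.5 * A[s,d]; A[i,j] = 0.5 * (A[j,s] + A[j,d]) for j < i.
# sire/dam are integer indices (0 = unknown), parents before offspring.
tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1L) for (j in seq_len(i - 1L)) {
      aij <- 0
      if (s > 0) aij <- aij + 0.5 * A[j, s]
      if (d > 0) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# map integer parent indices (0 = unknown) onto id strings, keeping
# alignment (plain ids[idx] would drop the zeros and shift everything)
parent_ids <- function(ids, idx) {
  out <- rep(NA_character_, length(idx))
  out[idx > 0] <- ids[idx[idx > 0]]
  out
}

# r^2 from an exhaustive haplotype table (phased 0/1 allele vectors)
brute_r2 <- function(hap_a, hap_b) {
  p_A <- mean(hap_a); p_B <- mean(hap_b)
  p_AB <- mean(hap_a == 1 & hap_b == 1)
  D <- p_AB - p_A * p_B
  D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
}

# Hudson-style FST from two populations' 0/1/2 call matrices
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  n1 <- nrow(g1); n2 <- nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# multi-population Balding-Nichols genotypes drawn straight from the
# population frequencies (site-independent, HWE within population)
bn_calls <- function(seed, n_pops, n_per, m, fst) {
  cc <- sprintf("P%02d", seq_len(n_pops))
  spec <- population_spec(
    breeds = "POP", countries = cc, n_founders = 2L, fst = fst,
    n_snps = m, n_chromosomes = 1L, seed = seed,
    export_rate = matrix(0, n_pops, n_pops, dimnames = list(cc, cc)))
  P <- draw_population_frequencies(spec)$populations
  withr::with_seed(seed, {
    calls <- do.call(rbind, lapply(seq_len(n_pops), function(p)
      matrix(stats::rbinom(n_per * m, 2L, rep(P[p, ], each = n_per)),
             n_per, m)))
    storage.mode(calls) <- "integer"
    calls
  })
}

# wrap a call matrix into a genotype_matrix on a uniform 1-chromosome map
as_gm <- function(calls, spacing_bp = 1e4, phase = NULL,
                  breed = "POP", country = "XXX") {
  m <- ncol(calls)
  n <- nrow(calls)
  map <- data.frame(snp = sprintf("s%05d", seq_len(m)), chrom = 1L,
                    bp = spacing_bp * seq_len(m), a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  ids <- standardize_id(seq_len(n) + 1000000L, breed,
                        if (nchar(country) == 3) country else "XXX",
                        rep(c("F", "M"), length.out = n))
  samples <- data.frame(id = ids, breed = breed, country = country,
                        sex = rep(c("F", "M"), length.out = n),
                        birth_year = 2010L, stringsAsFactors = FALSE)
  genotype_matrix(calls, map, samples, phase = phase)
}

# two populations gene-dropped from shared founders, with `gens`
# generations of separate random mating; returns list of phased
# genotype_matrix objects sharing one map
shared_founder_pops <- function(seed, n_founders = 40L, gens = 25L,
                                m = 120L, chrom_len = 2.4e6,
                                n_templates = 8L) {
  cc <- c("AAA", "BBB")
  spec <- population_spec(
    breeds = "POP", countries = cc, n_founders = n_founders,
    n_generations = gens, fst = 0.05, n_snps = m, n_chromosomes = 1L,
    chrom_length_bp = chrom_len, n_ancestral_haplotypes = n_templates,
    mosaic_switch_rate = 2e-6, seed = seed,
    export_rate = matrix(0, 2, 2, dimnames = list(cc, cc)))
  freqs <- draw_population_frequencies(spec)
  # one shared founder pool: both populations use POP.AAA haplotypes
  haps <- simulate_founder_haplotypes(spec, freqs)
  haps[["POP.BBB"]] <- haps[["POP.AAA"]]
  ped <- simulate_pedigree(spec)
  drop <- gene_drop(spec, ped$registry, haps, map = freqs$map)
  reg <- ped$registry[match(rownames(drop$h1), ped$registry$id), ]
  out <- lapply(cc, function(ct) {
    sel <- which(reg$origin == ct & reg$generation == max(reg$generation))
    h1 <- drop$h1[sel, , drop = FALSE]; h2 <- drop$h2[sel, , drop = FALSE]
    genotype_matrix(h1 + h2, freqs$map,
                    data.frame(id = reg$id[sel], breed = "POP",
                               country = ct, sex = reg$sex[sel],
                               birth_year = reg$birth_year[sel],
                               stringsAsFactors = FALSE),
                    phase = list(h1 = h1, h2 = h2))
  })
  names(out) <- cc
  out
}

# small default dataset reused by several files
tiny_sim <- function(seed = 11L, n_founders = 16L, n_generations = 3L,
                     n_snps = 60L, n_chromosomes = 2L,
                     chrom_length_bp = 2e6, ...) {
  simulate_dataset(population_spec(n_founders = n_founders,
                                   n_generations = n_generations,
                                   n_snps = n_snps,
                                   n_chromosomes = n_chromosomes,
                                   chrom_length_bp = chrom_length_bp,
                                   seed = seed, ...))
}
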