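# phased toy with known haplotype counts: AB = 40, Ab = 10, aB = 10, ab = 40
phased_toy <- function() {
  h_a <- c(rep(1L, 40), rep(1L, 10), rep(0L, 10), rep(0L, 40))
  h_b <- c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 40))
  # 50 diploids: haplotypes paired in order
  odd <- seq(1, 99, 2); even <- odd + 1
  h1 <- cbind(h_a[odd], h_b[odd]); h2 <- cbind(h_a[even], h_b[even])
  as_gm(h1 + h2, phase = list(h1 = h1, h2 = h2))
}

test_that("haplotype frequencies: direct counting and EM limits", {
  gm <- phased_toy()
  hf <- haplotype_freq(gm, 1, 2, use_phase = TRUE)
  expect_equal(hf$p_AB, 0.40)
  expect_equal(hf$p_A, 0.5)

  # without double heterozygotes the EM lands on the counting estimate in
  # one pass
  calls <- rbind(c(2L, 2L), c(0L, 0L), c(2L, 0L), c(0L, 2L), c(1L, 2L))
  gm2 <- as_gm(calls)
  hf2 <- haplotype_freq(gm2, 1, 2, use_phase = FALSE)
  # haplotypes directly countable: 10 haplotypes, AB = 2 + 0 + 0 + 1 = 3
  expect_equal(hf2$p_AB, 0.3)
  expect_identical(hf2$iterations, 1L)

  # monomorphic locus -> undefined, flagged
  mono <- as_gm(cbind(rep(2L, 6), rep(c(0L, 1L, 2L), 2)))
  expect_false(haplotype_freq(mono, 1, 2, use_phase = FALSE)$defined)
})

test_that("ld_pair reproduces the hand-computed worked examples", {
  gm <- phased_toy()
  st <- ld_pair(gm, 1, 2, use_phase = TRUE)
  # p_A = p_B = 0.5, p_AB = 0.40: D = 0.15, r2 = 0.36, signed r = 0.6
  expect_equal(st$D, 0.15)
  expect_equal(st$r2, 0.36)
  expect_equal(st$signed_r, 0.6)
  expect_equal(st$distance_bp, 1e4)

  # complete LD: p_AB = p_A = p_B = 0.5 -> D = 0.25, r2 = 1, signed r = 1
  h <- cbind(rep(c(1L, 0L), 20), rep(c(1L, 0L), 20))
  gm2 <- as_gm(h[seq(1, 39, 2), ] + h[seq(2, 40, 2), ],
               phase = list(h1 = h[seq(1, 39, 2), ], h2 = h[seq(2, 40, 2), ]))
  st2 <- ld_pair(gm2, 1, 2, use_phase = TRUE)
  expect_equal(st2$D, 0.25)
  expect_equal(st2$r2, 1)
  expect_equal(st2$signed_r, 1)

  # linkage equilibrium: p_AB = p_A p_B -> D = 0, r2 = 0
  h_a <- rep(c(1L, 1L, 0L, 0L), 25); h_b <- rep(c(1L, 0L, 1L, 0L), 25)
  odd <- seq(1, 99, 2); even <- odd + 1
  gm3 <- as_gm(cbind(h_a[odd] + h_a[even], h_b[odd] + h_b[even]),
               phase = list(h1 = cbind(h_a[odd], h_b[odd]),
                            h2 = cbind(h_a[even], h_b[even])))
  st3 <- ld_pair(gm3, 1, 2, use_phase = TRUE)
  expect_equal(st3$D, 0)
  expect_equal(st3$r2, 0)
  expect_equal(st3$signed_r, 0)

  expect_error(ld_pair(tiny_sim(5L)$genotypes$FRA, 1,
                       61),   # SNP 61 sits on chromosome 2
               "different chromosomes")
})

test_that("phased ld_pair equals brute-force haplotype-table computation", {
  sim <- tiny_sim(seed = 41L, missing_rate = 0)
  gm <- sim$genotypes$FRA
  H1 <- gm$phase$h1; H2 <- gm$phase$h2
  idx <- which(gm$map$chrom == 1)
  maf <- snp_maf(gm)
  poly <- idx[maf[idx] > 0][1:10]
  for (a in poly[1:5]) for (b in poly[6:10]) {
    st <- ld_pair(gm, a, b, use_phase = TRUE)
    oracle <- brute_r2(c(H1[, a], H2[, a]), c(H1[, b], H2[, b]))
    expect_lt(abs(st$r2 - oracle), 1e-12)
    expect_lt(abs(st$signed_r^2 - st$r2), 1e-12)
  }
})

test_that("EM from unphased genotypes recovers the phased truth", {
  # large founder population with mosaic LD, no missingness
  cc <- "AAA"
  spec <- population_spec(breeds = "POP", countries = cc,
                          n_founders = 500L, n_snps = 30L,
                          n_chromosomes = 1L, chrom_length_bp = 6e5,
                          n_ancestral_haplotypes = 6L,
                          mosaic_switch_rate = 2e-6, seed = 19L,
                          export_rate = matrix(0, 1, 1,
                                               dimnames = list(cc, cc)))
  freqs <- draw_population_frequencies(spec)
  H <- simulate_founder_haplotypes(spec, freqs)[["POP.AAA"]]
  h1 <- H[seq(1, nrow(H), 2), ]; h2 <- H[seq(2, nrow(H), 2), ]
  gm <- as_gm(h1 + h2, phase = list(h1 = h1, h2 = h2))
  poly <- which(snp_maf(gm) >= 0.05)
  diffs <- c()
  for (a in poly) for (b in poly) {
    if (b <= a) next
    em <- haplotype_freq(gm, a, b, use_phase = FALSE)
    ph <- haplotype_freq(gm, a, b, use_phase = TRUE)
    diffs <- c(diffs, abs(em$p_AB - ph$p_AB))
  }
  expect_gte(mean(diffs < 0.02), 0.99)
})

test_that("ld_decay bins pairs into labelled distance classes", {
  # 3 SNPs at 10 / 30 / 900 kb: pairs at 20, 870, 890 kb
  h <- matrix(rep(c(1L, 0L), 30), ncol = 3)
  gm <- as_gm(h[seq(1, 19, 2), ] + h[seq(2, 20, 2), ],
              phase = list(h1 = h[seq(1, 19, 2), ], h2 = h[seq(2, 20, 2), ]))
  gm$map$bp <- c(10e3, 30e3, 900e3)
  gm <- genotype_matrix(gm$calls, gm$map, gm$samples, gm$phase)
  dec <- ld_decay(gm, use_phase = TRUE)
  expect_identical(dec$curve$n_pairs[1], 1L)    # (0, 20] kb
  expect_identical(dec$curve$n_pairs[44], 1L)   # (860, 880] kb
  expect_identical(dec$curve$n_pairs[45], 1L)   # (880, 900] kb
  expect_identical(sum(dec$curve$n_pairs), 3L)
  expect_equal(dec$curve$label_bp[1], 20e3)
  expect_true(all(dec$curve$empty[c(2, 10, 50)]))

  # no pairs within range -> empty curve with zero counts
  gm2 <- subset_genotypes(gm, snps = 1L)
  dec2 <- ld_decay(gm2, use_phase = TRUE)
  expect_identical(sum(dec2$curve$n_pairs), 0L)
})

test_that("simulated founder LD decays with distance; limits behave", {
  first_last <- sapply(1:5, function(s) {
    cc <- "AAA"
    spec <- population_spec(breeds = "POP", countries = cc,
                            n_founders = 80L, n_snps = 150L,
                            n_chromosomes = 1L, chrom_length_bp = 1.5e6,
                            n_ancestral_haplotypes = 10L,
                            mosaic_switch_rate = 1e-6, seed = s,
                            export_rate = matrix(0, 1, 1,
                                                 dimnames = list(cc, cc)))
    freqs <- draw_population_frequencies(spec)
    H <- simulate_founder_haplotypes(spec, freqs)[["POP.AAA"]]
    h1 <- H[seq(1, nrow(H), 2), ]; h2 <- H[seq(2, nrow(H), 2), ]
    gm <- as_gm(h1 + h2, phase = list(h1 = h1, h2 = h2))
    pr <- ld_pairs_within(gm, use_phase = TRUE)
    near <- pr$distance_bp > 1e4 & pr$distance_bp <= 2e4
    far <- pr$distance_bp > 5e5 & pr$distance_bp <= 1e6
    c(mean(pr$r2[near], na.rm = TRUE), mean(pr$r2[far], na.rm = TRUE))
  })
  # averaged over seeds, r2 in (10, 20] kb exceeds r2 in (500, 1000] kb
  expect_gt(mean(first_last[1, ]), mean(first_last[2, ]))

  # switch rate -> infinity: no distance structure beyond pool sharing
  cc <- "AAA"
  spec <- population_spec(breeds = "POP", countries = cc, n_founders = 150L,
                          n_snps = 120L, n_chromosomes = 1L,
                          chrom_length_bp = 1.2e6,
                          n_ancestral_haplotypes = 10L,
                          mosaic_switch_rate = 1, seed = 2L,
                          export_rate = matrix(0, 1, 1,
                                               dimnames = list(cc, cc)))
  freqs <- draw_population_frequencies(spec)
  H <- simulate_founder_haplotypes(spec, freqs)[["POP.AAA"]]
  h1 <- H[seq(1, nrow(H), 2), ]; h2 <- H[seq(2, nrow(H), 2), ]
  gm <- as_gm(h1 + h2, phase = list(h1 = h1, h2 = h2))
  pr <- ld_pairs_within(gm, use_phase = TRUE)
  adj <- pr$distance_bp <= 2e4
  far <- pr$distance_bp > 9e5
  expect_lt(abs(mean(pr$r2[adj], na.rm = TRUE) -
                  mean(pr$r2[far], na.rm = TRUE)), 0.02)

  # a single ancestral template -> founders identical, all loci monomorphic
  spec1 <- population_spec(breeds = "POP", countries = cc, n_founders = 20L,
                           n_snps = 40L, n_chromosomes = 1L,
                           n_ancestral_haplotypes = 1L, seed = 3L,
                           export_rate = matrix(0, 1, 1,
                                                dimnames = list(cc, cc)))
  freqs1 <- draw_population_frequencies(spec1)
  H1 <- simulate_founder_haplotypes(spec1, freqs1)[["POP.AAA"]]
  expect_true(isTRUE(attr(H1, "monomorphic")))
  expect_identical(nrow(unique(H1)), 1L)
  gm1 <- as_gm(H1[seq(1, 39, 2), ] + H1[seq(2, 40, 2), ])
  expect_false(haplotype_freq(gm1, 1, 2, use_phase = FALSE)$defined)
})
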