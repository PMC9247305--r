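test_that("an animal homozygous at every SNP has F_het = 1", {
  calls <- bn_calls(3, 1, 40, 500, 0.2)
  calls[1, ] <- ifelse(calls[1, ] == 1L, 2L, calls[1, ])
  f <- genomic_inbreeding(as_gm(calls))
  expect_equal(f$F_het[1], 1)
  expect_false(f$low_confidence[1])
})

test_that("unrelated HWE samples average F_het near zero", {
  calls <- bn_calls(5, 1, 500, 5000, 0.2)
  f <- genomic_inbreeding(as_gm(calls))
  expect_lt(abs(mean(f$F_het)), 0.02)
  # the GRM-diagonal secondary estimator is present and centred too
  expect_lt(abs(mean(f$F_grm)), 0.05)
})

test_that("full-sib offspring average F_het near 0.25 in gene-dropped data", {
  # one population: 100 background founders plus 50 independent families
  # (founder pair -> full sibs -> inbred offspring), site-independent
  # founder haplotypes so the background sample is in HWE
  cc <- "AAA"
  m <- 1000L
  spec <- population_spec(breeds = "POP", countries = cc, n_founders = 2L,
                          n_snps = m, n_chromosomes = 1L,
                          chrom_length_bp = 1e7, seed = 77L,
                          export_rate = matrix(0, 1, 1,
                                               dimnames = list(cc, cc)))
  p <- draw_population_frequencies(spec)$populations[1, ]
  n_bg <- 100L; n_fam <- 50L
  n_founders <- n_bg + 2L * n_fam
  H <- withr::with_seed(7, matrix(stats::rbinom(2L * n_founders * m, 1L,
                                                rep(p, each = 2L * n_founders)),
                                  2L * n_founders, m))
  ids <- sprintf("A%04d", seq_len(n_founders + 3L * n_fam))
  sire <- dam <- rep(NA_character_, length(ids))
  sex <- rep(c("M", "F"), length.out = length(ids))
  k <- n_founders
  for (fam in seq_len(n_fam)) {
    f1 <- ids[n_bg + 2L * fam - 1L]; f2 <- ids[n_bg + 2L * fam]
    sib1 <- ids[k + 1L]; sib2 <- ids[k + 2L]; child <- ids[k + 3L]
    sire[k + 1L] <- f1; dam[k + 1L] <- f2; sex[k + 1L] <- "M"
    sire[k + 2L] <- f1; dam[k + 2L] <- f2; sex[k + 2L] <- "F"
    sire[k + 3L] <- sib1; dam[k + 3L] <- sib2
    k <- k + 3L
  }
  registry <- data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                         population = "POP.AAA", stringsAsFactors = FALSE)
  drop <- gene_drop(spec, registry, list(POP.AAA = H))
  children <- ids[n_founders + 3L * seq_len(n_fam)]
  sel_bg <- ids[seq_len(n_bg)]
  keep <- c(sel_bg, children)
  h1 <- drop$h1[keep, ]; h2 <- drop$h2[keep, ]
  gm <- as_gm(h1 + h2, phase = list(h1 = h1, h2 = h2))
  f <- genomic_inbreeding(gm)
  f_children <- f$F_het[match(children, keep)]
  expect_lt(abs(mean(f_children) - 0.25), 0.05)
  # pedigree expectation agrees: these are offspring of full sibs
  expect_lt(abs(mean(f$F_het[seq_len(n_bg)])), 0.05)
})

test_that("animals with few informative SNPs are flagged low-confidence", {
  calls <- bn_calls(9, 1, 20, 300, 0.2)
  calls[3, 1:250] <- NA
  f <- genomic_inbreeding(as_gm(calls), min_snps = 100L)
  expect_true(f$low_confidence[3])
  expect_false(any(f$low_confidence[-3]))
})
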