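test_that("deduplication keeps the highest call rate, ties to first", {
  calls <- rbind(c(0L, 1L, 2L), c(0L, NA, 2L), c(1L, 1L, 1L))
  gm <- as_gm(calls)
  gm$samples$id[2] <- gm$samples$id[1]     # duplicate pair, CR 1 vs 2/3
  dd <- deduplicate(gm)
  expect_identical(nrow(dd$genotypes$calls), 2L)
  expect_identical(unname(dd$genotypes$calls[1, ]), c(0L, 1L, 2L))
  expect_length(dd$report$ties, 0)

  gm2 <- as_gm(rbind(c(0L, 1L), c(2L, 1L), c(2L, 0L)))
  gm2$samples$id <- rep(gm2$samples$id[1], 3)   # three-way tie
  dd2 <- deduplicate(gm2)
  expect_identical(nrow(dd2$genotypes$calls), 1L)
  expect_identical(unname(dd2$genotypes$calls[1, ]), c(0L, 1L))
  expect_identical(dd2$report$ties, gm2$samples$id[1])

  # no duplicates -> identity
  dd3 <- deduplicate(as_gm(calls))
  expect_identical(dd3$report$n_removed, 0L)
  expect_identical(dd3$genotypes$calls, as_gm(calls)$calls)
})

test_that("qc_filter removes samples, then SNP call rate, then MAF", {
  # 4 x 3: one all-missing sample; after its removal one SNP is
  # monomorphic (MAF 0) and is caught by the MAF stage
  calls <- rbind(c(NA, NA, NA),
                 c(2L, 1L, 2L),
                 c(2L, 0L, 1L),
                 c(2L, 1L, 0L))
  qc <- qc_filter(as_gm(calls))
  expect_identical(dim(qc$genotypes$calls), c(3L, 2L))
  rep <- qc$report
  expect_identical(rep$removed[rep$stage == "sample_call_rate"], 1L)
  expect_identical(rep$removed[rep$stage == "snp_call_rate"], 0L)
  expect_identical(rep$removed[rep$stage == "maf"], 1L)
  # conservation at every stage
  expect_true(all(rep$removed + rep$retained ==
                    c(4L, 3L, 3L)))

  # clean common input -> identity, and qc_filter is idempotent
  calls2 <- bn_calls(7, 1, 30, 40, 0.2)
  keep <- snp_maf(as_gm(calls2)) >= 0.05
  gm2 <- as_gm(calls2[, keep])
  qc2 <- qc_filter(gm2)
  expect_identical(qc2$genotypes$calls, gm2$calls)
  qc3 <- qc_filter(qc2$genotypes)
  expect_identical(qc3$genotypes$calls, qc2$genotypes$calls)
  expect_true(all(qc3$report$removed == 0L))
})

test_that("a MAF sitting exactly on the threshold is retained", {
  # 50 individuals, one SNP with exactly one heterozygote: MAF = 0.01
  calls <- matrix(0L, 50, 2)
  calls[, 2] <- rep(c(0L, 2L), 25)     # common companion SNP
  calls[1, 1] <- 1L
  gm <- as_gm(calls)
  expect_equal(unname(snp_maf(gm)[1]), 0.01)
  qc <- qc_filter(gm, maf_min = 0.01)
  expect_identical(ncol(qc$genotypes$calls), 2L)
})

test_that("merging concatenates samples, reconciles labels, pools counts", {
  calls <- bn_calls(5, 2, 25, 60, 0.1)
  a <- as_gm(calls[1:25, ], country = "AAA")
  b <- as_gm(calls[26:50, ], country = "BBB")
  mg <- merge_datasets(list(a, b), requalify = FALSE)
  expect_identical(nrow(mg$genotypes$calls), 50L)
  expect_identical(mg$genotypes$map$snp, a$map$snp)

  # flipped allele labels on some SNPs are recoded before pooling
  b2 <- b
  flip <- c(3L, 10L, 41L)
  b2$calls[, flip] <- 2L - b2$calls[, flip]
  b2$map$a1[flip] <- "B"; b2$map$a2[flip] <- "A"
  mg2 <- merge_datasets(list(a, b2), requalify = FALSE)
  # pooled frequency must equal brute-force pooled counts on original coding
  pooled <- colSums(calls) / (2 * nrow(calls))
  expect_equal(unname(allele_freq(mg2$genotypes)), unname(pooled),
               tolerance = 1e-12)

  # irreconcilable labels drop the SNP
  b3 <- b
  b3$map$a1[5] <- "C"
  mg3 <- merge_datasets(list(a, b3), requalify = FALSE)
  expect_identical(mg3$dropped_snps, a$map$snp[5])
  expect_identical(ncol(mg3$genotypes$calls), 59L)

  # disjoint SNP sets are a degenerate error
  b4 <- b
  b4$map$snp <- paste0("other_", b4$map$snp)
  expect_error(merge_datasets(list(a, b4)), "no SNPs shared")
})

test_that("PED/MAP files round-trip through write and read", {
  sim <- tiny_sim(seed = 3L)
  gm <- sim$genotypes$FRA
  prefix <- file.path(withr::local_tempdir(), "geno")
  write_pedmap(gm, prefix)
  back <- read_pedmap(prefix)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_identical(back$map$bp, gm$map$bp)
  expect_identical(back$samples$id, gm$samples$id)
})
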