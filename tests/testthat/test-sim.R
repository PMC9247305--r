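one_pop_spec <- function(seed, fst, m = 5000L, ...) {
  cc <- "AAA"
  population_spec(breeds = "POP", countries = cc, n_founders = 2L,
                  fst = fst, n_snps = m, n_chromosomes = 1L, seed = seed,
                  export_rate = matrix(0, 1, 1, dimnames = list(cc, cc)),
                  ...)
}

test_that("Balding-Nichols draws have the right limits and variance", {
  # fst -> 0: population frequencies collapse onto the ancestral ones
  fr <- draw_population_frequencies(one_pop_spec(3L, 1e-6, m = 2000L))
  expect_lt(max(abs(fr$populations[1, ] - fr$ancestral)), 0.05)

  # fst = 0.5: normalized squared deviation averages to F (Beta variance
  # p(1-p)F; e.g. 0.125 at p = 0.5), Monte Carlo within 5%
  fr2 <- draw_population_frequencies(one_pop_spec(5L, 0.5, m = 10000L))
  z <- (fr2$populations[1, ] - fr2$ancestral)^2 /
    (fr2$ancestral * (1 - fr2$ancestral))
  expect_lt(abs(mean(z) - 0.5), 0.05 * 0.5)

  # determinism: same spec and seed give identical draws
  fr3 <- draw_population_frequencies(one_pop_spec(5L, 0.5, m = 10000L))
  expect_identical(fr2$populations, fr3$populations)

  expect_error(one_pop_spec(1L, 1.2), "fst")
  expect_error(one_pop_spec(1L, 0), "fst")
})

test_that("divergence is recovered from simulated genotypes (Hudson FST)", {
  fst <- 0.2
  # both populations diverge from one shared ancestral frequency draw
  g <- bn_calls(21, 2, 200, 5000, fst)
  g1 <- g[1:200, ]; g2 <- g[201:400, ]
  est <- hudson_fst(g1, g2)
  expect_lt(abs(est - fst) / fst, 0.2)
})

test_that("gene dropping is Mendelian-consistent and honours no-recombination", {
  sim <- tiny_sim(seed = 13L)
  expect_identical(mendelian_violations(sim$truth$haplotypes, sim$registry),
                   0L)

  # recomb_rate = 0: every transmitted haplotype is one parental haplotype
  sim0 <- tiny_sim(seed = 13L, recomb_rate = 0)
  drop <- sim0$truth$haplotypes
  reg <- sim0$registry
  ids <- rownames(drop$h1)
  sire <- match(reg$sire, ids)
  nonf <- which(!is.na(sire))
  chrom1 <- which(drop$map$chrom == 1)
  for (i in nonf[1:20]) {
    child <- drop$h1[reg$id[i], chrom1]
    s1 <- drop$h1[sire[i], chrom1]; s2 <- drop$h2[sire[i], chrom1]
    expect_true(identical(child, s1) || identical(child, s2))
  }
})

test_that("eight generations of selfing fix every locus", {
  cc <- "AAA"
  spec <- one_pop_spec(9L, 0.2, m = 100L, recomb_rate = 0,
                       n_ancestral_haplotypes = 50L)
  freqs <- draw_population_frequencies(spec)
  H <- simulate_founder_haplotypes(spec, freqs)
  ids <- sprintf("S%02d", 0:8)
  registry <- data.frame(id = ids,
                         sire = c(NA, ids[1:8]), dam = c(NA, ids[1:8]),
                         population = "POP.AAA", stringsAsFactors = FALSE)
  drop <- gene_drop(spec, registry, H)
  expect_identical(sum(drop$h1["S08", ] != drop$h2["S08", ]), 0L)
})

test_that("pedigree simulation respects export structure and truth table", {
  # no exchange at all -> no foreign records anywhere
  cc <- c("CAN", "CHE", "FRA", "ITA")
  sim0 <- tiny_sim(seed = 3L,
                   export_rate = matrix(0, 4, 4, dimnames = list(cc, cc)))
  for (ped in sim0$pedigrees)
    expect_identical(sum(is_foreign_id(ped$id)), 0L)
  expect_identical(nrow(sim0$matches), 0L)
  peds0 <- lapply(sim0$pedigrees, function(p) validate_pedigree(p)$pedigree)
  conn0 <- tabulate_connectedness(peds0, parent_origin = "FRA")
  expect_identical(conn0$totals$grand_total, 0L)

  # unilateral flow FRA -> ITA only
  er <- matrix(0, 4, 4, dimnames = list(cc, cc))
  er["FRA", "ITA"] <- 0.3
  sim1 <- tiny_sim(seed = 5L, export_rate = er)
  for (ct in c("CAN", "CHE"))
    expect_identical(sum(is_foreign_id(sim1$pedigrees[[ct]]$id)), 0L)
  ita <- sim1$pedigrees$ITA
  foreign <- ita$id[is_foreign_id(ita$id)]
  expect_gt(length(foreign), 0L)
  expect_true(all(substr(sub("^0+", "", substr(foreign, 8, 23)), 1, 2)
                  == "FR"))
  # truth table covers every deliberately corrupted identifier
  corrupted <- sim1$matches[sim1$matches$form != "exact", ]
  expect_true(all(corrupted$observed_id %in% ita$id |
                    corrupted$observed_id %in% unlist(ita[paste0("alias", 1:3)])))

  # every genotyped animal sits in exactly one country's genotype file
  all_ids <- unlist(lapply(sim1$genotypes, function(g) g$samples$id))
  expect_identical(anyDuplicated(all_ids), 0L)
})

test_that("simulation output is deterministic given spec and seed", {
  a <- tiny_sim(seed = 99L)
  b <- tiny_sim(seed = 99L)
  expect_identical(a$registry, b$registry)
  expect_identical(a$matches, b$matches)
  expect_identical(a$genotypes$FRA$calls, b$genotypes$FRA$calls)
  expect_identical(a$truth$haplotypes$h1, b$truth$haplotypes$h1)
  c <- tiny_sim(seed = 100L)
  expect_false(identical(a$registry$id, c$registry$id))
})

test_that("pedigree-expected ancestry sums to one and tracks imports", {
  sim <- tiny_sim(seed = 7L)
  anc <- sim$truth$ancestry
  expect_lt(max(abs(rowSums(anc) - 1)), 1e-12)
  # an Italian animal with a French sire has 50% French-population ancestry
  reg <- sim$registry
  fr_sired <- which(reg$origin == "ITA" & !is.na(reg$sire) &
                      substr(reg$sire, 4, 6) == "FRA" &
                      reg$generation == 1L)
  if (length(fr_sired)) {
    i <- fr_sired[1]
    expect_equal(unname(anc[i, paste0(reg$breed[i], ".FRA")]), 0.5)
  }
})
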