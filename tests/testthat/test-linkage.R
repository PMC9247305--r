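fr_id <- function(raw, sex = "M", reg = "FRA")
  standardize_id(raw, "ALP", reg, sex, "FR")

test_that("identical animals registered in two countries match exactly", {
  raws <- 5240000 + 1:8
  src <- pedigree_table(id = fr_id(raws), sex = "M", breed = "ALP",
                        country = "FRA")
  tgt <- pedigree_table(id = fr_id(raws, reg = "ITA"), sex = "M",
                        breed = "ALP", country = "ITA")
  res <- link_pedigrees(src, tgt, source_country = "FRA")
  expect_identical(nrow(res), 8L)
  expect_true(all(res$method == "exact"))
  expect_true(all(res$status == "accepted"))
  expect_identical(res$source_id, src$id)
})

test_that("a truncated identifier is recovered by unique suffix match", {
  src <- pedigree_table(id = fr_id(c(5248383, 1111111, 2222222)), sex = "M",
                        breed = "ALP", country = "FRA")
  # Swiss record kept only the last 5 digits
  tgt <- pedigree_table(id = fr_id("48383", reg = "CHE"), sex = "M",
                        breed = "ALP", country = "CHE")
  res <- link_pedigrees(src, tgt, source_country = "FRA")
  expect_identical(res$method, "suffix")
  expect_identical(res$status, "accepted")
  expect_identical(res$source_id, src$id[1])

  # ambiguous suffix (two sources share it) disqualifies the tier
  src2 <- pedigree_table(id = fr_id(c(5248383, 9948383)), sex = "M",
                         breed = "ALP", country = "FRA")
  res2 <- link_pedigrees(src2, tgt, source_country = "FRA")
  expect_false(identical(res2$method, "suffix"))
  expect_false(identical(res2$status, "accepted"))
})

test_that("a one-character typo lands in fuzzy review, never auto-accepted", {
  src <- pedigree_table(id = fr_id(5248383), sex = "M", breed = "ALP",
                        country = "FRA")
  tgt <- pedigree_table(id = fr_id(5248783, reg = "ITA"), sex = "M",
                        breed = "ALP", country = "ITA")
  res <- link_pedigrees(src, tgt, fuzzy_threshold = 90,
                        source_country = "FRA")
  expect_identical(res$method, "fuzzy")
  expect_gte(res$score, 90)       # 1 edit over a 16-char core: 93.75
  expect_identical(res$status, "review")
  expect_identical(res$source_id, src$id)
})

test_that("aliases recover renumbered imports; empty source matches nothing", {
  canon <- fr_id(5248383)
  src <- pedigree_table(id = canon, sex = "M", breed = "ALP",
                        country = "FRA")
  tgt <- pedigree_table(id = standardize_id(777, "ALP", "ITA", "M", "FR"),
                        sex = "M", breed = "ALP", country = "ITA",
                        alias1 = canon)
  res <- link_pedigrees(src, tgt, source_country = "FRA")
  expect_identical(res$method, "alias")
  expect_identical(res$status, "accepted")

  empty <- pedigree_table(id = character(0))
  res2 <- link_pedigrees(empty, tgt, source_country = "FRA")
  expect_true(all(res2$status == "unmatched"))
})

test_that("linkage against simulated truth: high recall, no false accepts", {
  sim <- tiny_sim(seed = 23L, n_founders = 24L, n_generations = 4L,
                  id_corruption = list(truncation = 0.1, typo = 0.05,
                                       alias = 0.1))
  peds <- lapply(sim$pedigrees, function(p) validate_pedigree(p)$pedigree)
  truth <- sim$matches
  recovered <- 0L; false_accepted <- 0L; total <- 0L
  for (src in names(peds)) for (tgt in setdiff(names(peds), src)) {
    tr <- truth[truth$country == tgt &
                  substr(truth$canonical_id, 4, 6) == src, ]
    if (!nrow(tr)) next
    res <- link_pedigrees(peds[[src]], peds[[tgt]], fuzzy_threshold = 90,
                          source_country = src)
    m <- match(res$target_id, tr$observed_id)
    expect_true(all(!is.na(m)))          # truth covers every foreign record
    correct <- !is.na(res$source_id) & res$source_id == tr$canonical_id[m]
    recovered <- recovered + sum(correct & res$status %in%
                                   c("accepted", "review"))
    false_accepted <- false_accepted +
      sum(res$status == "accepted" & !correct)
    total <- total + nrow(tr)
  }
  expect_gte(recovered / total, 0.95)
  expect_identical(false_accepted, 0L)
  expect_true(all(truth$form %in% c("exact", "truncated", "typo", "alias")))
})

test_that("clean identifiers are fully recovered by exact matching alone", {
  sim <- tiny_sim(seed = 31L,
                  id_corruption = list(truncation = 0, typo = 0, alias = 0))
  peds <- lapply(sim$pedigrees, function(p) validate_pedigree(p)$pedigree)
  truth <- sim$matches
  for (src in names(peds)) for (tgt in setdiff(names(peds), src)) {
    tr <- truth[truth$country == tgt &
                  substr(truth$canonical_id, 4, 6) == src, ]
    if (!nrow(tr)) next
    res <- link_pedigrees(peds[[src]], peds[[tgt]], source_country = src)
    expect_true(all(res$method == "exact"))
    m <- match(res$target_id, tr$observed_id)
    expect_identical(res$source_id, tr$canonical_id[m])
  }
})
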