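# random pedigree over `gens` non-overlapping generations; returns a
# data frame with integer-coded parents for the tabular oracle
random_pedigree <- function(seed, n_founders = 20L, gens = 5L,
                            per_gen = 45L) {
  withr::with_seed(seed, {
    id <- seq_len(n_founders)
    sire <- dam <- rep(0L, n_founders)
    sex <- rep(c("M", "F"), length.out = n_founders)
    gen_start <- 1L
    for (g in seq_len(gens)) {
      prev <- seq(gen_start, length(id))
      males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
      gen_start <- length(id) + 1L
      for (k in seq_len(per_gen)) {
        id <- c(id, length(id) + 1L)
        sire <- c(sire, sample(males, 1L))
        dam <- c(dam, sample(females, 1L))
        sex <- c(sex, sample(c("M", "F"), 1L))
      }
    }
    data.frame(id = id, sire = sire, dam = dam, sex = sex)
  })
}

as_ped_df <- function(tab) {
  ids <- standardize_id(tab$id + 5000000L, "ALP", "FRA", tab$sex)
  pedigree_table(id = ids,
                 sire = parent_ids(ids, tab$sire),
                 dam = parent_ids(ids, tab$dam),
                 sex = tab$sex, breed = "ALP", country = "FRA")
}

test_that("founders and textbook matings have closed-form inbreeding", {
  # all founders -> F = 0
  ped <- as_ped_df(data.frame(id = 1:4, sire = 0L, dam = 0L,
                              sex = c("M", "F", "M", "F")))
  expect_equal(pedigree_inbreeding(ped)$F_ped, rep(0, 4))

  # full-sib mating with unrelated, non-inbred grandparents -> F = 0.25
  tab <- data.frame(id = 1:5, sire = c(0L, 0L, 1L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 4L),
                    sex = c("M", "F", "M", "F", "F"))
  f <- pedigree_inbreeding(as_ped_df(tab))
  expect_equal(f$F_ped[5], 0.25)
  # an animal with one unknown parent side contributes only known paths
  tab2 <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 0L),
                     sex = c("M", "F", "F"))
  expect_equal(pedigree_inbreeding(as_ped_df(tab2))$F_ped, rep(0, 3))
})

test_that("Meuwissen-Luo agrees with the tabular relationship oracle", {
  for (seed in c(2, 9)) {
    tab <- random_pedigree(seed)
    A <- tabular_A(tab$sire, tab$dam)
    f <- pedigree_inbreeding(as_ped_df(tab))
    expect_lt(max(abs(f$F_ped - (diag(A) - 1))), 1e-12)
    expect_true(all(f$F_ped >= 0 & f$F_ped <= 1))
  }
})

test_that("inbreeding is invariant to pedigree record order", {
  tab <- random_pedigree(4, gens = 4L, per_gen = 30L)
  ped <- as_ped_df(tab)
  f1 <- pedigree_inbreeding(ped)
  perm <- withr::with_seed(1, sample(nrow(ped)))
  f2 <- pedigree_inbreeding(ped[perm, ])
  m <- match(f1$id, f2$id)
  expect_equal(f1$F_ped, f2$F_ped[m], tolerance = 1e-14)
})

test_that("cyclic pedigrees are a structural error", {
  a <- standardize_id(1, "ALP", "FRA", "M")
  b <- standardize_id(2, "ALP", "FRA", "M")
  ped <- pedigree_table(id = c(a, b), sire = c(b, a), sex = "M",
                        breed = "ALP", country = "FRA")
  expect_error(pedigree_inbreeding(ped), "cycle")
})
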