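#' Simulate multi-country pedigrees with export flows and corrupted IDs
#'
#' Builds, per country, a pedigree of discrete generations for every
#' breed.  Matings are within country except that a dam's sire is drawn
#' from country A with probability `export_rate[A, country]` (same breed,
#' previous generation).  An exported sire gains a record in the
#' importing pedigree whose identifier is, per the `id_corruption` rates,
#' either truncated to the trailing digits of the local number, hit by a
#' one-character typo, replaced by a fresh local number with the true
#' identity kept as an alias, or clean; every correspondence is written
#' to the truth match table.
#'
#' @param spec A `population_spec`.
#' @return List with:
#'   * `registry`: master pedigree over canonical identifiers (`id`,
#'     `sire`, `dam`, `sex`, `birth_year`, `breed`, `origin`,
#'     `population`, `generation`), topologically ordered;
#'   * `pedigrees`: named list of per-country `herd_pedigree` tables as
#'     each partner would submit them (imported records carry observed,
#'     possibly corrupted identifiers);
#'   * `matches`: truth table (`canonical_id`, `observed_id`, `country`,
#'     `form` in exact/truncated/typo/alias).
#' @export
simulate_pedigree <- function(spec) {
  spec <- validate_population_spec(spec)
  with_stream(spec$seed, 3L, simulate_pedigree_impl(spec))
}

simulate_pedigree_impl <- function(spec) {
  countries <- spec$countries
  breeds <- spec$breeds
  er <- spec$export_rate[countries, countries, drop = FALSE]

  # pool of unique 7-digit local numbers per country
  n_per_pop <- spec$n_founders +
    spec$n_generations * (spec$n_founders %/% 2L) * spec$offspring_per_mating
  pool_size <- length(breeds) * n_per_pop + 500L
  pools <- lapply(countries, function(ct)
    sample.int(9000000L, pool_size) + 999999L)
  names(pools) <- countries
  pool_ptr <- stats::setNames(rep(0L, length(countries)), countries)
  next_local <- function(ct) {
    pool_ptr[ct] <<- pool_ptr[ct] + 1L
    pools[[ct]][pool_ptr[ct]]
  }

  reg <- list()   # rows of the master registry
  add_animal <- function(breed, origin, sex, gen, sire = NA, dam = NA) {
    raw <- next_local(origin)
    id <- standardize_id(raw, breed, origin, sex, substr(origin, 1, 2))
    reg[[length(reg) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex,
      birth_year = spec$year0 + gen * spec$year_step,
      breed = breed, origin = origin,
      population = paste(breed, origin, sep = "."),
      generation = gen, local_number = raw, stringsAsFactors = FALSE)
    id
  }

  # founders, deterministic half males / half females
  by_pop_gen <- list()   # population -> generation -> ids by sex
  for (b in breeds) for (ct in countries) {
    nm <- paste(b, ct, sep = ".")
    nM <- spec$n_founders %/% 2L
    males <- vapply(seq_len(nM), function(i) add_animal(b, ct, "M", 0L), "")
    females <- vapply(seq_len(spec$n_founders - nM), function(i)
      add_animal(b, ct, "F", 0L), "")
    by_pop_gen[[nm]] <- list(list(M = males, F = females))
  }

  # exported-animal bookkeeping: observed form per (canonical id, importer)
  imports <- list()  # importer -> data.frame of imported records
  match_truth <- list()
  observed_form <- new.env(parent = emptyenv())

  import_record <- function(canonical_id, importer) {
    key <- paste(canonical_id, importer)
    if (!is.null(observed_form[[key]])) return(observed_form[[key]])
    row <- registry_row(reg, canonical_id)
    rates <- spec$id_corruption
    u <- stats::runif(1)
    raw <- as.character(row$local_number)
    origin2 <- substr(row$origin, 1, 2)
    alias1 <- NA_character_
    if (u < rates$truncation) {
      form <- "truncated"
      k <- sample(5:6, 1L)
      obs <- standardize_id(substring(raw, nchar(raw) - k + 1L),
                            row$breed, importer, row$sex, origin2)
    } else if (u < rates$truncation + rates$typo) {
      form <- "typo"
      digs <- strsplit(raw, "")[[1]]
      at <- sample(length(digs), 1L)
      digs[at] <- sample(setdiff(as.character(0:9), digs[at]), 1L)
      obs <- standardize_id(paste(digs, collapse = ""),
                            row$breed, importer, row$sex, origin2)
    } else if (u < rates$truncation + rates$typo + rates$alias) {
      form <- "alias"
      obs <- standardize_id(next_local(importer), row$breed, importer,
                            row$sex, origin2)
      alias1 <- row$id
    } else {
      form <- "exact"
      obs <- standardize_id(raw, row$breed, importer, row$sex, origin2)
    }
    imports[[importer]][[length(imports[[importer]]) + 1L]] <<- data.frame(
      id = obs, sire = NA_character_, dam = NA_character_, sex = row$sex,
      birth_year = row$birth_year, breed = row$breed, country = importer,
      alias1 = alias1, alias2 = NA_character_, alias3 = NA_character_,
      stringsAsFactors = FALSE)
    match_truth[[length(match_truth) + 1L]] <<- data.frame(
      canonical_id = row$id, observed_id = obs, country = importer,
      form = form, stringsAsFactors = FALSE)
    observed_form[[key]] <- obs
    obs
  }
  for (ct in countries) imports[[ct]] <- list()

  # observed sire/dam reference as it appears in a country's file
  parent_ref <- new.env(parent = emptyenv())   # canonical id -> importer obs

  # generations
  for (g in seq_len(spec$n_generations)) {
    for (b in breeds) for (ct in countries) {
      nm <- paste(b, ct, sep = ".")
      prev <- by_pop_gen[[nm]][[g]]
      dams <- prev$F
      local_sires <- prev$M
      # export probabilities into ct
      p_imp <- er[, ct]; p_imp[ct] <- 0
      origins <- names(p_imp)[p_imp > 0]
      males <- character(0); females <- character(0)
      for (dam in dams) {
        u <- stats::runif(1)
        cum <- 0
        sire_origin <- ct
        for (A in origins) {
          cum <- cum + p_imp[A]
          if (u < cum) { sire_origin <- A; break }
        }
        sire_pool <- if (sire_origin == ct) local_sires else
          by_pop_gen[[paste(b, sire_origin, sep = ".")]][[g]]$M
        if (!length(sire_pool)) sire_pool <- local_sires
        if (!length(sire_pool))
          stop("simulate_pedigree: population ", nm, " ran out of sires ",
               "at generation ", g, "; increase n_founders or ",
               "offspring_per_mating")
        sire <- sample(sire_pool, 1L)
        if (id_registration(sire) != ct) import_record(sire, ct)
        for (o in seq_len(spec$offspring_per_mating)) {
          # deterministic alternation keeps both sexes available every
          # generation even in small populations
          sx <- if ((length(males) + length(females)) %% 2L == 0L)
            "M" else "F"
          id <- add_animal(b, ct, sx, g, sire = sire, dam = dam)
          if (sx == "M") males <- c(males, id) else females <- c(females, id)
        }
      }
      by_pop_gen[[nm]][[g + 1L]] <- list(M = males, F = females)
    }
  }

  registry <- do.call(rbind, reg)
  rownames(registry) <- NULL

  # assemble per-country pedigrees with observed parent references
  pedigrees <- lapply(countries, function(ct) {
    native <- registry[registry$origin == ct, , drop = FALSE]
    obs_ref <- function(pid) {
      if (is.na(pid)) return(NA_character_)
      if (id_registration(pid) == ct) return(pid)
      key <- paste(pid, ct)
      if (!is.null(observed_form[[key]])) observed_form[[key]] else pid
    }
    ped <- pedigree_table(
      id = native$id,
      sire = vapply(native$sire, obs_ref, ""),
      dam = vapply(native$dam, obs_ref, ""),
      sex = native$sex, birth_year = native$birth_year,
      breed = native$breed, country = ct)
    imp <- imports[[ct]]
    if (length(imp)) {
      imp <- do.call(rbind, imp)
      imp$birth_year <- as.integer(imp$birth_year)
      class(imp) <- class(ped)
      ped <- rbind(ped, imp)
    }
    ped
  })
  names(pedigrees) <- countries

  matches <- if (length(match_truth)) do.call(rbind, match_truth) else
    data.frame(canonical_id = character(), observed_id = character(),
               country = character(), form = character(),
               stringsAsFactors = FALSE)

  list(registry = registry, pedigrees = pedigrees, matches = matches)
}

registry_row <- function(reg, id) {
  for (i in rev(seq_along(reg))) if (reg[[i]]$id == id) return(reg[[i]])
  stop("unknown animal: ", id)
}

id_registration <- function(id) substr(id, 4L, 6L)
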