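#' Simulate a complete multi-country dataset
#'
#' End-to-end generator: Balding-Nichols population frequencies, mosaic
#' founder haplotypes, multi-country pedigrees with export flows and
#' identifier corruption, gene-dropped phased genotypes, per-country
#' genotyping cohorts (birth-year windows) and i.i.d. missing calls.
#' Ground truth is kept for every downstream check: true allele
#' frequencies, pedigree-expected ancestry proportions, the cross-pedigree
#' match table, and the uncorrupted master registry.
#'
#' @param spec A `population_spec`.
#' @return List of class `simulated_dataset`:
#'   * `spec`, `registry`, `pedigrees`, `matches` (see
#'     [simulate_pedigree()]);
#'   * `genotypes`: named list (per country) of phased
#'     `genotype_matrix` objects — each genotyped animal appears in
#'     exactly one country's matrix (its country of origin);
#'   * `truth`: list with `frequencies` (population x SNP), `ancestry`
#'     (animal x population pedigree-expected proportions), `matches`
#'     and `haplotypes` (the full gene-drop result).
#' @export
simulate_dataset <- function(spec) {
  spec <- validate_population_spec(spec)
  freqs <- draw_population_frequencies(spec)
  haps <- simulate_founder_haplotypes(spec, freqs)
  ped <- simulate_pedigree(spec)
  drop <- gene_drop(spec, ped$registry, haps, map = freqs$map)

  registry <- ped$registry[match(rownames(drop$h1), ped$registry$id), ,
                           drop = FALSE]

  # pedigree-expected ancestry proportions
  pops <- rownames(freqs$populations)
  anc <- matrix(0, nrow(registry), length(pops),
                dimnames = list(registry$id, pops))
  sire <- match(registry$sire, registry$id)
  dam <- match(registry$dam, registry$id)
  for (i in seq_len(nrow(registry))) {
    if (is.na(sire[i]) && is.na(dam[i])) {
      anc[i, registry$population[i]] <- 1
    } else if (!is.na(sire[i]) && !is.na(dam[i])) {
      anc[i, ] <- (anc[sire[i], ] + anc[dam[i], ]) / 2
    } else {
      own <- numeric(length(pops)); names(own) <- pops
      own[registry$population[i]] <- 1
      known <- if (!is.na(sire[i])) anc[sire[i], ] else anc[dam[i], ]
      anc[i, ] <- (known + own) / 2
    }
  }

  # genotyping cohorts: an animal is genotyped by its origin country when
  # its birth year falls in that country's window
  windows <- spec$genotyping_windows
  if (is.null(windows)) {
    last <- spec$year0 + spec$n_generations * spec$year_step
    windows <- stats::setNames(
      lapply(seq_along(spec$countries), function(i)
        c(spec$year0 + (i - 1L) %/% 2L * spec$year_step, last)),
      spec$countries)
  }
  genotyped <- vapply(seq_len(nrow(registry)), function(i) {
    w <- windows[[registry$origin[i]]]
    !is.null(w) && registry$birth_year[i] >= w[1] &&
      registry$birth_year[i] <= w[2]
  }, TRUE)

  genotypes <- list()
  for (ct in spec$countries) {
    sel <- which(genotyped & registry$origin == ct)
    if (!length(sel)) next
    h1 <- drop$h1[sel, , drop = FALSE]
    h2 <- drop$h2[sel, , drop = FALSE]
    calls <- h1 + h2
    if (spec$missing_rate > 0) {
      mask <- with_stream(spec$seed, 500L + match(ct, spec$countries),
                          matrix(stats::runif(length(calls)) <
                                   spec$missing_rate, nrow(calls)))
      calls[mask] <- NA_integer_
    }
    genotypes[[ct]] <- genotype_matrix(
      calls, freqs$map,
      data.frame(id = registry$id[sel], breed = registry$breed[sel],
                 country = ct, sex = registry$sex[sel],
                 birth_year = registry$birth_year[sel],
                 stringsAsFactors = FALSE),
      phase = list(h1 = h1, h2 = h2))
  }

  structure(list(spec = spec, registry = registry,
                 pedigrees = ped$pedigrees, matches = ped$matches,
                 genotypes = genotypes,
                 truth = list(frequencies = freqs$populations,
                              ancestral = freqs$ancestral,
                              ancestry = anc, matches = ped$matches,
                              haplotypes = drop)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d animals, %d countries, %d genotyped, %d SNPs\n",
    nrow(x$registry), length(x$pedigrees),
    sum(vapply(x$genotypes, function(g) nrow(g$calls), 0L)),
    nrow(x$truth$haplotypes$map)))
  invisible(x)
}

#' Write a simulated dataset to disk as delimited text
#'
#' Pedigrees as per-country CSV, genotypes as PED/MAP pairs, the truth
#' match table as TSV.
#'
#' @param sim A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in names(sim$pedigrees))
    write_pedigree(sim$pedigrees[[ct]],
                   file.path(dir, paste0("pedigree_", ct, ".csv")))
  for (ct in names(sim$genotypes))
    write_pedmap(sim$genotypes[[ct]], file.path(dir, paste0("geno_", ct)))
  utils::write.table(sim$matches, file.path(dir, "truth_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
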