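#' Specification of a simulated multi-country population
#'
#' Collects every knob of the synthetic-data generator: population layout
#' (breeds x countries), Balding-Nichols divergence, the mosaic model
#' that gives founder haplotypes distance-decaying LD, pedigree dynamics
#' with directed export flows, identifier corruption, per-country
#' genotyping windows and the missing-call rate.  The defaults describe a
#' desk-scale version of a four-country, two-breed dairy goat exchange
#' with France as the dominant exporter.
#'
#' @param breeds Character vector of 3-letter breed codes.
#' @param countries Character vector of 3-letter country codes.
#' @param n_founders Founders per population (breed x country).
#' @param n_generations Number of discrete generations after the founders.
#' @param offspring_per_mating Offspring per mating.
#' @param fst Balding-Nichols divergence in (0,1): a single value, a
#'   vector named by country, or a vector named by population label
#'   (`"BRD.CTY"`); `NULL` (default) takes [default_fst()].
#' @param export_rate Square matrix (countries x countries, dimnames
#'   required) with entry `[A, B]` the probability that a sire used in
#'   country B originates in country A; the diagonal is ignored and rows
#'   need not sum to 1.
#' @param n_ancestral_haplotypes Size of each population's ancestral
#'   template pool.
#' @param n_snps SNPs per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param mosaic_switch_rate Per-bp rate of switching ancestral template
#'   between adjacent SNPs (switch probability `1 - exp(-rate * d)`).
#' @param recomb_rate Recombination rate in Morgans per bp (Haldane
#'   model; default 1e-8, i.e. 1 cM/Mb).
#' @param id_corruption Named list with rates `truncation`, `typo`,
#'   `alias` applied to imported-animal records.
#' @param missing_rate i.i.d. genotype missingness rate (default 0.02).
#' @param genotyping_windows Named list, per country, of `c(from, to)`
#'   birth years delimiting the genotyped cohorts; `NULL` means all
#'   years.
#' @param export_dams Also export dams at the same rates (default
#'   `FALSE`: exchange is sire-dominated).
#' @param year0 Birth year of the founder generation.
#' @param year_step Years between generations.
#' @param seed Integer master seed; every stage derives its own stream
#'   from it.
#' @return A validated list of class `population_spec`.
#' @export
population_spec <- function(breeds = c("ALP", "SAA"),
                            countries = c("CAN", "CHE", "FRA", "ITA"),
                            n_founders = 40L,
                            n_generations = 5L,
                            offspring_per_mating = 2L,
                            fst = NULL,
                            export_rate = default_export_rate(countries),
                            n_ancestral_haplotypes = 8L,
                            n_snps = 300L,
                            n_chromosomes = 3L,
                            chrom_length_bp = 1e7,
                            mosaic_switch_rate = 1e-6,
                            recomb_rate = 1e-8,
                            id_corruption = list(truncation = 0.1,
                                                 typo = 0.05, alias = 0.1),
                            missing_rate = 0.02,
                            genotyping_windows = NULL,
                            export_dams = FALSE,
                            year0 = 2000L,
                            year_step = 3L,
                            seed = 1L) {
  if (is.null(fst)) fst <- default_fst(toupper(countries))
  spec <- list(breeds = toupper(breeds), countries = toupper(countries),
               n_founders = as.integer(n_founders),
               n_generations = as.integer(n_generations),
               offspring_per_mating = as.integer(offspring_per_mating),
               fst = fst, export_rate = export_rate,
               n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
               n_snps = as.integer(n_snps),
               n_chromosomes = as.integer(n_chromosomes),
               chrom_length_bp = as.numeric(chrom_length_bp),
               mosaic_switch_rate = as.numeric(mosaic_switch_rate),
               recomb_rate = as.numeric(recomb_rate),
               id_corruption = id_corruption,
               missing_rate = as.numeric(missing_rate),
               genotyping_windows = genotyping_windows,
               export_dams = isTRUE(export_dams),
               year0 = as.integer(year0), year_step = as.integer(year_step),
               seed = as.integer(seed))
  validate_population_spec(spec)
}

#' @rdname population_spec
#' @export
default_fst <- function(countries) {
  # desk-scale divergence mirroring a close FRA/ITA pair, an
  # intermediate CHE and a distinct CAN; any other layout gets 0.10
  known <- c(CAN = 0.15, CHE = 0.10, FRA = 0.04, ITA = 0.05)
  if (all(countries %in% names(known))) known[countries]
  else 0.10
}

#' @rdname population_spec
#' @export
default_export_rate <- function(countries) {
  m <- matrix(0, length(countries), length(countries),
              dimnames = list(countries, countries))
  put <- function(a, b, r) if (a %in% countries && b %in% countries)
    m[a, b] <<- r
  put("FRA", "ITA", 0.20)
  put("FRA", "CHE", 0.10)
  put("FRA", "CAN", 0.05)
  put("CHE", "ITA", 0.05)
  m
}

validate_population_spec <- function(spec) {
  stopifnot(length(spec$breeds) >= 1L, length(spec$countries) >= 1L)
  counts <- c(spec$n_founders, spec$n_generations, spec$offspring_per_mating,
              spec$n_ancestral_haplotypes, spec$n_snps, spec$n_chromosomes,
              spec$chrom_length_bp)
  if (any(counts < 1)) stop("population_spec: all counts must be >= 1")
  f <- resolve_fst(spec)
  if (any(f <= 0 | f >= 1))
    stop("population_spec: fst must lie strictly in (0, 1)")
  rates <- c(unlist(spec$id_corruption), spec$missing_rate,
             spec$export_rate[is.finite(spec$export_rate)])
  if (any(rates < 0 | rates > 1))
    stop("population_spec: rates must lie in [0, 1]")
  er <- spec$export_rate
  if (!is.matrix(er) || nrow(er) != length(spec$countries) ||
      is.null(dimnames(er)) ||
      !setequal(rownames(er), spec$countries) ||
      !setequal(colnames(er), spec$countries))
    stop("population_spec: export_rate must be a countries x countries matrix with dimnames")
  if (spec$n_founders %% 2L != 0L)
    stop("population_spec: n_founders must be even (half sires, half dams)")
  structure(spec, class = "population_spec")
}

#' Population labels of a spec (breed x country crossing)
#' @param spec A `population_spec`.
#' @return Character vector like `"ALP.FRA"`.
#' @export
population_labels <- function(spec) {
  as.vector(outer(spec$breeds, spec$countries, paste, sep = "."))
}

# per-population fst vector, resolved from the three accepted shapes
resolve_fst <- function(spec) {
  pops <- as.vector(outer(spec$breeds, spec$countries, paste, sep = "."))
  f <- spec$fst
  if (length(f) == 1L && is.null(names(f)))
    return(stats::setNames(rep(as.numeric(f), length(pops)), pops))
  if (!is.null(names(f)) && all(spec$countries %in% names(f))) {
    ctry <- sub("^.*\\.", "", pops)
    return(stats::setNames(as.numeric(f[ctry]), pops))
  }
  if (!is.null(names(f)) && all(pops %in% names(f)))
    return(stats::setNames(as.numeric(f[pops]), pops))
  stop("population_spec: fst must be unnamed scalar, named by country, or named by population")
}

#' Marker map implied by a spec
#'
#' SNPs are evenly spaced along each chromosome.
#'
#' @param spec A `population_spec`.
#' @return Data frame `snp`, `chrom`, `bp`, `a1`, `a2`.
#' @export
spec_marker_map <- function(spec) {
  spacing <- spec$chrom_length_bp / spec$n_snps
  do.call(rbind, lapply(seq_len(spec$n_chromosomes), function(ch) {
    bp <- round(spacing * (seq_len(spec$n_snps) - 0.5))
    data.frame(snp = sprintf("chr%d_%d", ch, bp), chrom = ch, bp = bp,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
}

# evaluate expr under a derived RNG stream, restoring the caller's stream
with_stream <- function(seed, offset, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed((seed * 97L + offset) %% .Machine$integer.max)
  expr
}
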