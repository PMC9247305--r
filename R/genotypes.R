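#' Genotype matrix container
#'
#' Diploid SNP calls for a set of individuals, stored as counts of the
#' first (reference) allele in `{0, 1, 2, NA}`, together with a marker map
#' and per-individual metadata.  When the genotypes come from the
#' simulator the two underlying haplotypes are retained in `phase` as
#' ground truth.
#'
#' @param calls Integer matrix, individuals in rows, SNPs in columns,
#'   values 0/1/2/`NA` (count of allele `a1`).  Row names are canonical
#'   animal identifiers, column names SNP identifiers.
#' @param map Data frame with columns `snp`, `chrom`, `bp`, `a1`, `a2`,
#'   sorted by (`chrom`, `bp`), positions 1-based.
#' @param samples Data frame with columns `id`, `breed`, `country`,
#'   `sex`, `birth_year` aligned with the rows of `calls`.
#' @param phase Optional list of two 0/1 matrices (`h1`, `h2`) with the
#'   same shape as `calls`, such that `calls = h1 + h2`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, samples, phase = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(map) == ncol(calls), nrow(samples) == nrow(calls))
  if (!all(c("snp", "chrom", "bp") %in% names(map)))
    stop("map needs columns snp, chrom, bp")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$bp <- as.numeric(map$bp)
  o <- order(map$chrom, map$bp)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
    if (!is.null(phase)) phase <- lapply(phase, function(h) h[, o, drop = FALSE])
  }
  if (any(map$bp < 1)) stop("bp positions must be 1-based (>= 1)")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples$id
  colnames(calls) <- map$snp
  rownames(map) <- NULL
  rownames(samples) <- NULL
  if (!is.null(phase)) {
    phase <- lapply(phase, function(h) {
      h <- as.matrix(h); storage.mode(h) <- "integer"
      dimnames(h) <- dimnames(calls); h
    })
    names(phase) <- c("h1", "h2")
  }
  structure(list(calls = calls, map = map, samples = samples, phase = phase),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)%s\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
              if (!is.null(x$phase)) ", phased" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param gm A `genotype_matrix`.
#' @param samples Row index (logical/integer/character over individuals).
#' @param snps Column index (logical/integer/character over SNPs).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(snps)) snps <- seq_len(ncol(gm$calls))
  if (is.character(samples)) samples <- match(samples, gm$samples$id)
  if (is.character(snps)) snps <- match(snps, gm$map$snp)
  genotype_matrix(gm$calls[samples, snps, drop = FALSE],
                  gm$map[snps, , drop = FALSE],
                  gm$samples[samples, , drop = FALSE],
                  phase = if (!is.null(gm$phase))
                    lapply(gm$phase, function(h) h[samples, snps, drop = FALSE]))
}

#' Per-SNP allele frequency, call rate and MAF
#'
#' Frequencies refer to allele `a1` (the allele whose copies are counted),
#' computed over non-missing calls.
#'
#' @param gm A `genotype_matrix`.
#' @return `allele_freq()`: numeric vector of `a1` frequencies;
#'   `snp_call_rate()`, `sample_call_rate()`: fraction of non-missing
#'   calls; `snp_maf()`: minor allele frequency in `[0, 0.5]`.
#' @export
allele_freq <- function(gm) {
  colMeans(gm$calls, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
snp_call_rate <- function(gm) colMeans(!is.na(gm$calls))

#' @rdname allele_freq
#' @export
sample_call_rate <- function(gm) rowMeans(!is.na(gm$calls))

#' @rdname allele_freq
#' @export
snp_maf <- function(gm) {
  p <- allele_freq(gm)
  pmin(p, 1 - p)
}

#' Write genotypes as PED/MAP text files
#'
#' The PED format carries one line per individual: family (country),
#' individual id, sire, dam, sex (1 = male, 2 = female), a phenotype
#' placeholder (-9), then two allele characters per SNP (`0 0` for a
#' missing call).  The MAP file has one line per SNP: chromosome, SNP id,
#' genetic position placeholder (0) and base-pair position.
#'
#' @param gm A `genotype_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_pedmap <- function(gm, prefix) {
  map <- gm$map
  utils::write.table(
    data.frame(map$chrom, map$snp, 0, map$bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(gm$calls); m <- ncol(gm$calls)
  a1 <- map$a1; a2 <- map$a2
  lines <- character(n)
  sexcode <- ifelse(gm$samples$sex == "M", 1L, 2L)
  for (i in seq_len(n)) {
    g <- gm$calls[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1L, a1, a2))
    second <- ifelse(is.na(g), "0", ifelse(g == 2L, a1, a2))
    lines[i] <- paste(gm$samples$country[i], gm$samples$id[i], "0", "0",
                      sexcode[i], -9,
                      paste(first, second, collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read genotypes from PED/MAP text files
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @param samples Optional sample metadata data frame (columns `id`,
#'   `breed`, `country`, `sex`, `birth_year`) to attach; by default
#'   metadata are reconstructed from the PED columns and the canonical
#'   identifier.
#' @return A `genotype_matrix` (unphased).
#' @export
read_pedmap <- function(prefix, samples = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp", "cm", "bp"))
  lines <- readLines(paste0(prefix, ".ped"))
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  n <- length(toks)
  meta <- matrix("", n, 6L)
  al1 <- matrix("", n, m); al2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6L + 2L * m)
      stop("PED line ", i, " has ", length(tk), " fields, expected ",
           6L + 2L * m)
    meta[i, ] <- tk[1:6]
    al <- matrix(tk[-(1:6)], nrow = 2L)
    al1[i, ] <- al[1L, ]; al2[i, ] <- al[2L, ]
  }
  # a1 = alphabetically first allele label observed at the SNP ("A" under
  # the package's A/B coding); calls count copies of a1
  calls <- matrix(NA_integer_, n, m)
  map$a1 <- "A"; map$a2 <- "B"
  for (j in seq_len(m)) {
    obs <- sort(setdiff(unique(c(al1[, j], al2[, j])), "0"))
    if (!length(obs)) next
    if (all(obs %in% c("A", "B"))) {
      # package A/B coding: a1 is always "A", even if only "B" was seen
      map$a1[j] <- "A"; map$a2[j] <- "B"
    } else {
      map$a1[j] <- obs[1L]
      map$a2[j] <- if (length(obs) > 1L) obs[2L] else paste0(obs[1L], "'")
    }
    miss <- al1[, j] == "0" | al2[, j] == "0"
    calls[, j] <- (al1[, j] == map$a1[j]) + (al2[, j] == map$a1[j])
    calls[miss, j] <- NA_integer_
  }
  ids <- meta[, 2L]
  if (is.null(samples)) {
    parsed <- tryCatch(parse_canonical_id(ids), error = function(e) NULL)
    samples <- data.frame(
      id = ids,
      breed = if (!is.null(parsed)) parsed$breed else NA_character_,
      country = meta[, 1L],
      sex = ifelse(meta[, 5L] == "1", "M", "F"),
      birth_year = NA_integer_,
      stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(ids, samples$id), , drop = FALSE]
  }
  genotype_matrix(calls, map[, c("snp", "chrom", "bp", "a1", "a2")], samples)
}
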