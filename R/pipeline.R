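#' Run configuration
#'
#' A run configuration collects every threshold of the pipeline plus the
#' simulation layout, in a plain nested list that round-trips losslessly
#' through YAML.  `export_rate` is flattened to named `"A>B"` entries for
#' serialization.
#'
#' @param spec A `population_spec` (or argument list for one).
#' @param qc List: `maf_min`, `snp_cr_min`, `sample_cr_min`.
#' @param prune List: `window_snps`, `step`, `vif_max`.
#' @param fuzzy_threshold Linkage review threshold (0-100).
#' @param ld List: `max_dist`, `n_bins`.
#' @param admixture List: `enabled`, `k_grid`, `cv_folds`.
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Master seed of the run (overrides the spec seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(spec = population_spec(),
                       qc = list(maf_min = 0.01, snp_cr_min = 0.90,
                                 sample_cr_min = 0.90),
                       prune = list(window_snps = 50L, step = 5L,
                                    vif_max = 2.0),
                       fuzzy_threshold = 90,
                       ld = list(max_dist = 1e6, n_bins = 50L),
                       admixture = list(enabled = TRUE, k_grid = 2:8,
                                        cv_folds = 3L),
                       out_dir = tempfile("herdlink_run_"),
                       seed = 1L) {
  if (!inherits(spec, "population_spec")) spec <- do.call(population_spec, spec)
  spec$seed <- as.integer(seed)
  structure(list(spec = spec, qc = qc, prune = prune,
                 fuzzy_threshold = fuzzy_threshold, ld = ld,
                 admixture = admixture, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  sp <- unclass(x$spec)
  er <- sp$export_rate
  flat <- list()
  for (a in rownames(er)) for (b in colnames(er))
    if (er[a, b] > 0) flat[[paste0(a, ">", b)]] <- er[a, b]
  sp$export_rate <- flat
  sp$fst <- as.list(sp$fst)
  x$spec <- sp
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sp <- x$spec
  countries <- toupper(unlist(sp$countries))
  er <- matrix(0, length(countries), length(countries),
               dimnames = list(countries, countries))
  for (key in names(sp$export_rate)) {
    ab <- strsplit(key, ">", fixed = TRUE)[[1]]
    er[ab[1], ab[2]] <- sp$export_rate[[key]]
  }
  sp$export_rate <- er
  sp$fst <- unlist(sp$fst)
  sp$breeds <- unlist(sp$breeds)
  sp$countries <- countries
  if (!is.null(sp$genotyping_windows))
    sp$genotyping_windows <- lapply(sp$genotyping_windows, unlist)
  sp$id_corruption <- as.list(sp$id_corruption)
  spec <- do.call(population_spec, sp)
  run_config(spec = spec, qc = x$qc, prune = x$prune,
             fuzzy_threshold = x$fuzzy_threshold, ld = x$ld,
             admixture = x$admixture, out_dir = x$out_dir, seed = x$seed)
}

#' Census summary of pedigrees and genotypes
#'
#' Per (country, breed): pedigree record count and genotyped-animal
#' count, with `All` margins; the grand totals equal the column sums.
#'
#' @param pedigrees Named list of pedigree data frames (per country).
#' @param genotypes Named list of `genotype_matrix` objects (per
#'   country), or data frames with `breed` per genotyped animal.
#' @return Data frame `country`, `breed`, `pedigree_n`, `genotype_n`.
#' @export
summarize_counts <- function(pedigrees, genotypes = list()) {
  countries <- names(pedigrees)
  breeds <- sort(unique(unlist(lapply(pedigrees, function(p)
    unique(as.data.frame(p)$breed)))))
  gsamp <- lapply(genotypes, function(g)
    if (inherits(g, "genotype_matrix")) g$samples else as.data.frame(g))
  cell <- function(ct, b) {
    ped_n <- sum(vapply(if (ct == "All") countries else ct, function(k) {
      p <- as.data.frame(pedigrees[[k]])
      sum(if (b == "All") rep(TRUE, nrow(p)) else p$breed == b)
    }, 0L))
    gen_n <- sum(vapply(if (ct == "All") names(gsamp) else
      intersect(ct, names(gsamp)), function(k) {
        s <- gsamp[[k]]
        sum(if (b == "All") rep(TRUE, nrow(s)) else s$breed == b)
      }, 0L))
    data.frame(country = ct, breed = b, pedigree_n = ped_n,
               genotype_n = gen_n, stringsAsFactors = FALSE)
  }
  grid <- expand.grid(country = c(countries, "All"), breed = c(breeds, "All"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    cell(grid$country[i], grid$breed[i])))
  out[order(out$country != "All", out$country,
            out$breed != "All", out$breed), ][, ] -> out
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a simulated dataset
#'
#' Executes the stages in order — simulate, validate pedigrees, QC and
#' merge genotypes, link pedigrees and tabulate connectedness, pedigree
#' and genomic inbreeding, LD decay, gametic-phase consistency, pruning,
#' GRM/PCA and (optionally) admixture with cross-validated k — and
#' writes each summary as TSV into `config$out_dir` together with a YAML
#' run manifest.  One seed governs the run; stage seeds are derived from
#' it.  Timings go to a separate `timings.log` (the only
#' non-reproducible file in the bundle).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- character(0)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings <<- c(timings, sprintf("%s\t%.2f", stage, t1 - t0))
    t0 <<- t1
  }
  emit <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  sim <- tryCatch(simulate_dataset(config$spec),
                  error = function(e) fail("simulate", e))
  tick("simulate")

  peds <- tryCatch(lapply(sim$pedigrees, function(p) validate_pedigree(p)$pedigree),
                   error = function(e) fail("validate_pedigree", e))
  tick("validate_pedigree")

  qc <- tryCatch({
    per_country <- lapply(sim$genotypes, function(g)
      qc_filter(deduplicate(g)$genotypes,
                maf_min = config$qc$maf_min,
                snp_cr_min = config$qc$snp_cr_min,
                sample_cr_min = config$qc$sample_cr_min))
    merged <- merge_datasets(lapply(per_country, `[[`, "genotypes"),
                             maf_min = config$qc$maf_min,
                             snp_cr_min = config$qc$snp_cr_min,
                             sample_cr_min = config$qc$sample_cr_min)
    list(per_country = per_country, merged = merged)
  }, error = function(e) fail("genotype_qc", e))
  gm <- qc$merged$genotypes
  tick("genotype_qc")

  genotyped_ids <- lapply(sim$genotypes, function(g) g$samples$id)
  conn <- tryCatch(
    tabulate_connectedness(peds, genotyped_ids,
                           fuzzy_threshold = config$fuzzy_threshold),
    error = function(e) fail("connectedness", e))
  tick("connectedness")

  fped <- tryCatch(pedigree_inbreeding(sim$registry),
                   error = function(e) fail("pedigree_inbreeding", e))
  tick("pedigree_inbreeding")

  ld <- tryCatch({
    lapply(split(seq_len(nrow(gm$samples)),
                 paste(gm$samples$breed, gm$samples$country, sep = ".")),
           function(ix) {
             if (length(ix) < 10L) return(NULL)
             ld_decay(subset_genotypes(gm, samples = ix),
                      max_dist = config$ld$max_dist,
                      n_bins = config$ld$n_bins)
           })
  }, error = function(e) fail("ld_decay", e))
  tick("ld_decay")

  phase <- tryCatch({
    out <- list()
    for (b in config$spec$breeds) {
      ctys <- unique(gm$samples$country[gm$samples$breed == b])
      if (length(ctys) < 2L) next
      prs <- utils::combn(sort(ctys), 2L)
      for (pc in seq_len(ncol(prs))) {
        ia <- which(gm$samples$breed == b & gm$samples$country == prs[1, pc])
        ib <- which(gm$samples$breed == b & gm$samples$country == prs[2, pc])
        if (length(ia) < 10L || length(ib) < 10L) next
        key <- paste0(b, ":", prs[1, pc], "-", prs[2, pc])
        out[[key]] <- phase_consistency(subset_genotypes(gm, samples = ia),
                                        subset_genotypes(gm, samples = ib),
                                        max_dist = config$ld$max_dist)
      }
    }
    out
  }, error = function(e) fail("phase_consistency", e))
  tick("phase_consistency")

  kept <- tryCatch(ld_prune(gm, window_snps = config$prune$window_snps,
                            step = config$prune$step,
                            vif_max = config$prune$vif_max),
                   error = function(e) fail("ld_prune", e))
  pruned <- subset_genotypes(gm, snps = kept)
  tick("ld_prune")

  g <- tryCatch(grm(pruned), error = function(e) fail("grm", e))
  pc <- tryCatch(pca_grm(g, n_components = min(10L, nrow(g$G))),
                 error = function(e) fail("pca", e))
  fgen <- tryCatch(genomic_inbreeding(pruned),
                   error = function(e) fail("genomic_inbreeding", e))
  tick("structure")

  adm <- NULL
  if (isTRUE(config$admixture$enabled)) {
    adm <- tryCatch({
      ck <- choose_k(pruned, k_grid = config$admixture$k_grid,
                     cv_folds = config$admixture$cv_folds,
                     seed = config$seed)
      fit <- admixture_em(pruned, ck$selected_k, seed = config$seed)
      list(cv = ck, fit = fit)
    }, error = function(e) fail("admixture", e))
  }
  tick("admixture")

  # --- report bundle -------------------------------------------------------
  counts <- summarize_counts(peds, sim$genotypes)
  emit(counts, "table1_counts")
  emit(conn$pairwise, "table2_pairwise_connectedness")
  emit(conn$foreign_sire, "table3_foreign_sire")
  emit(conn$foreign_dam, "table3b_foreign_dam")
  emit(conn$shared_genotyped, "table4_shared_genotyped")

  fped_sum <- inbreeding_by_group(fped, sim$registry,
                                  ids = unlist(genotyped_ids))
  fgen_sum <- inbreeding_by_group(fgen, sim$registry,
                                  ids = unlist(genotyped_ids),
                                  value = "F_het")
  emit(inbreeding_comparison(fped_sum, fgen_sum), "table5_inbreeding")

  for (nm in names(ld)) if (!is.null(ld[[nm]]))
    emit(ld[[nm]]$curve, paste0("ld_decay_", nm))
  for (nm in names(phase))
    emit(phase[[nm]], paste0("phase_", gsub("[^A-Za-z0-9_-]", "_", nm)))
  emit(data.frame(id = rownames(pc$coords), gm$samples[
    match(rownames(pc$coords), gm$samples$id), c("breed", "country")],
    pc$coords[, 1:min(4L, ncol(pc$coords))]), "pca_coords")
  if (!is.null(adm)) {
    emit(adm$cv$cv_error, "admixture_cv")
    q <- data.frame(id = pruned$samples$id, adm$fit$Q)
    names(q) <- c("id", paste0("q", seq_len(adm$fit$k)))
    emit(q, "admixture_q")
  }

  manifest <- list(
    package = "herdlink",
    version = as.character(utils::packageVersion("herdlink")),
    seed = config$seed,
    thresholds = list(qc = config$qc, prune = config$prune,
                      fuzzy_threshold = config$fuzzy_threshold,
                      ld = config$ld),
    sizes = list(animals = nrow(sim$registry),
                 genotyped = length(unlist(genotyped_ids)),
                 snps_qc = ncol(gm$calls), snps_pruned = length(kept)))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  writeLines(timings, file.path(config$out_dir, "timings.log"))

  invisible(list(sim = sim, pedigrees = peds, qc = qc,
                 connectedness = conn, fped = fped, fped_summary = fped_sum,
                 ld = ld, phase = phase, pruned_snps = kept, grm = g,
                 pca = pc, fgen = fgen, fgen_summary = fgen_sum,
                 admixture = adm, counts = counts))
}
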