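#' Pairwise cross-country connectedness counts
#'
#' For every unordered pair of countries, counts the animals of each origin
#' country that are registered in both members of the pair (or, when the
#' origin is one of the pair, registered in the other member), split by
#' breed and by whether the animal's record was recovered in its native
#' pedigree (`found`) or not (`missing`).  An accepted linkage match means
#' `found`; `review` and `unmatched` records count as `missing`.
#'
#' @param pedigrees Named list of pedigree data frames, one per country
#'   (names are the 3-letter country codes).
#' @param links Named list of [link_pedigrees()] results; element
#'   `"SRC>TGT"` holds the matches of foreign animals born in `SRC` found
#'   in the pedigree of `TGT` against the pedigree of `SRC`.
#' @return Data frame with columns `pair` (e.g. `"CAN-FRA"`), `origin`,
#'   `breed`, `status` (`found`/`missing`) and `count`, covering every
#'   combination (zero cells included) for origins that appear abroad.
#' @export
connectedness_pairwise <- function(pedigrees, links) {
  countries <- names(pedigrees)
  breeds <- sort(unique(unlist(lapply(pedigrees, function(p)
    unique(as.data.frame(p)$breed)))))

  # foreign records of each origin in each target country, with canonical
  # identity (accepted match -> source id) and found/missing status
  foreign <- list()
  for (src in countries) for (tgt in setdiff(countries, src)) {
    key <- paste0(src, ">", tgt)
    tp <- as.data.frame(pedigrees[[tgt]])
    rows <- tp[id_birth_country(tp$id) == substr(src, 1, 2) &
                 is_foreign_id(tp$id), , drop = FALSE]
    if (!nrow(rows)) { foreign[[key]] <- NULL; next }
    mt <- links[[key]]
    status <- rep("missing", nrow(rows))
    canon <- rows$id
    if (!is.null(mt)) {
      m <- match(rows$id, mt$target_id)
      acc <- !is.na(m) & mt$status[m] == "accepted"
      status[acc] <- "found"
      canon[acc] <- mt$source_id[m[acc]]
    }
    foreign[[key]] <- data.frame(canon = canon, breed = rows$breed,
                                 status = status, stringsAsFactors = FALSE)
  }

  pairs <- utils::combn(sort(countries), 2L)
  out <- expand.grid(status = c("found", "missing"),
                     origin = sort(countries), breed = breeds,
                     pair = apply(pairs, 2L, paste, collapse = "-"),
                     stringsAsFactors = FALSE)
  out$count <- 0L
  bump <- function(out, pair, origin, tab) {
    if (!length(tab)) return(out)
    for (r in seq_len(nrow(tab))) {
      i <- which(out$pair == pair & out$origin == origin &
                   out$breed == tab$breed[r] & out$status == tab$status[r])
      out$count[i] <- out$count[i] + tab$count[r]
    }
    out
  }
  for (pc in seq_len(ncol(pairs))) {
    x <- pairs[1L, pc]; y <- pairs[2L, pc]
    pair <- paste(x, y, sep = "-")
    for (origin in sort(countries)) {
      if (origin == x || origin == y) {
        tgt <- if (origin == x) y else x
        f <- foreign[[paste0(origin, ">", tgt)]]
        if (is.null(f)) next
        tab <- stats::aggregate(list(count = rep(1L, nrow(f))),
                                by = f[c("breed", "status")], FUN = sum)
      } else {
        fx <- foreign[[paste0(origin, ">", x)]]
        fy <- foreign[[paste0(origin, ">", y)]]
        if (is.null(fx) || is.null(fy)) next
        m <- match(fx$canon, fy$canon)
        both <- !is.na(m)
        if (!any(both)) next
        tab <- data.frame(breed = fx$breed[both],
                          status = ifelse(fx$status[both] == "found" &
                                            fy$status[m[both]] == "found",
                                          "found", "missing"),
                          stringsAsFactors = FALSE)
        tab <- stats::aggregate(list(count = rep(1L, nrow(tab))),
                                by = tab[c("breed", "status")], FUN = sum)
      }
      out <- bump(out, pair, origin, tab)
    }
  }
  # drop origins that never occur abroad, matching the published table shape
  tot <- tapply(out$count, out$origin, sum)
  out <- out[out$origin %in% names(tot)[tot > 0], , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$status, out$origin, out$breed, out$pair), ]
}

#' Totals of a pairwise connectedness table
#'
#' @param cells Data frame as returned by [connectedness_pairwise()] (or
#'   any table with `pair` and `count` columns).
#' @return List with `per_pair` (named totals per country pair) and
#'   `grand_total` (sum over every cell, the "All" figure).
#' @export
connectedness_totals <- function(cells) {
  per_pair <- tapply(cells$count, cells$pair, sum)
  list(per_pair = per_pair, grand_total = sum(cells$count))
}

#' Foreign-parent progeny counts
#'
#' Scans each pedigree for animals whose sire (or dam) was born in a given
#' foreign country, counted by breed and sex of the progeny.
#'
#' @param pedigrees Named list of pedigrees.
#' @param origin 3-letter code of the parents' country of birth.
#' @param parent `"sire"` or `"dam"`.
#' @return Data frame `country`, `breed`, `sex`, `count` (zero cells
#'   included) over the non-origin countries.
#' @export
foreign_parent_counts <- function(pedigrees, origin, parent = c("sire", "dam")) {
  parent <- match.arg(parent)
  cc <- substr(origin, 1L, 2L)
  countries <- setdiff(names(pedigrees), origin)
  breeds <- sort(unique(unlist(lapply(pedigrees, function(p)
    unique(as.data.frame(p)$breed)))))
  out <- expand.grid(country = countries, breed = breeds, sex = c("F", "M"),
                     stringsAsFactors = FALSE)
  out$count <- 0L
  for (ctry in countries) {
    p <- as.data.frame(pedigrees[[ctry]])
    par <- p[[parent]]
    hit <- !is.na(par) & nchar(par) == 23L & id_birth_country(par) == cc
    if (!any(hit)) next
    tab <- table(breed = p$breed[hit], sex = p$sex[hit])
    for (b in rownames(tab)) for (s in colnames(tab)) {
      i <- which(out$country == ctry & out$breed == b & out$sex == s)
      if (length(i)) out$count[i] <- out$count[i] + tab[b, s]
    }
  }
  out
}

#' Foreign-parent table with margins and pedigree proportions
#'
#' Builds the published-style summary of foreign-sired (or dammed) progeny:
#' one row per importing country, one column per breed-by-sex cell, a total
#' column, and a bottom total row.  Every count is accompanied by its
#' percentage of the matching native-pedigree margin: cell counts are
#' divided by the (country, breed) pedigree size, country totals by the
#' country pedigree size, bottom-row cells by the across-country breed
#' size, and the grand total by the overall pedigree size.
#'
#' @param counts Data frame `country`, `breed`, `sex`, `count` (as from
#'   [foreign_parent_counts()], or printed cells being checked).
#' @param ped_sizes Data frame `country`, `breed`, `n` with native
#'   pedigree sizes.
#' @return Data frame with columns `country`, `breed`, `sex`, `count`,
#'   `pct`; margin rows/columns carry the label `"All"`.
#' @export
foreign_parent_table <- function(counts, ped_sizes) {
  size <- function(ctry, brd) {
    s <- ped_sizes
    if (ctry != "All") s <- s[s$country == ctry, , drop = FALSE]
    if (brd != "All") s <- s[s$breed == brd, , drop = FALSE]
    sum(s$n)
  }
  cell <- function(ctry, brd, sx) {
    k <- counts
    if (ctry != "All") k <- k[k$country == ctry, , drop = FALSE]
    if (brd != "All") k <- k[k$breed == brd, , drop = FALSE]
    if (sx != "All") k <- k[k$sex == sx, , drop = FALSE]
    sum(k$count)
  }
  rows <- c(sort(unique(counts$country)), "All")
  cols <- rbind(expand.grid(breed = sort(unique(counts$breed)),
                            sex = c("F", "M"), stringsAsFactors = FALSE),
                data.frame(breed = "All", sex = "All"))
  out <- do.call(rbind, lapply(rows, function(ctry) {
    do.call(rbind, lapply(seq_len(nrow(cols)), function(j) {
      b <- cols$breed[j]; s <- cols$sex[j]
      cnt <- as.integer(round(cell(ctry, b, s)))
      den <- size(ctry, b)
      data.frame(country = ctry, breed = b, sex = s, count = cnt,
                 pct = if (den > 0) 100 * cnt / den else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Genotyped animals recorded in several countries
#'
#' Counts, for each national pedigree and breed, the genotyped animals that
#' are registered in at least two national pedigrees, together with the
#' proportion of the native pedigree they represent.
#'
#' @param pedigrees Named list of pedigrees.
#' @param genotyped Named list (per country) of character vectors of
#'   genotyped canonical identifiers.
#' @param links Named list of linkage results (as in
#'   [connectedness_pairwise()]) used to resolve corrupted foreign records
#'   to canonical identities.
#' @return Data frame `country`, `breed`, `count`, `pct` where `pct` is
#'   the percentage of the (country, breed) pedigree size.
#' @export
shared_genotyped_counts <- function(pedigrees, genotyped, links = list()) {
  countries <- names(pedigrees)
  # canonical identity set per country
  canon <- lapply(countries, function(ctry) {
    p <- as.data.frame(pedigrees[[ctry]])
    ids <- p$id
    for (src in setdiff(countries, ctry)) {
      mt <- links[[paste0(src, ">", ctry)]]
      if (is.null(mt)) next
      acc <- mt$status == "accepted"
      m <- match(mt$target_id[acc], ids)
      ids[m[!is.na(m)]] <- mt$source_id[acc][!is.na(m)]
    }
    ids
  })
  names(canon) <- countries
  all_gen <- unique(unlist(genotyped, use.names = FALSE))
  if (length(all_gen)) {
    presence <- vapply(canon, function(ids) all_gen %in% ids,
                       logical(length(all_gen)))
    if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1L)
    shared <- all_gen[rowSums(presence) >= 2L]
  } else {
    shared <- character(0)
  }

  out <- do.call(rbind, lapply(countries, function(ctry) {
    p <- as.data.frame(pedigrees[[ctry]])
    ids <- canon[[ctry]]
    do.call(rbind, lapply(sort(unique(p$breed)), function(b) {
      in_ped <- ids[p$breed == b]
      cnt <- sum(shared %in% in_ped)
      den <- sum(p$breed == b)
      data.frame(country = ctry, breed = b, count = cnt,
                 pct = if (den > 0) 100 * cnt / den else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Side-by-side pedigree vs genomic inbreeding summary
#'
#' Joins two per-group inbreeding summaries (means and dispersions per
#' breed-by-country group) and computes the genomic-minus-pedigree
#' difference of the means — the figure used to judge how much inbreeding
#' the pedigree fails to capture.
#'
#' @param ped_summary,gen_summary Data frames with columns `breed`,
#'   `country`, `mean` (and optionally `sd`, `n`).
#' @return Data frame `breed`, `country`, `mean_ped`, `mean_gen`, `diff`.
#' @export
inbreeding_comparison <- function(ped_summary, gen_summary) {
  key <- c("breed", "country")
  m <- merge(ped_summary[, c(key, "mean")], gen_summary[, c(key, "mean")],
             by = key, suffixes = c("_ped", "_gen"))
  names(m)[names(m) == "mean_ped"] <- "mean_ped"
  m$diff <- m$mean_gen - m$mean_ped
  m[order(m$breed, m$country), , drop = FALSE]
}

#' Full connectedness report
#'
#' Runs the 12 ordered pedigree comparisons (for four countries) and
#' assembles the pairwise table, foreign-sire and foreign-dam counts per
#' importing country, and shared-genotyped counts.
#'
#' @param pedigrees Named list of validated pedigrees.
#' @param genotyped Named list of genotyped canonical id vectors.
#' @param fuzzy_threshold Passed to [link_pedigrees()].
#' @param parent_origin Country whose exported parents are tallied
#'   (default the country with the largest pedigree).
#' @return List with `links`, `pairwise`, `totals`, `foreign_sire`,
#'   `foreign_dam`, `shared_genotyped`.
#' @export
tabulate_connectedness <- function(pedigrees, genotyped = list(),
                                   fuzzy_threshold = 90,
                                   parent_origin = NULL) {
  countries <- names(pedigrees)
  links <- list()
  for (src in countries) for (tgt in setdiff(countries, src)) {
    links[[paste0(src, ">", tgt)]] <-
      link_pedigrees(pedigrees[[src]], pedigrees[[tgt]],
                     fuzzy_threshold = fuzzy_threshold,
                     source_country = src)
  }
  if (is.null(parent_origin)) {
    # dominant exporter: birth country most often seen in foreign pedigrees
    abroad <- stats::setNames(numeric(length(countries)), countries)
    for (ct in countries) {
      p <- as.data.frame(pedigrees[[ct]])
      cc <- id_birth_country(p$id[is_foreign_id(p$id)])
      for (oc in countries)
        if (oc != ct) abroad[oc] <- abroad[oc] + sum(cc == substr(oc, 1, 2))
    }
    parent_origin <- names(abroad)[which.max(abroad)]
  }
  ped_sizes <- do.call(rbind, lapply(countries, function(ctry) {
    p <- as.data.frame(pedigrees[[ctry]])
    stats::aggregate(list(n = rep(1L, nrow(p))),
                     by = list(country = rep(ctry, nrow(p)), breed = p$breed),
                     FUN = sum)
  }))
  pairwise <- connectedness_pairwise(pedigrees, links)
  list(links = links,
       pairwise = pairwise,
       totals = connectedness_totals(pairwise),
       foreign_sire = foreign_parent_table(
         foreign_parent_counts(pedigrees, parent_origin, "sire"), ped_sizes),
       foreign_dam = foreign_parent_table(
         foreign_parent_counts(pedigrees, parent_origin, "dam"), ped_sizes),
       shared_genotyped = shared_genotyped_counts(pedigrees, genotyped, links),
       ped_sizes = ped_sizes)
}
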