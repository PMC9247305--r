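#' Link foreign animals of a target pedigree back to their source pedigree
#'
#' For every animal of the target pedigree whose identifier core carries a
#' foreign birth-country code matching the source country, four matching
#' tiers are tried in order:
#'
#' 1. **exact** — the canonical identifier is present in the source
#'    pedigree (accepted);
#' 2. **alias** — any alias of the target record equals a source
#'    identifier or alias, or the target identifier equals a source alias
#'    (accepted);
#' 3. **suffix** — the trailing digit run of the target core (at least
#'    `min_suffix` digits) equals the trailing digits of exactly one
#'    source identifier; ties disqualify the tier (accepted);
#' 4. **fuzzy** — highest normalized Levenshtein similarity (0-100 scale,
#'    computed on the 16-character cores) among source animals born in the
#'    same country; a score at or above `fuzzy_threshold` yields status
#'    `review` (never auto-accepted, mirroring manual verification), below
#'    it the animal stays `unmatched`.
#'
#' Within each tier a source identifier is consumed by at most one target
#' animal (first come, and for the fuzzy tier highest score first).
#'
#' @param source_ped Pedigree of the country of origin.
#' @param target_ped Pedigree possibly containing animals born in the
#'   source country.
#' @param fuzzy_threshold Minimum 0-100 similarity for a fuzzy candidate
#'   to be reported for review (default 90).
#' @param min_suffix Minimum trailing-digit length for the suffix tier
#'   (default 5; shorter suffixes collide in large pedigrees).
#' @param source_country Optional 3-letter code of the source country; by
#'   default taken from the most frequent `country` of `source_ped`.
#' @return A data frame of match results: `target_id`, `source_id`,
#'   `method` (`exact`/`alias`/`suffix`/`fuzzy`/`none`), `score` (0-100)
#'   and `status` (`accepted`/`review`/`unmatched`).
#' @export
link_pedigrees <- function(source_ped, target_ped, fuzzy_threshold = 90,
                           min_suffix = 5L, source_country = NULL) {
  source_ped <- as.data.frame(source_ped)
  target_ped <- as.data.frame(target_ped)
  if (is.null(source_country)) {
    tab <- table(source_ped$country)
    source_country <- if (length(tab)) names(tab)[which.max(tab)] else "XXX"
  }
  birth_cc <- substr(source_country, 1L, 2L)

  foreign <- target_ped[id_birth_country(target_ped$id) == birth_cc &
                          is_foreign_id(target_ped$id), , drop = FALSE]
  nf <- nrow(foreign)
  res <- data.frame(target_id = foreign$id,
                    source_id = rep(NA_character_, nf),
                    method = rep("none", nf), score = rep(NA_real_, nf),
                    status = rep("unmatched", nf), stringsAsFactors = FALSE)
  if (!nrow(foreign) || !nrow(source_ped)) return(res)

  src_ids <- source_ped$id
  src_alias <- c(source_ped$alias1, source_ped$alias2, source_ped$alias3)
  src_alias_owner <- rep(src_ids, 3L)
  keep <- !is.na(src_alias)
  src_alias <- src_alias[keep]; src_alias_owner <- src_alias_owner[keep]

  used <- list(exact = character(), alias = character(),
               suffix = character(), fuzzy = character())
  pending <- rep(TRUE, nrow(res))

  # identity is registration-invariant: an animal registered in two
  # countries shares breed, sex and core but not the country field
  src_keys <- id_identity_key(src_ids)
  src_alias_keys <- id_identity_key(src_alias)

  # tier 1: exact ----------------------------------------------------------
  tgt_keys <- id_identity_key(res$target_id)
  for (i in which(pending)) {
    hit <- which(src_keys == tgt_keys[i] & !(src_ids %in% used$exact))
    if (length(hit)) {
      res$source_id[i] <- src_ids[hit[1L]]; res$method[i] <- "exact"
      res$score[i] <- 100; res$status[i] <- "accepted"
      used$exact <- c(used$exact, src_ids[hit[1L]]); pending[i] <- FALSE
    }
  }

  # tier 2: alias -----------------------------------------------------------
  tgt_alias <- foreign[, c("alias1", "alias2", "alias3"), drop = FALSE]
  for (i in which(pending)) {
    cand <- character(0)
    ta <- stats::na.omit(unlist(tgt_alias[i, ], use.names = FALSE))
    ta_keys <- id_identity_key(ta)
    if (length(ta)) cand <- c(cand, src_ids[src_keys %in% ta_keys],
                              src_alias_owner[src_alias_keys %in% ta_keys])
    cand <- c(cand, src_alias_owner[src_alias_keys == tgt_keys[i]])
    cand <- setdiff(unique(cand), used$alias)
    if (length(cand)) {
      res$source_id[i] <- cand[1L]; res$method[i] <- "alias"
      res$score[i] <- 100; res$status[i] <- "accepted"
      used$alias <- c(used$alias, cand[1L]); pending[i] <- FALSE
    }
  }

  # tier 3: unique suffix ---------------------------------------------------
  src_suffix <- trailing_digits(src_ids)
  for (i in which(pending)) {
    sfx <- trailing_digits(res$target_id[i])
    if (nchar(sfx) < min_suffix) next
    hit <- which(nchar(src_suffix) >= nchar(sfx) &
                   endsWith(src_suffix, sfx) & !(src_ids %in% used$suffix))
    if (length(hit) == 1L) {
      res$source_id[i] <- src_ids[hit]; res$method[i] <- "suffix"
      res$score[i] <- 100; res$status[i] <- "accepted"
      used$suffix <- c(used$suffix, src_ids[hit]); pending[i] <- FALSE
    }
  }

  # tier 4: fuzzy (same birth country), highest score first -----------------
  if (any(pending)) {
    src_cc <- id_birth_country(src_ids)
    cand_idx <- which(src_cc == birth_cc)
    if (length(cand_idx)) {
      tgt_core <- substr(res$target_id[pending], 8L, 23L)
      src_core <- substr(src_ids[cand_idx], 8L, 23L)
      dist <- utils::adist(tgt_core, src_core)
      len <- outer(nchar(tgt_core), nchar(src_core), pmax)
      sim <- 100 * (1 - dist / len)
      pend_idx <- which(pending)
      best <- apply(sim, 1L, which.max)
      score <- sim[cbind(seq_along(best), best)]
      for (o in order(score, decreasing = TRUE)) {
        i <- pend_idx[o]
        # best available candidate for this target
        srow <- sim[o, ]
        avail <- !(src_ids[cand_idx] %in% used$fuzzy)
        if (!any(avail)) break
        j <- which(avail)[which.max(srow[avail])]
        sc <- srow[j]
        res$method[i] <- "fuzzy"
        res$score[i] <- sc
        if (sc >= fuzzy_threshold) {
          res$source_id[i] <- src_ids[cand_idx][j]
          res$status[i] <- "review"
          used$fuzzy <- c(used$fuzzy, src_ids[cand_idx][j])
        }
      }
    }
  }
  res
}

# breed + sex + core: the parts of a canonical id that identify the animal
# regardless of where it is registered
id_identity_key <- function(id) {
  if (!length(id)) return(character(0))
  paste0(substr(id, 1L, 3L), substring(id, 7L))
}

trailing_digits <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+$", x))
  out <- character(length(x))
  out[regexpr("[0-9]+$", x) > 0] <- m
  out
}
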