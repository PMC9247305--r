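#' Pedigree tables
#'
#' A pedigree is stored as a plain data frame with one row per animal and
#' columns `id`, `sire`, `dam` (canonical identifiers, `NA` when unknown),
#' `sex` (`"F"`/`"M"`), `birth_year`, `breed`, `country` and `alias1` ..
#' `alias3` (alternative identifiers, `NA` when absent).
#'
#' @param id,sire,dam Canonical identifiers (`NA` for unknown parents).
#' @param sex,birth_year,breed,country Per-animal metadata.
#' @param alias1,alias2,alias3 Optional alternative identifiers.
#' @return A `herd_pedigree` data frame.
#' @export
pedigree_table <- function(id, sire = NA, dam = NA, sex = NA,
                           birth_year = NA, breed = NA, country = NA,
                           alias1 = NA, alias2 = NA, alias3 = NA) {
  n <- length(id)
  ped <- data.frame(
    id = as.character(id),
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    sex = rep_len(as.character(sex), n),
    birth_year = rep_len(as.integer(birth_year), n),
    breed = rep_len(as.character(breed), n),
    country = rep_len(as.character(country), n),
    alias1 = rep_len(as.character(alias1), n),
    alias2 = rep_len(as.character(alias2), n),
    alias3 = rep_len(as.character(alias3), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("herd_pedigree", "data.frame")
  ped
}

pedigree_columns <- c("id", "sire", "dam", "sex", "birth_year", "breed",
                      "country", "alias1", "alias2", "alias3")

#' Read / write pedigree CSV files
#'
#' @param path File path.
#' @return `read_pedigree()` returns a `herd_pedigree` data frame;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(pedigree_columns, names(df))
  for (cc in missing_cols) df[[cc]] <- NA_character_
  df <- df[pedigree_columns]
  df$birth_year <- suppressWarnings(as.integer(df$birth_year))
  for (cc in setdiff(pedigree_columns, "birth_year"))
    df[[cc]][!is.na(df[[cc]]) & df[[cc]] == ""] <- NA_character_
  class(df) <- c("herd_pedigree", "data.frame")
  df
}

#' @rdname read_pedigree
#' @param ped A pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped)[pedigree_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate and repair a pedigree
#'
#' Applies the standard herdbook consistency checks: every animal referenced
#' as a sire or dam must have its own record (missing parents are added as
#' founder records, sex inferred from the role); duplicated identifiers are
#' collapsed to the first occurrence (conflicting rows are logged); parent
#' links that create a cycle (an animal among its own ancestors) are broken
#' by unlinking the offending parent.  No issue is fatal; everything is
#' counted in the report.
#'
#' @param ped A pedigree data frame (see [pedigree_table()]).
#' @return A list with elements `pedigree` (the cleaned pedigree) and
#'   `report` (named counts: `added_founders`, `collapsed_duplicates`,
#'   `broken_cycles`, `sex_conflicts`).
#' @export
validate_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  for (cc in setdiff(pedigree_columns, names(ped))) ped[[cc]] <- NA
  ped <- ped[pedigree_columns]
  log <- list(added_founders = character(), collapsed_duplicates = character(),
              broken_cycles = character(), sex_conflicts = character())

  # collapse duplicated ids, first record wins
  dup <- duplicated(ped$id)
  if (any(dup)) {
    log$collapsed_duplicates <- unique(ped$id[dup])
    ped <- ped[!dup, , drop = FALSE]
  }

  # phantom founders for referenced-but-absent parents
  ref_sires <- setdiff(stats::na.omit(unique(ped$sire)), ped$id)
  ref_dams  <- setdiff(stats::na.omit(unique(ped$dam)),  ped$id)
  ref_dams  <- setdiff(ref_dams, ref_sires)
  add <- function(ids, sex) {
    if (!length(ids)) return(NULL)
    info <- parse_canonical_id_or_na(ids)
    pedigree_table(id = ids, sex = sex, breed = info$breed,
                   country = info$country)
  }
  phantoms <- rbind(add(ref_sires, "M"), add(ref_dams, "F"))
  if (!is.null(phantoms) && nrow(phantoms)) {
    log$added_founders <- phantoms$id
    ped <- rbind(ped, phantoms)
  }

  # parent sex consistency
  idx <- match(ped$sire, ped$id)
  bad <- !is.na(idx) & !is.na(ped$sex[idx]) & ped$sex[idx] != "M"
  log$sex_conflicts <- ped$sire[bad]
  idx <- match(ped$dam, ped$id)
  bad <- !is.na(idx) & !is.na(ped$sex[idx]) & ped$sex[idx] != "F"
  log$sex_conflicts <- unique(c(log$sex_conflicts, ped$dam[bad]))

  # cycle detection by Kahn peeling; unresolved animals sit on a cycle
  repeat {
    ord <- pedigree_order(ped, partial = TRUE)
    if (!length(ord$cyclic)) break
    culprit <- ord$cyclic[1L]
    i <- match(culprit, ped$id)
    log$broken_cycles <- c(log$broken_cycles, culprit)
    if (!is.na(ped$sire[i])) ped$sire[i] <- NA_character_
    else ped$dam[i] <- NA_character_
  }

  rownames(ped) <- NULL
  class(ped) <- c("herd_pedigree", "data.frame")
  list(pedigree = ped,
       report = list(added_founders = length(log$added_founders),
                     collapsed_duplicates = length(log$collapsed_duplicates),
                     broken_cycles = length(log$broken_cycles),
                     sex_conflicts = length(unique(log$sex_conflicts)),
                     detail = log))
}

parse_canonical_id_or_na <- function(ids) {
  ok <- nchar(ids) == 23L
  out <- data.frame(breed = rep(NA_character_, length(ids)),
                    country = NA_character_, stringsAsFactors = FALSE)
  if (any(ok)) {
    p <- parse_canonical_id(ids[ok])
    out$breed[ok] <- p$breed
    out$country[ok] <- p$country
  }
  out
}

#' Topological order of a pedigree (parents before offspring)
#'
#' @param ped Pedigree data frame.
#' @param partial If `TRUE`, return a list with the orderable ids and the
#'   ids stuck on a cycle instead of erroring.
#' @return Integer row order, or a list with `order` and `cyclic`.
#' @keywords internal
pedigree_order <- function(ped, partial = FALSE) {
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  indeg <- (!is.na(sire)) + (!is.na(dam))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(sire[i])) children[[sire[i]]] <- c(children[[sire[i]]], i)
    if (!is.na(dam[i])) children[[dam[i]]] <- c(children[[dam[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    if (!partial) stop("pedigree contains a cycle")
    return(list(order = ord, cyclic = ped$id[setdiff(seq_len(n), ord)]))
  }
  if (partial) list(order = ord, cyclic = character(0)) else ord
}
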