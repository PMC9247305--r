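#' Canonical animal identifiers
#'
#' Animals exchanged between herdbooks are keyed by a fixed-width
#' 23-character identifier: a 3-letter breed code, the 3-letter code of the
#' country of registration, one letter for sex (`F`/`M`), and a 16-character
#' core consisting of the 2-letter birth-country code followed by the local
#' identifier, left-padded with `0` to fill the 16 characters.  An Alpine
#' female with local ID 5248383, born in France and raised in Switzerland,
#' is `ALPCHEF0000000FR5248383`.
#'
#' @param raw_id Local identifier (digits and letters), at most 14
#'   characters once any leading zeros and a leading birth-country code are
#'   stripped.  Passing an already-canonical 16-character core is allowed
#'   and idempotent.
#' @param breed 3-letter breed code (e.g. `"ALP"`, `"SAA"`).
#' @param registration_country 3-letter code of the registering country.
#' @param sex `"F"` or `"M"`.
#' @param birth_country 2-letter code of the country of birth (defaults to
#'   the first two letters of `registration_country`).
#' @return A 23-character canonical identifier string (vectorized).
#' @examples
#' standardize_id("5248383", "ALP", "CHE", "F", "FR")
#' @export
standardize_id <- function(raw_id, breed, registration_country, sex,
                           birth_country = substr(registration_country, 1, 2)) {
  raw_id <- as.character(raw_id)
  if (any(is.na(raw_id) | !nzchar(raw_id)))
    stop("raw_id must be non-empty")
  breed <- toupper(breed)
  registration_country <- toupper(registration_country)
  sex <- toupper(sex)
  birth_country <- toupper(birth_country)
  if (any(nchar(breed) != 3L))
    stop("breed must be a 3-letter code")
  if (any(nchar(registration_country) != 3L))
    stop("registration_country must be a 3-letter code")
  if (!all(sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  if (any(nchar(birth_country) != 2L))
    stop("birth_country must be a 2-letter code")

  n <- max(length(raw_id), length(breed), length(registration_country),
           length(sex), length(birth_country))
  raw_id <- rep_len(raw_id, n); breed <- rep_len(breed, n)
  registration_country <- rep_len(registration_country, n)
  sex <- rep_len(sex, n); birth_country <- rep_len(birth_country, n)

  # strip any left zero-padding, then a leading birth-country code if the
  # caller handed us something already (partially) canonical
  bare <- sub("^0+", "", toupper(raw_id))
  has_cc <- startsWith(bare, birth_country)
  bare[has_cc] <- substring(bare[has_cc], 3L)
  too_long <- nchar(bare) > 14L
  if (any(too_long))
    stop("raw_id longer than 14 characters after stripping padding: ",
         paste(raw_id[too_long], collapse = ", "))
  core <- paste0(birth_country, bare)
  core <- paste0(strrep("0", 16L - nchar(core)), core)
  paste0(breed, registration_country, sex, core)
}

#' Parse canonical identifiers into their components
#'
#' @param id Character vector of 23-character canonical identifiers.
#' @return A data frame with columns `id`, `breed`, `country`, `sex`,
#'   `core`, `birth_country` (the 2-letter code recovered from the core)
#'   and `local_id` (the core with padding and birth code removed).
#' @export
parse_canonical_id <- function(id) {
  id <- as.character(id)
  bad <- !is.na(id) & nchar(id) != 23L
  if (any(bad))
    stop("canonical identifiers must have 23 characters; offending: ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  core <- substr(id, 8L, 23L)
  bare <- sub("^0+", "", core)
  data.frame(
    id = id,
    breed = substr(id, 1L, 3L),
    country = substr(id, 4L, 6L),
    sex = substr(id, 7L, 7L),
    core = core,
    birth_country = substr(bare, 1L, 2L),
    local_id = substring(bare, 3L),
    stringsAsFactors = FALSE
  )
}

#' Birth-country code of canonical identifiers
#'
#' @param id Character vector of canonical identifiers.
#' @return 2-letter birth-country codes.
#' @keywords internal
id_birth_country <- function(id) {
  substr(sub("^0+", "", substr(id, 8L, 23L)), 1L, 2L)
}

#' Is an animal foreign to its registering country?
#'
#' An animal is foreign when the birth-country code embedded in its
#' identifier core differs from the first two letters of the country of
#' registration.
#'
#' @param id Canonical identifiers.
#' @param registration_country Optional 3-letter codes; defaults to the
#'   codes embedded in `id`.
#' @return Logical vector.
#' @export
is_foreign_id <- function(id, registration_country = substr(id, 4L, 6L)) {
  id_birth_country(id) != substr(toupper(registration_country), 1L, 2L)
}
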