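#' Reference tables from a four-country dairy-goat exchange
#'
#' Cell-level reference summaries for a two-breed (Alpine, Saanen),
#' four-country (Canada, Switzerland, France, Italy) genotype- and
#' pedigree-sharing programme, bundled as worked-example inputs for the
#' tabulation arithmetic: census sizes, pairwise connectedness cells,
#' French-sire progeny cells and inbreeding means.  The package's report
#' functions recompute every total, margin and proportion of these
#' tables from the cells.
#'
#' @return Each function returns a plain data frame of cells:
#'   * `example_census()`: `country`, `breed`, `pedigree_n`,
#'     `genotype_n`;
#'   * `example_pairwise_connectedness()`: `pair`, `origin`, `breed`,
#'     `status` (`found`/`missing` in the native pedigree), `count`;
#'   * `example_foreign_sire()`: progeny of French sires — `country`,
#'     `breed`, `sex`, `count`;
#'   * `example_inbreeding()`: `breed`, `country`, `mean`, `se` per
#'     `method` (`pedigree`/`genomic`).
#' @name example_tables
NULL

#' @rdname example_tables
#' @export
example_census <- function() {
  data.frame(
    country = rep(c("CAN", "FRA", "ITA", "CHE"), each = 2L),
    breed = rep(c("ALP", "SAA"), 4L),
    pedigree_n = c(56601, 36741, 3518473, 2527443, 107566, 131376,
                   28083, 28906),
    genotype_n = c(793, 903, 2968, 2009, 1061, 338, 1280, 503),
    stringsAsFactors = FALSE)
}

#' @rdname example_tables
#' @export
example_pairwise_connectedness <- function() {
  pairs <- c("CAN-FRA", "CAN-ITA", "CAN-CHE", "FRA-ITA", "CHE-FRA",
             "CHE-ITA")
  cells <- rbind(
    c("found",   "CHE", "ALP", 0,   0,   0,  0,    0,   798),
    c("found",   "CHE", "SAA", 0,   0,   0,  0,    0,   297),
    c("found",   "FRA", "ALP", 119, 94,  25, 4580, 187, 138),
    c("found",   "FRA", "SAA", 61,  41,  9,  4457, 135, 85),
    c("missing", "CHE", "ALP", 0,   0,   0,  0,    0,   305),
    c("missing", "CHE", "SAA", 0,   0,   0,  0,    0,   190),
    c("missing", "FRA", "ALP", 0,   0,   0,  859,  215, 0),
    c("missing", "FRA", "SAA", 0,   0,   0,  1004, 94,  0))
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(pair = pairs, origin = cells[i, 2], breed = cells[i, 3],
               status = cells[i, 1],
               count = as.integer(cells[i, 4:9]),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @rdname example_tables
#' @export
example_foreign_sire <- function() {
  data.frame(
    country = rep(c("ITA", "CHE", "CAN"), each = 4L),
    breed = rep(c("ALP", "ALP", "SAA", "SAA"), 3L),
    sex = rep(c("F", "M", "F", "M"), 3L),
    count = c(5396, 1821, 8216, 1704,
              374, 107, 305, 93,
              276, 167, 69, 30),
    stringsAsFactors = FALSE)
}

#' @rdname example_tables
#' @export
example_inbreeding <- function() {
  grid <- expand.grid(country = c("ITA", "CAN", "CHE", "FRA"),
                      breed = c("ALP", "SAA"), stringsAsFactors = FALSE)
  ped <- c(0.021, 0.015, 0.019, 0.022, 0.036, 0.048, 0.015, 0.025)
  ped_se <- c(0.045, 0.032, 0.036, 0.012, 0.048, 0.042, 0.027, 0.013)
  gen <- c(0.073, 0.116, 0.042, 0.084, 0.127, 0.095, 0.078, 0.121)
  gen_se <- c(0.049, 0.058, 0.039, 0.034, 0.044, 0.078, 0.034, 0.039)
  rbind(
    data.frame(grid, method = "pedigree", mean = ped, se = ped_se,
               stringsAsFactors = FALSE),
    data.frame(grid, method = "genomic", mean = gen, se = gen_se,
               stringsAsFactors = FALSE))
}
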