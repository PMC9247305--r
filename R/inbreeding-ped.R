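#' Pedigree inbreeding by the Meuwissen & Luo (1992) algorithm
#'
#' Computes the inbreeding coefficient F of every animal from the numerator
#' relationship structure, without ever forming the full relationship
#' matrix.  The algorithm sweeps each animal's ancestor list once,
#' accumulating \eqn{A_{ii} = \sum_j L_{ij}^2 D_j} where \eqn{L} are the
#' path coefficients and \eqn{D_j = 0.5 - 0.25 (F_s + F_d)} is the
#' Mendelian-sampling variance of ancestor j (with the convention F = -1
#' for an unknown parent, which makes the identity hold for incomplete
#' pedigrees).  Animals with an unknown parent side get F = 0: the unknown
#' path contributes nothing.
#'
#' @param ped A validated, acyclic pedigree data frame.
#' @return A data frame with columns `id` and `F_ped`, in the input record
#'   order (F is invariant to the record order of `ped`).
#' @references Meuwissen, T.H.E. and Luo, Z. (1992) Computing inbreeding
#'   coefficients in large populations. Genetics Selection Evolution 24:305.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- as.data.frame(ped)
  ord <- pedigree_order(ped)           # errors on cycles
  ids <- ped$id[ord]
  sire <- match(ped$sire[ord], ids, nomatch = 0L)
  dam <- match(ped$dam[ord], ids, nomatch = 0L)
  n <- length(ids)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Fs <- if (s > 0L) F[s] else -1
    Fd <- if (d > 0L) F[d] else -1
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s == 0L || d == 0L) { F[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    Aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      Aii <- Aii + lj * lj * D[j]
      if (sire[j] > 0L) L[sire[j]] <- L[sire[j]] + 0.5 * lj
      if (dam[j] > 0L) L[dam[j]] <- L[dam[j]] + 0.5 * lj
    }
    F[i] <- Aii - 1
  }
  out <- data.frame(id = ids, F_ped = F, stringsAsFactors = FALSE)
  out[match(ped$id, out$id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Group summary of inbreeding for the genotyped subset
#'
#' Means and standard deviations of an inbreeding coefficient per
#' breed-by-country group, restricted to a set of (genotyped) animals.
#'
#' @param inb Data frame with columns `id` and one coefficient column.
#' @param ped Pedigree data frame carrying `breed` and `country` (or
#'   `origin`, as in the simulator registry) per id.
#' @param ids Optional subset of animal ids (e.g. the genotyped animals).
#' @param value Name of the coefficient column in `inb`.
#' @return Data frame `breed`, `country`, `n`, `mean`, `sd`.
#' @export
inbreeding_by_group <- function(inb, ped, ids = NULL, value = "F_ped") {
  ped <- as.data.frame(ped)
  if (is.null(ped$country)) ped$country <- ped$origin
  if (!is.null(ids)) inb <- inb[inb$id %in% ids, , drop = FALSE]
  m <- match(inb$id, ped$id)
  grp <- data.frame(breed = ped$breed[m], country = ped$country[m],
                    f = inb[[value]], stringsAsFactors = FALSE)
  grp <- grp[!is.na(grp$breed) & !is.na(grp$country), , drop = FALSE]
  agg <- stats::aggregate(f ~ breed + country, data = grp, FUN = function(x)
    c(n = length(x), mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(breed = agg$breed, country = agg$country,
                    n = agg$f[, "n"], mean = agg$f[, "mean"],
                    sd = agg$f[, "sd"], stringsAsFactors = FALSE)
  out[order(out$breed, out$country), , drop = FALSE]
}
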