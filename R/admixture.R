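#' Admixture estimation by EM
#'
#' Maximum-likelihood estimation of the classical admixture (frappe)
#' model: individual i's genotype at SNP j is a Binomial(2) draw with
#' success probability \eqn{\pi_{ij} = \sum_c q_{ic} f_{cj}}, where Q
#' holds ancestry proportions (rows sum to 1) and F the ancestral allele
#' frequencies of the k clusters.  The log-likelihood
#' \deqn{\sum_{ij} g_{ij} \log \pi_{ij} + (2 - g_{ij}) \log(1 - \pi_{ij})}
#' is maximised by alternating exact EM updates of Q and F, which makes
#' it non-decreasing at every iteration.  Missing calls simply drop their
#' likelihood terms (an observation-mask EM), so entry-wise holdout
#' cross-validation is exact.
#'
#' @param gm A pruned `genotype_matrix`, or a 0/1/2/`NA` call matrix.
#' @param k Number of ancestral clusters.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap (default 2000).
#' @param tol Stop when the log-likelihood gain drops below this
#'   (default 1e-4).
#' @param mask Optional logical matrix, `FALSE` entries are treated as
#'   unobserved (on top of `NA` calls); used for cross-validation.
#' @return List of class `admixture_fit`: `k`, `Q` (n x k), `F` (k x m,
#'   clipped to `[0.01, 0.99]`), `loglik` (trace over iterations),
#'   `iterations`, `converged`.
#' @export
admixture_em <- function(gm, k, seed = 1L, max_iter = 2000L, tol = 1e-4,
                         mask = NULL) {
  G <- if (inherits(gm, "genotype_matrix")) gm$calls else as.matrix(gm)
  n <- nrow(G); m <- ncol(G)
  if (k < 1L || k > n) stop("admixture_em: k must be in [1, n]")
  W <- !is.na(G)
  if (!is.null(mask)) W <- W & mask
  Gn <- G; Gn[!W] <- 0L
  storage.mode(Gn) <- "double"
  Wd <- matrix(as.double(W), n, m)
  G1 <- Gn                # observed a1 allele counts
  G0 <- (2 - Gn) * Wd     # observed a2 allele counts

  if (k == 1L) {
    p <- colSums(G1) / pmax(2 * colSums(Wd), 1)
    F <- matrix(pmin(pmax(p, 0.01), 0.99), 1L, m)
    PI <- matrix(F, n, m, byrow = TRUE)
    ll <- loglik_admix(G1, G0, PI)
    return(structure(list(k = 1L, Q = matrix(1, n, 1L), F = F,
                          loglik = ll, iterations = 0L, converged = TRUE),
                     class = "admixture_fit"))
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  Q <- matrix(stats::rexp(n * k), n, k)
  Q <- Q / rowSums(Q)
  p <- colSums(G1) / pmax(2 * colSums(Wd), 1)
  F <- matrix(rep(p, each = k), k, m) +
    matrix(stats::runif(k * m, -0.1, 0.1), k, m)
  F <- pmin(pmax(F, 0.01), 0.99)

  ll <- numeric(0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    PI <- Q %*% F
    PI <- pmin(pmax(PI, 1e-12), 1 - 1e-12)
    ll[it] <- loglik_admix(G1, G0, PI)
    if (it > 1L && ll[it] - ll[it - 1L] < tol) { conv <- TRUE; break }
    A1 <- G1 / PI          # n x m, weight of a1 terms
    A0 <- G0 / (1 - PI)
    Qn <- matrix(0, n, k); Fn1 <- matrix(0, k, m); Fn0 <- matrix(0, k, m)
    for (c in seq_len(k)) {
      # responsibilities of cluster c for a1 and a2 alleles
      r1 <- A1 * tcrossprod(Q[, c], F[c, ])
      r0 <- A0 * tcrossprod(Q[, c], 1 - F[c, ])
      Qn[, c] <- rowSums(r1) + rowSums(r0)
      Fn1[c, ] <- colSums(r1)
      Fn0[c, ] <- colSums(r0)
    }
    Q <- Qn / rowSums(Qn)
    F <- Fn1 / pmax(Fn1 + Fn0, 1e-300)
    F <- pmin(pmax(F, 0.01), 0.99)
  }
  structure(list(k = k, Q = Q, F = F, loglik = ll,
                 iterations = length(ll), converged = conv),
            class = "admixture_fit")
}

loglik_admix <- function(G1, G0, PI) {
  sum(G1 * log(PI)) + sum(G0 * log1p(-PI))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: k = %d, n = %d, %d iterations, logLik %.2f%s\n",
              x$k, nrow(x$Q), x$iterations, utils::tail(x$loglik, 1),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Choose the number of ancestral clusters by cross-validation
#'
#' For each candidate k, `cv_folds` independent folds each mask a random
#' `holdout` fraction of the observed genotype entries, the model is
#' fitted on the remainder, and the held-out entries are scored by their
#' binomial deviance against the fitted dosage \eqn{2 \sum_c q_{ic}
#' f_{cj}}.  The cross-validation error of k is the mean held-out
#' deviance over folds; the selected k minimises it (ties go to the
#' smallest k).
#'
#' @inheritParams admixture_em
#' @param k_grid Candidate numbers of clusters (default `2:8`).
#' @param cv_folds Folds per k (default 5).
#' @param holdout Fraction of observed entries masked per fold
#'   (default 0.1).
#' @param seed Master seed; per-(k, fold) seeds are derived from it.
#' @param ... Passed to [admixture_em()] (e.g. `max_iter`, `tol`).
#' @return List with `cv_error` (data frame `k`, `cv_error`),
#'   `selected_k`, and `fits` = `NULL` (fits are not kept).
#' @export
choose_k <- function(gm, k_grid = 2:8, cv_folds = 5L, holdout = 0.1,
                     seed = 1L, ...) {
  G <- if (inherits(gm, "genotype_matrix")) gm$calls else as.matrix(gm)
  n <- nrow(G)
  k_grid <- sort(unique(as.integer(k_grid)))
  skip <- k_grid > n
  if (any(skip)) {
    warning("choose_k: dropping k > n: ", paste(k_grid[skip], collapse = ", "))
    k_grid <- k_grid[!skip]
  }
  obs_idx <- which(!is.na(G))
  err <- matrix(NA_real_, length(k_grid), cv_folds)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  for (f in seq_len(cv_folds)) {
    set.seed(seed * 1000L + f)
    held <- sample(obs_idx, max(1L, round(holdout * length(obs_idx))))
    mask <- matrix(TRUE, n, ncol(G))
    mask[held] <- FALSE
    for (ki in seq_along(k_grid)) {
      fit <- admixture_em(G, k_grid[ki], seed = seed * 1000L + f,
                          mask = mask, ...)
      PI <- fit$Q %*% fit$F
      PI <- pmin(pmax(PI, 1e-12), 1 - 1e-12)
      g <- G[held]; pi <- PI[held]
      # binomial deviance of held-out calls vs fitted dosage
      dev <- 2 * (xlogy(g, g / (2 * pi)) + xlogy(2 - g, (2 - g) / (2 - 2 * pi)))
      err[ki, f] <- mean(dev)
    }
  }
  cv <- data.frame(k = k_grid, cv_error = rowMeans(err))
  list(cv_error = cv,
       selected_k = cv$k[which.min(cv$cv_error)],
       folds = err)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Align cluster labels of an ancestry matrix to a reference
#'
#' Cluster labels of an admixture fit are arbitrary; this greedily
#' permutes the columns of `Q` to maximise agreement with a reference
#' ancestry matrix (used when scoring against simulation truth).
#'
#' @param Q Fitted n x k ancestry matrix.
#' @param Q_ref Reference n x k matrix.
#' @return `Q` with columns permuted to best match `Q_ref`.
#' @export
align_clusters <- function(Q, Q_ref) {
  k <- ncol(Q)
  stopifnot(ncol(Q_ref) == k)
  sim <- crossprod(Q_ref, Q)      # k x k agreement
  perm <- integer(k)
  used <- logical(k)
  for (step in seq_len(k)) {
    best <- which(sim == max(sim[!is.na(sim)]), arr.ind = TRUE)[1L, ]
    perm[best[1L]] <- best[2L]
    sim[best[1L], ] <- NA; sim[, best[2L]] <- NA
    used[best[2L]] <- TRUE
  }
  Q[, perm, drop = FALSE]
}
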