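## Population structure: genotype PCA, an admixture model fit by EM with
## entry-wise cross-validation over K, and a neighbor-joining tree on an
## allele-sharing distance (structural plumbing; no ML phylogenetics here).

## samples x sites dosage matrix with segregating sites only
.dosage_for_structure <- function(v) {
  g <- t(v$genotypes)               # samples x sites
  p <- colMeans(g, na.rm = TRUE) / v$ploidy
  keep <- !is.na(p) & p > 0 & p < 1
  list(g = g[, keep, drop = FALSE], p = p[keep])
}

#' Genotype principal component analysis
#'
#' Mean-imputes missing dosages per site, centers each site and scales it by
#' `sqrt(2 p (1-p))`, and eigendecomposes the sample covariance matrix.
#' Percent explained is eigenvalue over the covariance trace.
#'
#' @param v a `variant_table`.
#' @param n_axes number of axes to return (default 2).
#' @return list of class `ordination` with `coordinates` (samples x axes,
#'   eigenvector scaled by the square root of its eigenvalue),
#'   `eigenvalues`, `pct_explained`.
#' @export
genotype_pca <- function(v, n_axes = 2) {
  if (length(v$sample_ids) < 2) stop("need at least 2 samples")
  ds <- .dosage_for_structure(v)
  if (ncol(ds$g) == 0) stop("no segregating sites")
  g <- ds$g
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  sdv <- sqrt(2 * ds$p * (1 - ds$p))
  x <- sweep(sweep(g, 2, mu), 2, sdv, "/")
  cv <- tcrossprod(x) / ncol(x)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  n_axes <- min(n_axes, length(vals))
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_axes)]), n_axes)
  rownames(coords) <- v$sample_ids
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 pct_explained = 100 * vals[seq_len(n_axes)] / sum(vals)),
            class = "ordination")
}

## binomial admixture log-likelihood (constant terms dropped)
.admix_loglik <- function(g, Q, F, obs) {
  P <- Q %*% F
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  sum((g * log(P) + (2 - g) * log(1 - P))[obs], na.rm = TRUE)
}

#' Admixture model fit by EM
#'
#' Maximises the binomial admixture log-likelihood
#' `sum_ij [ g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(1 - sum_k q_ik f_kj) ]`
#' by the standard EM updates, alternating expected allele-origin counts
#' with closed-form Q and F maximisations. Missing genotypes are excluded
#' from the likelihood. Q is initialised from a seeded Dirichlet; allele
#' frequencies are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param v a `variant_table` (diploid-coded dosages).
#' @param K number of ancestral populations.
#' @param seed RNG seed for the initialisation.
#' @param max_iter maximum EM iterations (default 2000).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @return list of class `admixture_fit`: `Q` (samples x K), `F`
#'   (K x sites), `loglik_trace`, `K`, `seed`, `converged`, `n_iter`.
#' @export
admixture_em <- function(v, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  stop_if_not_scalar_count(K, "K")
  if (K > length(v$sample_ids)) stop("K exceeds the number of samples")
  ds <- .dosage_for_structure(v)
  .admix_em_core(ds$g, K, seed = seed, max_iter = max_iter, tol = tol)
}

## EM on a samples x sites dosage matrix (no site filtering)
.admix_em_core <- function(g, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  obs <- !is.na(g)
  gz <- g; gz[!obs] <- 0          # zero-filled copy for matrix products
  n <- nrow(g); m <- ncol(g)
  eps <- 1e-6
  if (K == 1) {
    F <- matrix(pmin(pmax(colSums(gz) / pmax(2 * colSums(obs), 1), eps),
                     1 - eps), 1, m)
    Q <- matrix(1, n, 1)
    ll <- .admix_loglik(g, Q, F, obs)
    return(structure(list(Q = Q, F = F, loglik_trace = ll, K = 1L,
                          seed = seed, converged = TRUE, n_iter = 0L),
                     class = "admixture_fit"))
  }
  set.seed(seed)
  Q <- rdirichlet(n, rep(1, K))
  F <- matrix(runif(K * m, 0.05, 0.95), K, m)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  M_i <- pmax(rowSums(obs), 1)
  while (it < max_iter) {
    it <- it + 1L
    P <- Q %*% F
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    num_f <- matrix(0, K, m)   # expected derived-allele counts per k, site
    den_f <- matrix(0, K, m)
    q_new <- matrix(0, n, K)
    for (k in seq_len(K)) {
      A <- sweep(sweep(1 / P, 1, Q[, k], "*"), 2, F[k, ], "*")    # q f / P
      B <- sweep(sweep(1 / (1 - P), 1, Q[, k], "*"), 2, 1 - F[k, ], "*")
      A[!obs] <- 0; B[!obs] <- 0
      EA <- gz * A               # expected alt-origin counts
      EB <- (2 - gz) * B; EB[!obs] <- 0
      num_f[k, ] <- colSums(EA)
      den_f[k, ] <- colSums(EA) + colSums(EB)
      q_new[, k] <- rowSums(EA) + rowSums(EB)
    }
    F <- num_f / pmax(den_f, 1e-12)
    F <- pmin(pmax(F, eps), 1 - eps)
    Q <- q_new / (2 * M_i)
    Q <- Q / rowSums(Q)
    ll <- .admix_loglik(g, Q, F, obs)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  rownames(Q) <- rownames(g)
  structure(list(Q = Q, F = F, loglik_trace = trace, K = as.integer(K),
                 seed = seed, converged = converged, n_iter = it),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, %d samples, %s after %d iterations\n",
              x$K, nrow(x$Q),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Cross-validation error over K for the admixture model
#'
#' Partitions the observed genotype entries into `folds` seeded folds. For
#' each fold the entries are masked, the model refit, and the masked
#' genotypes predicted as `2 * sum_k q_ik f_kj`; the error is the mean
#' binomial deviance over masked entries, averaged over folds, reported per
#' K.
#'
#' @param v a `variant_table`.
#' @param K_range integer vector of K values (e.g. `2:4`).
#' @param folds number of folds (>= 2, default 5).
#' @param seed RNG seed (fold assignment and EM initialisations).
#' @param max_iter EM iteration cap per refit (default 500).
#' @return data.frame of class `cv_report` with `K` and `cv_error`.
#' @export
cv_error <- function(v, K_range, folds = 5, seed = 1, max_iter = 500) {
  if (folds < 2) stop("folds must be >= 2")
  ds <- .dosage_for_structure(v)
  g0 <- ds$g
  obs_idx <- which(!is.na(g0))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
  errs <- vapply(K_range, function(K) {
    fold_err <- vapply(seq_len(folds), function(f) {
      g <- g0
      masked <- obs_idx[fold_of == f]
      g[masked] <- NA_integer_
      fit <- .admix_em_core(g, K, seed = derive_seed(seed, K * 100 + f),
                            max_iter = max_iter)
      P <- fit$Q %*% fit$F
      P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
      gm <- g0[masked]
      -mean(gm * log(P[masked]) + (2 - gm) * log(1 - P[masked]))
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))
  out <- data.frame(K = as.integer(K_range), cv_error = errs)
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) with deterministic tie-breaking
#' by label order: labels are sorted before tree construction, so permuting
#' the input order cannot change the topology.
#'
#' @param d symmetric distance matrix with zero diagonal (matrix or `dist`).
#' @param labels optional taxon labels (default: `d` dimnames).
#' @return a newick string with branch lengths.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("d must be symmetric with zero diagonal")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tree <- ape::nj(stats::as.dist(d))
  ape::write.tree(tree)
}

#' Allele-sharing distance between samples
#'
#' `1 - (proportion of matching dosages)` over sites called in both samples;
#' the default pairwise distance for the sample tree.
#'
#' @param v a `variant_table`.
#' @return symmetric matrix with zero diagonal.
#' @export
allele_sharing_dist <- function(v) {
  g <- t(v$genotypes)
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(v$sample_ids, v$sample_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    d[i, j] <- d[j, i] <- if (any(ok)) 1 - mean(g[i, ok] == g[j, ok]) else NA
  }
  d
}
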