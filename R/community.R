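## Gut-community comparison: depth-matching subsampling, health filtering,
## canonical k-mer profiles and distances, PCoA, PERMANOVA and rank-sum
## abundance tests.

#' Subsample reads to a common depth
#'
#' Uniform sampling without replacement, seeded, order-stable (the retained
#' reads keep their original relative order). If `n` exceeds the number of
#' reads all reads are returned with a warning.
#'
#' @param reads character vector of read sequences.
#' @param n target read count.
#' @param seed RNG seed.
#' @return character vector of `n` reads.
#' @export
subsample_reads <- function(reads, n, seed = 100) {
  if (n < 0) stop("n must be non-negative")
  if (n >= length(reads)) {
    if (n > length(reads))
      warning("n exceeds the number of reads; returning all reads")
    return(reads)
  }
  set.seed(seed)
  reads[sort(sample.int(length(reads), n))]
}

#' Construct an abundance table
#'
#' @param abundance samples x taxa matrix of relative abundances; rows must
#'   sum to 1 (within 1e-9).
#' @param unhealthy optional logical vector of health flags per sample.
#' @return list of class `abundance_table` with `abundance` and `unhealthy`.
#' @export
abundance_table <- function(abundance, unhealthy = NULL) {
  abundance <- as.matrix(abundance)
  if (any(abs(rowSums(abundance) - 1) > 1e-9))
    stop("abundance rows must sum to 1")
  if (is.null(unhealthy)) unhealthy <- rep(FALSE, nrow(abundance))
  if (length(unhealthy) != nrow(abundance)) stop("unhealthy length mismatch")
  structure(list(abundance = abundance,
                 unhealthy = setNames(unhealthy, rownames(abundance))),
            class = "abundance_table")
}

#' Flag pathogen-dominated samples
#'
#' A sample is flagged unhealthy when the summed relative abundance of the
#' pathogen taxa strictly exceeds `threshold` (a mass of exactly the
#' threshold stays healthy). Flagged samples are meant to be excluded from
#' downstream distance and ordination calls.
#'
#' @param a an `abundance_table` (or a samples x taxa matrix).
#' @param pathogen_taxa character vector of pathogen taxon names; names
#'   absent from the table produce a warning.
#' @param threshold strict threshold on total pathogen mass (default 0.5).
#' @return the `abundance_table` with `unhealthy` filled.
#' @export
flag_unhealthy <- function(a, pathogen_taxa, threshold = 0.5) {
  if (!inherits(a, "abundance_table")) a <- abundance_table(a)
  present <- intersect(pathogen_taxa, colnames(a$abundance))
  missing <- setdiff(pathogen_taxa, colnames(a$abundance))
  if (length(missing))
    warning("pathogen taxa absent from table: ",
            paste(missing, collapse = ", "))
  mass <- if (length(present))
    rowSums(a$abundance[, present, drop = FALSE]) else
      rep(0, nrow(a$abundance))
  a$unhealthy <- setNames(mass > threshold, rownames(a$abundance))
  a
}

## locale-proof lexicographic canonicalisation: map bases to digits
.canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  fk <- chartr("ACGT", "1234", kmers)
  rk <- chartr("ACGT", "1234", rc)
  ifelse(fk <= rk, kmers, rc)
}

#' Canonical k-mer frequency profile of a read set
#'
#' Counts every length-`k` window consisting only of A/C/G/T (windows with
#' other symbols are skipped) and canonicalises each k-mer to the
#' lexicographic minimum of itself and its reverse complement, so profiles
#' are strand-independent. An odd `k` guarantees no palindromic ties.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences.
#' @param k k-mer length (default 21).
#' @param sample_id optional label stored in the profile.
#' @return list of class `kmer_profile` with `sample_id`, `k`, `counts`
#'   (named integer vector keyed by canonical k-mer), `total`, `freq`.
#' @export
kmer_profile <- function(reads, k = 21, sample_id = NULL) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  if (!length(reads)) stop("no reads supplied")
  wide <- reads[nchar(reads) >= k]
  if (!length(wide)) stop("all reads shorter than k")
  kmers <- unlist(lapply(wide, function(r) {
    n <- nchar(r) - k + 1L
    substring(r, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) stop("all windows invalid (non-ACGT symbols)")
  canon <- .canonical_kmers(kmers)
  counts <- table(canon)
  counts <- setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  structure(list(sample_id = sample_id, k = as.integer(k), counts = counts,
                 total = total, freq = counts / total),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile%s: k = %d, %d distinct canonical k-mers, %d total\n",
              if (is.null(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$k, length(x$counts), x$total))
  invisible(x)
}

#' Distance between two k-mer profiles
#'
#' Default is cosine distance (`1 -` cosine similarity) on the frequency
#' vectors over the union of canonical k-mers; `euclidean` and
#' `bray_curtis` are available. Cosine distance lies in `[0, 1]` on
#' non-negative vectors.
#'
#' @param a,b `kmer_profile`s with equal `k`.
#' @param metric `"cosine"` (default), `"euclidean"` or `"bray_curtis"`.
#' @return a single non-negative distance.
#' @export
kmer_distance <- function(a, b, metric = c("cosine", "euclidean",
                                           "bray_curtis")) {
  metric <- match.arg(metric)
  if (a$k != b$k) stop("k mismatch between profiles")
  if (a$total == 0 || b$total == 0) stop("empty profile")
  keys <- union(names(a$freq), names(b$freq))
  fa <- fb <- numeric(length(keys))
  names(fa) <- names(fb) <- keys
  fa[names(a$freq)] <- a$freq
  fb[names(b$freq)] <- b$freq
  switch(metric,
         cosine = 1 - sum(fa * fb) / (sqrt(sum(fa^2)) * sqrt(sum(fb^2))),
         euclidean = sqrt(sum((fa - fb)^2)),
         bray_curtis = sum(abs(fa - fb)) / sum(fa + fb))
}

#' Pairwise k-mer distance matrix over samples
#'
#' @param profiles named list of `kmer_profile`s.
#' @param metric passed to [kmer_distance()].
#' @return symmetric matrix with zero diagonal; attribute `metric` records
#'   the choice.
#' @export
kmer_distance_matrix <- function(profiles, metric = "cosine") {
  n <- length(profiles)
  labels <- names(profiles) %||% sprintf("S%03d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- kmer_distance(profiles[[i]], profiles[[j]], metric)
  }
  attr(d, "metric") <- metric
  d
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: Gower double-centering of `-d^2/2` and
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Percent explained uses the sum of
#' positive eigenvalues as denominator; negative eigenvalues are reported
#' but never used to build axes.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes (default 2).
#' @return list of class `ordination` with `coordinates`, `eigenvalues`
#'   (all, including negatives), `pct_explained`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  k <- min(n_axes, n - 1)
  fit <- cmdscale(d, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  coords <- fit$points
  navail <- ncol(coords)
  colnames(coords) <- paste0("PCo", seq_len(navail))
  structure(list(coordinates = coords,
                 eigenvalues = fit$eig,
                 pct_explained = 100 * fit$eig[seq_len(navail)] / sum(pos)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples x %d axes; %% explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f", x$pct_explained), collapse = ", ")))
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances
#' (`SS_total = sum_{i<j} d_ij^2 / n`) into between- and within-group
#' components, forms the pseudo-F
#' `(SS_between/df_between) / (SS_within/df_within)`, and assesses it by
#' seeded label permutation: `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix.
#' @param labels group labels (length = samples; >= 2 non-empty groups).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `df_between`, `df_within`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match distance matrix")
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(labels) == 0)) stop("empty group")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  within_ss <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  ss_w <- within_ss(labels)
  ss_b <- ss_total - ss_w
  df_b <- length(groups) - 1L
  df_w <- n - length(groups)
  f_obs <- (ss_b / df_b) / (ss_w / df_w)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    lp <- labels[sample.int(n)]
    ss_wp <- within_ss(lp)
    fp <- ((ss_total - ss_wp) / df_b) / (ss_wp / df_w)
    if (fp >= f_obs) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs, r_squared = ss_b / ss_total,
                 p_value = (1 + exceed) / (1 + n_perm),
                 df_between = df_b, df_within = df_w,
                 n_permutations = n_perm, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F_%d,%d = %.2f, r2 = %.2f, P = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$r_squared,
              x$p_value, x$n_permutations))
  invisible(x)
}

## exact two-sided rank-sum null distribution by dynamic programming over
## doubled midranks (integers even under ties)
.ranksum_exact_p <- function(r2, n1, w2_obs) {
  n <- length(r2)
  total <- sum(r2)
  dp <- matrix(0, n1 + 1, total + 1)   # dp[j+1, s+1] = #subsets size j sum s
  dp[1, 1] <- 1
  for (e in r2) {
    jmax <- n1
    for (j in jmax:1) {
      src <- dp[j, ]
      if (any(src > 0)) {
        shifted <- c(rep(0, e), src)[seq_len(total + 1)]
        dp[j + 1, ] <- dp[j + 1, ] + shifted
      }
    }
  }
  dist <- dp[n1 + 1, ]
  sums <- 0:total
  mu2 <- n1 * sum(r2) / n
  extreme <- abs(sums - mu2) >= abs(w2_obs - mu2) - 1e-9
  sum(dist[extreme]) / sum(dist)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with midrank ties
#'
#' Uses exact null enumeration (dynamic programming over the observed
#' midranks) when the combined sample size is at most `exact_max`, and a
#' normal approximation with tie and continuity correction otherwise. The
#' exact two-sided p-value is the null probability of a rank sum at least
#' as far from its expectation as observed.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max largest combined n for the exact branch (default 20).
#' @return list with `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    p <- .ranksum_exact_p(r2, n1, as.integer(round(2 * w)))
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 * (n + 1) / 12 -
    n1 * n2 * sum(tie_tab^3 - tie_tab) / (12 * n * (n - 1))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1, method = "normal"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * pnorm(-max(z, 0))),
       method = "normal")
}

#' Rank-sum test of one taxon's abundance between two groups
#'
#' @param a an `abundance_table` (or samples x taxa matrix).
#' @param groups group labels per sample (exactly two distinct values).
#' @param taxon taxon (column) name.
#' @param ... passed to [rank_sum_test()].
#' @return list with `statistic`, `p_value`, `method`.
#' @export
rank_sum_abundance <- function(a, groups, taxon, ...) {
  if (!inherits(a, "abundance_table")) a <- abundance_table(a)
  if (!taxon %in% colnames(a$abundance)) stop("unknown taxon: ", taxon)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("need exactly two groups")
  vals <- a$abundance[, taxon]
  rank_sum_test(vals[groups == gl[1]], vals[groups == gl[2]], ...)
}
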