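## Population-genetic summaries: windowed nucleotide diversity, composite
## linkage disequilibrium (r^2) decay, and the Waples LD effective-size
## estimator.

## dosage submatrix for one population, sites x samples
.pop_dosage <- function(v, pop, panel) {
  check_panel(v, panel)
  ids <- intersect(v$sample_ids, panel_samples(panel, pop))
  if (!length(ids)) stop("unknown or empty population label: ", pop)
  v$genotypes[, ids, drop = FALSE]
}

## per-site alt frequency and non-missing allele count
.site_freq <- function(g, ploidy) {
  n <- rowSums(!is.na(g)) * ploidy
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  list(p = p, n = n)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, `pi_site = (n/(n-1)) * 2 p (1-p)` where `p` is the alt-allele
#' frequency among non-missing alleles and `n` the non-missing allele count.
#' Windows of fixed width tile each chromosome from position 1 and window pi
#' is the sum of site values divided by the window length (truncated at the
#' chromosome end when known).
#'
#' @param v a `variant_table`.
#' @param pop population label.
#' @param window window width in bases.
#' @param panel a `population_panel`.
#' @param chrom_lengths optional named vector of chromosome lengths; default
#'   is the last variant position per chromosome.
#' @return data.frame with `chrom`, `start`, `end`, `n_variant_sites`, `pi`.
#' @export
nucleotide_diversity <- function(v, pop, window, panel,
                                 chrom_lengths = NULL) {
  if (window <= 0) stop("window must be positive")
  g <- .pop_dosage(v, pop, panel)
  f <- .site_freq(g, v$ploidy)
  ok <- f$n >= 2
  pi_site <- numeric(nrow(g))
  pi_site[ok] <- (f$n[ok] / (f$n[ok] - 1)) * 2 * f$p[ok] * (1 - f$p[ok])
  s <- v$sites
  if (is.null(chrom_lengths)) chrom_lengths <- tapply(s$pos, s$chrom, max)
  out <- lapply(unique(s$chrom), function(ch) {
    idx <- which(s$chrom == ch)
    L <- as.numeric(chrom_lengths[[ch]])
    win <- (s$pos[idx] - 1L) %/% window
    nw <- max(win) + 1L
    starts <- (seq_len(nw) - 1L) * window + 1L
    ends <- pmin(starts + window - 1L, L)
    psum <- vapply(seq_len(nw) - 1L,
                   function(w) sum(pi_site[idx][win == w]), numeric(1))
    nvar <- vapply(seq_len(nw) - 1L,
                   function(w) sum(win == w & pi_site[idx] > 0), integer(1))
    data.frame(chrom = ch, start = starts, end = ends,
               n_variant_sites = nvar,
               pi = psum / (ends - starts + 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("pi_windows", "data.frame")
  res
}

## pairwise-complete composite r^2 between two dosage rows
.pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Linkage-disequilibrium decay
#'
#' For every intra-chromosomal site pair within `max_dist` whose minor-allele
#' frequencies both reach `maf`, computes composite r^2 (squared Pearson
#' correlation of unphased dosage vectors over samples non-missing at both
#' sites), bins pairs by distance and reports the mean per bin.
#'
#' @param v a `variant_table`.
#' @param pop population label.
#' @param max_dist maximum pair distance in bases.
#' @param bins number of equal-width distance bins.
#' @param maf minor-allele-frequency cutoff (default 0.05).
#' @param panel a `population_panel`.
#' @return data.frame with `lo`, `hi`, `mean_r2`, `n_pairs`.
#' @export
ld_r2 <- function(v, pop, max_dist, bins, maf = 0.05, panel) {
  g <- .pop_dosage(v, pop, panel)
  if (ncol(g) < 2) stop("need at least 2 samples in population")
  f <- .site_freq(g, v$ploidy)
  keep <- !is.na(f$p) & pmin(f$p, 1 - f$p) >= maf
  g <- g[keep, , drop = FALSE]
  s <- v$sites[keep, , drop = FALSE]
  brk <- seq(0, max_dist, length.out = bins + 1)
  r2_bin <- numeric(bins); n_bin <- integer(bins)
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    if (length(idx) < 2) next
    pos <- s$pos[idx]
    cc <- suppressWarnings(cor(t(g[idx, , drop = FALSE]),
                               use = "pairwise.complete.obs"))
    for (i in seq_along(idx)[-length(idx)]) {
      js <- which(pos > pos[i] & pos - pos[i] <= max_dist)
      js <- js[js > i]
      if (!length(js)) next
      r2 <- cc[i, js]^2
      d <- pos[js] - pos[i]
      b <- pmin(pmax(ceiling(d / max_dist * bins), 1L), bins)
      ok <- !is.na(r2)
      for (k in which(ok)) {
        r2_bin[b[k]] <- r2_bin[b[k]] + r2[k]
        n_bin[b[k]] <- n_bin[b[k]] + 1L
      }
    }
  }
  data.frame(lo = brk[-(bins + 1)], hi = brk[-1],
             mean_r2 = ifelse(n_bin > 0, r2_bin / n_bin, NA_real_),
             n_pairs = n_bin)
}

## sampling expectation of r^2 under random mating with no drift signal
.r2_sample_expectation <- function(S) {
  if (S > 29) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

## Waples (2006) random-mating solution for Ne from the drift component
.ne_solution <- function(r2_drift, S) {
  if (is.na(r2_drift) || r2_drift <= 0) return(Inf)
  if (S > 29) {
    disc <- max(1 / 9 - 2.76 * r2_drift, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- max(0.308^2 - 2.08 * r2_drift, 0)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

#' LD-based effective population size (Waples method)
#'
#' Computes mean composite r^2 across unlinked site pairs (different
#' chromosomes, or distance above `min_dist`), subtracts the sampling
#' expectation `E(r^2 | Ne = Inf)` for the harmonic-mean sample size S
#' (1/S + 3.19/S^2 for S > 29, else the small-S variant), and solves the
#' random-mating drift equation for Ne. When the mean r^2 does not exceed
#' its sampling expectation the estimate is reported as `Inf` (no drift
#' signal).
#'
#' @param v a `variant_table`.
#' @param pop population label.
#' @param panel a `population_panel`.
#' @param maf minor-allele-frequency cutoff (Pcrit), default 0.05.
#' @param min_dist pairs on the same chromosome closer than this are
#'   excluded as linked; default `Inf` (different chromosomes only).
#' @return list of class `ne_estimate` with `ne`, `r2_mean`, `r2_expected`,
#'   `S`, `maf_cutoff`, `n_pairs`.
#' @export
ne_from_ld <- function(v, pop, panel, maf = 0.05, min_dist = Inf) {
  g <- .pop_dosage(v, pop, panel)
  f <- .site_freq(g, v$ploidy)
  keep <- !is.na(f$p) & pmin(f$p, 1 - f$p) >= maf
  g <- g[keep, , drop = FALSE]
  s <- v$sites[keep, , drop = FALSE]
  m <- nrow(g)
  if (m < 2) stop("fewer than 2 usable sites")
  cc <- suppressWarnings(cor(t(g), use = "pairwise.complete.obs"))
  obs <- !is.na(g)
  ## pairwise non-missing sample counts via crossprod
  Smat <- tcrossprod(obs * 1L)
  same_chrom <- outer(s$chrom, s$chrom, "==")
  dist_ok <- if (is.infinite(min_dist)) !same_chrom else
    (!same_chrom | abs(outer(s$pos, s$pos, "-")) > min_dist)
  ut <- upper.tri(cc)
  use <- ut & dist_ok & !is.na(cc) & Smat >= 2
  if (sum(use) < 2) stop("fewer than 2 usable unlinked pairs")
  ## Burrows-composite small-sample weighting: the squared correlation is
  ## scaled by (S/(S-1))^2 per pair, the statistic whose no-drift
  ## expectation the 1/S + 3.19/S^2 formula describes
  w <- (Smat[use] / (Smat[use] - 1))^2
  r2 <- cc[use]^2 * w
  S <- 1 / mean(1 / Smat[use])   # harmonic mean sample size
  r2_mean <- mean(r2)
  e0 <- .r2_sample_expectation(S)
  ne <- .ne_solution(r2_mean - e0, S)
  structure(list(ne = ne, r2_mean = r2_mean, r2_expected = e0, S = S,
                 maf_cutoff = maf, n_pairs = sum(use)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "LD-based Ne estimate: %s\n  mean r2 = %.5f (expectation %.5f), S = %.1f, %d pairs, maf >= %.2f\n",
    if (is.infinite(x$ne)) "infinite (no drift signal)" else
      sprintf("%.1f", x$ne),
    x$r2_mean, x$r2_expected, x$S, x$n_pairs, x$maf_cutoff))
  invisible(x)
}
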