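# shared fixture builders (everything generated in code; no data files)

# minimal variant table: supply a dosage matrix, positions default 1,2,...
make_vt <- function(genotypes, chrom = "c1", pos = NULL, ref = "A",
                    alt = "G", qual = 1000, depths = NULL, ploidy = 2,
                    info = list()) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (is.null(pos)) pos <- seq_len(n)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      qual = rep_len(qual, n), is_indel = FALSE,
                      n_alleles = 2L)
  for (f in names(info)) sites[[f]] <- info[[f]]
  if (is.null(depths))
    depths <- matrix(30L, n, ncol(genotypes))
  variant_table(sites, genotypes, depths, ploidy = ploidy)
}

two_pop_panel <- function(n1, n2, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n1 + n2))
  population_panel(ids, rep(c("pop1", "pop2"), c(n1, n2)))
}

# small two-population host simulation reused across structure tests
small_structure_sim <- function(seed) {
  simulate_host_populations(host_sim_config(
    n_genes = 20, gene_len_codons = 100, n_samples_pop1 = 15,
    n_samples_pop2 = 15, theta = 0.008, divergence = 0.03, seed = seed))
}

# independent lchoose-based enumeration of the two-sided Fisher p-value
fisher_oracle <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  d <- rep_len(d, n)
  R1 <- a + b; R2 <- c + d; C1 <- a + c; N <- R1 + R2
  lo <- pmax(0, C1 - R2); hi <- pmin(C1, R1)
  lens <- hi - lo + 1
  g <- rep.int(seq_len(n), lens)
  av <- sequence(lens, from = lo)
  probs <- exp(lchoose(R1[g], av) + lchoose(R2[g], C1[g] - av) -
                 lchoose(N[g], C1[g]))
  pobs <- exp(lchoose(R1, a) + lchoose(R2, C1 - a) - lchoose(N, C1))
  pmin(as.numeric(rowsum(probs * (probs <= pobs[g] * (1 + 1e-7)), g)), 1)
}

# exhaustive rank-sum two-sided p by direct subset enumeration
ranksum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  subs <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[subs], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# build a kmer_profile object directly from a named frequency vector
profile_from_freq <- function(freq, k = 3) {
  counts <- setNames(as.integer(round(freq * 1000)), names(freq))
  structure(list(sample_id = NULL, k = as.integer(k), counts = counts,
                 total = sum(counts), freq = counts / sum(counts)),
            class = "kmer_profile")
}
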