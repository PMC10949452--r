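test_that("subsampling is seeded, order-stable and proportion-preserving", {
  reads <- c(rep("AAAA", 7000), rep("CCCC", 3000))
  expect_identical(subsample_reads(reads, length(reads), seed = 1), reads)
  s1 <- subsample_reads(reads, 1000, seed = 100)
  s2 <- subsample_reads(reads, 1000, seed = 100)
  expect_identical(s1, s2)
  # binomial expectation: proportions within 3 SDs
  p_hat <- mean(s1 == "AAAA")
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  expect_warning(subsample_reads(reads[1:5], 10), "exceeds")
  expect_error(subsample_reads(reads, -1), "non-negative")
})

test_that("unhealthy flagging uses a strict threshold", {
  ab <- rbind(s1 = c(0.5, 0.5), s2 = c(0.51, 0.49), s3 = c(0.2, 0.8))
  colnames(ab) <- c("path", "good")
  a <- flag_unhealthy(abundance_table(ab), "path")
  expect_equal(unname(a$unhealthy), c(FALSE, TRUE, FALSE))
  # empty pathogen set: everyone healthy (with a warning for unknown names)
  a2 <- flag_unhealthy(abundance_table(ab), character(0))
  expect_false(any(a2$unhealthy))
  expect_warning(flag_unhealthy(abundance_table(ab), "missing_taxon"),
                 "absent")
})

test_that("k-mer profiles canonicalise reverse complements", {
  # "ACGT", k = 3: windows ACG and CGT are reverse complements -> one
  # canonical key with count 2 and frequency 1
  p <- kmer_profile("ACGT", k = 3)
  expect_equal(length(p$counts), 1)
  expect_equal(unname(p$counts[["ACG"]]), 2)
  expect_equal(unname(p$freq[[1]]), 1)
  # a read and its reverse complement give identical profiles
  set.seed(3)
  r <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  p1 <- kmer_profile(r, k = 21)
  p2 <- kmer_profile(rc, k = 21)
  expect_identical(p1$counts[order(names(p1$counts))],
                   p2$counts[order(names(p2$counts))])
  # read order invariance
  p3 <- kmer_profile(c(r, rc), k = 21)
  p4 <- kmer_profile(c(rc, r), k = 21)
  expect_identical(p3$counts[order(names(p3$counts))],
                   p4$counts[order(names(p4$counts))])
  # ambiguous symbols: windows skipped; all-invalid errors
  expect_error(kmer_profile("ANNNA", k = 3), "invalid")
  expect_error(kmer_profile(c("AC", "GT"), k = 3), "shorter than k")
  pn <- kmer_profile("ACGNACG", k = 3)
  expect_equal(pn$total, 2)
})

test_that("profile frequencies sum to one", {
  set.seed(8)
  reads <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1))
  p <- kmer_profile(reads, k = 21)
  expect_equal(sum(p$freq), 1, tolerance = 1e-9)
})

test_that("k-mer distances match hand computations", {
  a <- profile_from_freq(c(AAC = 0.5, AAG = 0.5))
  b <- profile_from_freq(c(AAG = 0.5, AAT = 0.5))
  # cosine: 1 - 0.25 / 0.5 = 0.5
  expect_equal(kmer_distance(a, b), 0.5)
  expect_equal(kmer_distance(a, a), 0)
  disj <- profile_from_freq(c(CCC = 1))
  expect_equal(kmer_distance(a, disj), 1)
  expect_equal(kmer_distance(a, b, metric = "euclidean"),
               sqrt(0.25 + 0.25))
  expect_equal(kmer_distance(a, b, metric = "bray_curtis"), 0.5)
  bad_k <- profile_from_freq(c(AAAA = 1), k = 4)
  expect_error(kmer_distance(a, bad_k), "k mismatch")
})

test_that("PCoA embeds collinear points on one axis and round-trips 2-D configurations", {
  # points on a line at 0, 1, 2
  d <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  ord <- pcoa(d, 2)
  expect_equal(ord$pct_explained[1], 100, tolerance = 1e-8)
  rec <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)

  set.seed(21)
  xy <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(xy))
  ord2 <- pcoa(d2, 2)
  rec2 <- as.matrix(dist(ord2$coordinates))
  expect_equal(unname(rec2), unname(d2), tolerance = 1e-8)
  # permuting labels leaves the eigenvalues unchanged
  perm <- sample(10)
  ord3 <- pcoa(d2[perm, perm], 2)
  expect_equal(ord2$eigenvalues, ord3$eigenvalues, tolerance = 1e-8)
})

test_that("PERMANOVA matches vegan::adonis2 on the observed statistic", {
  set.seed(14)
  xy <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 1.5), 10, 2))
  d <- as.matrix(dist(xy))
  lab <- rep(c("a", "b"), each = 10)
  res <- permanova(d, lab, n_perm = 99, seed = 2)
  ad <- vegan::adonis2(as.dist(d) ~ g,
                       data = data.frame(g = lab), permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-9)
  expect_equal(res$df_between, ad$Df[1])
})

test_that("PERMANOVA is invariant to group renaming and errors on one group", {
  set.seed(15)
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  lab <- rep(c("x", "y"), 6)
  r1 <- permanova(d, lab, n_perm = 199, seed = 7)
  r2 <- permanova(d, ifelse(lab == "x", "y", "x"), n_perm = 199, seed = 7)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(permanova(d, rep("x", 12)), "2 groups")
  # p-value resolution is 1/(n_perm + 1)
  expect_gte(r1$p_value, 1 / 200)
})

test_that("rank-sum test matches exhaustive enumeration and the textbook example", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$method, "exact")
  # identical values give p = 1
  expect_equal(rank_sum_test(c(2, 2), c(2, 2))$p_value, 1)
  # random data with ties: exact branch equals subset enumeration
  set.seed(19)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, TRUE); y <- sample(1:5, n2, TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, ranksum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree at moderate n", {
  set.seed(23)
  diffs <- replicate(30, {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    pe <- rank_sum_test(x, y, exact_max = 20)$p_value
    pn <- rank_sum_test(x, y, exact_max = 0)$p_value
    abs(pe - pn)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("rank_sum_abundance compares one taxon between two groups", {
  ab <- cbind(t1 = c(0.8, 0.7, 0.9, 0.1, 0.2, 0.3),
              t2 = c(0.2, 0.3, 0.1, 0.9, 0.8, 0.7))
  rownames(ab) <- sprintf("s%d", 1:6)
  g <- rep(c("a", "b"), each = 3)
  rs <- rank_sum_abundance(abundance_table(ab), g, "t1")
  expect_equal(rs$p_value, 0.1)
  expect_error(rank_sum_abundance(abundance_table(ab), g, "nope"),
               "unknown taxon")
  expect_error(rank_sum_abundance(abundance_table(ab), rep("a", 6), "t1"),
               "two groups")
})
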