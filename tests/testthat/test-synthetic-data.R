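test_that("zero mutational input yields an empty variant table", {
  cfg <- host_sim_config(n_genes = 5, gene_len_codons = 30, theta = 0,
                         divergence = 0, n_samples_pop1 = 4,
                         n_samples_pop2 = 4, seed = 1)
  sim <- simulate_host_populations(cfg)
  expect_equal(n_sites(sim$variants), 0)
  expect_equal(length(sim$panel$sample), 8)
})

test_that("identical config and seed give byte-identical VCF output", {
  cfg <- host_sim_config(n_genes = 8, gene_len_codons = 60,
                         n_samples_pop1 = 5, n_samples_pop2 = 5,
                         theta = 0.01, divergence = 0.02, seed = 77)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_host_sim(simulate_host_populations(cfg), d1 <- tempfile())
  write_host_sim(simulate_host_populations(cfg), d2 <- tempfile())
  expect_identical(readLines(file.path(d1, "hosts.vcf")),
                   readLines(file.path(d2, "hosts.vcf")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("every emitted site is a biallelic SNP consistent with the reference", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 15, gene_len_codons = 80, n_samples_pop1 = 6,
    n_samples_pop2 = 6, theta = 0.01, divergence = 0.03, seed = 3))
  s <- sim$variants$sites
  expect_true(all(s$n_alleles == 2))
  expect_true(all(nchar(s$ref) == 1 & nchar(s$alt) == 1))
  expect_true(all(s$ref != s$alt))
  # REF base must match the reference sequence at every position
  refb <- vapply(seq_len(nrow(s)), function(i)
    as.character(Biostrings::subseq(sim$reference[[s$chrom[i]]],
                                    s$pos[i], s$pos[i])), character(1))
  expect_identical(refb, s$ref)
})

test_that("selected genes carry the nonsynonymous fixation multiplier", {
  # ratio of Poisson means: F_N/F_S in selected genes should be ~multiplier
  # times the neutral ratio; verified on pooled counts over 20 replicates
  mult <- 10
  rat <- vapply(1:20, function(s) {
    sim <- simulate_host_populations(host_sim_config(
      n_genes = 40, gene_len_codons = 150, n_samples_pop1 = 4,
      n_samples_pop2 = 4, theta = 0.002, divergence = 0.02,
      selected_genes = 1:15, nonsyn_fix_multiplier = mult, seed = 500 + s))
    tf <- sim$truth$sites
    fx <- tf[tf$category == "fixed", ]
    sel <- fx$gene %in% sim$truth$selected_genes
    r_sel <- sum(fx$functional[sel] == "nonsynonymous") /
      sum(fx$functional[sel] == "synonymous")
    r_neu <- sum(fx$functional[!sel] == "nonsynonymous") /
      sum(fx$functional[!sel] == "synonymous")
    r_sel / r_neu
  }, numeric(1))
  expect_gt(mean(rat), mult * 0.8)
  expect_lt(mean(rat), mult * 1.2)
})

test_that("config validation rejects degenerate settings", {
  expect_error(host_sim_config(n_samples_pop1 = 0), "positive integer")
  expect_error(host_sim_config(nonsyn_fix_multiplier = 0.5), ">= 1")
  expect_error(host_sim_config(selected_genes = 1000, n_genes = 10),
               "out of range")
  # multi-hit guard: expected mutations per codon must stay below 1
  expect_error(host_sim_config(theta = 0.05, divergence = 0.2,
                               selected_genes = 1,
                               nonsyn_fix_multiplier = 10),
               "multi-hit")
  expect_error(host_sim_config(true_ne_pop1 = 10, n_samples_pop1 = 20),
               "Ne")
})

test_that("haploid emission mode produces 0/1 dosages and haploid VCF calls", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 6, gene_len_codons = 50, n_samples_pop1 = 6,
    n_samples_pop2 = 6, theta = 0.01, divergence = 0.02, ploidy = 1,
    seed = 9))
  expect_true(all(sim$variants$genotypes %in% c(0L, 1L, NA)))
  d <- tempfile(); write_host_sim(sim, d)
  vcf <- readLines(file.path(d, "hosts.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_false(any(grepl("0/1", body, fixed = TRUE)))
})

test_that("shared polymorphism mode plants sites segregating in both populations", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 20, gene_len_codons = 100, n_samples_pop1 = 10,
    n_samples_pop2 = 10, theta = 0.01, divergence = 0,
    shared_poly_rate = 0.5, seed = 21))
  seg <- classify_segregation(sim$variants, sim$panel)
  expect_gt(sum(seg == "polymorphic_shared"), 0)
  tf <- sim$truth$sites
  expect_setequal(unique(tf$category[match(
    paste(sim$variants$sites$chrom, sim$variants$sites$pos)[
      seg == "polymorphic_shared"],
    paste(tf$chrom, tf$pos))]), "poly_shared")
})

test_that("community simulator respects health flags and composition bounds", {
  cfg <- community_sim_config(n_samples_per_pop = 6, frac_unhealthy = 0,
                              reads_per_sample = 50, read_len = 60,
                              taxon_genome_len = 500, seed = 2)
  sim <- simulate_metagenomes(cfg)
  expect_true(all(!sim$truth$unhealthy))
  expect_true(all(abs(rowSums(sim$abundance) - 1) < 1e-12))
  # planted unhealthy samples exceed 50% pathogen mass
  cfg2 <- community_sim_config(n_samples_per_pop = 10,
                               frac_unhealthy = 0.2,
                               reads_per_sample = 0, seed = 5)
  sim2 <- simulate_metagenomes(cfg2)
  expect_equal(sum(sim2$truth$unhealthy), 4)
  mass <- rowSums(sim2$abundance[, cfg2$pathogen_taxa])
  expect_true(all(mass[sim2$truth$unhealthy] > 0.5))
})

test_that("near-identical compositions give near-zero k-mer distance compared with the between-host distance", {
  cfg <- community_sim_config(
    dirichlet_pop1 = c(8, 6, 4, 2, 1, 1, 0.3, 0.2) * 1e5,
    dirichlet_pop2 = c(2, 1, 6, 8, 0.5, 3, 0.3, 0.2) * 1e5,
    n_samples_per_pop = 2, reads_per_sample = 2500, read_len = 80,
    taxon_genome_len = 1000, seed = 31)
  sim <- simulate_metagenomes(cfg)
  prof <- lapply(names(sim$reads), function(s)
    kmer_profile(sim$reads[[s]], k = 21, sample_id = s))
  names(prof) <- names(sim$reads)
  d <- kmer_distance_matrix(prof)
  within <- d[1, 2]
  between <- mean(d[1:2, 3:4])
  expect_lt(within, 0.05)
  expect_lt(within, between)
})

test_that("empty samples are emitted when reads_per_sample is zero and profiling errors cleanly", {
  sim <- simulate_metagenomes(community_sim_config(
    n_samples_per_pop = 2, reads_per_sample = 0, seed = 8))
  expect_true(all(lengths(sim$reads) == 0))
  expect_error(kmer_profile(sim$reads[[1]]), "no reads")
})

test_that("community config validation", {
  expect_error(community_sim_config(read_len = 600, taxon_genome_len = 500),
               "read_len")
  expect_error(community_sim_config(dirichlet_pop1 = c(1, -1)),
               "match the number|positive")
  expect_error(community_sim_config(pathogen_taxa = "NotATaxon"),
               "subset")
  expect_error(community_sim_config(frac_unhealthy = 1.5), "frac_unhealthy")
})
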