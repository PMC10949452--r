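test_that("segregation classes follow the frequency rules", {
  # columns: 3 samples pop1, 3 samples pop2
  g <- rbind(
    c(2L, 2L, 2L, 0L, 0L, 0L),   # fixed difference
    c(0L, 1L, 1L, 0L, 0L, 0L),   # polymorphic pop1
    c(2L, 2L, 2L, 2L, 1L, 0L),   # polymorphic pop2
    c(1L, 1L, 1L, 1L, 1L, 1L),   # shared polymorphism
    c(2L, 2L, 2L, 2L, 2L, 2L),   # same allele fixed in both: uninformative
    c(0L, 0L, 0L, 0L, 0L, 0L))   # uninformative
  v <- make_vt(g)
  panel <- two_pop_panel(3, 3, v$sample_ids)
  expect_equal(classify_segregation(v, panel),
               c("fixed_difference", "polymorphic_pop1",
                 "polymorphic_pop2", "polymorphic_shared",
                 "uninformative", "uninformative"))
})

test_that("maf cutoff demotes rare polymorphisms to the major-allele state", {
  # pop1 of 10 samples: one heterozygote -> maf 0.05
  g <- matrix(0L, 1, 14)
  g[1, 1] <- 1L
  g[1, 11:14] <- 2L
  v <- make_vt(g)
  panel <- two_pop_panel(10, 4, v$sample_ids)
  expect_equal(classify_segregation(v, panel), "polymorphic_pop1")
  # with maf_cut = 0.10 the rare variant is treated as absent and the site
  # becomes a clean fixed difference
  expect_equal(classify_segregation(v, panel, maf_cut = 0.10),
               "fixed_difference")
})

test_that("a population with no called genotype makes the site uninformative with a warning", {
  g <- matrix(c(1L, 1L, NA, NA), 1, 4)
  v <- make_vt(g, depths = matrix(c(9L, 9L, NA, NA), 1, 4))
  panel <- two_pop_panel(2, 2, v$sample_ids)
  expect_warning(cls <- classify_segregation(v, panel), "entirely missing")
  expect_equal(cls, "uninformative")
})

test_that("MK counts respect the single-count rule for shared polymorphisms", {
  fun <- c("nonsynonymous", "synonymous", "nonsynonymous", "synonymous",
           "nonsynonymous", "nonsynonymous")
  seg <- c("fixed_difference", "fixed_difference", "polymorphic_pop1",
           "polymorphic_pop2", "polymorphic_shared", "uninformative")
  ct <- mk_table(fun, seg)
  expect_equal(ct, c(F_N = 1L, F_S = 1L, P_N = 2L, P_S = 1L))
  ct2 <- mk_table(fun, seg, count_shared_twice = TRUE)
  expect_equal(ct2[["P_N"]], 3L)
  expect_equal(mk_table(character(0), character(0)),
               c(F_N = 0L, F_S = 0L, P_N = 0L, P_S = 0L))
})

test_that("mk_test handles canonical tables and matches the enumeration oracle", {
  rec <- mk_test(data.frame(F_N = c(1, 10, 0), F_S = c(1, 2, 5),
                            P_N = c(1, 1, 0), P_S = c(1, 5, 7)))
  # perfectly neutral table
  expect_equal(rec$ni_ratio[1], 1)
  expect_equal(rec$p_value[1], 1)
  expect_false(rec$selected[1])
  # (10,2,1,5): NI = 25, p from the oracle
  expect_equal(rec$ni_ratio[2], 25)
  expect_equal(rec$p_value[2], fisher_oracle(10, 2, 1, 5),
               tolerance = 1e-12)
  expect_equal(rec$selected[2], rec$p_value[2] < 0.05)
  # no nonsynonymous events: NI undefined, never selected, p = 1
  expect_true(is.na(rec$ni_ratio[3]))
  expect_false(rec$selected[3])
  expect_equal(rec$p_value[3], 1)
})

test_that("Fisher p-values match the enumeration oracle and stats::fisher.test", {
  set.seed(11)
  a <- sample(0:25, 200, TRUE); b <- sample(0:25, 200, TRUE)
  c <- sample(0:25, 200, TRUE); d <- sample(0:25, 200, TRUE)
  p <- fisher_exact_2x2(a, b, c, d)
  expect_equal(p, fisher_oracle(a, b, c, d), tolerance = 1e-12)
  idx <- sample(200, 40)
  pf <- mapply(function(x, y, z, w)
    stats::fisher.test(matrix(c(x, z, y, w), 2))$p.value,
    a[idx], b[idx], c[idx], d[idx])
  expect_equal(p[idx], unname(pf), tolerance = 1e-9)
})

test_that("pooled alpha is zero for neutral tables and undefined without fixations", {
  rec <- data.frame(F_N = rep(3, 10), F_S = rep(3, 10),
                    P_N = rep(3, 10), P_S = rep(3, 10))
  expect_equal(pooled_alpha(rec)$alpha, 0)
  rec0 <- data.frame(F_N = 0, F_S = 5, P_N = 3, P_S = 4)
  a0 <- pooled_alpha(rec0)
  expect_true(a0$undefined)
  # bootstrap CI brackets the point estimate
  set.seed(2)
  rec2 <- data.frame(F_N = rpois(50, 20), F_S = rpois(50, 7),
                     P_N = rpois(50, 30), P_S = rpois(50, 10))
  ae <- pooled_alpha(rec2, n_boot = 200, seed = 4)
  expect_true(ae$ci[1] <= ae$alpha && ae$alpha <= ae$ci[2])
})

test_that("the scan is invariant to population label swap and sample order", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 12, gene_len_codons = 80, n_samples_pop1 = 6,
    n_samples_pop2 = 6, theta = 0.01, divergence = 0.03,
    selected_genes = 1:3, seed = 17))
  v <- sim$variants
  scan <- run_mk_scan(v, sim$genes, sim$panel, sim$reference)

  # swap population labels
  panel_sw <- population_panel(sim$panel$sample,
                               ifelse(sim$panel$population == "pop1",
                                      "pop2", "pop1"))
  scan_sw <- run_mk_scan(v, sim$genes, panel_sw, sim$reference)
  expect_equal(scan$records[, c("F_N", "F_S", "P_N", "P_S", "p_value")],
               scan_sw$records[, c("F_N", "F_S", "P_N", "P_S", "p_value")])
  expect_equal(scan$alpha$alpha, scan_sw$alpha$alpha)

  # permute sample order
  perm <- sample(length(v$sample_ids))
  v2 <- v
  v2$genotypes <- v$genotypes[, perm]
  v2$depths <- v$depths[, perm]
  v2$sample_ids <- v$sample_ids[perm]
  scan_p <- run_mk_scan(v2, sim$genes, sim$panel, sim$reference)
  expect_identical(scan$records, scan_p$records)
})

test_that("min_poly excludes genes lacking sufficient polymorphisms", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 10, gene_len_codons = 60, n_samples_pop1 = 5,
    n_samples_pop2 = 5, theta = 0.002, divergence = 0.03, seed = 23))
  scan1 <- run_mk_scan(sim$variants, sim$genes, sim$panel, sim$reference,
                       min_poly = 1)
  scan5 <- run_mk_scan(sim$variants, sim$genes, sim$panel, sim$reference,
                       min_poly = 5)
  expect_lte(scan5$n_genes_used, scan1$n_genes_used)
  expect_true(all(scan5$records$P_N + scan5$records$P_S >= 5))
  expect_equal(scan1$n_genes_total, 10)
  # records come back sorted by gene id
  expect_identical(scan1$records$gene_id, sort(scan1$records$gene_id))
})

test_that("an empty gene set produces empty outputs", {
  sim <- simulate_host_populations(host_sim_config(
    n_genes = 4, gene_len_codons = 40, n_samples_pop1 = 3,
    n_samples_pop2 = 3, theta = 0.01, divergence = 0.02, seed = 29))
  scan <- run_mk_scan(sim$variants, sim$genes[0, ], sim$panel,
                      sim$reference)
  expect_equal(nrow(scan$records), 0)
  expect_equal(length(scan$selected_genes), 0)
})

test_that("alpha increases with the planted nonsynonymous fixation multiplier", {
  alphas <- vapply(c(2, 5, 10), function(m) {
    sim <- simulate_host_populations(host_sim_config(
      n_genes = 60, gene_len_codons = 150, n_samples_pop1 = 8,
      n_samples_pop2 = 8, theta = 0.008, divergence = 0.02,
      selected_genes = 1:12, nonsyn_fix_multiplier = m, seed = 37))
    run_mk_scan(sim$variants, sim$genes, sim$panel,
                sim$reference)$alpha$alpha
  }, numeric(1))
  expect_gt(alphas[1], 0)
  expect_true(all(diff(alphas) > 0))
})
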