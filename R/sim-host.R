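## Synthetic two-population host genetics with planted ground truth.
##
## The generator is rate-based: ancestral coding sequences are drawn
## uniformly over sense codons; fixed differences per gene are Poisson with
## synonymous rate divergence x (synonymous opportunity) and nonsynonymous
## rate divergence x (nonsynonymous opportunity) x multiplier-if-selected;
## polymorphic sites are private to one population with derived-allele
## frequencies from the neutral site-frequency spectrum (P(i) proportional
## to 1/i). This gives exact control of the expected McDonald-Kreitman
## table. When a finite true Ne is requested, genotypes at polymorphic loci
## are produced by a short discrete Wright-Fisher epoch at that size, so
## that drift generates the between-locus linkage disequilibrium the LD-Ne
## estimator reads.

#' Configuration for the two-population host simulator
#'
#' @param n_genes number of genes (one contig per gene).
#' @param gene_len_codons codons per gene.
#' @param n_samples_pop1,n_samples_pop2 sampled individuals per population.
#' @param theta scaled polymorphism rate per site, per population.
#' @param divergence expected fixed differences per synonymous site between
#'   the populations.
#' @param selected_genes integer vector of gene indices (1-based) under
#'   positive selection.
#' @param nonsyn_fix_multiplier factor (>= 1) applied to the nonsynonymous
#'   fixation rate in selected genes.
#' @param true_ne_pop1,true_ne_pop2 true effective sizes; `Inf` (default)
#'   draws genotypes directly at the SFS frequency (no drift LD), a finite
#'   value runs a Wright-Fisher epoch of that size.
#' @param mean_depth mean simulated read depth per genotype (Poisson).
#' @param seed RNG seed.
#' @param ploidy 2 (diploid-coded, default) or 1 (haploid emission mode).
#' @param frac_minus_strand fraction of genes placed on the minus strand.
#' @param shared_poly_rate probability that a pop1 polymorphism is also made
#'   polymorphic in pop2 (exercises the shared-polymorphism branch of the MK
#'   classifier); only honoured in the infinite-Ne mode.
#' @param frac_fail_info fraction of sites given one INFO value violating a
#'   hard-filter clause (exercises the QC stage).
#' @param wf_generations Wright-Fisher burn-in generations (finite Ne only).
#' @param pop_names labels for the two populations.
#' @return an object of class `host_sim_config`.
#' @export
host_sim_config <- function(n_genes = 500, gene_len_codons = 400,
                            n_samples_pop1 = 20, n_samples_pop2 = 20,
                            theta = 0.015, divergence = 0.025,
                            selected_genes = integer(0),
                            nonsyn_fix_multiplier = 10,
                            true_ne_pop1 = Inf, true_ne_pop2 = Inf,
                            mean_depth = 20, seed = 1, ploidy = 2,
                            frac_minus_strand = 0.3,
                            shared_poly_rate = 0, frac_fail_info = 0,
                            wf_generations = 25,
                            pop_names = c("pop1", "pop2")) {
  for (nm in c("n_genes", "gene_len_codons", "n_samples_pop1",
               "n_samples_pop2"))
    stop_if_not_scalar_count(get(nm), nm)
  if (theta < 0 || divergence < 0) stop("theta and divergence must be >= 0")
  if (nonsyn_fix_multiplier < 1) stop("nonsyn_fix_multiplier must be >= 1")
  selected_genes <- as.integer(selected_genes)
  if (length(selected_genes) &&
      (min(selected_genes) < 1 || max(selected_genes) > n_genes))
    stop("selected_genes out of range 1..n_genes")
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  ne <- c(true_ne_pop1, true_ne_pop2)
  if (any(ne <= 0)) stop("true Ne must be positive (or Inf)")
  for (p in 1:2) {
    n_s <- c(n_samples_pop1, n_samples_pop2)[p]
    if (is.finite(ne[p]) && ne[p] < n_s)
      stop("finite true Ne must be >= the number of sampled individuals")
  }
  cfg <- list(
    n_genes = n_genes, gene_len_codons = gene_len_codons,
    n_samples_pop1 = n_samples_pop1, n_samples_pop2 = n_samples_pop2,
    theta = theta, divergence = divergence,
    selected_genes = sort(unique(selected_genes)),
    nonsyn_fix_multiplier = nonsyn_fix_multiplier,
    true_ne_pop1 = true_ne_pop1, true_ne_pop2 = true_ne_pop2,
    mean_depth = mean_depth, seed = as.integer(seed), ploidy = ploidy,
    frac_minus_strand = frac_minus_strand,
    shared_poly_rate = shared_poly_rate,
    frac_fail_info = frac_fail_info,
    wf_generations = as.integer(wf_generations),
    pop_names = pop_names
  )
  ## guard against multi-hit codons dominating: expected mutations per
  ## codon must stay below 1 for the worst-case (selected) gene, using the
  ## mean synonymous/nonsynonymous opportunity of sense codons
  n_all <- c(ploidy * n_samples_pop1, ploidy * n_samples_pop2)
  a_sum <- sum(vapply(n_all, function(n) harmonic_number(max(n - 1, 0)),
                      numeric(1)))
  opp <- codon_data()$opportunity
  sense <- codon_data()$sense_codons
  sbar <- mean(opp[sense, "syn_sites"])
  nbar <- mean(opp[sense, "nonsyn_sites"])
  mult_eff <- if (length(selected_genes)) nonsyn_fix_multiplier else 1
  per_codon <- divergence * (sbar + nbar * mult_eff) + theta * 3 * a_sum
  if (per_codon > 1)
    stop(sprintf(paste0("expected mutations per codon (%.2f) exceeds 1; ",
                        "multi-hit codons would dominate - reduce theta, ",
                        "divergence or the multiplier"), per_codon))
  class(cfg) <- "host_sim_config"
  cfg
}

## flat change tables per class (stop-creating excluded) with per-codon
## offset/count index, enabling fully vectorised sampling
.change_sampler <- function() {
  cd <- codon_data()
  ch <- cd$changes
  usable <- !ch$to_stop & ch$aa_ref != "*"
  ch <- ch[usable, c("codon", "pos", "alt", "synonymous")]
  build <- function(df) {
    df <- df[order(df$codon), , drop = FALSE]
    rownames(df) <- NULL
    cnt <- table(df$codon)
    off <- setNames(cumsum(c(0, as.integer(cnt)))[seq_along(cnt)],
                    names(cnt))
    full <- setNames(integer(length(cd$sense_codons)), cd$sense_codons)
    full[names(cnt)] <- as.integer(cnt)
    offs <- setNames(integer(length(cd$sense_codons)), cd$sense_codons)
    offs[names(off)] <- as.integer(off)
    list(df = df, cnt = full, off = offs)
  }
  list(any = build(ch),
       syn = build(ch[ch$synonymous, , drop = FALSE]),
       non = build(ch[!ch$synonymous, , drop = FALSE]))
}

## sample k changes of a class from a gene's codon vector (vectorised);
## returns data.frame(codon_idx, pos, alt, synonymous)
.sample_changes <- function(codons, k, class = c("any", "syn", "non"),
                            sampler) {
  class <- match.arg(class)
  if (k == 0)
    return(data.frame(codon_idx = integer(0), pos = integer(0),
                      alt = character(0), synonymous = logical(0)))
  sc <- sampler[[class]]
  w <- sc$cnt[codons]
  ci <- sample.int(length(codons), k, replace = TRUE, prob = w)
  cod <- codons[ci]
  ridx <- sc$off[cod] + ceiling(runif(k) * sc$cnt[cod])
  rows <- sc$df[ridx, , drop = FALSE]
  data.frame(codon_idx = ci, pos = rows$pos, alt = rows$alt,
             synonymous = rows$synonymous)
}

## SFS draw: derived count i in 1..(n-1) with P(i) proportional to 1/i
.rsfs <- function(k, n) {
  if (k == 0) return(integer(0))
  i <- seq_len(n - 1)
  sample(i, k, replace = TRUE, prob = 1 / i)
}

## assign `count` derived alleles among n_alleles slots; dosage per sample
.dosage_from_count <- function(count, n_samples, ploidy) {
  slots <- sample.int(n_samples * ploidy, count)
  tabulate((slots - 1L) %/% ploidy + 1L, nbins = n_samples)
}

## Wright-Fisher epoch: loci grouped in fully linked gene blocks, free
## recombination between blocks. Returns dosages (loci x n_samples) and a
## keep mask for loci still segregating.
.wf_genotypes <- function(n_loci, gene_block, ne, n_samples, gens, ploidy) {
  n2 <- 2L * ne
  init <- .rsfs(n_loci, n2)
  H1 <- matrix(0L, ne, n_loci)
  H2 <- matrix(0L, ne, n_loci)
  for (l in seq_len(n_loci)) {
    slots <- sample.int(n2, init[l])
    h1 <- slots[slots <= ne]
    h2 <- slots[slots > ne] - ne
    H1[h1, l] <- 1L
    H2[h2, l] <- 1L
  }
  blocks <- unique(gene_block)
  bidx <- match(gene_block, blocks)
  nb <- length(blocks)
  for (g in seq_len(gens)) {
    p1 <- sample.int(ne, ne, replace = TRUE)
    p2 <- sample.int(ne, ne, replace = TRUE)
    eq <- which(p2 == p1)
    while (length(eq)) {   # random mating without selfing
      p2[eq] <- sample.int(ne, length(eq), replace = TRUE)
      eq <- eq[p2[eq] == p1[eq]]
    }
    C1 <- matrix(rbinom(ne * nb, 1L, 0.5), ne, nb)[, bidx, drop = FALSE]
    C2 <- matrix(rbinom(ne * nb, 1L, 0.5), ne, nb)[, bidx, drop = FALSE]
    G1 <- H1[p1, , drop = FALSE] * C1 + H2[p1, , drop = FALSE] * (1L - C1)
    G2 <- H1[p2, , drop = FALSE] * C2 + H2[p2, , drop = FALSE] * (1L - C2)
    H1 <- G1
    H2 <- G2
  }
  freq <- colSums(H1) + colSums(H2)
  keep <- freq > 0L & freq < n2
  take <- sample.int(ne, n_samples)
  if (ploidy == 2) {
    dos <- t(H1[take, , drop = FALSE] + H2[take, , drop = FALSE])
  } else {
    dos <- t(H1[take, , drop = FALSE])
  }
  list(dosage = dos, keep = keep)
}

#' Simulate two diverged host populations with planted selection
#'
#' Generates reference coding sequences, a biallelic SNP table (fixed
#' differences between populations plus private polymorphisms), gene models,
#' a population panel and a ground-truth record. See [host_sim_config()] for
#' the knobs.
#'
#' @param cfg a `host_sim_config`.
#' @return a list of class `host_sim` with elements `variants`
#'   (`variant_table`), `genes` (BED-like data.frame), `reference`
#'   (`DNAStringSet`), `panel` (`population_panel`) and `truth` (list with
#'   `selected_genes`, `true_ne`, per-site `sites` truth, per-gene
#'   opportunities).
#' @export
simulate_host_populations <- function(cfg) {
  stopifnot(inherits(cfg, "host_sim_config"))
  set.seed(cfg$seed)
  cd <- codon_data()
  sampler <- .change_sampler()
  opp <- cd$opportunity
  ng <- cfg$n_genes
  len <- cfg$gene_len_codons
  lbp <- 3L * len
  gene_id <- sprintf("g%04d", seq_len(ng))
  strand <- ifelse(runif(ng) < cfg$frac_minus_strand, "-", "+")
  n_s <- c(cfg$n_samples_pop1, cfg$n_samples_pop2)
  n_all <- cfg$ploidy * n_s
  a_pop <- vapply(n_all, function(n) harmonic_number(max(n - 1, 0)),
                  numeric(1))
  ne_pop <- c(cfg$true_ne_pop1, cfg$true_ne_pop2)
  samples <- c(sprintf("%s_%02d", cfg$pop_names[1], seq_len(n_s[1])),
               sprintf("%s_%02d", cfg$pop_names[2], seq_len(n_s[2])))
  pop_of <- rep(cfg$pop_names, n_s)

  codon_mat <- matrix(sample(cd$sense_codons, ng * len, replace = TRUE),
                      nrow = ng)
  cds_seq <- apply(codon_mat, 1, paste, collapse = "")
  contig_seq <- ifelse(strand == "+", cds_seq, revcomp(cds_seq))

  gene_opp <- t(apply(codon_mat, 1, function(cods) {
    o <- opp[cods, ]
    c(syn = sum(o$syn_sites), non = sum(o$nonsyn_sites))
  }))

  is_sel <- seq_len(ng) %in% cfg$selected_genes
  mult <- ifelse(is_sel, cfg$nonsyn_fix_multiplier, 1)

  ## per-gene mutation draws: fixed syn / fixed non / poly per pop.
  ## Polymorphism count uses the full per-site rate theta (stop-creating
  ## draws are redrawn onto the usable change list), keeping E[pi] = theta.
  site_rows <- vector("list", ng)
  for (gi in seq_len(ng)) {
    cods <- codon_mat[gi, ]
    n_fix_s <- rpois(1, cfg$divergence * gene_opp[gi, "syn"])
    n_fix_n <- rpois(1, cfg$divergence * gene_opp[gi, "non"] * mult[gi])
    n_poly <- rpois(2, cfg$theta * a_pop * lbp)
    draw <- function(k, class) .sample_changes(cods, k, class, sampler)
    parts <- list(
      fixed_s = draw(n_fix_s, "syn"),
      fixed_n = draw(n_fix_n, "non"),
      poly1 = draw(n_poly[1], "any"),
      poly2 = draw(n_poly[2], "any")
    )
    cat_of <- rep(c("fixed", "fixed", "poly1", "poly2"),
                  vapply(parts, nrow, integer(1)))
    mut <- do.call(rbind, parts)
    if (nrow(mut) == 0) next
    mut$category <- cat_of
    mut$t <- 3L * (mut$codon_idx - 1L) + mut$pos - 1L  # 0-based CDS coord
    ## redraw collisions at the same CDS position (infinite-sites)
    for (it in 1:25) {
      dup <- which(duplicated(mut$t))
      if (!length(dup)) break
      cls_of <- ifelse(mut$category[dup] == "fixed",
                       ifelse(mut$synonymous[dup], "syn", "non"), "any")
      for (cl in unique(cls_of)) {
        dd <- dup[cls_of == cl]
        r <- .sample_changes(cods, length(dd), cl, sampler)
        mut$codon_idx[dd] <- r$codon_idx
        mut$pos[dd] <- r$pos
        mut$alt[dd] <- r$alt
        mut$synonymous[dd] <- r$synonymous
        mut$t[dd] <- 3L * (r$codon_idx - 1L) + r$pos - 1L
      }
    }
    mut <- mut[!duplicated(mut$t), , drop = FALSE]
    mut$gene <- gi
    site_rows[[gi]] <- mut
  }
  mut <- do.call(rbind, site_rows)

  empty_sites <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), qual = numeric(0), is_indel = logical(0),
    n_alleles = integer(0)
  )
  if (is.null(mut) || nrow(mut) == 0) {
    g0 <- matrix(integer(0), 0, sum(n_s), dimnames = list(NULL, samples))
    vt <- variant_table(empty_sites, g0, g0, samples, ploidy = cfg$ploidy)
    genes <- data.frame(chrom = gene_id, start = 0L, end = lbp,
                        gene_id = gene_id, strand = strand, frame = 0L)
    ref <- Biostrings::DNAStringSet(setNames(contig_seq, gene_id))
    panel <- population_panel(samples, pop_of)
    truth <- list(selected_genes = gene_id[is_sel],
                  true_ne = setNames(ne_pop, cfg$pop_names),
                  labels = setNames(pop_of, samples),
                  sites = NULL, gene_opportunity = gene_opp, config = cfg)
    return(structure(list(variants = vt, genes = genes, reference = ref,
                          panel = panel, truth = truth),
                     class = "host_sim"))
  }

  ## ---------------- genotypes -------------------------------------------
  n_sites <- nrow(mut)
  n_samp_tot <- sum(n_s)
  G <- matrix(0L, n_sites, n_samp_tot)
  cols_pop <- list(seq_len(n_s[1]), n_s[1] + seq_len(n_s[2]))

  idx_fix <- which(mut$category == "fixed")
  if (length(idx_fix)) {
    alt_pop <- rbinom(length(idx_fix), 1L, 0.5) + 1L
    for (j in seq_along(idx_fix)) {
      G[idx_fix[j], cols_pop[[alt_pop[j]]]] <- cfg$ploidy
    }
    mut$alt_pop <- NA_integer_
    mut$alt_pop[idx_fix] <- alt_pop
  } else mut$alt_pop <- NA_integer_

  drop_mask <- rep(FALSE, n_sites)
  for (p in 1:2) {
    idx_p <- which(mut$category == paste0("poly", p))
    if (!length(idx_p)) next
    if (is.finite(ne_pop[p])) {
      wf <- .wf_genotypes(length(idx_p), mut$gene[idx_p], as.integer(ne_pop[p]),
                          n_s[p], cfg$wf_generations, cfg$ploidy)
      G[idx_p, cols_pop[[p]]] <- wf$dosage
      drop_mask[idx_p[!wf$keep]] <- TRUE
    } else {
      cnt <- .rsfs(length(idx_p), n_all[p])
      for (j in seq_along(idx_p)) {
        G[idx_p[j], cols_pop[[p]]] <-
          .dosage_from_count(cnt[j], n_s[p], cfg$ploidy)
      }
    }
  }
  ## optional shared polymorphism: pop1 polys also segregate in pop2
  if (cfg$shared_poly_rate > 0 && !is.finite(ne_pop[2])) {
    idx1 <- which(mut$category == "poly1" & !drop_mask)
    sh <- idx1[runif(length(idx1)) < cfg$shared_poly_rate]
    if (length(sh)) {
      cnt <- .rsfs(length(sh), n_all[2])
      for (j in seq_along(sh)) {
        G[sh[j], cols_pop[[2]]] <- .dosage_from_count(cnt[j], n_s[2],
                                                      cfg$ploidy)
      }
      mut$category[sh] <- "poly_shared"
    }
  }

  if (any(drop_mask)) {
    mut <- mut[!drop_mask, , drop = FALSE]
    G <- G[!drop_mask, , drop = FALSE]
    n_sites <- nrow(mut)
  }

  ## ---------------- contig coordinates and alleles ----------------------
  st <- strand[mut$gene]
  pos0 <- ifelse(st == "+", mut$t, lbp - 1L - mut$t)
  ref_cds <- substring(codon_mat[cbind(mut$gene, mut$codon_idx)],
                       mut$pos, mut$pos)
  ref_b <- ifelse(st == "+", ref_cds, comp_base(ref_cds))
  alt_b <- ifelse(st == "+", mut$alt, comp_base(mut$alt))

  ## ---------------- site annotations ------------------------------------
  qd <- runif(n_sites, 10, 35)
  mq <- runif(n_sites, 45, 60)
  fs <- runif(n_sites, 0, 30)
  sor <- runif(n_sites, 0.3, 2.5)
  mqrs <- rnorm(n_sites, 0, 2)
  rprs <- rnorm(n_sites, 0, 2)
  qual <- round(runif(n_sites, 100, 2000), 2)
  if (cfg$frac_fail_info > 0) {
    n_fail <- floor(cfg$frac_fail_info * n_sites)
    fail_i <- sample.int(n_sites, n_fail)
    clause <- sample.int(6L, n_fail, replace = TRUE)
    for (j in seq_along(fail_i)) {
      i <- fail_i[j]
      switch(clause[j],
             qd[i] <- runif(1, 0, 1.99),
             mq[i] <- runif(1, 20, 39.9),
             fs[i] <- runif(1, 60.1, 120),
             sor[i] <- runif(1, 3.1, 6),
             mqrs[i] <- runif(1, -20, -12.6),
             rprs[i] <- runif(1, -15, -8.1))
    }
  }
  sites <- data.frame(
    chrom = gene_id[mut$gene], pos = pos0 + 1L, ref = ref_b, alt = alt_b,
    qual = qual, is_indel = FALSE, n_alleles = 2L,
    QD = round(qd, 2), MQ = round(mq, 2), FS = round(fs, 2),
    SOR = round(sor, 2), MQRankSum = round(mqrs, 2),
    ReadPosRankSum = round(rprs, 2),
    stringsAsFactors = FALSE
  )
  depth <- matrix(rpois(n_sites * n_samp_tot, cfg$mean_depth),
                  n_sites, n_samp_tot)
  G[depth == 0L] <- NA_integer_

  ## variant_table sorts rows by chrom/pos; carry the site truth through
  ord <- order(sites$chrom, sites$pos)
  site_truth <- data.frame(
    chrom = sites$chrom[ord], pos = sites$pos[ord],
    gene = gene_id[mut$gene][ord],
    category = mut$category[ord],
    functional = ifelse(mut$synonymous[ord], "synonymous", "nonsynonymous"),
    cds_pos = mut$t[ord],
    stringsAsFactors = FALSE
  )
  vt <- variant_table(sites, G, depth, samples, ploidy = cfg$ploidy)

  genes <- data.frame(chrom = gene_id, start = 0L, end = lbp,
                      gene_id = gene_id, strand = strand, frame = 0L,
                      stringsAsFactors = FALSE)
  ref <- Biostrings::DNAStringSet(setNames(contig_seq, gene_id))
  panel <- population_panel(samples, pop_of)
  truth <- list(
    selected_genes = gene_id[is_sel],
    true_ne = setNames(ne_pop, cfg$pop_names),
    labels = setNames(pop_of, samples),
    sites = site_truth,
    gene_opportunity = data.frame(gene_id = gene_id,
                                  syn_sites = gene_opp[, "syn"],
                                  nonsyn_sites = gene_opp[, "non"]),
    config = cfg
  )
  structure(list(variants = vt, genes = genes, reference = ref,
                 panel = panel, truth = truth),
            class = "host_sim")
}

#' Write a simulated host dataset to disk
#'
#' Emits `hosts.vcf`, `reference.fa`, `genes.tsv` (BED-like, 0-based
#' half-open), `panel.tsv` and `truth.json` under `out_dir`.
#'
#' @param sim a `host_sim` from [simulate_host_populations()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_host_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(Biostrings::width(sim$reference), names(sim$reference))
  write_vcf(sim$variants, file.path(out_dir, "hosts.vcf"),
            contig_lengths = lens)
  Biostrings::writeXStringSet(sim$reference, file.path(out_dir, "reference.fa"))
  write_gene_table(sim$genes, file.path(out_dir, "genes.tsv"))
  write_panel(sim$panel, file.path(out_dir, "panel.tsv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
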