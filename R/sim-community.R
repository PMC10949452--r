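## Synthetic gut-community metagenomes with planted ground truth.
##
## One random reference sequence per taxon (fixed per run); per sample the
## taxon composition is Dirichlet-distributed around its host population's
## profile, except for a planted subset of pathogen-dominated ("unhealthy")
## samples; reads are uniform substrings of the taxon references on a
## random strand.

#' Configuration for the gut-community simulator
#'
#' @param taxa taxon names.
#' @param dirichlet_pop1,dirichlet_pop2 strictly positive Dirichlet
#'   concentration vectors (length = number of taxa) for the two host
#'   populations.
#' @param pathogen_taxa subset of `taxa` treated as pathogens.
#' @param n_samples_per_pop samples per host population.
#' @param frac_unhealthy fraction of samples planted as pathogen-dominated;
#'   the planted count is `round(frac_unhealthy * total samples)`.
#' @param reads_per_sample reads per sample (0 allowed: empty sample).
#' @param read_len read length in bases.
#' @param taxon_genome_len length of each taxon reference sequence.
#' @param seed RNG seed.
#' @param pop_names host population labels.
#' @return object of class `community_sim_config`.
#' @export
community_sim_config <- function(
    taxa = c("Gilliamella", "Snodgrassella", "Lactobacillus_Firm5",
             "Bifidobacterium", "Bartonella", "Frischella",
             "Crithidia", "Paenibacillus"),
    dirichlet_pop1 = c(8, 6, 4, 2, 1, 1, 0.3, 0.2),
    dirichlet_pop2 = c(2, 1, 6, 8, 0.5, 3, 0.3, 0.2),
    pathogen_taxa = c("Crithidia", "Paenibacillus"),
    n_samples_per_pop = 20, frac_unhealthy = 0,
    reads_per_sample = 2000, read_len = 100, taxon_genome_len = 5000,
    seed = 1, pop_names = c("hostA", "hostB")) {
  if (length(dirichlet_pop1) != length(taxa) ||
      length(dirichlet_pop2) != length(taxa))
    stop("concentration vectors must match the number of taxa")
  if (any(dirichlet_pop1 <= 0) || any(dirichlet_pop2 <= 0))
    stop("concentration vectors must be strictly positive")
  if (!all(pathogen_taxa %in% taxa))
    stop("pathogen_taxa must be a subset of taxa")
  if (frac_unhealthy < 0 || frac_unhealthy > 1)
    stop("frac_unhealthy must lie in [0, 1]")
  if (read_len > taxon_genome_len)
    stop("read_len exceeds taxon_genome_len")
  stop_if_not_scalar_count(n_samples_per_pop, "n_samples_per_pop")
  cfg <- list(taxa = taxa, dirichlet_pop1 = dirichlet_pop1,
              dirichlet_pop2 = dirichlet_pop2,
              pathogen_taxa = pathogen_taxa,
              n_samples_per_pop = n_samples_per_pop,
              frac_unhealthy = frac_unhealthy,
              reads_per_sample = reads_per_sample, read_len = read_len,
              taxon_genome_len = taxon_genome_len,
              seed = as.integer(seed), pop_names = pop_names)
  class(cfg) <- "community_sim_config"
  cfg
}

#' Simulate per-sample gut metagenomes
#'
#' @param cfg a `community_sim_config`.
#' @return list of class `community_sim`: `reads` (named list of character
#'   vectors), `abundance` (samples x taxa true composition matrix, rows sum
#'   to 1), `metadata` (sample, host), `taxon_refs` (`DNAStringSet`) and
#'   `truth` (unhealthy flags, host labels, config).
#' @export
simulate_metagenomes <- function(cfg) {
  stopifnot(inherits(cfg, "community_sim_config"))
  set.seed(cfg$seed)
  nt <- length(cfg$taxa)
  n_pop <- cfg$n_samples_per_pop
  n_tot <- 2L * n_pop
  refs <- vapply(seq_len(nt), function(i) {
    paste(sample(DNA_BASES, cfg$taxon_genome_len, replace = TRUE),
          collapse = "")
  }, character(1))
  names(refs) <- cfg$taxa
  samples <- c(sprintf("%s_%02d", cfg$pop_names[1], seq_len(n_pop)),
               sprintf("%s_%02d", cfg$pop_names[2], seq_len(n_pop)))
  host <- rep(cfg$pop_names, each = n_pop)
  conc <- rbind(cfg$dirichlet_pop1, cfg$dirichlet_pop2)
  comp <- matrix(0, n_tot, nt, dimnames = list(samples, cfg$taxa))
  for (i in seq_len(n_tot)) {
    comp[i, ] <- rdirichlet(1, conc[if (host[i] == cfg$pop_names[1]) 1 else 2, ])
  }
  n_unh <- round(cfg$frac_unhealthy * n_tot)
  unhealthy <- rep(FALSE, n_tot)
  is_path <- cfg$taxa %in% cfg$pathogen_taxa
  if (n_unh > 0) {
    if (!any(is_path)) stop("cannot plant unhealthy samples without pathogen_taxa")
    pick <- sample.int(n_tot, n_unh)
    unhealthy[pick] <- TRUE
    for (i in pick) {
      mass <- runif(1, 0.6, 0.95)
      pshare <- rdirichlet(1, rep(1, sum(is_path)))
      rest <- rdirichlet(1, conc[if (host[i] == cfg$pop_names[1]) 1 else 2,
                                 !is_path, drop = TRUE])
      comp[i, is_path] <- mass * pshare
      comp[i, !is_path] <- (1 - mass) * rest
    }
  }
  reads <- vector("list", n_tot)
  names(reads) <- samples
  max_start <- cfg$taxon_genome_len - cfg$read_len + 1L
  for (i in seq_len(n_tot)) {
    if (cfg$reads_per_sample == 0) {
      reads[[i]] <- character(0)
      next
    }
    counts <- as.integer(rmultinom(1, cfg$reads_per_sample, comp[i, ]))
    rds <- character(cfg$reads_per_sample)
    pos <- 1L
    for (t in seq_len(nt)) {
      if (counts[t] == 0) next
      starts <- sample.int(max_start, counts[t], replace = TRUE)
      sub <- substring(refs[t], starts, starts + cfg$read_len - 1L)
      flip <- runif(counts[t]) < 0.5
      if (any(flip)) sub[flip] <- revcomp(sub[flip])
      rds[pos:(pos + counts[t] - 1L)] <- sub
      pos <- pos + counts[t]
    }
    reads[[i]] <- rds
  }
  structure(list(
    reads = reads,
    abundance = comp,
    metadata = data.frame(sample = samples, host = host,
                          stringsAsFactors = FALSE),
    taxon_refs = Biostrings::DNAStringSet(refs),
    truth = list(unhealthy = setNames(unhealthy, samples),
                 labels = setNames(host, samples),
                 composition = comp, config = cfg)
  ), class = "community_sim")
}

#' Write a simulated community dataset to disk
#'
#' Emits one `reads_<sample>.fa` per sample, `abundance.tsv`,
#' `metadata.tsv` and `truth.json` under `out_dir`.
#'
#' @param sim a `community_sim`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_community_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$reads)) {
    rds <- sim$reads[[s]]
    lines <- if (length(rds))
      as.vector(rbind(sprintf(">%s_r%06d", s, seq_along(rds)), rds))
    else character(0)
    writeLines(lines, file.path(out_dir, sprintf("reads_%s.fa", s)))
  }
  ab <- data.frame(sample = rownames(sim$abundance), sim$abundance,
                   check.names = FALSE)
  write.table(ab, file.path(out_dir, "abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$metadata, file.path(out_dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
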