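## Per-gene McDonald-Kreitman scan.
##
## Sites inside a gene's CDS are classified twice: functionally (synonymous
## vs nonsynonymous, strand-aware, against the reference codon background)
## and by segregation (fixed difference between the two populations, private
## polymorphism, shared polymorphism, uninformative). The per-gene 2x2 table
## [[F_N, F_S], [P_N, P_S]] gets a two-sided Fisher exact p-value; a gene is
## called positively selected when NI = (F_N/F_S)/(P_N/P_S) > 1 and
## p < 0.05. Pooled counts across genes give alpha, the proportion of
## amino-acid fixations attributable to positive selection:
## alpha = 1 - (sum F_S * sum P_N) / (sum F_N * sum P_S).

## ---------------------------------------------------------------- gene CDS

## rows of the gene table for one gene, sorted by start
.gene_rows <- function(genes, gene_id) {
  rows <- genes[genes$gene_id == gene_id, , drop = FALSE]
  rows[order(rows$start), , drop = FALSE]
}

## concatenated CDS string (already reverse-complemented on -)
.gene_cds <- function(rows, reference) {
  chrom <- rows$chrom[1]
  seqs <- vapply(seq_len(nrow(rows)), function(i) {
    as.character(Biostrings::subseq(reference[[chrom]],
                                    start = rows$start[i] + 1L,
                                    end = rows$end[i]))
  }, character(1))
  fwd <- paste(seqs, collapse = "")
  if (rows$strand[1] == "-") revcomp(fwd) else fwd
}

## map genomic 1-based positions to 0-based CDS coordinates (NA if outside)
.cds_coord <- function(pos, rows) {
  L <- sum(rows$end - rows$start)
  off <- cumsum(c(0L, rows$end - rows$start))
  fwd <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(rows))) {
    inside <- pos > rows$start[i] & pos <= rows$end[i]
    fwd[inside] <- off[i] + (pos[inside] - rows$start[i] - 1L)
  }
  if (rows$strand[1] == "-") ifelse(is.na(fwd), NA_integer_, L - 1L - fwd)
  else fwd
}

## vectorised functional classification of sites within one gene
.classify_gene_sites <- function(pos, alt, rows, reference) {
  cds <- .gene_cds(rows, reference)
  frame <- rows$frame[1] %||% 0L
  t0 <- .cds_coord(pos, rows)
  eff <- t0 - frame
  out <- rep("uninformative", length(pos))
  ok <- !is.na(eff) & eff >= 0 & eff < (nchar(cds) - frame) %/% 3 * 3
  if (!any(ok)) return(out)
  alt_cds <- if (rows$strand[1] == "-") comp_base(alt) else alt
  ci <- eff[ok] %/% 3L
  cp <- eff[ok] %% 3L + 1L
  codon <- substring(cds, 3L * ci + frame + 1L, 3L * ci + frame + 3L)
  ref_in_codon <- substring(codon, cp, cp)
  same <- alt_cds[ok] == ref_in_codon
  cls <- rep(NA_character_, sum(ok))
  if (any(!same)) {
    cls[!same] <- classify_codon_changes(codon[!same], cp[!same],
                                         alt_cds[ok][!same])
  }
  cls[same] <- "uninformative"
  out[ok] <- cls
  out
}

#' Functional classification of a coding SNP
#'
#' Builds the reference codon containing the site (strand-aware,
#' reverse-complementing minus-strand genes), substitutes the alternate
#' base, and compares amino acids under the standard genetic code with stop
#' treated as a 21st state. Other polymorphic positions in the codon are
#' held at their reference state. Sites outside the CDS are
#' `"uninformative"`.
#'
#' @param pos 1-based genomic position(s) on the gene's chromosome.
#' @param alt alternate base(s), in chromosome orientation.
#' @param gene gene table rows for one gene (columns `chrom`, `start`,
#'   `end`, `gene_id`, `strand`, `frame`; 0-based half-open intervals).
#' @param reference a `DNAStringSet` holding the gene's chromosome.
#' @return character vector: `"synonymous"`, `"nonsynonymous"` or
#'   `"uninformative"`.
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ATGGGTAAATAA"))
#' gene <- data.frame(chrom = "chr1", start = 0, end = 12,
#'                    gene_id = "g1", strand = "+", frame = 0)
#' classify_functional(6, "A", gene, ref)   # GGT -> GGA, synonymous
classify_functional <- function(pos, alt, gene, reference) {
  rows <- gene[order(gene$start), , drop = FALSE]
  .classify_gene_sites(pos, alt, rows, reference)
}

## ------------------------------------------------------------ segregation

#' Segregation classification of sites between two populations
#'
#' Computes alt-allele frequencies `p1`, `p2` over non-missing alleles per
#' population. A site is a `fixed_difference` when the frequencies are 0 and
#' 1 (either orientation); `polymorphic_pop1`/`_pop2` when exactly one
#' population segregates; `polymorphic_shared` when both do; otherwise
#' `uninformative`. Frequencies whose within-population minor-allele
#' frequency is below `maf_cut` are treated as fixed for the major allele
#' before the rules apply. Sites where a population has no called allele are
#' `uninformative` (with one warning summarising the count).
#'
#' @param v a `variant_table`.
#' @param panel a `population_panel` with exactly two labels.
#' @param maf_cut within-population minor-allele-frequency cutoff
#'   (default 0: no demotion).
#' @return character vector, one class per site.
#' @export
classify_segregation <- function(v, panel, maf_cut = 0) {
  check_panel(v, panel)
  pops <- unique(panel$population)
  if (length(pops) != 2) stop("panel must define exactly two populations")
  g1 <- v$genotypes[, intersect(v$sample_ids, panel_samples(panel, pops[1])),
                    drop = FALSE]
  g2 <- v$genotypes[, intersect(v$sample_ids, panel_samples(panel, pops[2])),
                    drop = FALSE]
  f1 <- .site_freq(g1, v$ploidy)
  f2 <- .site_freq(g2, v$ploidy)
  p1 <- f1$p; p2 <- f2$p
  n_empty <- sum(f1$n == 0 | f2$n == 0)
  if (n_empty > 0)
    warning(sprintf("%d site(s) with a population entirely missing: uninformative",
                    n_empty))
  demote <- function(p) {
    low <- !is.na(p) & pmin(p, 1 - p) < maf_cut
    ifelse(low, round(p), p)
  }
  if (maf_cut > 0) { p1 <- demote(p1); p2 <- demote(p2) }
  int1 <- !is.na(p1) & p1 > 0 & p1 < 1
  int2 <- !is.na(p2) & p2 > 0 & p2 < 1
  fix1 <- !is.na(p1) & (p1 == 0 | p1 == 1)
  fix2 <- !is.na(p2) & (p2 == 0 | p2 == 1)
  out <- rep("uninformative", length(p1))
  out[fix1 & fix2 & (p1 != p2)] <- "fixed_difference"
  out[int1 & fix2] <- "polymorphic_pop1"
  out[int2 & fix1] <- "polymorphic_pop2"
  out[int1 & int2] <- "polymorphic_shared"
  out[is.na(p1) | is.na(p2)] <- "uninformative"
  out
}

## ------------------------------------------------------------ 2x2 machinery

#' Vectorised two-sided Fisher exact p-value for 2x2 tables
#'
#' For each table `[[a, b], [c, d]]`, sums the hypergeometric probabilities
#' of all tables with the same margins whose probability does not exceed the
#' observed one (standard two-sided rule, with a `1 + 1e-7` relative
#' tolerance for ties, matching `stats::fisher.test`).
#'
#' @param a,b,c,d non-negative integer vectors (recycled to common length).
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  R1 <- a + b; R2 <- c + d; C1 <- a + c
  lo <- pmax(0, C1 - R2); hi <- pmin(C1, R1)
  lens <- hi - lo + 1
  g <- rep.int(seq_len(n), lens)
  av <- sequence(lens, from = lo)
  probs <- dhyper(av, R1[g], R2[g], C1[g])
  pobs <- dhyper(a, R1, R2, C1)
  keep <- probs <= pobs[g] * (1 + 1e-7)
  p <- as.numeric(rowsum(probs * keep, g))
  pmin(p, 1)
}

#' Per-gene MK counts from classified sites
#'
#' @param functional character vector from [classify_functional()].
#' @param segregation character vector from [classify_segregation()]
#'   (same sites).
#' @param count_shared_twice count shared polymorphisms once per population
#'   instead of once overall (default FALSE).
#' @return named integer vector `c(F_N, F_S, P_N, P_S)`.
#' @export
mk_table <- function(functional, segregation, count_shared_twice = FALSE) {
  stopifnot(length(functional) == length(segregation))
  syn <- functional == "synonymous"
  non <- functional == "nonsynonymous"
  fixed <- segregation == "fixed_difference"
  poly_w <- ifelse(segregation %in% c("polymorphic_pop1", "polymorphic_pop2"),
                   1L,
                   ifelse(segregation == "polymorphic_shared",
                          if (count_shared_twice) 2L else 1L, 0L))
  c(F_N = sum(fixed & non), F_S = sum(fixed & syn),
    P_N = sum(poly_w * non), P_S = sum(poly_w * syn))
}

#' MK test on per-gene count records
#'
#' Fills the neutrality index `NI = (F_N/F_S)/(P_N/P_S)` (defined when
#' `F_S > 0` and `P_N > 0`), the two-sided Fisher exact p-value of
#' `[[F_N, F_S], [P_N, P_S]]`, the per-gene alpha
#' `1 - (F_S * P_N)/(F_N * P_S)` where defined, and the selection call
#' `NI > 1 & p < 0.05` (an undefined NI is never called).
#'
#' @param records data.frame with integer columns `F_N`, `F_S`, `P_N`, `P_S`
#'   (and optionally `gene_id`).
#' @return the data.frame with columns `ni_ratio`, `p_value`, `alpha_gene`,
#'   `selected` added.
#' @export
mk_test <- function(records) {
  records <- as.data.frame(records)
  fn <- records$F_N; fs <- records$F_S
  pn <- records$P_N; ps <- records$P_S
  ni <- ifelse(fs > 0 & pn > 0, (fn / fs) / (pn / ps), NA_real_)
  p <- fisher_exact_2x2(fn, fs, pn, ps)
  records$ni_ratio <- ni
  records$p_value <- p
  records$alpha_gene <- ifelse(fn > 0 & ps > 0,
                               1 - (fs * pn) / (fn * ps), NA_real_)
  records$selected <- !is.na(ni) & ni > 1 & p < 0.05
  records
}

#' Pooled alpha across genes
#'
#' Sums counts over the supplied gene records and returns
#' `alpha = 1 - (sum F_S * sum P_N) / (sum F_N * sum P_S)`, the pooled-count
#' proportion of adaptive amino-acid fixations. Optionally a gene-level
#' bootstrap (resampling genes with replacement) gives a percentile CI.
#'
#' @param records data.frame of MK count records.
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @param conf CI coverage (default 0.95).
#' @return list of class `alpha_estimate`: `alpha` (NA with
#'   `undefined = TRUE` when `sum F_N` or `sum P_S` is zero),
#'   `n_genes_used`, `counts`, and `ci` when bootstrapped.
#' @export
pooled_alpha <- function(records, n_boot = 0, seed = 1, conf = 0.95) {
  records <- as.data.frame(records)
  tot <- colSums(records[, c("F_N", "F_S", "P_N", "P_S"), drop = FALSE])
  calc <- function(ct) {
    if (ct[["F_N"]] == 0 || ct[["P_S"]] == 0) return(NA_real_)
    1 - (ct[["F_S"]] * ct[["P_N"]]) / (ct[["F_N"]] * ct[["P_S"]])
  }
  alpha <- calc(tot)
  out <- list(alpha = alpha, undefined = is.na(alpha),
              n_genes_used = nrow(records), counts = tot, ci = NULL)
  if (n_boot > 0 && nrow(records) > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(records), replace = TRUE)
      calc(colSums(records[idx, c("F_N", "F_S", "P_N", "P_S"),
                           drop = FALSE]))
    }, numeric(1))
    q <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    out$ci <- unname(quantile(reps, q, na.rm = TRUE))
  }
  class(out) <- "alpha_estimate"
  out
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("pooled alpha = %s over %d genes (F_N=%d F_S=%d P_N=%d P_S=%d)\n",
              if (x$undefined) "undefined" else sprintf("%.4f", x$alpha),
              x$n_genes_used, x$counts[["F_N"]], x$counts[["F_S"]],
              x$counts[["P_N"]], x$counts[["P_S"]]))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap CI: [%.4f, %.4f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Run the full per-gene MK scan
#'
#' Classifies every SNP inside each gene's CDS, builds per-gene MK tables,
#' tests them, pools alpha, and returns the selected gene list. Genes with
#' `P_N + P_S < min_poly` are excluded as lacking sufficient polymorphisms.
#' A Benjamini-Hochberg column (`q_value`) is reported for transparency but
#' the selection call uses the raw `p < 0.05` rule.
#'
#' @param v a filtered `variant_table`.
#' @param genes BED-like gene table (chrom, start, end, gene_id, strand,
#'   frame).
#' @param panel a `population_panel` with two labels.
#' @param reference `DNAStringSet` of the reference sequences.
#' @param min_poly minimum `P_N + P_S` for a gene to enter the scan
#'   (default 1).
#' @param maf_cut within-population MAF cutoff for polymorphisms
#'   (default 0).
#' @param count_shared_twice see [mk_table()].
#' @return list of class `mk_scan` with `records` (gene_id-sorted
#'   data.frame), `alpha` (an `alpha_estimate`), `selected_genes`,
#'   `n_genes_total`, `n_genes_used`, and the settings used.
#' @export
run_mk_scan <- function(v, genes, panel, reference, min_poly = 1,
                        maf_cut = 0, count_shared_twice = FALSE) {
  seg <- classify_segregation(v, panel, maf_cut = maf_cut)
  gene_ids <- sort(unique(genes$gene_id))
  s <- v$sites
  recs <- vector("list", length(gene_ids))
  for (k in seq_along(gene_ids)) {
    rows <- .gene_rows(genes, gene_ids[k])
    on_chrom <- which(s$chrom == rows$chrom[1])
    if (length(on_chrom)) {
      inside <- rep(FALSE, length(on_chrom))
      for (i in seq_len(nrow(rows)))
        inside <- inside | (s$pos[on_chrom] > rows$start[i] &
                              s$pos[on_chrom] <= rows$end[i])
      on_chrom <- on_chrom[inside]
    }
    if (length(on_chrom)) {
      fun <- .classify_gene_sites(s$pos[on_chrom], s$alt[on_chrom], rows,
                                  reference)
      ct <- mk_table(fun, seg[on_chrom], count_shared_twice)
    } else {
      ct <- c(F_N = 0L, F_S = 0L, P_N = 0L, P_S = 0L)
    }
    recs[[k]] <- data.frame(gene_id = gene_ids[k], F_N = ct[["F_N"]],
                            F_S = ct[["F_S"]], P_N = ct[["P_N"]],
                            P_S = ct[["P_S"]], stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(gene_id = character(0), F_N = integer(0),
                          F_S = integer(0), P_N = integer(0),
                          P_S = integer(0))
  n_total <- nrow(records)
  records <- records[records$P_N + records$P_S >= min_poly, , drop = FALSE]
  records <- mk_test(records)
  records$q_value <- p.adjust(records$p_value, method = "BH")
  records <- records[order(records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  alpha <- pooled_alpha(records)
  structure(list(
    records = records,
    alpha = alpha,
    selected_genes = records$gene_id[records$selected],
    n_genes_total = n_total,
    n_genes_used = nrow(records),
    min_poly = min_poly, maf_cut = maf_cut,
    count_shared_twice = count_shared_twice
  ), class = "mk_scan")
}

#' @export
print.mk_scan <- function(x, ...) {
  cat(sprintf(
    "MK scan: %d candidate genes under positive selection from %d genes with sufficient polymorphisms (of %d total)\n",
    length(x$selected_genes), x$n_genes_used, x$n_genes_total))
  print(x$alpha)
  invisible(x)
}
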