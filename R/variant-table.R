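## VariantTable: the in-memory substrate of all host-genetics stages.
## Sites are rows (with VCF-style annotations), samples are columns of an
## alt-allele dosage matrix plus a parallel read-depth matrix.

INFO_FIELDS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Construct a variant table
#'
#' Container for a set of biallelic SNPs: per-site annotations (position,
#' alleles, quality, GATK-style INFO fields), an alt-allele dosage matrix and
#' a read-depth matrix.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, `is_indel`, `n_alleles` and optionally the INFO fields
#'   `QD`, `MQ`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum` (missing values
#'   allowed).
#' @param genotypes integer matrix, sites x samples, alt-allele dosage in
#'   `0:ploidy` with `NA` for missing.
#' @param depths integer matrix, sites x samples, read depth per genotype.
#' @param sample_ids character vector naming the genotype columns.
#' @param ploidy 2 (default, dosages 0/1/2) or 1 (haploid coding, dosages
#'   0/1), e.g. for symbiont bins.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, genotypes, depths = NULL, sample_ids = NULL,
                          ploidy = 2) {
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "ref", "alt", "qual", "is_indel", "n_alleles")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites lacks columns: ", paste(miss, collapse = ", "))
  for (f in INFO_FIELDS) if (is.null(sites[[f]]))
    sites[[f]] <- rep(NA_real_, nrow(sites))
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(sites))
    stop("genotypes rows must match sites rows")
  if (is.null(sample_ids)) sample_ids <- colnames(genotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(ncol(genotypes)))
  if (length(sample_ids) != ncol(genotypes))
    stop("sample_ids length must match genotype columns")
  if (is.null(depths)) {
    depths <- matrix(NA_integer_, nrow(genotypes), ncol(genotypes))
  }
  depths <- as.matrix(depths)
  if (!all(dim(depths) == dim(genotypes))) stop("depths dim mismatch")
  bad <- !is.na(genotypes) & (genotypes < 0 | genotypes > ploidy)
  if (any(bad)) stop("dosages must lie in 0..ploidy or be NA")
  if (any(genotypes != round(genotypes), na.rm = TRUE))
    stop("dosages must be integers")
  storage.mode(genotypes) <- "integer"
  storage.mode(depths) <- "integer"
  ## enforce sorted, strictly increasing positions within chrom
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  genotypes <- genotypes[o, , drop = FALSE]
  depths <- depths[o, , drop = FALSE]
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) stop("duplicated chrom/pos in sites")
  rownames(sites) <- NULL
  colnames(genotypes) <- sample_ids
  colnames(depths) <- sample_ids
  structure(
    list(sites = sites, genotypes = genotypes, depths = depths,
         sample_ids = sample_ids, ploidy = ploidy),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (ploidy %d)\n",
              nrow(x$sites), length(x$sample_ids), x$ploidy))
  cat(sprintf("  chroms: %d; missing genotypes: %.2f%%\n",
              length(unique(x$sites$chrom)),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Number of sites in a variant table
#' @param v a `variant_table`.
#' @return integer site count.
#' @export
n_sites <- function(v) nrow(v$sites)

## row-subset a variant table (logical or integer index over sites)
vt_subset <- function(v, idx) {
  variant_table(v$sites[idx, , drop = FALSE],
                v$genotypes[idx, , drop = FALSE],
                v$depths[idx, , drop = FALSE],
                v$sample_ids, v$ploidy)
}

#' Construct a population panel
#'
#' Maps each sample to a population label. The MK and divergence stages
#' require exactly two distinct labels.
#'
#' @param sample character vector of sample ids.
#' @param population character vector of population labels (same length).
#' @return data.frame of class `population_panel`.
#' @export
population_panel <- function(sample, population) {
  if (length(sample) != length(population)) stop("length mismatch")
  if (anyDuplicated(sample)) stop("duplicated sample ids")
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   stringsAsFactors = FALSE)
  class(df) <- c("population_panel", "data.frame")
  df
}

panel_samples <- function(panel, pop) panel$sample[panel$population == pop]

check_panel <- function(v, panel) {
  miss <- setdiff(v$sample_ids, panel$sample)
  if (length(miss))
    stop("samples missing from panel: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

## ---------------------------------------------------------------- VCF I/O

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = digits))
}

#' Write a variant table to a VCF 4.2 file
#'
#' Emits sorted sites with 1-based positions, the simulated/observed INFO
#' fields, and `GT:DP` genotype columns. Diploid tables use unphased `0/0`,
#' `0/1`, `1/1` calls; haploid tables (`ploidy = 1`) emit `0`/`1`.
#'
#' @param v a `variant_table`.
#' @param path output file path.
#' @param contig_lengths optional named integer vector of contig lengths for
#'   the header; defaults to the last observed position per contig.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, contig_lengths = NULL) {
  s <- v$sites
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(s$pos, s$chrom, max)
  }
  contigs <- unique(s$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=altipop",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            as.integer(contig_lengths[contigs])),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_FIELDS, INFO_FIELDS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", v$sample_ids), collapse = "\t")
  )
  info <- vapply(seq_len(nrow(s)), function(i) {
    vals <- unlist(s[i, INFO_FIELDS])
    ok <- !is.na(vals)
    if (!any(ok)) return(".")
    paste(sprintf("%s=%s", INFO_FIELDS[ok], fmt_num(vals[ok])), collapse = ";")
  }, character(1))
  if (v$ploidy == 2) {
    gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  } else {
    gt_map <- c(`0` = "0", `1` = "1")
  }
  g <- v$genotypes
  gt <- matrix(gt_map[as.character(g)], nrow(g), ncol(g))
  gt[is.na(g)] <- if (v$ploidy == 2) "./." else "."
  dp <- matrix(as.character(v$depths), nrow(g), ncol(g))
  dp[is.na(v$depths)] <- "."
  cells <- matrix(paste(gt, dp, sep = ":"), nrow(g), ncol(g))
  body_geno <- apply(cells, 1, paste, collapse = "\t")
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, fmt_num(s$qual), ".",
                info, "GT:DP", body_geno, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Parses a VCF via \pkg{vcfR} and extracts the site annotations, alt-allele
#' dosages and per-genotype depths used by the pipeline. Multiallelic records
#' keep their first ALT allele and record `n_alleles` so the genotype/site
#' filter can drop them.
#'
#' @param path VCF file path.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alt_split)
  alt1 <- vapply(alt_split, function(a) if (length(a)) a[[1]] else ".", "")
  is_indel <- nchar(fix$REF) != 1L | nchar(alt1) != 1L | alt1 == "*"
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = alt1,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    is_indel = is_indel, n_alleles = n_alleles,
    stringsAsFactors = FALSE
  )
  for (f in INFO_FIELDS) {
    sites[[f]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = f))
    )
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ploidy <- if (any(grepl("[/|]", gt[!is.na(gt)]))) 2L else 1L
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  dose[known] <- vapply(strsplit(gt[known], "[/|]"),
                        function(a) sum(a == "1"), integer(1))
  dp <- suppressWarnings(
    matrix(as.integer(vcfR::extract.gt(vcf, element = "DP")),
           nrow(gt), ncol(gt), dimnames = dimnames(gt))
  )
  variant_table(sites, dose, dp, colnames(gt), ploidy = ploidy)
}

#' Write a gene table as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), gene_id, strand, frame.
#'
#' @param genes data.frame with those columns (one row per CDS interval).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "gene_id", "strand", "frame")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene table
#' @param path TSV with columns chrom, start, end, gene_id, strand, frame.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a sample-to-population panel TSV
#' @param panel a `population_panel`.
#' @param path file path.
#' @return `path` (write) or a `population_panel` (read).
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  population_panel(df$sample, df$population)
}
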