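## Two-stage SNP quality control.
##
## Stage 1 is the GATK-style hard filter: a site is removed when ANY of the
## quoted clauses fires (all comparisons strict); a missing INFO field never
## fires its clause. Stage 2 mirrors the VCFtools flags: indels and
## multiallelic records are dropped, genotypes below a depth floor are
## masked missing (genotype-level semantics of --minDP), low-quality sites
## are dropped, and sites left with no called genotype are dropped.

#' GATK-style site hard filter
#'
#' Removes any site satisfying at least one of: QD < 2.0, MQ < 40.0,
#' FS > 60.0, SOR > 3.0, MQRankSum < -12.5, ReadPosRankSum < -8.0. All
#' comparisons are strict; a site whose INFO field is missing is retained
#' with respect to that clause. The input is not modified.
#'
#' @param v a `variant_table`.
#' @return a filtered `variant_table`; attribute `filter_summary` holds the
#'   number of sites failing each clause.
#' @export
site_hard_filter <- function(v) {
  s <- v$sites
  clause <- cbind(
    QD = !is.na(s$QD) & s$QD < 2.0,
    MQ = !is.na(s$MQ) & s$MQ < 40.0,
    FS = !is.na(s$FS) & s$FS > 60.0,
    SOR = !is.na(s$SOR) & s$SOR > 3.0,
    MQRankSum = !is.na(s$MQRankSum) & s$MQRankSum < -12.5,
    ReadPosRankSum = !is.na(s$ReadPosRankSum) & s$ReadPosRankSum < -8.0
  )
  fail <- rowSums(clause) > 0
  out <- vt_subset(v, !fail)
  attr(out, "filter_summary") <- colSums(clause)
  out
}

#' VCFtools-style genotype and site filter
#'
#' Removes indel and multiallelic records, masks genotypes with read depth
#' below `min_dp` to missing, removes sites with quality below `min_q`, and
#' removes sites left with all genotypes missing. Sites that become
#' monomorphic after masking are retained unless `drop_monomorphic = TRUE`.
#'
#' @param v a `variant_table`.
#' @param min_dp minimum genotype depth (default 4, strict: depth < 4 masks).
#' @param min_q minimum site quality (default 70, strict: qual < 70 drops).
#' @param drop_monomorphic also drop sites with no segregating allele among
#'   the remaining called genotypes (default FALSE).
#' @return a filtered `variant_table`.
#' @export
genotype_site_filter <- function(v, min_dp = 4, min_q = 70,
                                 drop_monomorphic = FALSE) {
  s <- v$sites
  keep <- !s$is_indel & s$n_alleles <= 2 &
    (!is.na(s$qual) & s$qual >= min_q)
  v2 <- vt_subset(v, keep)
  mask <- !is.na(v2$depths) & v2$depths < min_dp
  g <- v2$genotypes
  g[mask] <- NA_integer_
  v2$genotypes <- g
  called <- rowSums(!is.na(g)) > 0
  if (drop_monomorphic) {
    alt <- rowSums(g, na.rm = TRUE)
    tot <- rowSums(!is.na(g)) * v2$ploidy
    called <- called & alt > 0 & alt < tot
  }
  vt_subset(v2, called)
}
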