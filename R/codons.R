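## Codon-level machinery shared by the simulator and the MK scan.
##
## Everything is driven by one enumeration: for each of the 64 codons, the 9
## possible single-base changes, each labelled synonymous / nonsynonymous by
## comparing translations under the standard genetic code (stop is treated as
## a 21st amino-acid state, so changes into or out of stop are nonsynonymous
## unless both codons are stops).

DNA_BASES <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

codon_data <- function() {
  if (!is.null(.codon_env$changes)) return(as.list(.codon_env))
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- as.character(gc_tab)
  names(aa) <- codons

  rows <- vector("list", 64 * 9)
  n <- 0L
  for (cd in codons) {
    b <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(DNA_BASES, b[pos])) {
        nb <- b
        nb[pos] <- alt
        new_cd <- paste(nb, collapse = "")
        n <- n + 1L
        rows[[n]] <- data.frame(
          codon = cd, pos = pos, ref = b[pos], alt = alt, new_codon = new_cd,
          aa_ref = aa[[cd]], aa_alt = aa[[new_cd]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  changes <- do.call(rbind, rows)
  changes$synonymous <- changes$aa_ref == changes$aa_alt
  changes$to_stop <- changes$aa_alt == "*" & changes$aa_ref != "*"

  ## lookup: "codon|pos|alt" -> TRUE (synonymous) / FALSE (nonsynonymous)
  syn_lookup <- changes$synonymous
  names(syn_lookup) <- paste(changes$codon, changes$pos, changes$alt, sep = "|")

  ## per-codon mutational opportunity, excluding stop codons themselves and
  ## changes that create a stop (the simulator redraws those); site units
  ## (each position contributes 3 possible changes, so divide counts by 3)
  usable <- !changes$to_stop & changes$aa_ref != "*"
  n_syn <- tapply(changes$synonymous & usable, changes$codon, sum)
  n_non <- tapply(!changes$synonymous & usable, changes$codon, sum)
  opp <- data.frame(
    codon = names(n_syn),
    syn_sites = as.numeric(n_syn) / 3,
    nonsyn_sites = as.numeric(n_non) / 3,
    stringsAsFactors = FALSE
  )
  rownames(opp) <- opp$codon

  .codon_env$changes <- changes
  .codon_env$syn_lookup <- syn_lookup
  .codon_env$opportunity <- opp
  .codon_env$aa <- aa
  .codon_env$sense_codons <- codons[aa != "*"]
  as.list(.codon_env)
}

#' Synonymous and nonsynonymous mutational opportunity of a codon sequence
#'
#' Counts, in site units, how many of the single-base changes available to a
#' coding sequence are synonymous versus nonsynonymous under the standard
#' genetic code. Each codon offers 9 single-base changes weighted 1/3 per
#' position; changes that create a stop codon are excluded from both classes
#' (the simulator never plants them).
#'
#' @param codons character vector of codons (3-letter DNA strings).
#' @return named numeric vector with elements `syn_sites` and `nonsyn_sites`.
#' @export
#' @examples
#' codon_opportunity(c("GGT", "AAA"))
codon_opportunity <- function(codons) {
  cd <- codon_data()
  opp <- cd$opportunity[codons, , drop = FALSE]
  if (anyNA(opp$syn_sites)) stop("unknown codon in input")
  c(syn_sites = sum(opp$syn_sites), nonsyn_sites = sum(opp$nonsyn_sites))
}

## classify a vector of (codon, position-in-codon 1..3, alt base) changes;
## returns "synonymous"/"nonsynonymous" (identity changes are an error)
classify_codon_changes <- function(codon, pos, alt) {
  cd <- codon_data()
  key <- paste(codon, pos, alt, sep = "|")
  syn <- unname(cd$syn_lookup[key])
  if (anyNA(syn)) stop("invalid codon change (alt equals ref, or bad codon?)")
  ifelse(syn, "synonymous", "nonsynonymous")
}

translate_codon <- function(codon) {
  cd <- codon_data()
  aa <- cd$aa[codon]
  if (anyNA(aa)) stop("unknown codon")
  unname(aa)
}
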