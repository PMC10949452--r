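#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dhyper fisher.test rbinom rgamma rmultinom rnorm
#'   rpois runif cmdscale p.adjust pnorm setNames sd var quantile
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## harmonic number H(n) = sum_{i=1}^{n} 1/i (Watterson's a_{n-1} is H(n-1))
harmonic_number <- function(n) {
  if (n <= 0) return(0)
  sum(1 / seq_len(n))
}

## Dirichlet draw via gamma normalisation; rows are draws
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

## reverse complement for plain character vectors of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

## derive a child RNG seed below 2^31 from a base seed and a stream index
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435761 + stream * 97561) %% 2147483647L)
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
}
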