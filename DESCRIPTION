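Package: altipop
Title: Comparative Population Genomics and Gut-Community Analysis for
    Paired Host Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for comparing two closely related
    populations (or species) from biallelic SNP data and their associated
    gut microbial communities. Implements two-stage variant quality
    filtering, windowed nucleotide diversity, linkage-disequilibrium decay
    and LD-based effective population size (Waples random-mating
    estimator), genotype PCA, an admixture model fit by EM with
    cross-validated choice of K, per-gene McDonald-Kreitman tests with
    Fisher's exact p-values and a pooled alpha (proportion of adaptive
    amino-acid fixations), and community comparison via canonical k-mer
    frequency distances, principal coordinates analysis, PERMANOVA and
    rank-sum abundance tests. Ships a synthetic-data generator with
    planted ground truth (selected genes, true effective sizes,
    population labels, community compositions) so every stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
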