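---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`altipop` implements the analysis chain used to compare two closely related
host populations — variant QC, diversity and effective-size summaries,
structure inference, a per-gene McDonald–Kreitman selection scan — together
with a k-mer-based comparison of the gut communities those hosts carry.
This vignette records the models, the defaults and the design decisions, in
the order a user meets them.

## The synthetic-data generator

Every downstream stage is validated against data with planted truth, so
the generator's assumptions matter as much as the estimators'.

**Host genetics.** Each gene is an independent contig holding one CDS drawn
uniformly over the 61 sense codons (about 30% of genes are placed on the
minus strand, so strand handling is exercised everywhere). Mutational
opportunity is computed by enumerating all nine single-base changes of each
codon under the standard genetic code; changes that would create a stop
codon are redrawn, and the mean opportunity of a sense codon works out to
0.70 synonymous and 2.17 nonsynonymous sites. Fixed differences per gene
are Poisson: synonymous with rate `divergence × L_S`, nonsynonymous with
rate `divergence × L_N × m`, where `m` is the nonsynonymous-fixation
multiplier of a planted selected gene (default 10) and 1 otherwise. Each
fixed difference is assigned to one population at frequency 1 and the other
at 0. Polymorphic sites are private to one population (a `shared_poly_rate`
option plants shared polymorphisms to exercise that branch of the
classifier) with derived-allele frequencies drawn from the neutral site
frequency spectrum, `P(i) ∝ 1/i`. Because the polymorphism count uses the
full per-site rate θ while redraws land on non-stop changes, the expected
per-site heterozygosity equals θ exactly under the direct (infinite-Ne)
mode — which is what the π calibration tests rely on.

The generator is rate-based rather than a coalescent for one reason: the
expected MK table of every gene is then known in closed form, which makes
recall, false-positive and α checks exact rather than approximate. The
cost is that genealogical correlations between sites are absent in the
default mode. When linkage disequilibrium itself is the quantity under
study (the LD-based Ne estimator), a finite `true_ne_pop*` switches the
polymorphic loci to a short discrete Wright–Fisher epoch: a population of
Ne diploids, random mating without selfing, whole-gene linkage blocks with
free recombination between genes, run for `wf_generations = 25`
generations (unlinked-pair LD equilibrates within roughly ten). Sampled
individuals then carry drift LD of the expected magnitude `1/(3Ne)` between
unlinked loci.

A config is rejected when the expected number of mutations per codon
(computed from the mean codon opportunity, the divergence, the multiplier
and both populations' θ) exceeds 1, since multi-hit codons would then
dominate and the infinite-sites bookkeeping underlying the planted truth
would break down.

Defaults (500 genes × 400 codons, 20 + 20 samples, θ = 0.015,
divergence = 0.025) put roughly 9 × 10⁴ SNPs in a default run — the
deliberate scale-down of a ~10⁵-SNP two-species comparison — and give
per-gene MK tables with expected margins around 29 fixed and 153
polymorphic changes. Depths are Poisson (mean 20); a genotype with zero
depth is missing. INFO fields are drawn from distributions that pass the
hard filter; `frac_fail_info` plants single-clause violations to exercise
QC.

**Communities.** One random reference sequence per taxon (default eight
taxa, two of them pathogens, in the style of a bee gut community);
per-sample compositions are Dirichlet with host-specific concentration
vectors; reads are uniform substrings on a random strand. A planted
fraction of samples is made pathogen-dominated by forcing 60–95% of mass
onto the pathogen taxa; the planted count is `round(frac × n)` so recovery
tests are exact. What the generator does *not* emulate: sequencing error,
real genome composition, shared sequence between taxa, and read-length
heterogeneity — so passing tests demonstrate correctness of the pipeline's
bookkeeping and statistics, not robustness to those real-data features.

## Variant QC

The hard filter removes a site when *any* clause fires, all strict:
`QD < 2.0`, `MQ < 40.0`, `FS > 60.0`, `SOR > 3.0`, `MQRankSum < -12.5`,
`ReadPosRankSum < -8.0`. A missing annotation never fires its clause —
the standard behaviour of the tool this filter mirrors, and the only choice
that does not discard sites merely for lacking an annotation. The second
stage mirrors the cited flags' documented semantics: `minDP` masks
*genotypes* (it does not drop sites), `minQ`/indel/multiallelic checks drop
sites, and sites left with no called genotype are dropped. Sites that
become monomorphic after masking are retained — re-pruning is not part of
the quoted procedure — with a `drop_monomorphic` option for stages that
need segregating sites. The two stages are applied sequentially,
hard filter first.

## π, LD and Ne

Per site, `π = (n/(n-1)) · 2p(1-p)` over non-missing alleles; windows (no
stated window size exists for the original analysis; the default in
examples is 10 kb-scale, set explicitly by the caller) tile each contig
from position 1 and divide by window length, truncated at the contig end.

LD is composite: phase is unknown in unphased VCFs, so r² is the squared
Pearson correlation of dosage vectors over samples non-missing at both
sites — what the standard decay tools compute. Zero-variance sites and
pairs with fewer than two complete observations are skipped.

The Ne estimator follows the LD method with the random-mating solution:
pairs are restricted to unlinked proxies (different contigs by default, or
a distance threshold), both MAFs must reach `maf = 0.05` (the customary
Pcrit; the original analysis does not state one), and S is the harmonic
mean pairwise sample size. One numerical point deserves emphasis: the
sampling expectation `1/S + 3.19/S²` was derived for the Burrows composite
estimator with its `S/(S-1)` weighting, whose no-drift expectation differs
from plain Pearson r² (≈ `1/(S-1)`) by just enough to swallow half a
`1/(3Ne)` drift signal at S = 50. `ne_from_ld` therefore scales each
pair's squared correlation by `(S/(S-1))²` before subtracting the
expectation; without this the estimator is roughly two-fold biased upward.
`r²_drift ≤ 0` is reported as an infinite estimate (no drift signal), and a
negative discriminant in the quadratic is clamped to zero.

## Structure

PCA mean-imputes missing dosages, centres per site, scales by
`sqrt(2p(1-p))` and eigendecomposes the sample covariance; percent
explained is relative to the covariance trace.

The admixture model maximises the binomial likelihood in Q (ancestry
fractions) and F (ancestral allele frequencies) by EM — chosen over
quasi-Newton acceleration because it is simple, provably ascending, and
adequate at these problem sizes. Convergence is `tol = 1e-6` on the
log-likelihood with `max_iter = 2000` (500 inside cross-validation, where
dozens of refits run); F is clamped to `[1e-6, 1-1e-6]`; missing genotypes
are excluded from the likelihood rather than imputed (PCA imputes instead —
both documented here because they differ). K = 1 is handled in closed
form. Cross-validation masks entry-wise folds of the observed genotype
cells (seeded), refits, predicts masked dosages as `2·Σ q f`, and scores
mean binomial deviance — the same masking scheme the reference
implementation of this model family describes.

The tree stage is neighbor joining on allele-sharing distance
(1 − proportion of matching dosages), provided as structural plumbing for
visual checks; it makes no claim to replace maximum-likelihood
phylogenetics, which is out of scope. Labels are sorted before
construction so tie-breaking is deterministic under input permutation.

## The MK scan

Functional classification builds the reference codon containing the site
(strand-aware), substitutes the alternate base and compares amino acids,
with stop treated as a 21st state. When a codon carries more than one
variant, each SNP is classified against the reference state at the codon's
other positions: without haplotypes, path enumeration through multi-variant
codons is under-determined, so the reference-background convention is used
and applies uniformly.

Segregation classes come from the two populations' alt-allele frequencies
over non-missing alleles: fixed difference ({0,1}), private polymorphism,
shared polymorphism, or uninformative. A population with no called allele
makes the site uninformative with a warning. Frequencies below the
`maf_cut` minor-allele threshold (default 0 — the original procedure is
silent, and the choice materially affects α, so it is exposed and
recorded) are rounded to the major allele before the rules apply.

Per gene, `[[F_N, F_S], [P_N, P_S]]` is tested with a two-sided Fisher
exact p-value — implemented as vectorised hypergeometric enumeration with
the conventional `1 + 1e-7` tie tolerance, verified against an independent
factorial-arithmetic oracle and against `stats::fisher.test` — and a gene
is called selected when `NI > 1` and `p < 0.05`. Shared polymorphisms
count once toward P (the species-symmetric reading; `count_shared_twice`
switches to per-population counting). "Sufficient polymorphisms" is
`P_N + P_S ≥ min_poly` with `min_poly = 1` by default, reported in the
scan metadata. No multiple-testing correction enters the call — the raw-p
rule is the procedure being reproduced, and the pooled α is its stated
false-positive correction — but a Benjamini–Hochberg column is emitted for
transparency. α uses pooled counts across qualifying genes,
`1 − (ΣF_S·ΣP_N)/(ΣF_N·ΣP_S)` (the weighted-means variant of the estimator
exists; pooled counts is implemented as the straightforward reading), with
an optional seeded gene-level bootstrap CI, and an undefined flag when
`ΣF_N` or `ΣP_S` is zero. The same scan runs unchanged on haploid-coded
tables (`ploidy = 1`), the mode intended for symbiont bins. Because worker
bees are haplodiploid and the original calling convention is not stated,
both diploid and haploid emission modes exist rather than guessing.

A note on calibration: Fisher's exact test is conservative on discrete
tables. At the generator's default table sizes the neutral rejection rate
at p < 0.05 sits slightly below 0.05 (the acceptance suite measures it);
the deviation is in the safe direction for a selection scan and shrinks as
counts grow.

## Community comparison

Profiles count every A/C/G/T-only window of length k (default 21, odd so
no k-mer is its own reverse complement) and canonicalise to the
lexicographic minimum of the k-mer and its reverse complement — comparison
is done on a digit-mapped key so results are locale-independent. Exact
counting; no sketching, which desk-scale profiles do not need.

The distance is cosine on frequency vectors over the union of keys
(bounded in [0,1] on non-negative data), with euclidean and Bray–Curtis
selectable; the original tool's metric is not recoverable from its name,
so the default is a documented stand-in recorded with the output, not a
claim about that tool. PCoA is classical scaling (Gower centring of
−d²/2); negative eigenvalues are reported but never build axes, and
percent explained is relative to the positive-eigenvalue total. PERMANOVA
partitions squared distances, and the p-value is
`(1 + #{F* ≥ F})/(1 + n_perm)` under seeded free label permutation (no
strata); host and diet factors are meant to be tested as separate
single-factor calls. Unhealthy samples — strictly more than 50% summed
pathogen mass — are flagged before profiles and distances, and the
healthy-only subset is the intended input to every downstream call,
including the diet factor. Rank-sum tests use midranks with an exact
dynamic-programming null for combined n ≤ 20 and a tie- and
continuity-corrected normal approximation beyond (the textbook exact
distribution cannot handle ties, which abundance data always have — hence
the in-package implementation).

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data sized for a desk machine: 500-gene × 400-codon hosts (~9 × 10⁴ SNPs)
for the MK calibration and recovery checks, 50–60 short genes with a
Wright–Fisher epoch for Ne recovery (Ne = 200 truth, ~2 × 10⁴ unlinked
pairs), 30-sample communities at 600 reads × 80 bp for the
PERMANOVA/PCoA stage, and exhaustive enumerations for the Fisher
(all 2×2 tables with margins ≤ 30) and rank-sum (combined n ≤ 12) oracles.
A full run of either suite takes a few minutes on one CPU.

## Known limitations

No recombination maps, sweeps or demography beyond a clean split; no
read-level error model; polymorphisms are private to one population unless
explicitly planted as shared; the community simulator's taxa share no
sequence, so between-taxon k-mer distances are maximal by construction;
the NJ tree is a convenience, not an ML phylogeny; and the admixture EM,
while monotone, can need many iterations near degenerate optima — the
`converged` flag and log-likelihood trace are returned so users can check.
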