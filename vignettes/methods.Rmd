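---
title: "Methods: pipeline model, statistics and mock-community validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pipeline model, statistics and mock-community validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`mtxpipe` analyses paired-end metatranscriptomic RNA-Seq in four stages:
quality filtering, rRNA/tRNA sorting, functional quantification against an
annotated gene catalog, and 16S taxonomic profiling, followed by a
differential-expression (DE) layer and a mock-community simulation harness
that measures the whole chain's ranking accuracy as a ROC/AUC. Every stage
is implemented natively on a small, explicit data model: reads are rows of
a plain data frame (`id`, `seq`, `qual`, and the integer header tags
`copies` and `csize`), and counts move between stages as feature-by-sample
matrices.

The two header tags are the pipeline's bookkeeping currency. `copies`
records how many identical raw reads a collapsed record stands for;
`csize` records the total weight of the cluster a representative sequence
stands for. Both default to 1, and downstream counting always uses
`copies * csize`, so read totals are conserved through the
collapse-cluster-count chain (cluster representatives are re-emitted with
`copies = 1` to avoid double counting).

# Quality filtering

Reads are trimmed in a fixed order: leading/trailing runs of `N`
(cluster-N regions) are removed, then the longest 3' suffix whose bases
all fall below the Phred threshold (default 10) is dropped, and reads
shorter than the length floor (default 30 nt) are rejected. Suffix-only
quality trimming was chosen because 3' degradation is the dominant Illumina
failure mode and it keeps the rule order-free and deterministic; internal
`N`s are kept so that masked but otherwise long reads survive. A pair is
kept only when both mates survive; orphans are counted and discarded.
Collapsing of identical reads is pair-aware in the pipeline (the key is the
concatenation of both mate sequences) so that mate files never desynchronize;
the single-stream `collapse_identical()` is also exposed. The representative
quality is the per-position maximum over members — a deliberate, declared
convention, since collapsing is defined on sequences only.

# rRNA/tRNA sorting

Sorting against user-supplied SSU/LSU/5S/tRNA reference sets uses canonical
k-mer containment (default k = 15): a read is assigned the category with the
largest shared k-mer fraction when that fraction reaches `min_frac`
(default 0.25), otherwise it is potential mRNA. Ties break by the fixed
priority SSU > LSU > 5S > tRNA, and one rRNA mate condemns the whole pair.
The thresholds are not derived from data; they were fixed once at values
that give essentially perfect separation between reads drawn from reference
sequences and random-sequence reads (a 76 nt read shares well over half of
its 15-mers with its source), and the property suite checks recall and
contamination on such synthetic reads.

# Overlap merging

Paired-end merging reverse-complements the second mate and scans every
relative offset. An offset qualifies when the overlap is at least 8 bp with
at most a 10% mismatch fraction (the defaults mirror common practice for
76 bp libraries); the longest qualifying overlap wins, ties go to fewer
mismatches and then to the smaller offset, a rule declared purely for
determinism. In the overlapped region the higher-quality base is emitted
with the maximum of the two qualities; `N` never matches anything. The
implementation is checked against a brute-force all-offset oracle on
thousands of randomized pairs.

# Gene fragments, clustering and mapping

Putative coding fragments are all maximal stop-free whole-codon stretches
of at least 60 nt over all six frames (stops TAA/TAG/TGA). This is a
transparent, exactly testable gene caller whose contract —
predict-or-discard on short reads — is what the downstream stages rely on;
it does not model sequencing-error frameshifts the way an HMM-based caller
would, which is a known limitation.

Clustering is greedy and CD-HIT-like: fragments sorted by length descending
each join the earliest-founded cluster whose representative aligns at
>= 95% identity over >= 90% of the shorter sequence, else found a new
cluster. Alignments are ungapped diagonal alignments; candidate diagonals
come from a word filter (default word = 11) that is provably lossless at
these thresholds: an alignment with at most 5% mismatches over an overlap
of at least 28 nt always contains an exact 11-mer on its diagonal
(pigeonhole), and the module's minimum overlap is 0.9 x 60 = 54 nt. The
suite verifies exact agreement with a filter-free all-pairs oracle.
Cluster weight is the sum of member `copies` (a `--csize-mode members`
flag restores plain cardinality); representatives carry it as `csize`.

Best-hit mapping is seed-and-extend (seed k = 15, both strands): candidates
share at least one seed k-mer and are scored by ungapped identity on the
seeded diagonal; hits qualify at >= 90% identity over >= 80% of the query,
and the winner is the highest identity with ties broken by longer
alignment, then lexicographically smallest gene id — a deterministic
reading of "first match retained". Identity ties are compared on integer
cross products, never on floating point. Counting de-duplicates per query
id, so a read (or an unmerged pair, whose mates share one id) contributes
at most once; gene counts roll up to orthologous groups and one-letter
functional categories with an `unknown` sink so totals are conserved.

# Taxonomic profiling

Merged rRNA reads are reservoir-subsampled (Algorithm R, default capacity
100,000), pre-clustered at 97% identity (the conventional OTU radius,
reusing the greedy clusterer), and assigned lineages by best-hit mapping
against a 16S reference whose headers carry 7-rank Greengenes-style
lineages. Rank tables truncate each lineage at its first unknown rank
(grouping under the deepest known prefix), weight by `copies * csize`,
zero per-cell singletons, and sort rows by mean abundance. Relative
abundance filters (0.2% and 1%) and rarefaction (default depth 1,952,
multivariate hypergeometric via `vegan::rrarefy`, under-depth samples
dropped with a warning) are provided for diversity comparisons.

# Differential expression

Counts are normalized by median-of-ratios size factors. The paired test
forms per-subject ratios `log2((after + 1) / (before + 1))` (pseudocount 1,
since the ratio is undefined at zero; the pseudocount is a declared choice,
not inferred from data) and tests their mean against zero with a two-sided
one-sample t-test (`--test wilcoxon` is exposed for the rank-based
alternative; with typical 4-subject designs the t-test was preferred for
its non-degenerate p-value resolution). q-values are Benjamini-Hochberg,
and the default selection is q < 0.01 with |log2FC| > 1. The two-group
variant used by the mock experiments is a Welch t-test on
`log2(normalized + 1)`, because the mock design has independent groups
while the real-data design is paired.

The Friedman test uses within-subject midranks with the tie-corrected
statistic and a chi-square reference (df = k - 1); an exact mode enumerates
all `(k!)^n` within-subject orderings when that is small. The exact null
for small designs is very discrete: for n = 4 subjects and k = 3 conditions
it has nine support points, and the chi-square tail is within 0.02 of the
exact tail only in the rejection region (exact p <= 0.125) — at small
statistics the two differ by up to ~0.18. The suite therefore pins the
asymptotic-exact agreement where the approximation is actually consumed.
Spearman correlations take permutation p-values (exact enumeration when
`n! <= n_perm`, otherwise the add-one estimator, which never returns 0).
PCA operates on feature-centered `log2(normalized + 1)` with the
largest-magnitude loading of each component forced positive so that score
signs are reproducible.

# The mock-community generator

The generator defines the study conditions and is not tuned per run:

* **Functional mock.** 1,000 synthetic genes (drawn without replacement
  from 5 synthetic organisms), lengths uniform on 300-1500 nt and built
  from random non-stop codons so each gene is stop-free in its own frame,
  as a real CDS is. Exactly 20% of genes get a 4-fold increase and 20% a
  4-fold decrease in group 2. Truth counts are negative binomial with
  dispersion 0.2 (typical RNA-seq overdispersion) and mean proportional to
  gene length, at a baseline of 20 read pairs per average-length gene per
  sample — a desk-scale depth chosen once as realistic for a
  1,000-gene community. Fragments are truncated-normal 250 +- 25 bp with
  uniform placement; 76 bp mates are read from the fragment ends; per-base
  qualities come from a trainable per-position Phred histogram (flat
  Phred 30 by default) and bases are substituted at their Phred error
  probability. Two groups of 10 samples are simulated.
* **Taxonomic mock.** 200 organisms as leaves of a synthetic taxonomy
  (phyla roots mutated through class/order/family/genus/species at rates
  0.10/0.07/0.05/0.04/0.03), each with a unique 7-rank lineage, same DE
  design, baseline 30 pairs per organism per sample, fragments 130 +- 15 bp
  so that most pairs overlap by >= 8 bp — the taxonomy branch, like its
  real-data counterpart, quantifies only merged reads.

What the generator does **not** emulate: indels and platform-specific error
profiles, GC and positional coverage bias, chimeric fragments, strand
bias, and communities with near-identical 16S sequences. Passing the mock
ROC checks therefore demonstrates that the pipeline's plumbing — counting,
weighting, normalization, testing, scoring — preserves a differential
signal end to end; it does not certify accuracy on real libraries, where
divergence between sample and reference dominates.

Scores for ROC construction are `1 - p` with the nominal (not adjusted)
p-value, two-sided by construction; AUC is the trapezoid area over all
score thresholds, which equals midrank pairwise concordance under ties
(verified against a brute-force oracle). Organisms never observed in the
species tables score 0 rather than being excluded, so the taxonomic AUC is
penalized, not flattered, by dropouts.

# Numerical and degenerate-input choices

* Identity and coverage thresholds are compared with a 1e-9 slack toward
  acceptance so that exact rational boundaries (e.g. 19/20 = 95%) are
  stable across platforms; best-hit identity ties are resolved on integer
  cross products.
* All-zero features get log2FC 0 and p 1; constant vectors are an error in
  correlation; single-class truth is an error in ROC construction.
* Size factors require a feature observed in every sample and suggest the
  pseudocount mode otherwise; the normalization helper falls back to
  library-size factors only in that degenerate case.
* Every stochastic step (sampling, simulation, subsampling, rarefaction,
  permutation) takes an explicit seed; the pipeline driver derives
  per-stage seeds from one global seed by a fixed string hash, so a rerun
  of the same configuration is bit-identical.

# Problem sizes

The validation harness runs at 1,000 genes x 20 samples (~500k read pairs)
and 200 organisms x 20 samples for the taxonomic side; the unit and
property suites use smaller fixtures (hundreds of reads or sequences,
brute-force oracles up to a few hundred items) chosen so each oracle stays
exhaustively checkable.
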