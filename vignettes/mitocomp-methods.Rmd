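---
title: "Models and design choices in mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements the comparative-mitogenomics workflow used in
family-level studies of insect mitochondrial genomes: composition and
strand skews, codon-usage bias, divergence at stratified taxonomic ranks,
supermatrix assembly, distance trees, and phylogenetic-informativeness
profiling. This vignette documents the models behind each stage, the
parameters that matter, and the choices made where the design was open.

## Coordinates, alphabets and record validation

All genome coordinates are GenBank convention: 1-based, inclusive, with
origin-wrapping features written `join(a..L,1..b)` and allowed only on
circular molecules. Sequences are restricted to `A C G T N` (plus `-` in
alignments). Ambiguity codes other than `N` are rejected at parse time
rather than silently handled: a single `R` or `Y` absorbed into base
counts would bias skew statistics in a way that is invisible downstream.
Incomplete assemblies (no control region) are accepted with
`complete = FALSE`; whole-genome composition then covers only the
assembled span. Leucine/serine tRNA annotations must carry an anticodon
or a codon-family tag (`(UUR)/(CUN)/(AGN)/(UCN)`); without one the two
paralogues cannot be told apart and parsing fails rather than guessing.

## Composition and skews

Strand asymmetry uses AT-skew = (A − T)/(A + T) and
GC-skew = (G − C)/(G + C), computed on the majority strand as stored;
minus-strand genes are reverse-complemented during extraction before
being pooled into gene-class partitions, because skew is
strand-dependent. Partition composition pools bases over concatenated
genes ("overall" values are therefore pooled counts, not means of
per-genome percentages; per-genome rows are also emitted so either
convention can be recovered). Tribe-level values are unweighted means
over member samples; samples missing any gene of a partition are flagged
and excluded from those means. Percentages are reported at full precision
and conventionally rounded to one decimal for display.

## Codon-usage bias

The genetic code is injected (`genetic_code()`, default NCBI table 5 —
invertebrate mitochondrial: AGA/AGG serine, ATA methionine, TGA
tryptophan, stops TAA/TAG; 62 sense codons in 12 two-fold, 6 four-fold,
one six-fold and one eight-fold family), so the standard code can be
substituted in tests, where the family structure differs.

* **RSCU**: observed count over the uniform-usage expectation
  (family total / family size). An unobserved family yields `NA`, an
  unobserved codon in an observed family yields 0 — the two situations
  are deliberately distinct.
* **ENC** follows Wright: per amino acid with total count n ≥ 2,
  F̂ = (n Σp² − 1)/(n − 1); class means F̄ₖ over family sizes k;
  ENC = Σₖ Nₖ/F̄ₖ (12/F̄₂ + 6/F̄₄ + 1/F̄₆ + 1/F̄₈ under table 5), capped at
  the sense-codon count. When a size class has no usable F̄ (absent, or
  non-positive from finite counts), it is imputed as the weighted mean of
  the available classes with weights equal to the class family counts —
  keeping ENC defined on short genes while staying in the spirit of the
  statistic.
* **CBI** = (N_opt − N_ran)/(N_tot − N_ran) over multi-codon families,
  N_ran = Σ n_a/k_a. "Optimal" codons are the most frequent synonym per
  family in the pooled dataset under analysis (a self-referential
  collapse of the classical reference-set notion, recorded in the output
  metadata); ties break lexicographically for reproducibility.
* **GC3s** is the G+C fraction at third positions of codons in
  multi-codon families, stops excluded.
* The ENC~GC3s and CBI~GC3s relations are summarized by Pearson
  correlation on per-genome values over the 13 concatenated PCGs.

## Divergence

K2P distances use P (transitions) and Q (transversions) with
d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q). Gap handling differs deliberately
between statistics, matching the conventions of the tools each statistic
comes from: **pairwise deletion** for K2P (distance-software convention)
and **complete deletion** of any column containing `-`/`N` for π
(diversity-software convention). Saturated pairs (non-positive log
arguments) become `NA` sentinels, are excluded from category means and
counted separately rather than propagated.

Rank stratification assigns each unordered pair of samples to exactly one
of five categories by the most specific shared rank: within species,
among species within genus, among genera within tribe, among tribes
within subfamily, between subfamilies. Categories therefore partition all
pairs.

Sliding-window π uses 300-site windows at 25-site steps on gap-stripped
alignment columns, reported at window midpoints; a usable length below
one window yields the genewide value with an empty profile. Both the
genewide π and the mean of window values are available, since the two
conventions differ slightly.

Ka/Ks follows Nei–Gojobori (1986): per-codon synonymous site fractions by
exhaustive single-base mutation enumeration (mutations creating stops are
dropped from numerator and denominator, so S + N = 3 × codons);
differences resolved by averaging over substitution pathways that avoid
stop codons (falling back to all pathways in the rare case every pathway
is blocked); Jukes–Cantor correction d = −¾ ln(1 − 4p/3) with saturation
sentinels at p ≥ ¾. No likelihood-based dN/dS is attempted.

## Supermatrices and trees

Genes concatenate in a fixed canonical order (PCGs in the canonical
lepidopteran genome order, then rRNAs, then tRNAs alphabetically):
deterministic output matters more than the particular order. Missing
samples are padded with `-` (the standard supermatrix convention) and
reported. The four schemes select codon positions 1+2 (P12), all
positions (P123), plus rRNAs (P123R), plus tRNAs (P123RT). Column
provenance (gene, original column, codon position) is kept as an
invertible map, and charsets are exported 1-based inclusive with stride
notation for codon positions in NEXUS `sets` and RAxML dialects.

UPGMA (average linkage, node height = cluster distance/2) supplies the
rooted ultrametric tree; labels are sorted before clustering so tie-breaks
are reproducible. NJ (Saitou–Nei) serves topology checks, with negative
branch lengths clamped to zero under a warning. At desk scale the UPGMA
tree on K2P distances over the P123RT columns stands in for a dated
Bayesian chronogram; the profiling stage equally accepts a user-supplied
ultrametric newick tree, and no attempt is made to guess clock or model
settings for an external dating analysis.

## Phylogenetic informativeness

Per-site rates are estimated on the depth-normalized ultrametric tree by
maximizing the Jukes–Cantor pruning likelihood of each column in the rate
multiplier λ (uniform base frequencies; gaps and `N` as missing data).
The optimizer brackets λ̂ on a coarse log grid and refines by Brent search
to tolerance 1e-6; invariant columns (or columns with fewer than two
observed taxa) short-circuit to λ = 0, and identical site patterns are
collapsed before optimization. The rate cap defaults to 20 on the
depth-1 tree; capped sites are flagged so saturation artifacts remain
visible. JC rather than richer models is a deliberate desk-scale choice;
the model interface is a single likelihood function and can be swapped.

The profile uses the quartet-internode approximation
ρ(t; λ) = 16 λ² t e^(−4λt), whose peak at t = 1/(4λ) (value 4λ/e) is the
classical statement that a site is most useful at depths matching its
rate. Net informativeness sums ρ over sites (so it is additive over
disjoint site sets and scales with partition length); per-site divides by
the partition's full site count including invariant sites. The default
time grid is 200 uniform points on (0, 1]. Whether net or per-site values
are ranked is left to the caller, as published figures use either.

One property worth noting: for a single-change column, the ML rate is
governed mostly by the *conserved* branch length, so a change mapping to
a long deep branch receives a slightly **higher** λ̂ than one on a short
shallow branch (≈ −ln(1 − b/T)/b, increasing in b). Intuition borrowed
from multi-change counting ("deep change = slow site") does not apply to
single columns; the tests pin the estimator to a dense-grid search rather
than to that intuition.

## The synthetic generator

`simulate_set()` evolves each gene along a fixed tree under HKY, with the
rate matrix normalized so one unit of branch length is one expected
substitution per site at multiplier 1. HKY (not GTR) is the smallest
model producing both composition bias and the transition/transversion
distinction K2P measures; κ defaults to 4, a conventional mitochondrial
scale. Codon positions of PCGs are deterministic rate classes
(default multipliers 1 / 0.4 / 5, normalized to mean 1 within each gene),
which keeps ground-truth bookkeeping exact; rates are not drawn randomly.
Equilibrium frequencies default to A 0.405, C 0.115, G 0.078, T 0.402 (a
strongly AT-rich insect mitogenome with negative GC-skew), and can be
overridden per gene class — the study-like configuration runs the rRNAs
and tRNAs slightly more AT-rich than the PCGs, as real mitogenomes are.
Simulated alignments are gap-free; gap handling is exercised in dedicated
tests by masking columns, keeping simulation truth clean. There is no
indel process and no selection on codons (Ka/Ks is validated on
hand-built codon pairs instead), and no attempt to simulate control
regions, secondary structure or strand-asymmetric mutation.

`paper_like_config()` freezes the study conditions: a 30-tip ultrametric
tree with 2 subfamilies, 6 tribes, genera of 1–3 species and one species
sampled as six conspecific individuals (terminal branches 0.001). Clade
heights — species 0.012, genus 0.03, tribe 0.05, root 0.075 — were chosen
once so that rank-stratified K2P means span roughly 0.002 (within
species) to 0.15 (between subfamilies) without saturating third codon
positions. The 13 PCGs carry multipliers from 0.6 (slowest, assigned to
`nad5`) to 1.9 (fastest, `nad6`) with realistic gene lengths; rRNAs run
slow (0.5–0.55) and the 22 tRNAs (65–72 bp) slowest (0.35).

What passing tests on this generator do and do not show: they demonstrate
that the statistics recover known structure (rank-monotone distances,
rate-ordered diversity, third-position informativeness dominance,
composition within 1% of equilibrium at 15 kb) under a clean
substitution-only model. Real mitogenomes add alignment error, indels,
strand-asymmetric mutation pressure, selection, and annotation noise that
the generator deliberately omits, so simulation-based checks validate the
estimators, not the biology of any particular dataset.

## Problem sizes and determinism

All randomness flows through explicit seeds (`SimulationConfig$seed`, the
`--seed` flag of `scripts/acceptance.R`); identical seed and configuration
give bit-identical simulated sets and byte-identical exported files. The
shipped analyses run at the 30-genome / ~15 kb scale (about 20 seconds
for the full acceptance recomputation); replicated checks use 10–20
seeded replicates, and consistency checks compare sequence lengths 10³
against 10⁴. Pipeline tables carry a header with the package version,
configuration hash and input checksums, and reruns with unchanged inputs
are skipped, so regenerated outputs can be diffed byte for byte.

## Known limitations

* The GenBank reader targets well-formed single-record mitogenome flat
  files (the writer's output is a fixed point); it is not a general
  GenBank parser and supports `join` locations only as origin wraps.
* ENC on very short genes leans on the imputation rule; values from a
  handful of codons are noisy regardless.
* K2P is inconsistent under strong compositional bias (as any K2P-based
  study is); the simulator's equal-frequency mode exists precisely to
  validate the estimator where it is consistent.
* UPGMA assumes clock-likeness; on strongly non-clock data the
  informativeness time axis inherits that distortion. Supplying an
  externally dated ultrametric tree is the supported alternative.
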