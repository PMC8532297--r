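# mitocomp

Comparative mitogenomics below the family level, packaged for R. The
toolkit reproduces the analysis layout of family-scale studies of insect
mitochondrial genomes (the motivating system is the leaf-roller moths,
Lepidoptera: Tortricidae): a set of annotated ~15 kb circular genomes with
13 protein-coding genes (PCGs), 22 tRNAs and 2 rRNAs is summarized by

- **nucleotide composition and strand skews** per genome, gene class and
  codon position, with AT-skew = (A − T)/(A + T) and
  GC-skew = (G − C)/(G + C);
- **codon-usage bias** under the invertebrate mitochondrial genetic code
  (NCBI table 5): RSCU, Wright's effective number of codons
  ENC = Σₖ Nₖ/F̄ₖ, the codon bias index
  CBI = (N_opt − N_ran)/(N_tot − N_ran), GC3s, and the ENC~GC3s /
  CBI~GC3s correlations;
- **divergence**: Kimura-2-parameter distances
  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) stratified by taxonomic rank
  (within species → between subfamilies), sliding-window nucleotide
  diversity π (300 bp windows, 25 bp steps), and Nei–Gojobori Ka/Ks;
- **supermatrices** for four partitioning schemes (P12, P123, P123R,
  P123RT) with NEXUS/RAxML charset export;
- **distance trees** (UPGMA, NJ) and **phylogenetic-informativeness
  profiles**: per-site rates λ estimated by ML under Jukes–Cantor on an
  ultrametric tree, profiled as ρ(t; λ) = 16 λ² t e^(−4λt), which peaks
  at t = 1/(4λ).

Because the analyses are only meaningful on a full genome set, the package
ships a seeded simulator (`simulate_set()`, `paper_like_config()`) that
generates mitogenome sets by HKY evolution along a known tree, with
AT-rich equilibrium composition, per-gene and per-codon-position rate
heterogeneity (3rd ≫ 1st > 2nd), a five-level taxonomy and near-zero
intraspecific divergence — so every pipeline stage can be checked against
ground truth without downloading data.

## Worked example

```r
library(mitocomp)
library(dplyr)

cfg <- paper_like_config(seed = 1)   # 30 samples, 2 subfamilies, 6 tribes
sim <- simulate_set(cfg)
sim
#> <simulated_set> 30 samples, 37 gene blocks, 14842 bp per genome

composition_report(sim$records, cfg$taxonomy, partitions = "whole") |>
  filter(level == "tribe") |>
  select(group, at_content, at_skew, gc_skew)
#> # A tibble: 6 × 4
#>   group    at_content at_skew gc_skew
#> 1 Tribe_GA       81.5 0.0147   -0.174
#> 2 Tribe_GB       81.8 0.0105   -0.179
#> 3 Tribe_GE       81.6 0.0111   -0.166
#> 4 Tribe_GF       81.4 0.00735  -0.178
#> 5 Tribe_GH       81.5 0.00622  -0.171
#> 6 Tribe_GJ       81.4 0.00891  -0.176
```

AT content is high (~81.5%) with a negligible AT-skew and a clearly
negative GC-skew — the composition structure the generator is configured
to emulate. Per-gene nucleotide diversity ranks the fast genes:

```r
sort(sapply(sim$blocks[mito_gene_order("PCG")], nucleotide_diversity))
#>  nad5  cox1  cox2 nad4l  nad4  cox3   cob  nad1  atp6  nad3  nad2  atp8  nad6
#> 0.064 0.071 0.075 0.080 0.080 0.089 0.089 0.093 0.111 0.113 0.114 0.130 0.145
```

`nad6` (simulated fastest) shows the highest diversity and `nad5`
(slowest) the lowest, so π correctly recovers the per-gene rate ordering.
Codon-usage indices over the concatenated PCGs:

```r
codon_usage_report(sim$records, cfg$taxonomy) |>
  filter(level == "sample") |>
  summarise(enc = mean(enc), cbi = mean(cbi), gc3s = mean(gc3s))
#> # A tibble: 1 × 3
#>     enc   cbi  gc3s
#> 1  42.8 0.462 0.193
```

Downstream, `build_supermatrix()` concatenates the blocks under a scheme,
`upgma_tree()`/`nj_tree()` build distance trees, and
`pi_profiles_by_partition()` profiles informativeness per gene and per
pooled codon position. `run_pipeline()` orchestrates all stages from
plain files (GenBank records, per-gene FASTA, taxonomy TSV) and writes
TSV/newick/NEXUS outputs plus a JSON manifest.

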