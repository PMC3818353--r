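# mirsnp

`mirsnp` is an R package for studying single nucleotide polymorphisms
(SNPs) inside human microRNA precursor hairpins. MicroRNAs repress their
target mRNAs through the ~21 nt mature strand excised from a ~60–120 nt
hairpin, with nucleotides 2–8 of the mature (the *seed*) doing most of the
target recognition. Because function concentrates toward the seed,
polymorphism should thin out from hairpin to mature to seed, and should be
depleted in conserved, clustered and disease-associated miRNAs. `mirsnp`
is built for researchers who want to quantify those patterns on their own
variant catalogues — or on fully synthetic, seeded stand-ins — with every
statistical step explicit and testable.

## What it computes

* **Mapping.** Variants are projected into hairpin coordinates (0-based,
  sense strand, minus-strand alleles reverse-complemented), with
  per-mature and per-seed membership flags. The ancestral allele is the
  annotated hairpin base by convention.
* **SNP density.** For a unit with `n` distinct SNPs and length `L` bp,
  density = `n / L`. Region distributions are compared with one-tailed
  Mann–Whitney tests; conservation tiers (families in ≥ 10 / 2–9 / 1
  species), cluster membership (gap < 10 kb chains) and disease groups with
  one-tailed Welch t-tests.
* **Fragile sites.** Enrichment of multi-SNP miRNAs inside common/rare
  fragile sites by the exact upper-tail hypergeometric probability,
  P(X ≥ k) drawing n from K in-site + (N−K) out-of-site miRNAs.
* **Substitution spectrum.** The 12 ordered substitution types counted in
  seed/mature/precursor, with transition (purine↔purine,
  pyrimidine↔pyrimidine) and transversion subtotals.
* **Hairpin stability.** Each substitution is scored by
  `rel_change = (MFE_mut − MFE_anc) / |MFE_anc|` (positive =
  destabilizing) under a deterministic weighted base-pair-maximisation
  folder (G:C = 3, A:U = 2, G:U = 1, min loop 3); ViennaRNA's RNAfold can
  be plugged in as an external engine.
* **Burden correlations.** Spearman rank correlations of per-miRNA SNP
  counts against disease-association counts and QTL overlap counts.
* **Population differentiation.** Per-pair 2×2 allele-count chi-square
  tests with Monte-Carlo p-values (10,000 fixed-margin replicates,
  p = (1 + #{χ²ᵣ ≥ χ²}) / (reps + 1)), Benjamini–Hochberg FDR within each
  pair, significant-SNP count matrices at q < 0.01, and UPGMA clustering
  of populations with Newick output.

A seeded generator (`simulate_bundle()`) produces all eight input tables
with planted truth — region-rate ordering, conservation and cluster
effects, fragile-site boosts, burden–disease negative dependence, and
Balding–Nichols allele panels with a block of differentiated SNPs — so the
whole pipeline runs and is verified without any external download.

## Worked example

```r
library(mirsnp)

bundle <- simulate_bundle(sim_config(seed = 7))
report <- run_pipeline(bundle, mc_reps = 10000, seed = 7)
report
#> miRNA SNP pipeline report
#>   2069 SNPs mapped into 1194 of 2010 precursors (59%)
#>   density ordering (one-tailed Mann-Whitney): mature<precursor p=6.24e-228, seed<mature p=6.55e-60
#>   substitutions with no structural influence: 16%
```

2,069 synthetic SNPs land in 59% of the 2,010 hairpins; density drops
significantly from precursor to mature to seed, as planted. The
fragile-site, conservation, cluster, disease and population blocks are in
`report$summary`:

```r
report$summary$fragile_enrichment_p[["common"]]
#> [1] 3.970657e-35
report$summary$disease_rho
#> [1] -0.6567721
report$popgen$diff$matrix
#>     AFR AMR ASN EUR
#> AFR   0  20   0   0
#> AMR  20   0   0   0
#> ASN   0   0   0   0
#> EUR   0   0   0   0
```

Multi-SNP miRNAs are strongly enriched in common fragile sites, SNP burden
anti-correlates with disease count (rho ≈ −0.66), and exactly the 20
planted differentiated SNPs are recovered between the designated
population pair (AFR/AMR here), with no false cells.

The bundled published substitution spectrum aggregates through the same
code path used for synthetic data:

```r
substitution_subtotals(reference_substitution_counts()) |>
  dplyr::filter(is.na(from_base))
#> # A tibble: 3 × 6
#>   from_base to_base substitution              seed mature precursor
#>   <chr>     <chr>   <chr>                    <int>  <int>     <int>
#> 1 <NA>      <NA>    subtotal of transversion    37    111       439
#> 2 <NA>      <NA>    subtotal of transition      96    315      1106
#> 3 <NA>      <NA>    total                      133    426      1545
```

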