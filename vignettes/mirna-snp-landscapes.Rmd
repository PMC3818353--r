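---
title: "Methods: SNP landscapes of miRNA hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP landscapes of miRNA hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnp)
```

## The analysis

MicroRNA precursors (pre-miRNAs) are short (~60–120 nt) hairpin RNAs; a
~21 nt mature strand is excised from each arm, and nucleotides 2–8 from the
mature 5' end (the seed) drive target recognition. Because these segments
carry increasingly concentrated function, polymorphism is expected to thin
out from the hairpin as a whole, to the mature, to the seed. `mirsnp`
implements a complete analysis of that expectation and of its genomic
correlates: it projects a variant catalogue into hairpin coordinates,
quantifies SNP density, and asks how the density varies with conservation,
genomic clustering, fragile-site context, hairpin thermodynamics, disease
involvement, QTL overlap and population structure.

Everything operates on tidy tables, with a seeded synthetic-data generator
standing in for the external catalogues (variant databases, hairpin
annotation, family/conservation tables, fragile-site lists, disease and QTL
tables, allele-frequency panels), so the full pipeline is testable offline.

## Coordinates and mapping conventions

All internal coordinates are 0-based half-open; GFF3, VCF, and the 1-based
TSV dialects are converted at the I/O boundary, and nothing downstream ever
sees a 1-based value. Hairpin FASTA sequences follow the miRBase
convention (sense strand 5'→3', so a minus-strand hairpin stores the
reverse complement of the forward genome slice, transcribed to RNA).

A variant overlapping k precursors yields k mapped records; per-precursor
duplicates from multi-placement input are collapsed, and genome-wide unique
SNP counts always deduplicate by SNP id. On a minus-strand precursor
spanning `[start, end)`, forward position p maps to hairpin offset
`end - 1 - p` and alleles are reverse-complemented before transcription.
The *ancestral* allele is, by convention, the base of the annotated hairpin
sequence at the mapped position — not the chimpanzee-inferred allele, which
is carried through the variant table for reporting only. This means the
ancestral allele need not be the major allele. A substitution whose
reference base contradicts the hairpin sequence is flagged, kept for
density counting, and excluded from substitution-level analyses.

Multi-allelic records count once as "a SNP" for density (`n` distinct SNP
ids over length `L`, density `n/L`) but expand to one event per alternate
allele for the substitution spectrum and folding analyses. Indels and
unclassifiable records likewise count for density but never enter
substitution analyses.

## Genomic context

* **Conservation tiers.** A miRNA family seen in ≥ 10 species is *highly*
  conserved, in 2–9 species *lowly* conserved, and in one species
  *non-conserved*; tiers propagate to member miRNAs and familyless miRNAs
  default to non-conserved.
* **Clusters.** Precursors on one chromosome and strand are chained while
  consecutive interval gaps stay strictly below a threshold (10 kb default,
  20 kb as the robustness preset); maximal chains of ≥ 2 are clusters. The
  inter-miRNA distance is the gap between intervals, not start-to-start,
  which is what makes "flanking regions between clustered miRNAs" a
  positive-length unit for density comparison.
* **Fragile sites** are strandless cytogenetic intervals (common or rare).
  A miRNA is "in" a class when its precursor interval intersects a site of
  that class; abutting under half-open intervals is "out". Enrichment of
  multi-SNP (≥ 2 SNPs) miRNAs inside sites uses the exact upper-tail
  hypergeometric probability; no normal approximation is ever substituted.
* **Genic context** is a strand-agnostic interval intersection with
  protein-coding gene spans.

## Folding model

The builtin folding engine is a weighted base-pair-maximisation dynamic
program over non-crossing structures: pair weights G:C = 3, A:U = 2,
G:U = 1; minimum hairpin loop of 3 unpaired bases; no lonely-pair rule;
energy reported as minus the total pair weight so more negative = more
stable. Ties are broken deterministically (pair the smallest 5' index,
then the smallest 3' partner), making results bit-for-bit reproducible on
any platform and exhaustively verifiable against structure enumeration for
short sequences. It is deliberately *not* a thermodynamic nearest-neighbour
model: its energies are model units, and absolute energy values from
thermodynamic folders are not comparable. A pluggable external engine
(e.g. `rnafold_engine()`, which shells out to ViennaRNA's RNAfold) accepts
the same contract for users who want kcal/mol energies.

Each substitution is evaluated alone — the simultaneous presence of several
substitutions in one hairpin is taken to be unlikely — by folding the full
annotated precursor with the ancestral and the mutated base and scoring

rel_change = (MFE_mut − MFE_anc) / |MFE_anc|,

so positive values destabilize. Records with |rel_change| ≤ 1e−9 are
"neutral" (exact-zero detection under the integer-weight engine); hairpins
whose ancestral fold has zero energy yield an undefined relative change and
are counted separately, excluded from fraction summaries.

## Statistics

One-tailed Mann–Whitney tests compare density medians across regions and
fragile-site membership; one-tailed Welch t-tests (Satterthwaite df —
chosen over the pooled variant, which remains available) compare
conservation tiers, clusters and disease groups; Spearman's rank
correlation (tie-corrected) relates SNP burden to species counts, disease
counts and QTL overlap. Small samples take exact paths: full rank-split
enumeration for Mann–Whitney at group sizes ≤ 8, full permutation
enumeration for Spearman at n < 10; larger samples use the tie-corrected
normal approximation with continuity correction and the t approximation
respectively. These exact small-sample paths and tie conventions are
contractual and verified against independent brute-force oracles in the
test suite.

Population differentiation uses the Pearson chi-square on each pair's 2×2
allele-count table, with a Monte-Carlo p-value from resampling tables with
fixed margins (for 2×2, a hypergeometric draw of one cell), estimated as
`(1 + #{replicate χ² ≥ observed}) / (reps + 1)` over 10,000 replicates by
default — never exactly zero. Benjamini–Hochberg FDR is applied within each
population pair (the family is configurable to global), and q < 0.01 is
called significant. The per-pair significant counts form a symmetric
matrix whose rows are clustered agglomeratively (Euclidean distance,
average linkage by default — single and complete are available, and the
choice is recorded in the output; populations are pre-sorted so ties break
deterministically), yielding a merge table and a Newick tree with
branch lengths from merge heights.

A numerical note on the Monte-Carlo estimator: because it includes the
point mass at the observed statistic, its expectation exceeds the
continuous asymptotic chi-square tail by roughly half that point mass.
With allele counts in the low hundreds the conditional statistic is coarse
enough for this bias to reach a few percent at small χ² values; at pooled
superpopulation scale (thousands of chromosomes) the lattice is fine and
MC and asymptotic tails agree within ±0.02 essentially always. Calibration
checks therefore use the larger scale; at small scale the estimator is
conservative, which is the safe direction for significance calls.

## The synthetic generator

`sim_config()` fixes the study conditions; `simulate_bundle()` derives all
randomness from one seed via fixed per-stage child seeds, so bundles are
byte-identical across runs and skipping a stage never shifts another
stage's stream. Defaults (2,000 precursors of 60–120 nt on a 10 × 6 Mb toy
genome) were chosen once so that a full bundle exercises every stage in
seconds; they are documented constants, not claims about human biology:

* **Hairpins** get complementary arms around a small loop (10% arm
  mismatch), so folding baselines are non-degenerate and substitutions at
  paired positions are usually destabilizing.
* **SNP placement** is per-position Bernoulli at `background × tier ×
  region × cluster (× fragile)` with background 0.02/bp (the empirical
  per-bp rate of SNPs in human hairpins is ~0.015), region multipliers
  mature 0.5 and seed 0.25, tier multipliers 0.4/0.7/1.0
  (highly/lowly/non), cluster-member multiplier 0.5, and a ×3 boost inside
  common fragile sites. Alleles are drawn at 2:1 transition:transversion
  odds, with 6% indels and 3% multi-allelic records.
* **Families** are non/lowly/highly conserved with probability
  0.35/0.45/0.20, matching the observed predominance of poorly conserved
  families; ~10% of miRNAs are familyless.
* **Diseases** are Poisson with mean `λ·exp(−β·snp_count)` (λ = 3,
  β = 0.8), planting the negative burden–disease dependence; QTLs are
  placed independently of SNP rate, so the QTL correlation is null by
  construction.
* **The allele panel** follows the Balding–Nichols model: ancestral
  frequency p0 ~ U(0.05, 0.95) and per-population frequencies
  Beta(p0(1−F)/F, (1−p0)(1−F)/F), binomial counts at 2N = 200. The default
  F = 0.001 keeps the background effectively undifferentiated so it serves
  as a negative control; the planted block of 20 SNPs carries data only
  for one designated population pair, at frequencies 0.9 vs 0.1. Realistic
  continental differentiation (F ~ 0.1) is reachable through `bn_f` but is
  deliberately not the default study condition, since it would blur the
  planted/background distinction the recovery tests rely on.

What passing recovery tests show — and what they do not: the generator
emulates rate structure, not sequence realism. Mutational signatures, GC
heterogeneity, linkage between panel SNPs, ascertainment bias in disease
reports (publication begets publication) and genome-scale SNP density
variation are all absent, so recovered orderings demonstrate that the
pipeline detects the planted effects at realistic magnitudes, not that the
effects hold in any particular real catalogue.

## Problem sizes and numerical choices

Recovery tests run 20 seeded bundles at the default 2,000-precursor scale
with 10,000 Monte-Carlo replicates per allele test; folding oracles
enumerate all structures for sequences up to 14 nt; hypergeometric oracles
enumerate draws for populations up to 20; exact-test oracles enumerate
splits/permutations up to n = 8. Degenerate inputs have fixed conventions:
zero-information 2×2 margins give χ² = 0 and p = 1; two constant samples
with equal means give p = 1; a constant vector makes Spearman's rho an
error; zero-energy ancestral folds are "undefined", never divided by.

## Known limitations

The builtin folder ignores stacking, dangles and loop penalties, so its
relative-MFE values are rank-meaningful rather than thermodynamically
calibrated; published kcal/mol ΔMFE values are not reproduction targets.
Disease tables must already be resolved to precursor-level ids.
Genotype-level (per-individual) data, liftover between genome builds, and
remote retrieval of the real catalogues are out of scope.
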