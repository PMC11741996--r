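---
title: "Methods: functional repertoire comparison of MHC class I alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional repertoire comparison of MHC class I alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `mhcRepertoire`, the parameters
that matter, the synthetic data generators, and the numerical and design
choices made where several reasonable options existed.

## The pipeline

1. **Redundancy collapsing.** Per-virus proteomes are compared by
   Needleman–Wunsch global alignment of their id-sorted concatenated
   protein sequences (BLOSUM62, gap open 10, gap extend 0.5). Identity is
   the number of identical aligned columns over the full alignment length
   including gap columns. Viruses are scanned in input order; one is
   dropped when its identity to an already-retained virus strictly
   exceeds the threshold (default 95%), and it maps to the first retained
   virus that excluded it.

2. **Digestion.** Every protein is cut into all overlapping windows of
   the configured lengths — 8–11 residues for viral and self proteomes,
   8–12 for the rank-reference proteome. Windows overlapping a masked
   (nonstandard-residue) position are skipped. Both the total window
   count (with multiplicity) and the unique peptide set are kept, because
   downstream consumers differ: repertoires and Jaccard similarities are
   over unique peptides, while the epitope-density denominator is the
   total count.

3. **Binding scores and self-calibrated ranks.** Binding prediction is a
   contract: any object with a `bindingScore(model, peptides)` method.
   For each allele, 25,000 distinct digestion products per length 8–12
   are sampled (seeded, without replacement) from a reference proteome
   and scored; the pooled 125,000 sorted scores form the allele's rank
   reference. A peptide's percentile rank is the percentage of pool
   scores strictly greater than its own, so rank 0 is the strongest
   possible call, and ties with pool members favour the peptide. A
   peptide is a binder when rank ≤ threshold; the default threshold of 1%
   is inclusive at the boundary.

4. **Repertoires, distances, trees.** The binder repertoire is per
   (allele, virus) over that virus's unique peptides; a peptide occurring
   in two viruses contributes to both. Allele pairs are compared per
   virus by Jaccard similarity and overall by
   `D = 1 − mean_v(J_ab,v)`. UPGMA (size-weighted average linkage) builds
   an ultrametric tree whose merge heights are half the merge distances.
   Bootstrap replicates draw `ceil(0.2 × N)` viruses without replacement,
   re-average the precomputed per-virus Jaccard values, and recluster;
   clade support is the recurrence frequency over (default) 1000
   replicates, reported in [0, 1]. The extended majority-rule consensus
   keeps all clades above 50% frequency and then greedily adds compatible
   clades in decreasing frequency order.

5. **Densities and statistics.** Epitope density is the observed binder
   count over the chance expectation (threshold fraction × total
   digestion products). Group contrasts use the two-sided Mann–Whitney U
   test — exact when both groups are small (≤ 25) and untied, otherwise
   the tie-corrected normal approximation with continuity correction —
   with Bonferroni correction over all group pairs. The per-virus
   permutation test asks one-sidedly whether the focal group presents the
   virus *less* well; it enumerates all label assignments when feasible
   and otherwise samples with the +1 convention, so p is never 0. The
   sweep-candidate screen uses strict inequalities on both sides.

## Parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| viral/self digestion lengths | 8–11 | residues | class I ligand range used for query proteomes |
| reference digestion lengths | 8–12 | residues | wider range for the calibration pool |
| peptides per reference length | 25,000 | peptides | pool of 125,000 scores per allele |
| rank threshold | 1 | % | standard strong-binder cutoff |
| collapse threshold | 95 | % identity | redundancy removal; strictly-greater collapses |
| bootstrap replicates | 1000 | — | support resolution of 0.001 |
| bootstrap fraction | 0.2 | of viruses | subsample without replacement |
| filter low / high / min count | 1 / 2 / 10 | density, alleles | sweep-candidate screen |

All are configuration, not constants, and `defaultRunConfig()` carries
them into `runPipeline()`.

## The synthetic allele model

`SyntheticAlleleModel` scores a peptide as P2-anchor weight + C-terminal
anchor weight + mean background weight over the remaining positions +
`noiseScale × sin(k(p))`, where `k(p)` is a positional hash keyed by a
20 × 12 matrix drawn once from the model's seed. The perturbation is a
fixed function of (model, peptide) rather than an RNG stream, so scores
are reproducible regardless of evaluation order — a property the rank
calibration tests rely on. Anchors at P2 and the C-terminus mirror where
class I binding motifs concentrate; the model makes no claim to
predictive realism and exists so the pipeline's statistical behaviour can
be verified exactly.

## What the generators emulate — and what they do not

- `generateReferenceProteome()`: i.i.d. sequences, uniform residue
  background, lengths uniform on 100–600 — a stand-in for a random
  database draw. Uniform composition keeps the calibration null exact.
- `generateVirusSet()`: families seeded by independent ancestors; members
  derive by per-site substitution to a uniformly chosen *different*
  residue, so member–ancestor identity is analytically `1 − rate`. No
  indels (identity stays analytic), no codon structure, no gene
  architecture.
- `generateAllelePanel()`: one anchor archetype per supertype with
  distinct preferred residues at both anchor positions across supertypes;
  alleles are archetype + Gaussian weight perturbation of SD
  `anchorDivergence`. The hash key is shared within a supertype, so zero
  divergence yields literally identical models.

Passing tests on these generators show that the pipeline recovers planted
structure under controlled conditions; they do not show that any real
predictor's scores cluster real alleles correctly, nor that real viral
proteomes satisfy the generators' independence assumptions.

### Why lowering a supertype's density needs compositional mismatch

Self-calibrated percentile ranks are distribution-free: if query peptides
are exchangeable with the reference pool, the binder fraction equals the
threshold for *any* scoring function, so no modification of a model alone
can push its expected epitope density below 1. A systematically poor
presenter therefore requires the viral peptide distribution to differ
from the reference distribution where the allele's preferences lie.
`makeLowDensitySupertype()` implements exactly that: it interpolates the
focal supertype's anchors towards residues (default Trp and Cys — the
residues real viral proteomes are poorest in) that
`depletedResidueFreqs()` down-weights in the generated virus set, while
the rank reference keeps the background composition. Sharpening 0 leaves
the panel untouched; full sharpening concentrates the anchors on the
depleted residues, and the focal group's densities fall well below 1
while other groups stay near chance.

## Numerical choices

- **Empty-set Jaccard**: when both binder sets are empty for a virus the
  repertoires are indistinguishable there, so J = 1 by default; the
  `"skip"` policy instead drops such viruses and renormalizes N.
- **UPGMA ties**: equally close cluster pairs merge in order of the
  lexicographically smallest name-sorted pair of cluster labels (a
  cluster is labelled by its smallest leaf name), making trees
  deterministic and input-order invariant. Distances within 1e-12 count
  as tied.
- **Consensus branch lengths**: node heights are averaged over the
  replicate trees containing the clade and clamped so a child never sits
  above its parent — a presentation choice with no effect on clades or
  supports.
- **End gaps**: alignments are truly global (end gaps are charged
  open + length × extend), and identity is computed over the full
  alignment length including end-gap columns.
- **Permutation direction**: fixed to "focal group lower", matching the
  screening question; the statistic is the focal-minus-rest difference of
  mean densities.
- **Degenerate inputs**: proteins shorter than the smallest window yield
  zero products (not an error); a virus with zero products is an error at
  density time; a zero rank threshold leaves binder calls defined (only
  scores above the whole pool qualify) but densities undefined.
- **Self-presentation counts binder windows with multiplicity**, so the
  observed/expected ratio is exactly 1 at a 100% threshold; viral
  repertoires stay sets of unique peptides.

## Problem sizes used by the test suite

The packaged tests run the full calibration at the standard scale (5,000
reference proteins, 125,000-score pool, 100,000 query peptides) and the
clustering recovery at a reduced scale chosen to exercise every stage
while keeping the suite quick: 50 viruses of 10 × 300-residue proteins,
a 24-allele panel (4 supertypes × 6), 5,000 reference peptides per
length, and 200 bootstrap replicates at 20% subsampling. At these
settings the planted supertypes are recovered exactly and every supertype
clade reaches full bootstrap support.

## Known limitations

- The calibration pool is a finite sample from overlapping digestion
  windows; its sampled extreme tail fluctuates, so realized binder
  fractions at the 1% threshold scatter by a few hundredths of a
  percentage point around the nominal value even under the null.
- Identity-based collapsing aligns concatenated proteomes; viruses with
  rearranged gene orders but identical content are handled by the
  id-sorted concatenation only insofar as record ids correspond.
- PHYLIP's consense tie-breaking is version-dependent; the consensus here
  follows the documented extended-majority rule (frequency, then smaller
  clade, then lexicographic key), which can differ from a specific PHYLIP
  binary under exact ties.
- The Mann–Whitney "exact" path requires untied samples; tied data fall
  back to the corrected normal approximation even for tiny groups.
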