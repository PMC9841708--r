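---
title: "Methods: filtering, ordination, likelihood-free admixture and diagnostic markers in gbspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, ordination, likelihood-free admixture and diagnostic markers in gbspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbspop)
```

`gbspop` covers the post-assembly stages of a GBS/RAD population-genomics
study in a polyploid species complex: SNP filtering, ordination, admixture
estimation without a genotype likelihood, and discovery of species-diagnostic
markers with their flanking sequence. This vignette is the package's account
of the underlying models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data validation does and does not
demonstrate.

## Data model and the diploid-coding restriction

All analyses operate on unphased, *diploid-coded* genotype calls: each call
is an unordered pair of allele indices, missing calls are explicit, and
phase separators in input VCFs are accepted but discarded (`0|1` ≡ `1/0`).
Polyploid assemblers typically emit exactly this coding even for tetraploid
and hexaploid samples. A genotype field with arity other than 2 is rejected
with an error rather than collapsed: silently folding a true tetraploid call
into a diploid one would fabricate dosage information, and polyploid
genotype estimation is an open problem this package deliberately does not
attempt. The same restriction fixes the dosage scale at {0, 1, 2} alternate
alleles.

Multi-allelic records are parsed and carried through filtering, but the
dosage-matrix constructor requires biallelic records, since every downstream
statistic here is a biallelic-SNP statistic.

## The filtering cascade

Filters run in a fixed order, each recomputed on the previous stage's
output:

1. **Individual missingness** (`max_individual_missing`, default 0.40):
   drop a sample when its missing-call fraction is *strictly greater* than
   the threshold. Samples with pervasive dropout otherwise attract
   artefactual placements in ordination.
2. **Site completeness** (`min_site_presence`, default 0.80): keep a site
   when its non-missing fraction is *at least* the threshold (i.e. at most
   20% missing per site).
3. **Minor allele frequency** (`maf`, default 0.01): allele frequencies are
   computed over non-missing calls only, two alleles per call; MAF is the
   second-largest allele frequency. A site exactly at the threshold is kept
   ("below 1%" is discarded). Sites monomorphic after missingness have MAF 0.
   An alternative count-based mode (`min_allele_count`, e.g. 2) keeps sites
   whose minor allele was observed at least that many times; at 50–100
   individuals the two modes nearly coincide but are not identical, so both
   are exposed and neither is applied implicitly.
4. **Centre-SNP thinning** (`thin_to_center`): one SNP per contig, the one
   minimising |pos − centre|. This is deliberate *linkage* pruning — SNPs on
   one short GBS contig are effectively one marker, and keeping them all
   would overweight such contigs in PCA and admixture.

The order is part of the method: dropping a high-missingness individual
changes which sites pass the completeness bar. The test suite contains a
five-sample fixture where running completeness before individual
missingness keeps a site the canonical order removes.

Boundary semantics (strict-greater for individuals, at-least for sites and
MAF) follow the conventions of the standard VCF filtering tools this cascade
mirrors. The centre of a contig is `(alignment_length + 1) / 2` when the
per-locus alignment is available, else the midpoint of the observed SNP
positions; a distance tie is broken toward the lower position, which is
deterministic and independent of record order.

## Dosage matrix, imputation, centering

The dosage matrix is samples × sites with an explicit missingness mask.
Mean imputation replaces a masked cell by its site's unmasked mean — this
preserves every site mean exactly and adds no between-individual signal —
and is performed on raw dosages *before* centering so imputed values stay on
the dosage scale. Covariance PCA (no site standardisation) is the default;
correlation PCA is available via `scale = TRUE`, in which case zero-variance
sites (which can arise after sample subsetting) are dropped with a message
rather than producing divisions by zero.

## PCA

`run_pca()` eigendecomposes the sample-side cross-product of the centred
matrix, which for n samples ≪ m sites is the economical route to exactly
the covariance spectrum; explained variance per component is
100·λₖ/Σλ over the full spectrum. The solver is deterministic (base
`eigen`), so results are bit-reproducible on a platform; component signs
are arbitrary, and all comparisons in tests are sign-aligned. The test
suite cross-checks scores and variance fractions against an independent
SVD oracle at 1e−8.

## Likelihood-free admixture

The admixture model is the PSD model: dosage *x*ᵢⱼ ~ Binomial(2, *f*ᵢⱼ)
with **F** = **P Q**ᵀ of rank K, **Q** rows on the probability simplex.
Estimation is in two steps, neither of which evaluates a genotype
likelihood — the property that makes the method usable on diploid-coded
polyploid calls:

1. **Latent-subspace estimation.** With **W** = dosage/2 (sites × samples),
   the n × n matrix (1/m)**W**ᵀ**W** − diag(**d**), with
   *d*ⱼ = (1/m)Σᵢ*w*ᵢⱼ(1 − *w*ᵢⱼ), is an unbiased estimate of
   (1/m)**F**ᵀ**F**: the subtraction removes the binomial sampling variance
   from the diagonal. Rows of **W** are projected onto the span of its top-K
   eigenvectors and clipped to [ε, 1−ε], ε = 1e−6. The adjustment is
   switchable (`adjust = FALSE`) for noise-free inputs, where dosage equals
   2**F** exactly and the data-estimated diagonal would only perturb the
   subspace; with it off, noiseless recovery of **F** is exact to the
   clipping margin.
2. **Constrained alternating least squares.** Given **Q**, **P** is the
   least-squares solution clipped to [0, 1]; given **P**, each **Q** row is
   the least-squares solution projected onto the simplex (exact sort-based
   Euclidean projection — deterministic, no tuning). **Q** is initialised
   from seeded Dirichlet(1, …, 1) draws with 5 restarts, keeping the lowest
   reconstruction error; ALS on this problem is non-convex and restarts make
   recovery stable. Clipped/projected ALS carries no theoretical
   monotonicity guarantee, so an iteration that would increase the
   Frobenius objective is rejected and iteration stops there — the recorded
   objective trace is therefore non-increasing by construction. Convergence
   is declared at relative objective change below `tol` (default 1e−6,
   `max_iter` 500); hitting `max_iter` flags the fit rather than erroring.
   These tolerances are this package's defaults — the method as published
   names no specific values — and are exposed as arguments.

`fit_admixture()` sweeps K over a range (default 1–8). When the input
matrix contained missing data, it is mean-imputed first and the sweep
records that fact; per-K objectives are reported for inspection but no
"best K" is selected, because the subspace machinery underlying a principled
K estimate assumes complete data.

**Identifiability.** The factorisation **F** = **P Q**ᵀ under these
constraints is unique (up to cluster relabelling) only when the data are
*separable on both sides*: some individuals are effectively unadmixed
(anchor rows of **Q**) and some sites are effectively fixed in exactly one
cluster (anchor rows of **P**). Interior frequency matrices admit a small
continuum of exact alternative factorisations — empirically, reconstruction
error at machine zero can coexist with membership differences of order
1e−3. Recovery tests therefore plant both kinds of anchors, which is also
the realistic regime: real species panels contain unadmixed individuals and
fixed differences.

## Fixed differences and consensus extraction

A site is *fully segregated* between groups A and B when the allele sets
observed across their non-missing calls are disjoint and both groups meet a
minimum call count. Disjointness is the strictest reading of "fully
segregated": for a biallelic site it is equivalent to every A call being
homozygous for one allele and every B call homozygous for the other, and a
single heterozygote anywhere disqualifies the site. Missing calls are
ignored, never wildcards — so masking calls can only ever grow the reported
set, a monotonicity property the tests exercise. `min_calls_per_group`
defaults to 1 and deserves attention in real analyses: with tens of
individuals per group, a handful of segregated sites among ~10,000 is
sensitive to how much missingness is tolerated at a reported site.

Flanking consensus for a marker is per-column over the locus alignment:
majority base among non-gap, non-N characters; IUPAC ambiguity code at ties
and at the focal column (ambiguity is honest — an arbitrary pick would
fabricate certainty downstream homology searches don't need); majority-gap
columns removed and the focal position re-indexed; all-N columns inside the
kept span emit N. The focal column is always kept. FASTA headers carry the
locus id, focal offset and length, and round-trip through the package's own
reader byte-stably.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a post-assembly
GBS product, not its sequencing physics. Per locus: ancestral frequency
p ~ Uniform(0.05, 0.95); population frequencies pₖ ~
Beta(p(1−F)/F, (1−p)(1−F)/F) (Balding–Nichols, drift F per population —
a length-K `divergence` vector yields asymmetric designs such as two sister
groups plus one diverged group); linked SNPs on a contig share the locus's
pₖ with N(0, 0.02) jitter, a coalescent-free shortcut that produces the
within-contig correlation centre-thinning exists to remove. Memberships are
one-hot blocks or Dirichlet(α) draws; dosages are Binomial(2, **q**ᵀ**p**).
Missingness is MCAR per cell at rate 1 − (1 − r_ind)(1 − r_site).
Defaults (3 populations × 20 samples, 2000 loci of 100 bp with 1–3 SNPs,
F = 0.2, r = 0.05/0.05) give a desk-scale dataset with the proportions of a
filtered empirical GBS panel: tens of individuals, a few thousand contigs,
~10% missing cells.

Planted diagnostic markers are written over the first SNP of randomly
chosen loci — group A fixed `0/0`, group B fixed `1/1`, no missingness at
those sites — and, so that the returned truth is the *complete* list of
fully segregated sites, any accidental fixed difference between the two
designated groups at a background site is broken deterministically (the
first non-missing group-A call becomes heterozygous). Under default
settings such accidents are rare (expected ≲ 0.03 sites per 5,000), so the
perturbation is negligible for every other statistic; without it,
plant-and-recover tests would measure seed luck instead of detector
correctness.

In the emitted `.loci` alignments, heterozygous and missing calls are
written as `N` (the pinned alphabet is {A, C, G, T, N, -}); the consensus
caller ignores N exactly as it would a het's ambiguity code. Same seed,
same bytes: the generator is fully deterministic given its seed, and the
emitted VCF/popmap/.loci re-read through the package's own readers
reproduce the in-memory objects field-for-field.

**What passing tests show — and don't.** The generator produces unlinked
loci (beyond within-contig jitter), MCAR missingness, Hardy–Weinberg
binomial dosages and clean biallelic calls. Real GBS data violate all four:
missingness tracks restriction-site polymorphism and depth (not MCAR),
polyploid dosages are not Binomial(2, ·), paralog collapse creates
pseudo-heterozygosity, and allele dropout biases MAF. Recovery on synthetic
data validates the *algorithms* (filters count what they should; the
subspace/ALS machinery recovers planted structure; the detector finds
exactly the planted markers), not the biological reliability of any
particular empirical dataset.

## Problem sizes and determinism

The validation suite runs at deliberately desk-scale sizes chosen as the
package's own test design: 200 random datasets of up to 50 × 200 for
filter-oracle equivalence, 5,000 background SNPs for planted-marker
recovery, n = 100 / m = 1,000 / K = 3 / F = 0.2 / α = 0.1 for admixture
recovery (mean absolute membership error ≤ 0.10 after permutation
alignment), and K sweeps to 6–8. Every stochastic step — simulation,
Dirichlet initialisation — flows from caller-supplied seeds; the pipeline
driver writes an MD5 manifest of all artifacts and identical inputs plus
seed yield identical manifests.

## Known limitations

- Diploid-coded calls only; true polyploid dosage models are out of scope.
- Mean imputation shrinks admixed individuals toward the global centroid
  when missingness is heavy; the package reports (rather than hides) that
  imputation occurred and declines to estimate K in that case.
- The MAF stage's two modes (frequency vs count) differ at small sample
  sizes; neither is asserted to be "the" convention of any external tool.
- Consensus extraction assumes within-contig positions index alignment
  columns, as is the case for assembler-derived loci; it does not realign.
- No depth/quality-aware filtering and no Hardy–Weinberg filter — the
  latter is not meaningful for diploid-coded polyploid calls.
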