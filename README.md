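# gbspop

Post-assembly population genomics for GBS/RAD SNP data from polyploid
species complexes.

Reduced-representation sequencing (GBS, RAD-seq) of taxonomically difficult
plant groups — sea-lavenders and their relatives being a canonical case —
yields thousands of short contigs, each carrying a handful of linked SNPs,
called across tens of individuals from several putative species. Because the
individuals are often polyploid, genotype calls come out diploid-coded and
unphased, which rules out the usual likelihood-based structure analyses and
F-statistics. `gbspop` implements the analysis stages that remain valid in
that regime:

- **Ordered filtering cascade** — per-individual missingness (drop
  individuals with more than a fraction *t*₁ missing), per-site completeness
  (keep sites typed in at least a fraction *t*₂ of remaining individuals),
  minor allele frequency (keep sites with MAF ≥ *t*₃, or with a minimum
  minor-allele *count*), then linkage thinning to the single SNP closest to
  each contig's centre — with per-stage accounting. Two built-in profiles:
  `"species"` (*t*₁ = 0.40) and `"lvu_lma"` (*t*₁ = 0.10), both with
  *t*₂ = 0.80 and *t*₃ = 0.01.
- **PCA ordination** of the centred dosage matrix (mean-imputed), with
  explained-variance percentages per component.
- **Likelihood-free admixture estimation**. Dosages are modelled as
  *x*ᵢⱼ ~ Binomial(2, *f*ᵢⱼ) with a rank-*K* frequency matrix *F* = *P Q*ᵀ,
  where rows of *Q* (individual membership proportions) live on the
  probability simplex and *P* holds per-cluster allele frequencies.
  Individual-specific frequencies are estimated by projecting dosage/2 onto
  the top-*K* eigenvectors of the samples' noise-adjusted second-moment
  matrix, then factored by constrained alternating least squares (clipping
  for *P*, exact simplex projection for *Q* rows). No genotype likelihood is
  ever evaluated, so diploid-coded polyploid calls do not bias the fit.
- **Fixed-difference detection** — sites whose observed allele sets are
  disjoint between two labelled groups (every call in group A homozygous for
  one allele, every call in group B homozygous for the other; one
  heterozygote disqualifies) — and extraction of each marker's flanking
  consensus from the per-locus alignments to FASTA, for downstream homology
  searches.
- **A seeded synthetic-data generator** (Balding–Nichols population
  frequencies, Pritchard–Stephens–Donnelly admixture, MCAR missingness,
  planted diagnostic markers) that produces VCF / popmap / `.loci` files plus
  the ground truth needed to validate every stage.

## Worked example

```r
library(gbspop)

cfg <- sim_config(n_populations = 3, samples_per_population = 20,
                  n_loci = 500, snps_per_locus = 1:3,
                  n_planted_fixed_differences = 5, seed = 42)
sim <- simulate_dataset(cfg)
sim$dataset
#> variant_dataset: 976 records x 60 samples (500 contigs)

res <- apply_cascade(sim$dataset, filter_config(), sim$loci)
res$report
#> filter cascade report:
#>                   stage n_samples_in n_samples_out n_sites_in n_sites_out
#>  individual_missingness           60            60        976         976
#>       site_completeness           60            60        976         975
#>                     maf           60            60        975         952
#>             thin_center           60            60        952         494
```

Three populations of 20, none above 40% missing, so no individual is
dropped; one site fails the 80% completeness bar, 23 are monomorphic or
below 1% MAF, and centre-thinning leaves one SNP per contig (494 contigs
still carry a SNP after the earlier stages).

```r
pca <- run_pca(build_dosage_matrix(res$dataset), 2)
pca
#> pca_result: 60 samples, 2 components
#> explained variance (%): 14.52 13.24
```

With three equally drifted populations (F = 0.2), PC1 and PC2 each pick up
one between-population contrast and explain similar variance fractions.

```r
seg <- find_fixed_differences(sim$dataset, sim$popmap, "pop1", "pop2")
seg
#>        contig pos alleles_a alleles_b bases_a bases_b n_calls_a n_calls_b
#> 1 locus_00001  35         0         1       A       G        20        20
#> 2 locus_00043  14         0         1       C       G        20        20
#> 3 locus_00210  14         0         1       C       T        20        20
#> 4 locus_00215  27         0         1       G       C        20        20
#> 5 locus_00498  19         0         1       G       C        20        20

cons <- consensus_for_report(seg, sim$loci)
cons[[1]]
#> consensus_sequence locus_00001: 100 bp, focal SNP at 35
export_fasta(cons, "markers.fasta")
```

Exactly the 5 planted diagnostic markers are recovered — no background site
among the other 971 is fully segregated — and each marker's flanking
consensus is written to FASTA with its focal-SNP offset in the header.

The whole chain (filter → PCA → admixture sweep → segregation → consensus,
with a checksummed artifact manifest) is also available as one call,
`run_pipeline()`, or from the shell via
`Rscript inst/scripts/gbspop-pipeline.R`.

## Scope

The package operates downstream of assembly: demultiplexing, locus assembly
(ipyrad and kin), phylogenetics, and homology annotation of candidate
markers are out of scope. Genotypes are handled strictly as diploid-coded
calls; true polyploid genotype arities are rejected rather than silently
collapsed (see the methods vignette, `vignettes/gbspop-methods.Rmd`).
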