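Package: gbspop
Title: SNP Filtering, Ordination and Likelihood-Free Admixture for
    Reduced-Representation Data from Polyploid Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-assembly stages of genotyping-by-sequencing
    (GBS/RAD) population genomics in species complexes where genotype calls
    are diploid-coded from polyploid individuals. Provides an ordered SNP
    filtering cascade (per-individual missingness, per-site completeness,
    minor allele frequency) with one-SNP-per-locus centre thinning, dosage
    matrix construction, principal components analysis with
    explained-variance reporting, likelihood-free admixture estimation via
    latent-subspace projection followed by constrained alternating least
    squares, detection of SNPs fully segregated between two labelled groups
    with flanking-region consensus extraction to FASTA, and a seeded
    Balding-Nichols/PSD synthetic-data generator with ground truth for
    method validation. A pipeline driver chains the stages and writes a
    checksummed artifact manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
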