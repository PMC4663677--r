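Package: riskeqtl
Title: Two-Stage Risk-SNP-Anchored cis-eQTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps candidate target genes for GWAS risk variants by a two-stage
    cis-eQTL procedure: risk SNPs are expanded into linkage-disequilibrium
    (LD) sets and merged into unique risk intervals; normalized expression is
    regressed on minor-allele dosage with histology and expression principal
    component covariates inside interval windows (stage 1) and gene windows
    (stage 2); peak-conditioned rescans classify genes into single versus
    multiple regulatory domains; and target genes are grouped by the LD
    between the risk SNP and the peak eQTL SNP. Includes genotype quality
    control (call rate, exact Hardy-Weinberg test, minor allele frequency),
    Tracy-Widom screening of genotype principal components, count
    normalization with smooth GC/length offsets, a negative binomial
    sensitivity model, and a synthetic-data generator with LD-structured
    genotypes and planted cis effects for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
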