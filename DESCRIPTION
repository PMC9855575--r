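Package: poptrace
Title: Population-Genomic Tracing of Introduced Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling population genomics for tracing the origin of
    recently introduced populations from multi-sample SNP data. Provides VCF
    genotype input/output with missing-rate and minor-allele-frequency site
    filters; sliding-window Watterson's theta, nucleotide diversity and
    Tajima's D; pairwise FST (Weir-Cockerham and Hudson estimators); PCA with
    Patterson scaling; individual p-distances and neighbour-joining trees;
    directional relative-migration networks (divMigrate-style, from Gst,
    Jost's D or Nm) with bootstrap support; linkage-disequilibrium decay
    curves; and a reduction-of-diversity (ROD) selection scan with
    empirical-quantile outlier windows, candidate-region merging and gene
    overlap. Includes a synthetic-data generator emulating a multi-population
    founder-event design (Balding-Nichols drifted natives plus a bottlenecked
    introduction, and a forward Wright-Fisher simulator for linked loci) so
    every statistic can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
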