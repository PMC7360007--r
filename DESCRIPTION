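Package: badhap
Title: Gene Haplotype Characterization and Diagnostic Tag-SNP Design for
    the Rice BADH2 Aroma Gene
Version: 0.1.0
Authors@R:
    person("Rice", "Marker Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes haplotype diversity across a gene region from a
    samples-by-SNP allele-call matrix (or VCF interval), following the
    workflow used to develop breeder-facing KASP markers for the rice
    fragrance gene BADH2: heterozygous-call recoding and missingness
    filtering, Hamming-radius haplotype grouping with rare and unclassified
    labeling, subgroup assignment, minimal discriminating tag-SNP selection
    (greedy plus an exhaustive oracle), flanking diagnostic-SNP discovery,
    and marker validation via concordance with a functional indel assay,
    genotyping-job QC, and haplotype-phenotype (2AP) association. Includes
    a synthetic panel generator with a truth ledger for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
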