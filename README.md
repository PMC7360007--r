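# badhap

Gene haplotype characterization and diagnostic tag-SNP design for the rice
fragrance gene *BADH2*.

## What problem this solves

Aroma in rice is controlled by loss-of-function alleles of *BADH2*
(chromosome 8); the predominant functional allele is an 8-bp deletion in
exon 7. Direct indel assays misbehave on some germplasm, so applied
breeding programs want a single KASP-friendly SNP in perfect linkage
disequilibrium with the deletion, found and validated through haplotype
analysis of a large diversity panel. `badhap` implements that workflow for
breeders and rice geneticists as a tested R pipeline:

* **Haplotype grouping** from a samples x SNPs allele-call matrix (VCF
  interval or matrix-TSV): het recoding, missingness filtering, greedy
  leader clustering at Hamming radius *r* (default 3), rare (`R`) and
  unclassified (`U`) classes, subgroup letters, subpopulation cross-tabs.
* **Minimal discriminating tag-SNP selection** over group consensus
  vectors — greedy set-cover with an exhaustive oracle
  (`brute_force_min()`) for verification — plus sample calling with
  merged-class (`7/9`) and ambiguity handling.
* **Diagnostic-SNP discovery**: sites whose allele is private to and fixed
  in a target haplotype group and invariant elsewhere, scanning the gene
  then +/- 10 kb flanks.
* **Marker validation**: concordance/perfect-LD against a functional indel
  call set, genotyping-job call-rate and reproducibility QC, and
  haplotype - 2AP (ppm) phenotype association.
* **A synthetic panel generator** (`simulate_panel()`) with a truth ledger,
  emulating the published 3K-genomes haplotype structure (11 founders at
  the published per-subpopulation frequencies, n = 2932, light het/missing
  noise, one founder carrying the deletion plus a flanking SNP in perfect
  LD with it, bimodal 2AP phenotype).

The published group-level tables ship as in-package fixtures
(`badh2_3k_panel()`, `badh2_us_panel()`, and plain-text copies under
`inst/extdata/`).

## Worked example

```r
library(badhap)

## the published 11 consensus haplotypes over the 9 assay SNPs
gm <- badh2_consensus_gm()
cm <- gm$calls

## minimal discriminating tag set (exhaustive oracle)
brute_force_min(cm)
#> <tag_set> 8 sites: Chr8:20374951, Chr8:20380447, Chr8:20380886,
#>   Chr8:20381308, Chr8:20381787, Chr8:20382286, Chr8:20382480, Chr8:20384350
#>   resolved pairs: 54, unresolved: 1
```

Eight SNPs suffice to tell the eleven haplotype groups apart; the single
unresolved pair is Hap 7 / Hap 9, whose consensus vectors are identical
over all nine sites — exactly the published assay design.

```r
## which single SNP is diagnostic of the aromatic haplotype (Hap 6)?
p0  <- grouping_params(max_mismatch = 0)
cls <- group_haplotypes(preprocess(gm, p0), p0)
cmr <- consensus_matrix(cls)
target <- as.integer(rownames(cmr)[cmr[, "Chr8:20374951"] == "T"])
cand <- find_diagnostic(gm, cls, target, badh2_gene_interval())
cand[cand$strict, c("site", "target_allele", "background_allele", "provenance")]
#>            site target_allele background_allele provenance
#> 1 Chr8:20374951             T                 G      flank
```

The flanking SNP at Chr8:20,374,951 (T in the aromatic haplotype, G in all
others) is the unique strict candidate — the trait marker a breeding
program would order as a KASP assay.

```r
## full pipeline on a synthetic panel with known truth
cfg   <- simulation_config()             # 11 founders, n = 2932
panel <- simulate_panel(cfg, seed = 1)
pp    <- preprocess(subset_region(panel$genotypes, cfg$gene_interval))
cls   <- flag_unclassified(pp, label_rare(group_haplotypes(pp)))
score_recovery(cls, panel$ledger)$misassignment
#> [1] 0.001447178
```

## Command line

An installed launcher (`exec/badhap`) exposes the pipeline:

```sh
badhap simulate --config config.json --out-dir panel/ --seed 1
badhap classify --genotypes panel/genotypes.tsv --meta panel/metadata.tsv \
       --region Chr8:20380000-20386499 --out report.tsv --json cls.json
badhap select-tags --classification cls.json --out tags.json
badhap find-diagnostic --genotypes panel/genotypes.tsv \
       --classification cls.json --target-group 6 \
       --gene Chr8:20380000-20386499 --flank 10000 --out candidates.tsv
badhap validate --calls calls.tsv --reference panel/reference_marker.tsv \
       --mapping T=del,G=nodel --out concordance.json
```

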