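---
title: "Gene haplotype characterization and diagnostic tag-SNP design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene haplotype characterization and diagnostic tag-SNP design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badhap)
```

## The problem

Grain aroma in rice is essentially monogenic: loss-of-function alleles of
*BADH2* (betaine aldehyde dehydrogenase 2, chromosome 8) let
2-acetyl-1-pyrroline (2AP) accumulate, and an 8-bp exon-7 deletion is the
predominant functional allele. Direct assays on the indel are unreliable on
some germplasm, so breeding programs instead want a *single SNP in perfect
linkage disequilibrium with the deletion*, discovered and validated through
gene-haplotype analysis of a large diversity panel. badhap implements that
workflow as a reusable, tested pipeline:

1. **Haplotype grouping** of inbred-line SNP calls across the gene region,
2. **Minimal tag-SNP selection** that discriminates the haplotype groups,
3. **Diagnostic-SNP discovery** in the gene and its flanks for one target
   (aromatic) haplotype,
4. **Validation**: concordance with the functional indel assay, genotyping
   call-rate/reproducibility QC, and haplotype-2AP association.

Because the underlying accession-level panels are not redistributable, the
package ships (a) the published group-level tables as fixtures and (b) a
synthetic-panel generator with a truth ledger, and the test suite
establishes recovery on the synthetic world plus exact reproduction of the
published table arithmetic.

## Haplotype grouping

Inbred lines are effectively homozygous, so a sample's call vector over the
gene's SNPs *is* its haplotype; no phasing or EM-style inference is done
(and none is intended). The procedure, in order:

* **Het recoding** — heterozygous calls become missing (`preprocess()`);
  residual heterozygosity in an inbred panel is mostly technical.
* **Site filtering** — sites with more than `max_missing_per_site` missing
  calls (default 100, an absolute count; the rule is strictly "greater
  than", so a site at exactly the threshold survives) are removed.
* **Grouping** (`group_haplotypes()`) — identical vectors are collapsed,
  distinct vectors are sorted by carrier count (ties broken
  lexicographically), and greedy leader clustering assigns each vector to
  the first group whose *founder* vector is within `max_mismatch`
  (default 3) mismatches over mutually non-missing sites. Distances are
  only evaluable with at least `min_overlap` shared sites (default 50% of
  retained sites); a vector with insufficient overlap founds its own group
  and is later swept into R or U. Collapse-then-sort makes the result
  invariant to input sample order, which a naive incremental scan is not.
* **Rare labeling** (`label_rare()`) — groups below `min_group_fraction`
  of the panel go to class R. The default is 1%, not the sometimes-quoted
  5%: a 5% rule is self-contradictory for reference panels that retain
  ~1.1% and ~1.8% haplotype groups, while every retained group in the
  reference table clears 1%. The 5% variant is one parameter away.
* **Unclassified labeling** (`flag_unclassified()`) — samples with too
  much missing data over the key SNPs (default: all retained sites, more
  than 100 missing) go to class U. Which SNPs are "key" is configurable
  because the reference procedure does not pin them down; when a tag set
  exists it is the natural choice.
* **Subgroups** (`assign_subgroups()`) — within a group, identical-vector
  classes at >= 1% of the group get letters A, B, C, ... by descending
  size; the rest pool into X.

Groups are numbered by descending size (group 1 = most common haplotype).
Consensus vectors take the per-site majority allele with alphabetical
tie-break; an all-missing site yields a missing consensus.

## Tag-SNP selection

Discrimination is exact-match over group consensus vectors — deliberately
not an r²-based tagger. `greedy_select()` repeatedly picks the site
separating the most still-unseparated group pairs; ties break toward
higher group-level minor allele frequency (MAF computed *across the group
consensus vectors, unweighted by group size*), then toward lower position.
The reference procedure sorts candidates by exactly that MAF, which we
read as the tie-break inside sequential selection rather than a
pre-filter. A redundancy post-pass (disable with `prune = FALSE`) drops
any selected site whose removal changes nothing. Sites with a missing
consensus in any group are ineligible.

`brute_force_min()` is the independent oracle: exhaustive subset
enumeration in increasing cardinality, lexicographic by position within a
cardinality — feasible for the <= 25 candidate sites where it is used. On
the published nine-SNP consensus matrix the oracle confirms a minimum of
**8 sites**, with exactly one unresolvable pair (the two groups whose
vectors are identical), matching the published assay design. Note the
selection *order* of the published assay cannot be re-derived from the
nine-site table alone (the original selection ran over 255 genic SNPs),
so only set size and resolution are asserted.

`apply_tags()` scores samples against the group codes: groups with
identical codes merge into classes labeled like `7/9`; a sample whose
missing calls leave several classes open is `ambiguous`; a complete
profile matching nothing is `novel`. This reproduces the published
handling of a failed assay: without SNP9, Hap 1 and Hap 10 collide and
samples are called as the merged class.

## Diagnostic SNPs

`find_diagnostic()` looks for a site whose allele is fixed in the target
group and at a single, different, fixed allele in all other groups
("private and invariant"), scanning the gene first and then up to
`flank_bp` (default 10 kb) on either side. Rare and unclassified samples
are excluded from the background by default (`include_rare = FALSE`)
because uniqueness is assessed across the defined haplotype groups; a
multi-allelic background disqualifies a strict candidate. `min_purity`
(default 1) admits accession-level noise when relaxed. Strict candidates
rank first, by proximity to the gene.

One geometry wrinkle: the published flanking diagnostic SNP is described
as 7,908 bp from the gene, but the genic assay SNPs span
20,380,447-20,384,350 while the diagnostic sits at 20,374,951 — 5,496 bp
from that span. The annotated boundary implied by 7,908 bp would exclude
several "genic" SNPs. The package does not adjudicate: the fixture gene
interval is the span of the genic assay SNPs, and the synthetic world
plants its diagnostic exactly 7,908 bp upstream of its gene start, so the
published distance is reproduced where the geometry is under our control.

## Validation

* `concordance()` maps candidate SNP alleles to functional-marker states
  through an explicit mapping (e.g. `T = del`, `G = nodel`) and compares
  sample by sample; pairs with either call missing are excluded from the
  denominator but counted. "Perfect LD" is operationalized as 100%
  concordance with at least 30 compared samples — the reference analysis
  reports a perfect match without a floor, but a floor keeps tiny panels
  from claiming perfection vacuously.
* `assay_qc()` counts failed and ambiguous reactions as missing
  (itemized, since ambiguous clustering is a distinct failure mode of
  fluorescence assays) and computes reproducibility over samples with at
  least two non-missing calls. Both metrics are order-invariant.
* `aroma_association()` classifies each group against a ppm threshold:
  aromatic if every phenotyped member exceeds it, non-aromatic if none
  does, mixed otherwise; `perfect_association` requires exactly one
  aromatic group and no mixed ones. The default threshold of **0.2 ppm**
  is the approximate midpoint of the empirical gap between non-carrier
  maxima (~0.079 ppm) and carrier minima (~0.356 ppm); the reference
  analysis classifies by inspection, not by a stated cutoff. The standard
  error is the sample SD divided by sqrt(n).

## The synthetic world

`simulation_config()` states the world; its defaults are the conditions
the analysis assumes, not tuning dials:

| parameter | default | why |
|---|---|---|
| `n_sites` | 255 | genic SNPs surviving the missingness filter in the reference panel |
| `flank_sites` / `flank_span` | 20 / 10 kb | flank search window of the diagnostic scan |
| founder frequencies | published 3K per-subpopulation haplotype frequencies | the panel being emulated |
| `subpop_sizes` | 3K subpopulation totals (n = 2932) | same |
| `het_rate`, `missing_rate` | 0.5%, 1% | light call noise; chosen for testability (the reference panel's error model is unpublished) |
| `mutation_noise` | 0 | allele flips are not part of the stated noise world; a flip at the diagnostic site would contradict the observed perfect LD |
| `replicate_sd` | 0.02 ppm | small within-sample GC replicate noise; the published 0.058 value is a between-sample SE |
| carrier / non-carrier 2AP | U(0.356, 3.165) / U(0, 0.079) | published ranges; only range/mean/SE are published, so uniform is the assumption-lightest bounded choice |
| `diagnostic_offset_bp` | 7,908 | the published diagnostic-SNP geometry |

Design choices worth spelling out:

* **Founder separation.** Founder vectors are random biallelic columns,
  rejected until every pair is more than `2 * cluster_radius` mismatches
  apart (validated, with a hard error otherwise), so the Hamming-radius
  grouping is identifiable.
* **Anchor constraint.** At every non-diagnostic site the carrier
  founder's allele must be shared with an *anchor* founder (overall
  frequency >= 1.5%). The smallest emulated haplotype sits at 1.06% — on
  the wrong side of a coin flip from the 1% rare threshold — and when it
  drops into R it leaves the diagnostic background; without the
  constraint, sites it alone shared with the carrier would become
  spurious strict diagnostics. The constraint encodes the stated claim
  "no other site is diagnostic" at the level of the *retained* groups.
* **Recombinants.** The residual per-subpopulation frequency mass becomes
  crossovers of two non-carrier founders with the breakpoint inside the
  gene region: a flank-only crossover would not create a new gene
  haplotype, and excluding the carrier from recombination preserves the
  stated perfect LD between the diagnostic allele and the deletion (the
  aromatic haplotype is treated as young and unrecombined, which is the
  scenario the validation emulates).
* **Phenotype noise is mean-centered** across replicates, so the
  tabulated sample mean (the mean of replicates, per the data contract)
  equals the drawn class value and respects the class ranges exactly;
  truncation at zero can only raise a non-carrier mean, never push it
  above the class maximum in practice.
* **Noise-free reference marker.** The indel call table carries no noise,
  by construction: it models the gel-based assay used as ground truth.

What a green recovery test establishes: under founder-structured panels
with light, independent het/missing noise, the pipeline recovers the
planted partition (misassignment <= 1%), the planted diagnostic site and
nothing else, perfect concordance, and perfect phenotype association.
What it does not establish: behavior under coalescent LD structure,
correlated or batch-structured missingness, genotyping error that flips
alleles, or heterozygous residual segregation — none of which the
generator emulates.

## Numerical conventions and degenerate inputs

* Internal coordinates are 0-based half-open; everything user-facing is
  1-based (reports, site ids `chrom:pos`, region strings
  `Chr8:100-200`).
* Report rounding is half-away-from-zero (`round_half_away()`), matching
  printed-table conventions rather than R's banker's rounding.
* Ties: consensus ties break alphabetically; greedy-selection ties break
  by MAF then position; subgroup and group ordering ties break
  lexicographically / by founding order. All deterministic.
* Degenerate inputs: an empty region subset is a flagged empty matrix,
  not an error; dropping *all* sites in `preprocess()` is an error
  advising a threshold change; a single haplotype group yields an empty
  tag set; a target group identical to the background yields zero
  diagnostic candidates.
* Seeds: every stochastic function takes an explicit seed; identical
  config + seed is byte-identical, and founder geometry has its own
  `founder_seed` so panel draws can vary under a fixed world.

## Known limitations

* The greedy tag selector is not guaranteed minimal (the oracle is, and
  the suite asserts greedy never beats it and resolves the same pairs);
  on the published matrix both reach 8.
* The 5%-vs-1% rare-threshold ambiguity in the reference procedure is
  resolved by configuration, not adjudication.
* No LD statistics (r², D'), no segregation-distortion tests, no primer
  design: marker *placement* and *validation logic* only.
* VCF support covers hard diploid GT calls; genotype-quality filtering is
  deliberately out of scope (the reference analysis took database calls
  as-is).
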