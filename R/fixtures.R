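# Published reference data for the BADH2 (LOC_Os08g32870) gene region,
# IRGSP-1.0 coordinates on chromosome 8. These are the consensus haplotype
# vectors and subpopulation counts reported for the 3,000 Rice Genomes
# (SNP-Seek "3kAll") panel, and the haplotype/2AP summary reported for a
# 369-accession U.S. breeding germplasm panel. They serve as in-package
# fixtures for the marker-design workflow.

# Assay SNP positions in assay order SNP1..SNP9 (SNP1 is the flanking
# diagnostic SNP; SNP2-SNP9 lie within the gene).
BADH2_SNP_POS <- c(
  SNP1 = 20374951L, SNP2 = 20381787L, SNP3 = 20382161L, SNP4 = 20384350L,
  SNP5 = 20382286L, SNP6 = 20380447L, SNP7 = 20381308L, SNP8 = 20380886L,
  SNP9 = 20382480L)

BADH2_HAP_VECTORS <- c(
  Hap1  = "GAGGAGGTC",
  Hap2  = "GTAGACGTC",
  Hap3  = "GAGAACCTC",
  Hap4  = "GAGGAGCTC",
  Hap5  = "GTGGACCTC",
  Hap6  = "TTAGACCTC",
  Hap7  = "GAGGACCTC",
  Hap8  = "GAGGGGGTC",
  Hap9  = "GAGGACCTC",
  Hap10 = "GAGGAGGTT",
  Hap11 = "GAGGAGCCC")

BADH2_SUBPOPS <- c("aus", "indica", "admix", "aromatic",
                   "temperate japonica", "tropical japonica",
                   "japonica admixture")

# Haplotype group x subpopulation accession counts in the 3K panel,
# including the rare (R) and unclassified (U) classes. Margins: 2932 total.
BADH2_3K_COUNTS <- matrix(
  c(  1, 749, 12,  0,   1, 121,   8,
      2, 148, 19, 26, 215, 281,  64,
      0, 201,  1,  0,   1,   0,   0,
      9, 183,  5,  0,   0,   0,   0,
      1, 186,  5,  2,   0,   1,   0,
      0,  65,  9, 38,   3,  53,   3,
     97,  11,  6,  0,   0,   0,   0,
      0,  89,  2,  1,   0,   2,   0,
     63,  13,  6,  3,   0,   0,   0,
      1,  39,  6,  0,   2,   4,   0,
      3,  22,  6,  0,   0,   0,   0,
     22,  42,  6,  2,   0,   2,   0,
      2,  41, 16,  3,   2,   3,   2),
  nrow = 13, byrow = TRUE,
  dimnames = list(c(paste0("Hap", 1:11), "R", "U"), BADH2_SUBPOPS))

#' Published BADH2 haplotype characterization of the 3K rice genomes panel
#'
#' Reference data for the BADH2 gene region: the nine assay SNP positions
#' (IRGSP-1.0, chromosome 8), the eleven haplotype-group consensus allele
#' vectors over those SNPs, and the haplotype-by-subpopulation accession
#' counts of the 2,932-accession 3K diversity panel, including the rare
#' (`R`) and unclassified (`U`) classes.
#'
#' @return A list with elements
#'   * `positions`: named integer vector, assay ids `SNP1..SNP9` to 1-based
#'      positions;
#'   * `snp_ids`: site ids `Chr8:pos` in assay order;
#'   * `haplotypes`: 11 x 9 character matrix of consensus alleles
#'      (rows `Hap1..Hap11`, columns in assay order `SNP1..SNP9`);
#'   * `counts`: 13 x 7 integer matrix of accession counts
#'      (rows `Hap1..Hap11`, `R`, `U`; columns subpopulations);
#'   * `subpopulations`: the declared subpopulation label set;
#'   * `n_total`: 2932.
#' @examples
#' ref <- badh2_3k_panel()
#' colSums(ref$counts)   # subpopulation sizes
#' @export
badh2_3k_panel <- function() {
  hap <- do.call(rbind, strsplit(BADH2_HAP_VECTORS, ""))
  dimnames(hap) <- list(names(BADH2_HAP_VECTORS), names(BADH2_SNP_POS))
  list(positions = BADH2_SNP_POS,
       snp_ids = paste0("Chr8:", BADH2_SNP_POS),
       haplotypes = hap,
       counts = BADH2_3K_COUNTS,
       subpopulations = BADH2_SUBPOPS,
       n_total = sum(BADH2_3K_COUNTS))
}

#' The 3K consensus vectors as a genotype matrix
#'
#' The eleven published consensus haplotype vectors over the nine assay
#' SNPs, packaged as a [genotype_matrix()] with one "sample" per haplotype
#' group (sites sorted by position, as always).
#'
#' @return A `genotype_matrix` with samples `Hap1..Hap11`.
#' @export
badh2_consensus_gm <- function() {
  ref <- badh2_3k_panel()
  genotype_matrix(ref$haplotypes, chrom = "Chr8", pos = ref$positions)
}

#' Published U.S. breeding-panel haplotype and 2AP summary
#'
#' Haplotype characterization of a 369-accession U.S. rice breeding panel
#' scored with the eight converted assays (`SNP1..SNP8`; the SNP9 assay
#' failed to convert, so Hap 1 and Hap 10 are merged and Hap 7 / Hap 9 are
#' reported as the merged class `7/9`), with replicated 2AP phenotype
#' summaries (ppm) for the phenotyped subset of 39 accessions.
#'
#' Note: the published U.S.-panel code for Hap 2 disagrees with the 3K
#' consensus vector at SNP7 (`C` vs `G`); the 3K vector is taken as
#' canonical throughout the package and the printed code is kept verbatim
#' in the `code_printed` column.
#'
#' @return Data frame with one row per observed haplotype class: `hap`,
#'   `number` (accessions in the panel), `n_phenotyped`, `range_min`,
#'   `range_max`, `mean_2ap`, `se_2ap` (ppm), `aromatic`, `code_printed`
#'   (allele string over SNP1-SNP8 as printed).
#' @export
badh2_us_panel <- function() {
  data.frame(
    hap = c("1", "2", "3", "5", "6", "7/9"),
    number = c(181L, 134L, 11L, 5L, 27L, 11L),
    n_phenotyped = c(5L, 9L, 2L, 3L, 17L, 3L),
    range_min = c(0, 0, 0, 0, 0.356, 0),
    range_max = c(0, 0.079, 0, 0.001, 3.165, 0.009),
    mean_2ap = c(0, 0.009, 0, 0.0002, 1.30, 0.003),
    se_2ap = c(0, 0.005, 0, 0.0002, 0.058, 0.002),
    aromatic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    code_printed = c("GAGGAGGT", "GTAGACCT", "GAGAACCT", "GTGGACCT",
                     "TTAGACCT", "GAGGACCT"),
    stringsAsFactors = FALSE)
}

#' Gene interval spanned by the genic assay SNPs
#'
#' The tight 1-based interval on chromosome 8 covering the in-gene assay
#' SNPs (`SNP2..SNP9`). The flanking diagnostic SNP (`SNP1`, 20,374,951)
#' lies upstream of this span; relative to the annotated gene boundary it
#' was reported 7,908 bp away.
#'
#' @return `list(chrom, start, end)`, 1-based inclusive.
#' @export
badh2_gene_interval <- function() {
  pos <- BADH2_SNP_POS[-1]
  list(chrom = "Chr8", start = min(pos), end = max(pos))
}
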