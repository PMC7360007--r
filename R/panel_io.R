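#' Read a gene-region genotype matrix from VCF or matrix-TSV
#'
#' VCF input is parsed with `VariantAnnotation`; only SNP records (single
#' nucleotide REF, all single-nucleotide ALTs) are retained — indels are
#' excluded, since functional indels are handled as a separate
#' reference-marker call table. Diploid heterozygous genotypes map to the
#' het code, absent/uncalled genotypes to missing; multi-allelic records are
#' kept with all observed alleles. Phased and unphased separators are
#' treated identically.
#'
#' The matrix-TSV dialect has a first column of sample ids, a header of site
#' ids `chrom:pos`, and single-character cells with `H` = het and `.` or
#' `N` = missing.
#'
#' @param path Input file.
#' @param region Optional interval (`"Chr8:100-200"`, 1-based inclusive, or
#'   `list(chrom, start, end)`); only sites within it are retained. An empty
#'   selection yields an empty matrix, not an error.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, region = NULL,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  gm <- if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_tsv(path)
  if (!is.null(region)) gm <- subset_region(gm, region)
  gm
}

read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- lapply(rr$ALT, as.character)
  snp <- nchar(ref) == 1L & ref %in% NUCLEOTIDES &
    vapply(alt, function(a)
      length(a) >= 1L && all(nchar(a) == 1L & a %in% NUCLEOTIDES),
      logical(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF '", path, "' has no GT genotype field")
  gt <- gt[snp, , drop = FALSE]
  ref <- ref[snp]; alt <- alt[snp]
  pos <- IRanges::start(rr)[snp]
  chrom <- as.character(GenomicRanges::seqnames(rr))[snp]

  n_sites <- length(ref)
  samples <- colnames(gt)
  calls <- matrix(NA_character_, length(samples), n_sites,
                  dimnames = list(samples, NULL))
  alleles <- character(n_sites)
  for (j in seq_len(n_sites)) {
    site_alleles <- c(ref[j], alt[[j]])
    alleles[j] <- paste(site_alleles, collapse = ",")
    idx <- strsplit(gt[j, ], "[/|]")
    calls[, j] <- vapply(idx, function(g) {
      g <- g[g != "."]
      if (length(g) == 0L) return(NA_character_)
      u <- unique(g)
      if (length(u) > 1L) return(HET_CALL)
      site_alleles[as.integer(u) + 1L]
    }, character(1))
  }
  genotype_matrix(calls, chrom, pos, alleles)
}

read_genotypes_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("malformed matrix TSV '", path, "': ",
                             conditionMessage(e)))
  if (ncol(tab) < 2L)
    stop("matrix TSV '", path, "' needs a sample column plus >= 1 site")
  ids <- colnames(tab)[-1]
  m <- regmatches(ids, regexec("^(.+):([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("matrix TSV '", path, "': header ids not 'chrom:pos': ",
         paste(ids[bad], collapse = ", "))
  chrom <- vapply(m, `[`, character(1), 2)
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  calls <- as.matrix(tab[, -1, drop = FALSE])
  rownames(calls) <- tab[[1]]
  calls[calls %in% c(".", "N", "")] <- NA_character_
  calls <- toupper(calls)
  genotype_matrix(calls, chrom, pos)
}

#' Write a genotype matrix to VCF or matrix-TSV
#'
#' Writing then reading reproduces calls, positions and sample order
#' exactly. For VCF, het calls are emitted as `0/1`, which requires at least
#' two declared alleles at the site.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- gm$calls
    out[is.na(out)] <- "."
    tab <- data.frame(sample = rownames(out), out, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=badhap",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(gm$calls)),
                       collapse = "\t")), con)
    for (j in seq_len(ncol(gm$calls))) {
      a <- strsplit(gm$sites$alleles[j], ",", fixed = TRUE)[[1]]
      cc <- gm$calls[, j]
      if (any(cc == HET_CALL, na.rm = TRUE) && length(a) < 2L)
        stop("cannot encode het call at ", gm$sites$id[j],
             ": fewer than two declared alleles")
      if (length(a) == 0L) a <- "N"
      gt <- ifelse(is.na(cc), "./.",
                   ifelse(cc == HET_CALL, "0/1",
                          paste0(match(cc, a) - 1L, "/", match(cc, a) - 1L)))
      writeLines(paste(c(gm$sites$chrom[j], gm$sites$pos[j],
                         gm$sites$id[j], a[1],
                         if (length(a) > 1L)
                           paste(a[-1], collapse = ",") else ".",
                         ".", ".", ".", "GT", gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read sample metadata (subpopulation labels)
#'
#' @param path TSV with header columns `sample_id` (or `sample`) and
#'   `subpopulation`; any further columns are kept as free-form attributes.
#' @param known_subpops Optional declared label set; labels outside it are
#'   preserved verbatim and reported via a warning.
#' @return Data frame with columns `sample_id`, `subpopulation`, plus extras.
#' @export
read_metadata <- function(path, known_subpops = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  id_col <- intersect(c("sample_id", "sample"), colnames(tab))[1]
  if (is.na(id_col) || !"subpopulation" %in% colnames(tab))
    stop("metadata TSV needs 'sample_id' (or 'sample') and ",
         "'subpopulation' columns")
  names(tab)[names(tab) == id_col] <- "sample_id"
  dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(dup))
    stop("duplicate sample ids in metadata: ", paste(dup, collapse = ", "))
  if (!is.null(known_subpops)) {
    unknown <- setdiff(unique(tab$subpopulation), known_subpops)
    if (length(unknown))
      warning("unknown subpopulation labels kept verbatim: ",
              paste(unknown, collapse = ", "))
  }
  tab
}

#' Read a replicated phenotype table (2AP concentrations, ppm)
#'
#' @param path TSV with a `sample_id` (or `sample`) column and one or more
#'   replicate columns. Missing replicate cells are ignored; each sample's
#'   value is the arithmetic mean of its present replicates.
#' @return Data frame `sample_id`, `n_reps`, `mean_value`, plus the raw
#'   replicate columns.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  id_col <- intersect(c("sample_id", "sample"), colnames(tab))[1]
  if (is.na(id_col)) stop("phenotype TSV needs a 'sample_id' column")
  names(tab)[names(tab) == id_col] <- "sample_id"
  rep_cols <- setdiff(colnames(tab), "sample_id")
  if (length(rep_cols) == 0L) stop("phenotype TSV has no replicate columns")
  reps <- as.matrix(tab[, rep_cols, drop = FALSE])
  storage.mode(reps) <- "double"
  if (any(reps < 0, na.rm = TRUE))
    stop("negative 2AP concentration in ", path)
  out <- data.frame(sample_id = as.character(tab$sample_id),
                    n_reps = rowSums(!is.na(reps)),
                    mean_value = rowMeans(reps, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  cbind(out, tab[, rep_cols, drop = FALSE])
}

#' Write a haplotype report table
#'
#' One row per haplotype group plus `R` (rare) and `U` (unclassified) rows:
#' per-subpopulation counts, a total, and the group consensus allele string.
#' Row totals sum to the panel size.
#'
#' @param classification A [hap_classification][group_haplotypes] object.
#' @param meta Metadata data frame from [read_metadata()] covering every
#'   classified sample.
#' @param path Output TSV.
#' @return The report data frame, invisibly.
#' @export
write_haplotype_report <- function(classification, meta, path) {
  tab <- crosstab(classification, meta)
  cons <- vapply(classification$groups, function(g)
    paste(ifelse(is.na(g$consensus), ".", g$consensus), collapse = ""),
    character(1))
  rep_tab <- data.frame(group = rownames(tab), tab,
                        check.names = FALSE, stringsAsFactors = FALSE)
  rep_tab$consensus <- ""
  rep_tab$consensus[seq_along(cons)] <- cons
  rep_tab <- rep_tab[rep_tab$group != "Total", , drop = FALSE]
  utils::write.table(rep_tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rep_tab)
}
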