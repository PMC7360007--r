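# Call encoding used throughout: single nucleotide characters "A","C","G","T",
# "H" for a heterozygous diploid call, and NA for a missing call.
HET_CALL <- "H"
NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a gene-region genotype matrix
#'
#' The central container of the package: an ordered samples x SNPs matrix of
#' single-character allele calls over a chromosome interval. Inbred-line
#' genotypes are treated as haplotypes, so each cell holds one nucleotide,
#' `"H"` for a heterozygous call, or `NA` for a missing call.
#'
#' Sites are stored sorted by position. Internally the region is kept as a
#' 0-based half-open interval; all user-facing positions (site ids, reports)
#' are 1-based.
#'
#' @param calls Character matrix, samples in rows (rownames = sample ids),
#'   sites in columns. Entries in `A,C,G,T,H,NA`.
#' @param chrom Chromosome name (scalar, recycled) or vector per site.
#' @param pos Integer vector of 1-based physical positions, one per column.
#' @param alleles Optional character vector (one per site) of comma-joined
#'   allele codes in reference-first order, e.g. `"G,T"`. Defaults to the
#'   alphabetically sorted set of alleles observed in `calls`.
#' @param region Optional list `(chrom, start, end)` with 0-based half-open
#'   `start`/`end`; defaults to the tight span of the sites.
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `sites` (data.frame `chrom`, `pos`, `id`, `alleles`) and `region`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c("G", "T", "A", "A"), 2, 2,
#'          dimnames = list(c("s1", "s2"), NULL)),
#'   chrom = "Chr8", pos = c(100, 200))
#' gm
#' @export
genotype_matrix <- function(calls, chrom, pos, alleles = NULL, region = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  if (is.null(rownames(calls)))
    stop("`calls` must carry sample ids as rownames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "))
  pos <- as.integer(pos)
  if (length(pos) != ncol(calls))
    stop("`pos` must have one entry per site")
  if (any(pos < 1L)) stop("positions must be 1-based (>= 1)")
  chrom <- rep_len(as.character(chrom), ncol(calls))
  bad <- !(calls %in% c(NUCLEOTIDES, HET_CALL)) & !is.na(calls)
  if (any(bad))
    stop("invalid call codes: ", paste(unique(calls[bad]), collapse = ", "))

  if (is.null(alleles)) {
    alleles <- vapply(seq_len(ncol(calls)), function(j) {
      obs <- sort(unique(calls[, j][calls[, j] %in% NUCLEOTIDES]))
      paste(obs, collapse = ",")
    }, character(1))
  } else {
    alleles <- rep_len(as.character(alleles), ncol(calls))
  }

  sites <- data.frame(
    chrom = chrom, pos = pos,
    id = paste0(chrom, ":", pos),
    alleles = alleles,
    stringsAsFactors = FALSE)
  if (anyDuplicated(sites$id))
    stop("duplicate site ids: ",
         paste(unique(sites$id[duplicated(sites$id)]), collapse = ", "))

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  calls <- calls[, ord, drop = FALSE]
  colnames(calls) <- sites$id

  # reject non-special calls outside the declared allele set
  for (j in seq_len(ncol(calls))) {
    a <- strsplit(sites$alleles[j], ",", fixed = TRUE)[[1]]
    cc <- calls[, j]
    off <- cc %in% NUCLEOTIDES & !(cc %in% a)
    if (any(off))
      stop("call not in declared alleles at ", sites$id[j], ": ",
           paste(unique(cc[off]), collapse = ", "))
  }

  if (is.null(region)) {
    region <- list(chrom = sites$chrom[1],
                   start = min(sites$pos) - 1L,
                   end = max(sites$pos))
  }
  structure(list(calls = calls, sites = sites, region = region),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%s:%d-%d)\n",
              nrow(x$calls), ncol(x$calls),
              x$region$chrom, x$region$start + 1L, x$region$end))
  n_miss <- sum(is.na(x$calls))
  n_het <- sum(x$calls == HET_CALL, na.rm = TRUE)
  cat(sprintf("  missing calls: %d (%.2f%%), het calls: %d (%.2f%%)\n",
              n_miss, 100 * n_miss / max(1, length(x$calls)),
              n_het, 100 * n_het / max(1, length(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x A `genotype_matrix`.
#' @param i Sample selector (ids, indices or logical).
#' @param j Site selector (site ids, indices or logical).
#' @param ... Ignored.
#' @return A `genotype_matrix` over the selected samples and sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$sites$id)
  if (anyNA(j)) stop("unknown site id(s)")
  calls <- x$calls[i, j, drop = FALSE]
  sites <- x$sites[j, , drop = FALSE]
  genotype_matrix(calls, sites$chrom, sites$pos, sites$alleles,
                  region = x$region)
}

#' Sample ids of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
samples <- function(x) rownames(x$calls)

#' Restrict a genotype matrix to a chromosome interval
#'
#' @param x A `genotype_matrix`.
#' @param region Interval as `"Chr8:100-200"` (1-based inclusive) or a list
#'   `(chrom, start, end)` with 1-based inclusive coordinates.
#' @return A `genotype_matrix` with only the sites inside the interval; an
#'   empty selection yields a 0-site matrix (flagged by a message), not an
#'   error.
#' @export
subset_region <- function(x, region) {
  r <- parse_region(region)
  keep <- x$sites$chrom == r$chrom &
    x$sites$pos >= r$start & x$sites$pos <= r$end
  if (!any(keep)) message("region ", r$chrom, ":", r$start, "-", r$end,
                          " contains no sites; returning empty matrix")
  out <- x
  out$calls <- x$calls[, keep, drop = FALSE]
  out$sites <- x$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$region <- list(chrom = r$chrom, start = r$start - 1L, end = r$end)
  out
}

# Accepts "Chr8:100-200" or list(chrom=, start=, end=), 1-based inclusive.
parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4L) stop("cannot parse region string: ", region)
    list(chrom = m[2],
         start = as.integer(gsub(",", "", m[3])),
         end = as.integer(gsub(",", "", m[4])))
  } else if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    list(chrom = as.character(region$chrom),
         start = as.integer(region$start), end = as.integer(region$end))
  } else stop("region must be a string or a list(chrom, start, end)")
}
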