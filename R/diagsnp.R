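#' Distance from a site to a gene interval
#'
#' Zero inside the interval, otherwise the distance (bp) to the nearest
#' boundary, under the 1-based inclusive user convention.
#'
#' @param pos 1-based position(s).
#' @param gene_interval `list(chrom, start, end)` (1-based inclusive) or a
#'   `"Chr8:start-end"` string.
#' @param chrom Optional chromosome of the site(s); if given it must match
#'   the interval's chromosome.
#' @return Integer vector of distances.
#' @export
gene_distance <- function(pos, gene_interval, chrom = NULL) {
  gi <- parse_region(gene_interval)
  if (!is.null(chrom) && any(chrom != gi$chrom))
    stop("site chromosome (", paste(unique(chrom), collapse = ","),
         ") differs from gene interval chromosome (", gi$chrom, ")")
  pos <- as.integer(pos)
  ifelse(pos >= gi$start & pos <= gi$end, 0L,
         pmin(abs(pos - gi$start), abs(pos - gi$end)))
}

#' Find SNPs diagnostic of one haplotype group
#'
#' Scans the gene interval plus `flank_bp` on either side for sites whose
#' allele is private to and fixed in the target group, with a single fixed
#' allele in all other groups ("invariant in all the other haplotypes").
#' Strict candidates (target and background purity both 1 and a single
#' background allele) rank first, ordered by proximity to the gene; the
#' `min_purity` knob admits accession-level noise. Rare and unclassified
#' samples are excluded from the background by default, since uniqueness is
#' assessed across the defined haplotype groups only.
#'
#' @param gm A [genotype_matrix()] including flanking sites.
#' @param classification A `hap_classification`.
#' @param target_group Group id (integer) to find diagnostics for.
#' @param gene_interval `list(chrom, start, end)` 1-based inclusive, or a
#'   region string.
#' @param flank_bp Flank width to search either side of the gene
#'   (default 10000).
#' @param min_purity Minimum fraction of non-missing members carrying the
#'   modal allele, for target and background alike (default 1, strict).
#' @param include_rare Include rare (R) samples in the background
#'   (default `FALSE`).
#' @return Data frame of candidates: `site`, `chrom`, `pos`,
#'   `target_allele`, `background_allele`, `purity`, `background_purity`,
#'   `n_target`, `n_background`, `strict`, `provenance` (`gene`/`flank`),
#'   `distance_to_gene`; ranked strict-first then by distance.
#' @export
find_diagnostic <- function(gm, classification, target_group, gene_interval,
                            flank_bp = 10000, min_purity = 1,
                            include_rare = FALSE) {
  stopifnot(flank_bp >= 0)
  gi <- parse_region(gene_interval)
  ids <- vapply(classification$groups, `[[`, integer(1), "group_id")
  if (!target_group %in% ids) stop("no such group: ", target_group)
  target <- classification$groups[[which(ids == target_group)]]$members
  if (!length(target)) stop("target group ", target_group, " is empty")
  background <- unlist(lapply(
    classification$groups[ids != target_group], `[[`, "members"),
    use.names = FALSE)
  if (include_rare) background <- c(background, classification$rare)
  if (!length(background)) stop("background is empty")

  in_window <- gm$sites$chrom == gi$chrom &
    gm$sites$pos >= gi$start - flank_bp & gm$sites$pos <= gi$end + flank_bp
  sites <- gm$sites[in_window, , drop = FALSE]
  if (!nrow(sites)) return(empty_candidates())

  calls <- gm$calls
  calls[calls == HET_CALL] <- NA_character_
  t_calls <- calls[intersect(target, rownames(calls)), sites$id,
                   drop = FALSE]
  b_calls <- calls[intersect(background, rownames(calls)), sites$id,
                   drop = FALSE]

  rows <- lapply(seq_len(nrow(sites)), function(j) {
    tc <- t_calls[, j]; tc <- tc[!is.na(tc)]
    bc <- b_calls[, j]; bc <- bc[!is.na(bc)]
    if (!length(tc) || !length(bc)) return(NULL)
    t_tab <- sort(table(tc), decreasing = TRUE)
    b_tab <- sort(table(bc), decreasing = TRUE)
    target_allele <- names(t_tab)[1L]
    background_allele <- names(b_tab)[1L]
    purity <- as.numeric(t_tab[1L]) / length(tc)
    background_purity <- as.numeric(b_tab[1L]) / length(bc)
    if (target_allele == background_allele) return(NULL)
    if (purity < min_purity || background_purity < min_purity) return(NULL)
    data.frame(site = sites$id[j], chrom = sites$chrom[j],
               pos = sites$pos[j],
               target_allele = target_allele,
               background_allele = background_allele,
               purity = purity, background_purity = background_purity,
               n_target = length(tc), n_background = length(bc),
               strict = purity == 1 && background_purity == 1 &&
                 length(b_tab) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_candidates())
  out$distance_to_gene <- gene_distance(out$pos, gi, chrom = out$chrom)
  out$provenance <- ifelse(out$distance_to_gene == 0L, "gene", "flank")
  out <- out[order(-out$strict, out$distance_to_gene, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(site = character(0), chrom = character(0), pos = integer(0),
             target_allele = character(0), background_allele = character(0),
             purity = numeric(0), background_purity = numeric(0),
             n_target = integer(0), n_background = integer(0),
             strict = logical(0), distance_to_gene = integer(0),
             provenance = character(0), stringsAsFactors = FALSE)
}
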