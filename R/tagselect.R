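# A consensus matrix is a haplotype-group x site character matrix of
# consensus alleles (NA = missing consensus), with site ids "chrom:pos" as
# colnames and group labels as rownames. Sites whose consensus is missing
# in any group are ineligible for selection.

#' Consensus matrix of a classification
#'
#' @param classification A `hap_classification` from [group_haplotypes()].
#' @return Character matrix, one row per group (rownames = group ids), one
#'   column per retained site.
#' @export
consensus_matrix <- function(classification) {
  m <- do.call(rbind, lapply(classification$groups, `[[`, "consensus"))
  rownames(m) <- vapply(classification$groups, `[[`, integer(1), "group_id")
  m
}

site_positions <- function(ids) {
  as.integer(sub("^.*:", "", ids))
}

#' Minor allele frequency among haplotype groups
#'
#' Per site, the frequency of the second most common consensus allele
#' across groups, unweighted by group size (so a site private to one of 11
#' groups has MAF 1/11). Monomorphic sites return 0 and are flagged
#' uninformative; sites with a missing consensus in some group return `NA`.
#'
#' @param cm Consensus matrix (groups x sites).
#' @return Named numeric vector in `[0, 0.5]` (or `NA`), with attribute
#'   `uninformative` marking MAF-0 sites.
#' @export
group_maf <- function(cm) {
  if (nrow(cm) < 2L) stop("need at least two haplotype groups")
  maf <- apply(cm, 2L, function(col) {
    if (anyNA(col)) return(NA_real_)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) return(0)
    as.numeric(tab[2L]) / length(col)
  })
  names(maf) <- colnames(cm)
  attr(maf, "uninformative") <- !is.na(maf) & maf == 0
  maf
}

pair_matrix <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  t(utils::combn(n, 2L))
}

# logical sites x pairs matrix: does site s separate group pair p?
separation_matrix <- function(cm, pairs) {
  vapply(seq_len(nrow(pairs)), function(p)
    cm[pairs[p, 1L], ] != cm[pairs[p, 2L], ],
    logical(ncol(cm)))
}

#' Greedy minimal discriminating tag-SNP selection
#'
#' Iteratively selects the site that separates the largest number of
#' still-unseparated haplotype-group pairs, breaking ties by higher
#' group-level MAF and then by lower position; stops when no site separates
#' a new pair. A post-pass drops any selected site whose removal leaves the
#' separated pair set unchanged (disable with `prune = FALSE` for the raw
#' greedy output). Sites with a missing consensus allele are ineligible.
#'
#' @param cm Consensus matrix (groups x sites).
#' @param prune Run the redundancy post-pass (default `TRUE`).
#' @return An object of class `tag_set`: `selected_sites` (ids in selection
#'   order), `codes` (group -> allele string over the selected sites),
#'   `resolved_pairs` / `unresolved_pairs` (2-column matrices of group
#'   labels; unresolved pairs are identical over *all* candidate sites),
#'   and `maf`.
#' @export
greedy_select <- function(cm, prune = TRUE) {
  groups <- rownames(cm)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(cm)))
  if (nrow(cm) < 2L)
    return(new_tag_set(character(0), cm, matrix(character(0), 0, 2),
                       matrix(character(0), 0, 2)))
  eligible <- colnames(cm)[colSums(is.na(cm)) == 0L]
  cme <- cm[, eligible, drop = FALSE]
  pairs <- pair_matrix(nrow(cm))
  sep <- separation_matrix(cme, pairs)          # sites x pairs
  if (!is.matrix(sep)) sep <- matrix(sep, nrow = length(eligible))
  resolvable <- colSums(sep) > 0L
  maf <- group_maf(cme)
  pos <- site_positions(eligible)

  unresolved <- resolvable
  selected <- integer(0)
  while (any(unresolved)) {
    gain <- rowSums(sep[, unresolved, drop = FALSE])
    gain[selected] <- 0L
    if (max(gain) == 0L) break
    cand <- which(gain == max(gain))
    cand <- cand[order(-maf[cand], pos[cand])]
    pick <- cand[1L]
    selected <- c(selected, pick)
    unresolved <- unresolved & !sep[pick, ]
  }

  if (prune && length(selected) > 1L) {
    covered <- function(idx) {
      if (!length(idx)) return(rep(FALSE, nrow(pairs)))
      colSums(sep[idx, , drop = FALSE]) > 0L
    }
    full <- covered(selected)
    i <- 1L
    while (i <= length(selected)) {
      trial <- selected[-i]
      if (identical(covered(trial), full)) selected <- trial
      else i <- i + 1L
    }
  }

  sel_ids <- eligible[selected]
  resolved <- if (length(selected))
    colSums(sep[selected, , drop = FALSE]) > 0L else
      rep(FALSE, nrow(pairs))
  new_tag_set(sel_ids, cm,
              resolved_pairs = pair_labels(pairs, groups, resolved),
              unresolved_pairs = pair_labels(pairs, groups, !resolvable),
              maf = maf)
}

pair_labels <- function(pairs, groups, which_rows) {
  m <- cbind(groups[pairs[which_rows, 1L]], groups[pairs[which_rows, 2L]])
  colnames(m) <- c("group_a", "group_b")
  m
}

new_tag_set <- function(selected_sites, cm, resolved_pairs,
                        unresolved_pairs, maf = NULL) {
  codes <- if (length(selected_sites))
    apply(cm[, selected_sites, drop = FALSE], 1L, paste, collapse = "")
  else stats::setNames(rep("", nrow(cm)), rownames(cm))
  structure(list(selected_sites = selected_sites,
                 codes = codes,
                 resolved_pairs = resolved_pairs,
                 unresolved_pairs = unresolved_pairs,
                 maf = maf),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> %d sites: %s\n", length(x$selected_sites),
              paste(x$selected_sites, collapse = ", ")))
  cat(sprintf("  resolved pairs: %d, unresolved: %d\n",
              nrow(x$resolved_pairs), nrow(x$unresolved_pairs)))
  invisible(x)
}

#' Exhaustive minimal tag-set search (test oracle)
#'
#' Enumerates site subsets in increasing cardinality (and, within a
#' cardinality, in lexicographic order by position) and returns the first
#' subset that separates every pair separable by the full candidate set.
#' If no subset within `max_size` achieves full separation, the best
#' achievable subset of size `max_size` is returned with a warning.
#'
#' Intended as an independent oracle for [greedy_select()]; feasible up to
#' roughly 25 candidate sites.
#'
#' @param cm Consensus matrix (groups x sites).
#' @param max_size Largest subset size to try (default: all sites).
#' @return A `tag_set` (see [greedy_select()]).
#' @export
brute_force_min <- function(cm, max_size = ncol(cm)) {
  groups <- rownames(cm)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(cm)))
  eligible <- colnames(cm)[colSums(is.na(cm)) == 0L]
  ord <- order(site_positions(eligible))
  eligible <- eligible[ord]
  cme <- cm[, eligible, drop = FALSE]
  pairs <- pair_matrix(nrow(cm))
  sep <- separation_matrix(cme, pairs)
  if (!is.matrix(sep)) sep <- matrix(sep, nrow = length(eligible))
  resolvable <- colSums(sep) > 0L
  if (nrow(cm) < 2L || !any(resolvable))
    return(new_tag_set(character(0), cm, pair_labels(pairs, groups,
                                                     logical(nrow(pairs))),
                       pair_labels(pairs, groups, !resolvable)))

  best <- NULL; best_n <- -1L
  for (k in seq_len(min(max_size, length(eligible)))) {
    combs <- utils::combn(length(eligible), k)
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      cov <- colSums(sep[idx, , drop = FALSE]) > 0L
      n_cov <- sum(cov)
      if (all(cov == resolvable))
        return(new_tag_set(eligible[idx], cm,
                           pair_labels(pairs, groups, cov),
                           pair_labels(pairs, groups, !resolvable)))
      if (k == min(max_size, length(eligible)) && n_cov > best_n) {
        best <- idx; best_n <- n_cov
      }
    }
  }
  warning("no subset of size <= ", max_size,
          " achieves full separation; returning best achievable")
  cov <- colSums(sep[best, , drop = FALSE]) > 0L
  new_tag_set(eligible[best], cm, pair_labels(pairs, groups, cov),
              pair_labels(pairs, groups, !(cov | !resolvable)))
}

#' Call haplotype groups from tag-SNP alleles
#'
#' Matches each sample's alleles over the selected sites to the group
#' codes. Groups sharing an identical code form a merged class labeled
#' e.g. `"7/9"`. A sample matching exactly one class is `assigned` (or
#' `merged`); a sample whose missing calls leave several classes possible
#' is `ambiguous` (call = classes joined by `|`); a complete profile
#' matching nothing is `novel`. Het calls are treated as missing.
#'
#' @param gm A [genotype_matrix()] containing the tag sites.
#' @param tagset A `tag_set` (or a named character vector of group codes
#'   over `sites`).
#' @param sites Site ids to score; defaults to `tagset$selected_sites`.
#' @return Data frame `sample`, `call`, `status`
#'   (`assigned`/`merged`/`ambiguous`/`novel`), `n_compatible`.
#' @export
apply_tags <- function(gm, tagset, sites = NULL) {
  codes <- if (inherits(tagset, "tag_set")) tagset$codes else tagset
  if (is.null(sites))
    sites <- if (inherits(tagset, "tag_set")) tagset$selected_sites
    else stop("`sites` required when passing raw codes")
  missing_sites <- setdiff(sites, gm$sites$id)
  if (length(missing_sites))
    stop("tag sites absent from matrix: ",
         paste(missing_sites, collapse = ", "))
  code_mat <- do.call(rbind, strsplit(codes, ""))
  if (ncol(code_mat) != length(sites))
    stop("code length does not match number of sites")
  # merge groups with identical codes
  class_of <- match(codes, unique(codes))
  class_label <- vapply(seq_len(max(class_of)), function(cl)
    paste(names(codes)[class_of == cl], collapse = "/"), character(1))

  calls <- gm$calls[, sites, drop = FALSE]
  calls[calls == HET_CALL] <- NA_character_
  res <- lapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    ok <- !is.na(v)
    compat_groups <- which(apply(code_mat, 1L, function(cd)
      all(cd[ok] == v[ok])))
    compat_classes <- sort(unique(class_of[compat_groups]))
    n <- length(compat_classes)
    if (n == 0L)
      list(call = "novel", status = "novel", n = 0L)
    else if (n == 1L) {
      lab <- class_label[compat_classes]
      list(call = lab,
           status = if (grepl("/", lab, fixed = TRUE)) "merged"
           else "assigned",
           n = 1L)
    } else
      list(call = paste(class_label[compat_classes], collapse = "|"),
           status = "ambiguous", n = n)
  })
  data.frame(sample = rownames(calls),
             call = vapply(res, `[[`, character(1), "call"),
             status = vapply(res, `[[`, character(1), "status"),
             n_compatible = vapply(res, `[[`, integer(1), "n"),
             stringsAsFactors = FALSE)
}
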