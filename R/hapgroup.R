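#' Grouping parameters for haplotype characterization
#'
#' @param max_missing_per_site Sites with more than this many missing calls
#'   (after het recoding) are dropped. Values < 1 are read as a fraction of
#'   the panel. Default 100 calls.
#' @param max_mismatch Hamming radius for group membership: vectors within
#'   this many mismatches of a group founder (over mutually non-missing
#'   sites) join the group. Default 3.
#' @param min_group_fraction Groups below this fraction of the panel are
#'   labeled rare (`R`). Default 0.01; the 5% variant sometimes quoted for
#'   this workflow is available by setting 0.05 (see the methods vignette
#'   for why 1% is the default).
#' @param min_subgroup_fraction Within-group fraction an identical-vector
#'   class needs to receive a subgroup letter (`A`, `B`, ...); smaller
#'   classes pool into `X`. Default 0.01.
#' @param min_overlap Minimum number of mutually non-missing sites for a
#'   pairwise distance to be evaluable; values < 1 are read as a fraction
#'   of the retained sites. Default 0.5.
#' @return A list of class `grouping_params`.
#' @export
grouping_params <- function(max_missing_per_site = 100,
                            max_mismatch = 3,
                            min_group_fraction = 0.01,
                            min_subgroup_fraction = 0.01,
                            min_overlap = 0.5) {
  stopifnot(max_mismatch >= 0,
            min_group_fraction >= 0, min_group_fraction <= 1,
            min_subgroup_fraction >= 0, min_subgroup_fraction <= 1,
            min_overlap >= 0)
  structure(list(max_missing_per_site = max_missing_per_site,
                 max_mismatch = max_mismatch,
                 min_group_fraction = min_group_fraction,
                 min_subgroup_fraction = min_subgroup_fraction,
                 min_overlap = min_overlap),
            class = "grouping_params")
}

#' Recode heterozygous calls and drop high-missingness sites
#'
#' Heterozygous calls are recoded as missing, then sites whose missing count
#' exceeds `max_missing_per_site` are removed (a site at exactly the
#' threshold is kept). Site order is preserved.
#'
#' @param gm A [genotype_matrix()].
#' @param params A [grouping_params()].
#' @return The filtered `genotype_matrix`.
#' @export
preprocess <- function(gm, params = grouping_params()) {
  if (ncol(gm$calls) == 0L || nrow(gm$calls) == 0L)
    stop("empty genotype matrix")
  calls <- gm$calls
  calls[calls == HET_CALL] <- NA_character_
  thr <- params$max_missing_per_site
  if (thr < 1) thr <- thr * nrow(calls)
  n_missing <- colSums(is.na(calls))
  keep <- n_missing <= thr
  if (!any(keep))
    stop("all sites exceed max_missing_per_site (", thr,
         "); raise the threshold")
  out <- gm
  out$calls <- calls[, keep, drop = FALSE]
  out$sites <- gm$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

# Integer recode for fast Hamming arithmetic: A..T -> 1..4, missing -> NA.
calls_to_int <- function(calls) {
  m <- matrix(match(calls, NUCLEOTIDES), nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  m
}

# mismatches/overlap of one integer vector against the rows of an integer
# matrix, counting only mutually non-missing sites
dist_to_leaders <- function(v, leaders) {
  vm <- matrix(v, nrow(leaders), length(v), byrow = TRUE)
  valid <- !is.na(vm) & !is.na(leaders)
  list(mismatch = rowSums(valid & vm != leaders, na.rm = TRUE),
       overlap = rowSums(valid))
}

#' Group gene haplotypes by greedy leader clustering
#'
#' Identical call vectors are collapsed first; distinct vectors are sorted
#' by descending carrier count (ties broken by lexicographic vector order)
#' and clustered greedily: each vector joins the first existing group whose
#' founder vector is within `max_mismatch` mismatches over mutually
#' non-missing sites (requiring at least `min_overlap` shared sites), and
#' otherwise founds a new group. Groups are finally renumbered by
#' descending size, so group 1 is the most common haplotype. The design is
#' invariant to the input sample order.
#'
#' @param gm A preprocessed [genotype_matrix()] (no het calls).
#' @param params A [grouping_params()].
#' @return An object of class `hap_classification`: a list with `groups`
#'   (each a `hap_group` with `group_id`, `founder`, `consensus`, `members`,
#'   `subgroups`), empty `rare` / `unclassified` vectors, `params`, and the
#'   retained `site_ids`.
#' @export
group_haplotypes <- function(gm, params = grouping_params()) {
  calls <- gm$calls
  if (any(calls == HET_CALL, na.rm = TRUE))
    stop("het calls present; run preprocess() first")
  n_sites <- ncol(calls)
  min_overlap <- params$min_overlap
  if (min_overlap < 1) min_overlap <- ceiling(min_overlap * n_sites)

  key <- apply(calls, 1L, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = ""))
  classes <- split(rownames(calls), key)
  counts <- lengths(classes)
  ord <- order(-counts, names(classes))
  classes <- classes[ord]

  int_calls <- calls_to_int(calls)
  rep_vec <- int_calls[vapply(classes, `[`, character(1), 1L), ,
                       drop = FALSE]

  leader_idx <- integer(0)        # row index into rep_vec of each founder
  membership <- integer(length(classes))
  for (k in seq_along(classes)) {
    v <- rep_vec[k, ]
    assigned <- 0L
    if (length(leader_idx)) {
      d <- dist_to_leaders(v, rep_vec[leader_idx, , drop = FALSE])
      ok <- d$overlap >= min_overlap & d$mismatch <= params$max_mismatch
      if (any(ok)) assigned <- which(ok)[1L]
    }
    if (assigned == 0L) {
      leader_idx <- c(leader_idx, k)
      assigned <- length(leader_idx)
    }
    membership[k] <- assigned
  }

  members <- lapply(seq_along(leader_idx), function(g)
    unlist(classes[membership == g], use.names = FALSE))
  sizes <- lengths(members)
  renum <- order(-sizes, seq_along(sizes))

  groups <- lapply(seq_along(renum), function(i) {
    g <- renum[i]
    founder <- calls[classes[[leader_idx[g]]][1L], ]
    mem <- members[[g]]
    structure(list(group_id = i,
                   founder = founder,
                   consensus = consensus(gm, mem),
                   members = mem,
                   subgroups = NULL),
              class = "hap_group")
  })

  structure(list(groups = groups,
                 rare = character(0),
                 unclassified = character(0),
                 params = params,
                 site_ids = gm$sites$id),
            class = "hap_classification")
}

#' @export
print.hap_classification <- function(x, ...) {
  n <- sum(lengths(lapply(x$groups, `[[`, "members"))) +
    length(x$rare) + length(x$unclassified)
  cat(sprintf("<hap_classification> %d samples over %d sites\n",
              n, length(x$site_ids)))
  for (g in x$groups) {
    cons <- paste(ifelse(is.na(g$consensus), ".", g$consensus),
                  collapse = "")
    if (nchar(cons) > 40) cons <- paste0(substr(cons, 1, 40), "...")
    cat(sprintf("  Hap %-3d n=%-5d consensus %s\n", g$group_id,
                length(g$members), cons))
  }
  cat(sprintf("  R (rare): %d, U (unclassified): %d\n",
              length(x$rare), length(x$unclassified)))
  invisible(x)
}

#' Move low-frequency groups to the rare (R) class
#'
#' Groups whose size falls below `min_group_fraction` of the panel are moved
#' wholesale to the rare class; remaining groups are renumbered by
#' descending size.
#'
#' @param classification A `hap_classification`.
#' @param params A [grouping_params()]; `min_group_fraction` is used.
#' @param n_total Panel size the fraction refers to; defaults to the number
#'   of samples in the classification.
#' @return The updated `hap_classification`.
#' @export
label_rare <- function(classification, params = classification$params,
                       n_total = NULL) {
  if (is.null(n_total))
    n_total <- sum(lengths(lapply(classification$groups, `[[`, "members"))) +
      length(classification$rare) + length(classification$unclassified)
  sizes <- lengths(lapply(classification$groups, `[[`, "members"))
  rare_idx <- which(sizes / n_total < params$min_group_fraction)
  new_rare <- unlist(lapply(classification$groups[rare_idx], `[[`,
                            "members"), use.names = FALSE)
  classification$rare <- c(classification$rare, new_rare)
  classification$groups <- renumber_groups(
    classification$groups[setdiff(seq_along(sizes), rare_idx)])
  classification
}

renumber_groups <- function(groups) {
  sizes <- lengths(lapply(groups, `[[`, "members"))
  groups <- groups[order(-sizes, seq_along(groups))]
  for (i in seq_along(groups)) groups[[i]]$group_id <- i
  groups
}

#' Move samples with unusable key-SNP data to the unclassified (U) class
#'
#' Samples whose missing-call count over `key_sites` exceeds
#' `max_missing_key` are moved to `U` (from groups and from the rare class
#' alike). With `key_sites = NULL` the whole retained site vector is used,
#' matching the whole-vector "> 100 data points missing" rule; in that mode
#' `max_missing_key` defaults to 100, otherwise to 0 (any missing key SNP).
#'
#' @param gm The preprocessed [genotype_matrix()] the classification came
#'   from.
#' @param classification A `hap_classification`.
#' @param key_sites Site ids to inspect, or `NULL` for all retained sites.
#' @param max_missing_key Missing-call tolerance over the key sites.
#' @return The updated `hap_classification`.
#' @export
flag_unclassified <- function(gm, classification, key_sites = NULL,
                              max_missing_key = NULL) {
  if (is.null(key_sites)) {
    key_sites <- classification$site_ids
    if (is.null(max_missing_key)) max_missing_key <- 100
  } else if (is.null(max_missing_key)) max_missing_key <- 0
  unknown <- setdiff(key_sites, gm$sites$id)
  if (length(unknown))
    stop("unknown key site id(s): ", paste(unknown, collapse = ", "))
  universe <- c(unlist(lapply(classification$groups, `[[`, "members")),
                classification$rare, classification$unclassified)
  sub <- gm$calls[intersect(rownames(gm$calls), universe), , drop = FALSE]
  sub <- sub[, key_sites, drop = FALSE]
  n_missing <- rowSums(is.na(sub) | sub == HET_CALL)
  u_samples <- rownames(sub)[n_missing > max_missing_key]

  classification$groups <- lapply(classification$groups, function(g) {
    g$members <- setdiff(g$members, u_samples)
    g
  })
  keep <- lengths(lapply(classification$groups, `[[`, "members")) > 0L
  classification$groups <- renumber_groups(classification$groups[keep])
  classification$rare <- setdiff(classification$rare, u_samples)
  classification$unclassified <- union(classification$unclassified,
                                       u_samples)
  classification
}

#' Assign subgroup letters within each haplotype group
#'
#' Within a group, classes of samples with identical call vectors are
#' ranked by size; classes reaching `min_subgroup_fraction` of the group
#' receive letters `A`, `B`, `C`, ... in rank order, and all remaining
#' samples pool into the extremely-rare subgroup `X`.
#'
#' @param gm The preprocessed [genotype_matrix()].
#' @param classification A `hap_classification`.
#' @param params A [grouping_params()].
#' @return The classification with each group's `subgroups` filled in as a
#'   named list label -> member ids.
#' @export
assign_subgroups <- function(gm, classification,
                             params = classification$params) {
  classification$groups <- lapply(classification$groups, function(g) {
    calls <- gm$calls[g$members, , drop = FALSE]
    key <- apply(calls, 1L, function(r)
      paste(ifelse(is.na(r), ".", r), collapse = ""))
    classes <- split(g$members, key)
    classes <- classes[order(-lengths(classes), names(classes))]
    named <- lengths(classes) / length(g$members) >=
      params$min_subgroup_fraction
    labels <- character(length(classes))
    labels[named] <- make_subgroup_letters(sum(named))
    sub <- classes[named]
    names(sub) <- labels[named]
    x_members <- unlist(classes[!named], use.names = FALSE)
    if (length(x_members)) sub$X <- x_members
    g$subgroups <- sub
    g
  })
  classification
}

make_subgroup_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(n)]
}

#' Consensus allele vector of a sample set
#'
#' Per site, the most frequent non-missing allele among the given samples;
#' ties break to the alphabetically first allele; an all-missing site gives
#' `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param members Sample ids (default: all samples).
#' @return Named character vector over the matrix's site ids.
#' @export
consensus <- function(gm, members = samples(gm)) {
  calls <- gm$calls[members, , drop = FALSE]
  out <- apply(calls, 2L, function(col) {
    col <- col[!is.na(col) & col != HET_CALL]
    if (!length(col)) return(NA_character_)
    tab <- table(col)
    names(tab)[which.max(tab)]   # table() is alphabetical; max is first
  })
  names(out) <- gm$sites$id
  out
}

#' Haplotype-group by subpopulation count table
#'
#' @param classification A `hap_classification`.
#' @param meta Metadata data frame (from [read_metadata()]) with
#'   `sample_id` and `subpopulation`; must cover every classified sample.
#' @return Integer matrix with one row per group plus `R`, `U` and `Total`
#'   rows, one column per subpopulation plus a `Total` column.
#' @export
crosstab <- function(classification, meta) {
  all_samples <- c(unlist(lapply(classification$groups, `[[`, "members")),
                   classification$rare, classification$unclassified)
  missing_meta <- setdiff(all_samples, meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "),
         if (length(missing_meta) > 5) ", ...")
  subpop <- stats::setNames(meta$subpopulation, meta$sample_id)
  levels <- unique(meta$subpopulation)
  row_sets <- c(stats::setNames(
    lapply(classification$groups, `[[`, "members"),
    paste0("Hap", vapply(classification$groups, `[[`, integer(1),
                         "group_id"))),
    list(R = classification$rare, U = classification$unclassified))
  tab <- vapply(row_sets, function(s)
    as.integer(table(factor(subpop[s], levels = levels))),
    integer(length(levels)))
  tab <- t(matrix(tab, nrow = length(levels),
                  dimnames = list(levels, names(row_sets))))
  tab <- cbind(tab, Total = rowSums(tab))
  rbind(tab, Total = colSums(tab))
}

#' Round half away from zero
#'
#' Display rounding used in the haplotype reports (R's `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
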