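test_that("preprocess recodes het and applies the strict >threshold rule", {
  set.seed(2)
  n <- 120
  calls <- matrix("A", n, 3,
                  dimnames = list(sprintf("s%03d", 1:n), NULL))
  calls[1:101, 1] <- NA          # 101 missing: dropped
  calls[1:98, 2] <- NA
  calls[99:100, 2] <- "H"        # 98 + 2 het = 100 missing: kept
  gm <- genotype_matrix(calls, "Chr1", c(10L, 20L, 30L))
  out <- preprocess(gm, grouping_params(max_missing_per_site = 100))
  expect_equal(out$sites$pos, c(20L, 30L))
  expect_false(any(out$calls == "H", na.rm = TRUE))
  expect_equal(sum(is.na(out$calls[, "Chr1:20"])), 100L)

  clean <- make_gm(c(a = "ACGT", b = "TGCA"))
  expect_identical(preprocess(clean)$calls, clean$calls)

  expect_error(preprocess(gm, grouping_params(max_missing_per_site = 0.5)),
               NA)
  all_bad <- make_gm(c(a = "..", b = ".."))
  expect_error(preprocess(all_bad, grouping_params(max_missing_per_site = 1)),
               "threshold")
})

test_that("surviving sites equal a brute-force recount on random input", {
  for (seed in 1:5) {
    gm <- rand_gm(seed, n_samples = 30, n_sites = 10, missing_rate = 0.3,
                  het_rate = 0.2)
    thr <- 12
    out <- preprocess(gm, grouping_params(max_missing_per_site = thr))
    manual <- vapply(seq_len(10), function(j) {
      n_bad <- 0
      for (i in 1:30) {
        v <- gm$calls[i, j]
        if (is.na(v) || v == "H") n_bad <- n_bad + 1
      }
      n_bad <= thr
    }, logical(1))
    expect_equal(out$sites$id, gm$sites$id[manual])
  }
})

test_that("leader clustering respects the mismatch radius", {
  gm <- make_gm(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                  c = "AAAAAAAATT",          # Hamming 2 from a/b
                  d = "TTTTTTTTTT"))         # Hamming 10
  cls <- group_haplotypes(gm, grouping_params(max_mismatch = 3))
  sizes <- sort(lengths(lapply(cls$groups, `[[`, "members")),
                decreasing = TRUE)
  expect_equal(unname(sizes), c(3L, 1L))
  expect_setequal(cls$groups[[1]]$members, c("a", "b", "c"))
})

test_that("published vectors collapse to 10 classes at radius 0", {
  gm <- badh2_consensus_gm()
  p <- grouping_params(max_mismatch = 0)
  cls <- group_haplotypes(preprocess(gm, p), p)
  expect_equal(length(cls$groups), 10L)
  merged <- Filter(function(g) length(g$members) == 2L, cls$groups)
  expect_equal(length(merged), 1L)
  expect_setequal(merged[[1]]$members, c("Hap7", "Hap9"))
})

test_that("light-noise simulation recovers the founder partition", {
  # frequencies sum to 1: isolates het/missing noise from the
  # recombinant class, which has its own tests
  cfg <- tiny_config(freqs = matrix(c(0.5, 0.3, 0.2), 3, 1,
                                    dimnames = list(NULL, "pop")))
  panel <- simulate_panel(cfg, seed = 13)
  gene <- subset_region(panel$genotypes, cfg$gene_interval)
  cls <- label_rare(group_haplotypes(preprocess(gene)))
  sc <- score_recovery(cls, panel$ledger)
  expect_equal(length(unique(sc$mapping$founder)), 3L)
  expect_lte(sc$misassignment, 0.01)
})

test_that("rare labeling moves whole groups and renumbers", {
  mk_group <- function(id, n, tag)
    structure(list(group_id = id,
                   founder = c("A", "A"), consensus = c("A", "A"),
                   members = paste0(tag, seq_len(n)), subgroups = NULL),
              class = "hap_group")
  cls <- structure(list(groups = list(mk_group(1, 60, "a"),
                                      mk_group(2, 30, "b"),
                                      mk_group(3, 6, "c"),
                                      mk_group(4, 4, "d")),
                        rare = character(0), unclassified = character(0),
                        params = grouping_params(min_group_fraction = 0.05),
                        site_ids = c("Chr1:10", "Chr1:20")),
                   class = "hap_classification")
  out <- label_rare(cls, n_total = 100)
  expect_equal(lengths(lapply(out$groups, `[[`, "members")), c(60L, 30L, 6L))
  expect_equal(vapply(out$groups, `[[`, integer(1), "group_id"), 1:3)
  expect_setequal(out$rare, paste0("d", 1:4))

  none <- label_rare(cls, grouping_params(min_group_fraction = 0),
                     n_total = 100)
  expect_equal(length(none$groups), 4L)
  expect_equal(length(none$rare), 0L)
})

test_that("rare labeling is monotone in the threshold", {
  gm <- rand_gm(42, n_samples = 40, n_sites = 10, missing_rate = 0.05)
  pp <- preprocess(gm)
  base <- group_haplotypes(pp)
  sizes <- vapply(seq(0, 0.3, by = 0.05), function(thr)
    length(label_rare(base, grouping_params(min_group_fraction = thr))$rare),
    integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("unclassified flagging targets exactly the high-missing samples", {
  gm <- make_gm(c(a = "AAAA", b = "AAAA", c = "....", d = "AA..",
                  e = "TTTT"))
  p <- grouping_params(min_overlap = 2)
  cls <- group_haplotypes(gm, p)
  out <- flag_unclassified(gm, cls, key_sites = gm$sites$id,
                           max_missing_key = 1)
  expect_setequal(out$unclassified, c("c", "d"))
  expect_false("a" %in% out$unclassified)
  expect_error(flag_unclassified(gm, cls, key_sites = "Chr1:999"),
               "unknown key site")

  cfg <- tiny_config(n_high_missing = 5)
  panel <- simulate_panel(cfg, seed = 6)
  gene <- subset_region(panel$genotypes, cfg$gene_interval)
  pp <- preprocess(gene, grouping_params(max_missing_per_site = 0.5))
  cls <- label_rare(group_haplotypes(pp),
                    grouping_params(min_group_fraction = 0.02))
  cls <- flag_unclassified(pp, cls, max_missing_key = 10)
  forced <- panel$ledger$sample_id[panel$ledger$high_missing]
  expect_true(all(forced %in% cls$unclassified))
})

test_that("subgroup letters follow class size with an X pool", {
  vecs <- c(rep("AAAA", 150), rep("AATT", 49), "GGGG")
  names(vecs) <- sprintf("s%03d", seq_along(vecs))
  gm <- make_gm(vecs)
  p <- grouping_params(max_mismatch = 4, min_subgroup_fraction = 0.01)
  cls <- assign_subgroups(gm, group_haplotypes(gm, p), p)
  sub <- cls$groups[[1]]$subgroups
  expect_equal(length(sub$A), 150L)
  expect_equal(length(sub$B), 49L)
  expect_equal(length(sub$X), 1L)     # 1/200 < 1%

  one <- make_gm(c(a = "AC", b = "AC"))
  cls1 <- assign_subgroups(one, group_haplotypes(one))
  expect_equal(names(cls1$groups[[1]]$subgroups), "A")

  # letters ordered by class size, against an explicit sort
  gm2 <- rand_gm(7, n_samples = 60, n_sites = 4, missing_rate = 0,
                 het_rate = 0)
  p2 <- grouping_params(max_mismatch = 4, min_subgroup_fraction = 0)
  cls2 <- assign_subgroups(gm2, group_haplotypes(gm2, p2), p2)
  for (g in cls2$groups) {
    sizes <- lengths(g$subgroups[setdiff(names(g$subgroups), "X")])
    expect_false(is.unsorted(rev(sizes)))
  }
})

test_that("consensus takes the majority with alphabetical ties", {
  gm <- make_gm(c(a = "GGA.", b = "GTC.", c = "TTC."))
  expect_equal(unname(consensus(gm, c("a", "b", "c"))),
               c("G", "T", "C", NA))
  # tie G vs T at site 1 for members a,c -> alphabetical G
  expect_equal(unname(consensus(gm, c("a", "c"))[1]), "G")
  ident <- make_gm(c(x = "ACGT", y = "ACGT"))
  expect_equal(unname(consensus(ident)), c("A", "C", "G", "T"))
})

test_that("crosstab conserves margins and demands metadata", {
  gm <- make_gm(c(a = "AAAA", b = "AAAA", c = "AAAT", d = "TTTT",
                  e = "TTTT", f = "TTTA", g = "AAAA", h = "TTTT",
                  i = "AAAA", j = "TTTT"))
  cls <- group_haplotypes(gm)
  meta <- data.frame(sample_id = letters[1:10],
                     subpopulation = rep(c("p1", "p2"), each = 5))
  tab <- crosstab(cls, meta)
  expect_equal(unname(tab["Total", "Total"]), 10L)
  expect_equal(unname(tab[, "Total"])[seq_len(nrow(tab) - 1L)],
               unname(rowSums(tab[seq_len(nrow(tab) - 1L),
                                  c("p1", "p2")])))
  expect_error(crosstab(cls, meta[1:3, ]), "without metadata")
})

test_that("partition and radius invariants hold on random matrices", {
  for (seed in 1:30) {
    gm <- rand_gm(seed, n_samples = 25, n_sites = 15)
    pp <- preprocess(gm, grouping_params(max_missing_per_site = 0.9))
    p <- grouping_params(max_mismatch = 3, min_overlap = 0.3)
    cls <- flag_unclassified(pp, label_rare(group_haplotypes(pp, p), p),
                             max_missing_key = 10)
    all_ids <- c(unlist(lapply(cls$groups, `[[`, "members")),
                 cls$rare, cls$unclassified)
    expect_setequal(all_ids, rownames(pp$calls))
    expect_equal(length(all_ids), nrow(pp$calls))   # no double counting

    min_ov <- ceiling(0.3 * ncol(pp$calls))
    for (g in cls$groups) for (m in g$members) {
      v <- pp$calls[m, ]
      ok <- !is.na(v) & !is.na(g$founder)
      if (sum(ok) >= min_ov)
        expect_lte(sum(v[ok] != g$founder[ok]), 3)
    }
  }
})

test_that("grouping is invariant to sample order", {
  gm <- rand_gm(101, n_samples = 30, n_sites = 12)
  pp <- preprocess(gm, grouping_params(max_missing_per_site = 0.9))
  cls1 <- group_haplotypes(pp)
  perm <- pp
  set.seed(1)
  ord <- sample(nrow(pp$calls))
  perm$calls <- pp$calls[ord, , drop = FALSE]
  cls2 <- group_haplotypes(perm)
  sets1 <- lapply(cls1$groups, function(g) sort(g$members))
  sets2 <- lapply(cls2$groups, function(g) sort(g$members))
  expect_equal(sets1, sets2)
})
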