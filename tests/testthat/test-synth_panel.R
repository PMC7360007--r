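test_that("zero-noise panels are deterministic and collapse to founders", {
  cfg <- tiny_config(het_rate = 0, missing_rate = 0)
  freqs <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(NULL, "pop"))
  cfg2 <- simulation_config(n_sites = 30, flank_sites = 3,
                            flank_span = 1000,
                            founder_frequencies = freqs,
                            subpop_sizes = c(pop = 100),
                            het_rate = 0, missing_rate = 0,
                            indel_haplotype = 2,
                            gene_start = 10000, gene_length = 600,
                            diagnostic_offset_bp = 300)
  panel <- simulate_panel(cfg2, seed = 5)
  distinct <- unique(apply(panel$genotypes$calls, 1, paste, collapse = ""))
  expect_equal(length(distinct), 2L)

  p1 <- simulate_panel(cfg, seed = 11)
  p2 <- simulate_panel(cfg, seed = 11)
  expect_identical(p1, p2)
  p3 <- simulate_panel(cfg, seed = 12)
  expect_false(identical(p1$genotypes$calls, p3$genotypes$calls))
})

test_that("too-close founders are rejected", {
  freqs <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(NULL, "pop"))
  # 8 sites total and radius 10: pairwise distance can never exceed 8
  expect_error(
    simulation_config(n_sites = 6, flank_sites = 1, flank_span = 100,
                      founder_frequencies = freqs,
                      subpop_sizes = c(pop = 10),
                      indel_haplotype = 2, cluster_radius = 10,
                      gene_start = 10000, gene_length = 100,
                      diagnostic_offset_bp = 50),
    "founders too close")
})

test_that("realized founder frequencies converge to the configuration", {
  freqs <- matrix(c(0.5, 0.3, 0.1), 3, 1, dimnames = list(NULL, "pop"))
  cfg <- simulation_config(n_sites = 30, flank_sites = 3,
                           flank_span = 1000,
                           founder_frequencies = freqs,
                           subpop_sizes = c(pop = 10000),
                           het_rate = 0, missing_rate = 0,
                           indel_haplotype = 3,
                           gene_start = 10000, gene_length = 600,
                           diagnostic_offset_bp = 300)
  panel <- simulate_panel(cfg, seed = 77)
  n <- 10000
  for (k in 1:3) {
    obs <- sum(panel$ledger$founder == k, na.rm = TRUE)
    se <- sqrt(n * freqs[k, 1] * (1 - freqs[k, 1]))
    expect_lt(abs(obs - n * freqs[k, 1]), 3 * se, label = paste("founder", k))
  }
  expect_equal(sum(is.na(panel$ledger$founder)),
               n - sum(!is.na(panel$ledger$founder)))
})

test_that("default world reproduces the published counts within binomial bounds", {
  cfg <- simulation_config()
  panel <- simulate_panel(cfg, seed = 31)
  ref <- badh2_3k_panel()
  totals <- colSums(ref$counts)
  violations <- 0L
  for (s in colnames(ref$counts)) {
    n <- totals[[s]]
    for (k in 1:11) {
      p <- ref$counts[k, s] / n
      obs <- sum(panel$ledger$founder == k &
                   panel$ledger$subpopulation == s, na.rm = TRUE)
      lo <- qbinom(0.005, n, p)
      hi <- qbinom(0.995, n, p)
      if (obs < lo || obs > hi) violations <- violations + 1L
    }
  }
  # 77 cells at a 99% interval each: a handful of misses is expected noise
  expect_lte(violations, 3L)
})

test_that("truth ledger, reference marker and diagnostic site are consistent", {
  cfg <- tiny_config()
  panel <- simulate_panel(cfg, seed = 9)
  expect_identical(panel$ledger$carrier,
                   panel$marker$indel_call == "del")
  expect_identical(panel$ledger$carrier,
                   !is.na(panel$ledger$founder) &
                     panel$ledger$founder == cfg$indel_haplotype)
  # private allele at the planted site, at the founder level (pre-noise)
  diag_col <- match(cfg$diagnostic_site, cfg$site_ids)
  expect_equal(unname(cfg$founders[cfg$indel_haplotype, diag_col]), "T")
  expect_true(all(cfg$founders[-cfg$indel_haplotype, diag_col] == "G"))
  # the reference-marker table never carries noise
  expect_false(any(is.na(panel$marker$indel_call)))
})

test_that("phenotype draws respect the carrier and non-carrier ranges", {
  cfg <- tiny_config()
  all_car <- data.frame(sample_id = sprintf("c%02d", 1:40),
                        carrier = TRUE)
  ph <- simulate_phenotypes(all_car, cfg, seed = 3)
  expect_true(all(ph$mean_value >= 0.356))
  expect_true(all(ph$mean_value <= 3.165))

  none <- data.frame(sample_id = sprintf("n%02d", 1:40), carrier = FALSE)
  ph0 <- simulate_phenotypes(none, cfg, seed = 4)
  expect_true(all(ph0$mean_value <= 0.079))
  expect_true(all(ph0$mean_value >= 0))
  # the tabulated mean is the replicate mean
  expect_equal(ph0$mean_value,
               rowMeans(ph0[, paste0("rep", 1:3)]))
})

test_that("mixed panels separate perfectly downstream", {
  led <- data.frame(sample_id = sprintf("m%02d", 1:39),
                    carrier = rep(c(TRUE, FALSE), c(17, 22)))
  cfg <- tiny_config()
  ph <- simulate_phenotypes(led, cfg, seed = 8)
  grp <- setNames(ifelse(led$carrier, "6", "1"), led$sample_id)
  assoc <- aroma_association(grp, ph, threshold_ppm = 0.2)
  expect_true(assoc$perfect_association)
  expect_equal(assoc$per_group$verdict[assoc$per_group$group == "6"],
               "aromatic")
})

test_that("genotyping-job simulation honors rates, counts and discordance", {
  ids <- sprintf("L%03d", 1:351)
  jobs <- simulate_jobs(ids, n_jobs = 3, fail_rate = 0, seed = 1)
  qc <- assay_qc(jobs)
  expect_equal(qc$call_rate, 1)
  expect_equal(qc$reproducibility, 1)

  jobs11 <- simulate_jobs(ids, n_jobs = 3, n_fail = 7, n_ambiguous = 4,
                          seed = 2)
  qc11 <- assay_qc(jobs11)
  expect_equal(qc11$n_reactions, 1053L)
  expect_equal(qc11$n_missing, 11L)
  expect_equal(round_half_away(100 * qc11$call_rate), 99)

  # per-call flip model: P(sample consistent) = p^3 + (1-p)^3
  p <- 0.05
  jd <- simulate_jobs(ids, n_jobs = 3, discordance_rate = p, seed = 3)
  qcd <- assay_qc(jd)
  expected <- p^3 + (1 - p)^3
  bounds <- qbinom(c(0.005, 0.995), 351, expected) / 351
  expect_gte(qcd$reproducibility, bounds[1])
  expect_lte(qcd$reproducibility, bounds[2])
})

test_that("zero-noise recovery is exact against the ledger", {
  cfg <- tiny_config(het_rate = 0, missing_rate = 0,
                     freqs = matrix(c(0.5, 0.3, 0.2), 3, 1,
                                    dimnames = list(NULL, "pop")))
  panel <- simulate_panel(cfg, seed = 21)
  gene <- subset_region(panel$genotypes, cfg$gene_interval)
  cls <- label_rare(group_haplotypes(preprocess(gene)))
  sc <- score_recovery(cls, panel$ledger)
  expect_equal(sc$n_misassigned, 0L)
  # every founder group recovered with exactly the ledger's members
  for (g in cls$groups) {
    truth <- panel$ledger$founder[match(g$members,
                                        panel$ledger$sample_id)]
    expect_equal(length(unique(truth)), 1L)
  }
})
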