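#' Configuration for the synthetic diversity-panel generator
#'
#' Builds the stated world the analysis assumes: a set of well-separated
#' founder haplotype vectors over gene-region and flanking SNPs,
#' subpopulation-specific founder frequencies (defaulting to the published
#' 3K haplotype counts), low-frequency recombinant variants absorbing the
#' residual frequency mass, heterozygous- and missing-call noise, one
#' founder carrying the functional 8-bp deletion plus a flanking SNP in
#' perfect LD with it, and a bimodal 2AP phenotype.
#'
#' Founder vectors and site positions are generated deterministically from
#' `founder_seed` (independent of the panel seed), and validated to be
#' pairwise more than `2 * cluster_radius` mismatches apart, so that the
#' downstream Hamming-radius grouping is well posed.
#'
#' @param n_sites Gene-region SNP count (default 255).
#' @param flank_sites Flanking SNPs per side (default 20).
#' @param flank_span Flank width in bp either side of the gene
#'   (default 10000).
#' @param founder_frequencies Founders x subpopulations probability matrix;
#'   columns may sum to less than 1 and the residual mass becomes random
#'   recombinant variants. Default: the published 3K per-subpopulation
#'   haplotype frequencies, with the rare + unclassified mass as residual.
#' @param subpop_sizes Named integer vector of samples per subpopulation
#'   (default: the 3K subpopulation totals, n = 2932).
#' @param mutation_noise Per-call probability of flipping to the site's
#'   alternate allele (default 0; the stated noise model is het + missing).
#' @param het_rate,missing_rate Independent per-call probabilities of a
#'   heterozygous or missing call (defaults 0.005 and 0.01).
#' @param indel_haplotype Founder index carrying the functional deletion
#'   (default 6).
#' @param diagnostic_offset_bp Distance (bp) of the planted flanking
#'   diagnostic SNP upstream of the gene start (default 7908).
#' @param carrier_range,noncarrier_range 2AP sample-mean ranges in ppm
#'   (defaults 0.356-3.165 and 0-0.079).
#' @param replicate_sd Within-sample replicate noise SD, ppm
#'   (default 0.02).
#' @param n_replicates Phenotype replicates per sample (default 3).
#' @param n_high_missing Samples forced to heavy gene-region missingness,
#'   emulating unclassifiable accessions (default 0).
#' @param high_missing_fraction Fraction of gene sites blanked in those
#'   samples (default 0.6).
#' @param cluster_radius Downstream grouping radius the founders must
#'   respect (default 3).
#' @param chrom,gene_start,gene_length Gene geometry (defaults Chr8,
#'   20,380,000, 6,500 bp).
#' @param founder_seed Seed for founder/site generation (default 3000).
#' @param seed Default panel seed used when [simulate_panel()] is called
#'   without one.
#' @return A list of class `sim_config`, including the realized `founders`
#'   character matrix, `positions`, `site_ids`, `diagnostic_site`,
#'   `gene_interval` and `alleles`.
#' @export
simulation_config <- function(n_sites = 255,
                              flank_sites = 20,
                              flank_span = 10000,
                              founder_frequencies = NULL,
                              subpop_sizes = NULL,
                              mutation_noise = 0,
                              het_rate = 0.005,
                              missing_rate = 0.01,
                              indel_haplotype = 6,
                              diagnostic_offset_bp = 7908,
                              carrier_range = c(0.356, 3.165),
                              noncarrier_range = c(0, 0.079),
                              replicate_sd = 0.02,
                              n_replicates = 3,
                              n_high_missing = 0,
                              high_missing_fraction = 0.6,
                              cluster_radius = 3,
                              chrom = "Chr8",
                              gene_start = 20380000,
                              gene_length = 6500,
                              founder_seed = 3000,
                              seed = 1) {
  rates <- c(mutation_noise, het_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("noise rates must lie in [0, 1]")
  if (is.null(founder_frequencies)) {
    counts <- BADH2_3K_COUNTS
    totals <- colSums(counts)
    founder_frequencies <- sweep(counts[1:11, , drop = FALSE], 2L,
                                 totals, "/")
  }
  if (any(colSums(founder_frequencies) > 1 + 1e-9))
    stop("founder frequencies must sum to <= 1 per subpopulation")
  n_founders <- nrow(founder_frequencies)
  if (indel_haplotype < 1 || indel_haplotype > n_founders)
    stop("indel_haplotype out of range")
  if (is.null(subpop_sizes)) {
    if (identical(colnames(founder_frequencies), BADH2_SUBPOPS))
      subpop_sizes <- colSums(BADH2_3K_COUNTS)
    else stop("subpop_sizes required for custom founder_frequencies")
  }
  stopifnot(identical(sort(names(subpop_sizes)),
                      sort(colnames(founder_frequencies))))

  # anchors: founders common enough that sampling noise cannot push their
  # group below a 1% rare threshold; the carrier's allele must always be
  # shared with an anchor so that no site other than the planted one can
  # become strictly diagnostic, even if a borderline group lands in R
  overall <- rowSums(sweep(founder_frequencies, 2L,
                           subpop_sizes[colnames(founder_frequencies)],
                           "*")) / sum(subpop_sizes)
  anchors <- setdiff(which(overall >= 0.015), indel_haplotype)
  if (!length(anchors)) anchors <- setdiff(seq_len(n_founders),
                                           indel_haplotype)

  geom <- with_local_seed(founder_seed, generate_founders(
    n_sites, flank_sites, flank_span, n_founders, indel_haplotype,
    diagnostic_offset_bp, chrom, gene_start, gene_length, anchors))

  d <- founder_pairwise_distance(geom$founders)
  if (min(d) <= 2 * cluster_radius)
    stop("founders too close: minimum pairwise Hamming distance ", min(d),
         " must exceed 2 * cluster_radius = ", 2 * cluster_radius)

  structure(c(geom, list(
    n_sites = n_sites, flank_sites = flank_sites, flank_span = flank_span,
    founder_frequencies = founder_frequencies,
    subpop_sizes = subpop_sizes,
    mutation_noise = mutation_noise, het_rate = het_rate,
    missing_rate = missing_rate,
    indel_haplotype = indel_haplotype,
    diagnostic_offset_bp = diagnostic_offset_bp,
    carrier_range = carrier_range, noncarrier_range = noncarrier_range,
    replicate_sd = replicate_sd, n_replicates = n_replicates,
    n_high_missing = n_high_missing,
    high_missing_fraction = high_missing_fraction,
    cluster_radius = cluster_radius,
    founder_seed = founder_seed, seed = seed)),
    class = "sim_config")
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

founder_pairwise_distance <- function(founders) {
  n <- nrow(founders)
  d <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- sum(founders[i, ] != founders[j, ])
  d[upper.tri(d)]
}

generate_founders <- function(n_sites, flank_sites, flank_span, n_founders,
                              indel_haplotype, diagnostic_offset_bp, chrom,
                              gene_start, gene_length, anchors) {
  gene_end <- gene_start + gene_length - 1L
  diag_pos <- gene_start - diagnostic_offset_bp
  if (diag_pos < 1L) stop("diagnostic offset larger than gene start")
  gene_pos <- sort(sample(gene_start:gene_end, n_sites))
  left_pool <- setdiff((gene_start - flank_span):(gene_start - 1L),
                       diag_pos)
  left_pos <- sort(c(diag_pos,
                     sample(left_pool, max(0L, flank_sites - 1L))))
  right_pos <- sort(sample((gene_end + 1L):(gene_end + flank_span),
                           flank_sites))
  pos <- c(left_pos, gene_pos, right_pos)

  founders <- matrix(NA_character_, n_founders, length(pos))
  alleles <- character(length(pos))
  for (j in seq_along(pos)) {
    pair <- sample(NUCLEOTIDES, 2L)
    if (pos[j] == diag_pos) {
      pair <- c("G", "T")           # background G, target T
      carriers <- rep(FALSE, n_founders)
      carriers[indel_haplotype] <- TRUE
    } else {
      repeat {
        carriers <- stats::runif(n_founders) < 0.5
        n_alt <- sum(carriers)
        if (n_alt == 0L || n_alt == n_founders) next
        # the indel founder's allele must be shared with an anchor
        # founder, so no site other than the planted one can be strictly
        # diagnostic of it (see simulation_config); with only two
        # founders every site separates them and the constraint is moot
        if (n_founders > 2L) {
          side_of_carrier <- carriers == carriers[indel_haplotype]
          if (!any(side_of_carrier[anchors])) next
        }
        break
      }
    }
    founders[, j] <- ifelse(carriers, pair[2L], pair[1L])
    alleles[j] <- paste(pair, collapse = ",")
  }
  list(founders = founders,
       positions = pos,
       site_ids = paste0(chrom, ":", pos),
       alleles = alleles,
       chrom = chrom,
       diagnostic_site = paste0(chrom, ":", diag_pos),
       gene_interval = list(chrom = chrom, start = gene_start,
                            end = gene_end),
       gene_site_ids = paste0(chrom, ":", gene_pos))
}

#' Simulate a genotype panel with truth ledger
#'
#' Draws a founder haplotype (or a rare recombinant, from the residual
#' frequency mass) per sample within each subpopulation, emits the
#' genotype matrix with het/missing/mutation noise applied after founder
#' assignment, the sample metadata, a noise-free reference-marker call
#' table (`del` for carriers of the functional deletion, `nodel`
#' otherwise), and a truth ledger. Carriers are exactly the samples whose
#' founder is `indel_haplotype`; they carry the private allele at the
#' planted flanking diagnostic site. Recombinants are crossovers of two
#' non-carrier founders, so the diagnostic-site / deletion linkage is
#' never broken by recombination. Deterministic under a fixed
#' config + seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return List of class `sim_panel` with `genotypes`
#'   ([genotype_matrix()] over gene + flank sites), `meta`, `marker`
#'   (data frame `sample_id`, `indel_call`), `ledger` (data frame
#'   `sample_id`, `subpopulation`, `founder` — `NA` for recombinants —
#'   `carrier`, `high_missing`), `noise` (data frame `sample_id`, `site`,
#'   `type`), and `config`.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  freqs <- config$founder_frequencies
  subpops <- names(config$subpop_sizes)
  n_founders <- nrow(freqs)

  founder_draw <- integer(0)
  subpop_lab <- character(0)
  for (s in subpops) {
    n <- config$subpop_sizes[[s]]
    p <- freqs[, s]
    resid <- max(0, 1 - sum(p))
    founder_draw <- c(founder_draw,
                      sample(c(seq_len(n_founders), 0L), n, replace = TRUE,
                             prob = c(p, resid)))
    subpop_lab <- c(subpop_lab, rep(s, n))
  }
  n_samples <- length(founder_draw)
  ids <- sprintf("S%04d", seq_len(n_samples))

  n_sites_all <- length(config$positions)
  calls <- matrix(NA_character_, n_samples, n_sites_all,
                  dimnames = list(ids, NULL))
  is_founder <- founder_draw > 0L
  if (any(is_founder))
    calls[is_founder, ] <- config$founders[founder_draw[is_founder], ,
                                           drop = FALSE]
  # rare recombinant gene haplotypes: crossover of two non-carrier
  # founders with the breakpoint inside the gene region (a breakpoint
  # outside it would not create a new gene haplotype)
  non_carrier_founders <- setdiff(seq_len(n_founders),
                                  config$indel_haplotype)
  # a 2-founder world has no two non-carriers to recombine; fall back to
  # all founders there (the LD guarantee is moot with a single background)
  parent_pool <- if (length(non_carrier_founders) >= 2L)
    non_carrier_founders else seq_len(n_founders)
  gene_idx <- match(config$gene_site_ids, config$site_ids)
  brk_range <- seq(min(gene_idx), max(gene_idx) - 1L)
  for (i in which(!is_founder)) {
    parents <- sample(parent_pool, 2L)
    brk <- sample(brk_range, 1L)
    calls[i, ] <- c(config$founders[parents[1L], seq_len(brk)],
                    config$founders[parents[2L], (brk + 1L):n_sites_all])
  }

  carrier <- is_founder & founder_draw == config$indel_haplotype

  # independent per-call noise, applied after founder assignment;
  # missing overrides het overrides mutation
  noise <- list()
  n_cells <- n_samples * n_sites_all
  if (config$mutation_noise > 0) {
    hit <- which(stats::runif(n_cells) < config$mutation_noise)
    if (length(hit)) {
      pair <- strsplit(config$alleles[ceiling(hit / n_samples)], ",",
                       fixed = TRUE)
      cur <- calls[hit]
      calls[hit] <- vapply(seq_along(hit), function(k) {
        other <- setdiff(pair[[k]], cur[k])
        if (length(other)) other[1L] else cur[k]
      }, character(1))
      noise$mutation <- hit
    }
  }
  if (config$het_rate > 0) {
    hit <- which(stats::runif(n_cells) < config$het_rate)
    calls[hit] <- HET_CALL
    noise$het <- hit
  }
  if (config$missing_rate > 0) {
    hit <- which(stats::runif(n_cells) < config$missing_rate)
    calls[hit] <- NA_character_
    noise$missing <- hit
  }

  high_missing <- rep(FALSE, n_samples)
  if (config$n_high_missing > 0) {
    hm <- sample(n_samples, min(config$n_high_missing, n_samples))
    high_missing[hm] <- TRUE
    gene_cols <- match(config$gene_site_ids, config$site_ids)
    n_blank <- floor(config$high_missing_fraction * length(gene_cols))
    for (i in hm)
      calls[i, sample(gene_cols, n_blank)] <- NA_character_
  }

  gm <- genotype_matrix(calls, config$chrom, config$positions,
                        alleles = config$alleles)
  meta <- data.frame(sample_id = ids, subpopulation = subpop_lab,
                     stringsAsFactors = FALSE)
  marker <- data.frame(sample_id = ids,
                       indel_call = ifelse(carrier, "del", "nodel"),
                       stringsAsFactors = FALSE)
  ledger <- data.frame(
    sample_id = ids, subpopulation = subpop_lab,
    founder = ifelse(is_founder, founder_draw, NA_integer_),
    carrier = carrier, high_missing = high_missing,
    stringsAsFactors = FALSE)

  noise_df <- do.call(rbind, lapply(names(noise), function(type) {
    hit <- noise[[type]]
    data.frame(sample_id = ids[((hit - 1L) %% n_samples) + 1L],
               site = config$site_ids[ceiling(hit / n_samples)],
               type = type, stringsAsFactors = FALSE)
  }))
  if (is.null(noise_df))
    noise_df <- data.frame(sample_id = character(0), site = character(0),
                           type = character(0), stringsAsFactors = FALSE)

  structure(list(genotypes = gm, meta = meta, marker = marker,
                 ledger = ledger, noise = noise_df, config = config),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d samples, %d sites (%d gene + %d flank), %d carriers\n",
              nrow(x$ledger), length(x$config$positions),
              x$config$n_sites, 2L * x$config$flank_sites,
              sum(x$ledger$carrier)))
  invisible(x)
}

#' Simulate replicated 2AP phenotypes from a truth ledger
#'
#' Carriers draw sample-mean 2AP uniformly inside the carrier range,
#' non-carriers inside the non-carrier range; replicates are the drawn
#' mean plus mean-centered Gaussian noise, truncated at zero (so the
#' realized replicate mean equals the drawn mean unless truncation bites).
#'
#' @param ledger Truth ledger from [simulate_panel()] (needs `sample_id`
#'   and `carrier`).
#' @param config A [simulation_config()].
#' @param seed Integer seed (default `config$seed + 1`).
#' @return Data frame `sample_id`, `n_reps`, `mean_value`, `rep1..repN`.
#' @export
simulate_phenotypes <- function(ledger, config, seed = config$seed + 1) {
  set.seed(seed)
  n <- nrow(ledger)
  lo <- ifelse(ledger$carrier, config$carrier_range[1],
               config$noncarrier_range[1])
  hi <- ifelse(ledger$carrier, config$carrier_range[2],
               config$noncarrier_range[2])
  mu <- stats::runif(n, lo, hi)
  k <- config$n_replicates
  eps <- matrix(stats::rnorm(n * k, 0, config$replicate_sd), n, k)
  eps <- eps - rowMeans(eps)
  reps <- mu + eps
  reps[reps < 0] <- 0
  colnames(reps) <- paste0("rep", seq_len(k))
  data.frame(sample_id = ledger$sample_id,
             n_reps = k,
             mean_value = rowMeans(reps),
             reps, stringsAsFactors = FALSE)
}

#' Simulate repeated genotyping jobs for one assay
#'
#' Each (sample, job) reaction is called, failed, or ambiguous. Non-failed
#' repeat calls of a sample are identical by construction unless a
#' `discordance_rate` is set (each called reaction then flips to the other
#' assay allele independently with that probability). Exact missing counts
#' can be requested with `n_fail` / `n_ambiguous` (placed uniformly at
#' random), e.g. to reconstruct a known plate outcome.
#'
#' @param samples Sample ids.
#' @param n_jobs Number of genotyping jobs (default 3).
#' @param fail_rate,ambiguous_rate Per-reaction probabilities
#'   (defaults 0).
#' @param discordance_rate Per-called-reaction flip probability
#'   (default 0).
#' @param true_calls Named character vector sample -> true allele;
#'   defaults to all `"G"`.
#' @param alleles The assay's two alleles (default `c("G", "T")`).
#' @param n_fail,n_ambiguous Optional exact counts overriding the rates.
#' @param seed Optional integer seed.
#' @return Data frame `sample`, `job`, `status`
#'   (`called`/`failed`/`ambiguous`), `call`.
#' @export
simulate_jobs <- function(samples, n_jobs = 3, fail_rate = 0,
                          ambiguous_rate = 0, discordance_rate = 0,
                          true_calls = NULL, alleles = c("G", "T"),
                          n_fail = NULL, n_ambiguous = NULL, seed = NULL) {
  stopifnot(fail_rate >= 0, fail_rate <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_calls))
    true_calls <- stats::setNames(rep(alleles[1], length(samples)),
                                  samples)
  tab <- expand.grid(sample = samples, job = seq_len(n_jobs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(tab)
  status <- rep("called", n)
  if (!is.null(n_fail) || !is.null(n_ambiguous)) {
    n_fail <- if (is.null(n_fail)) 0L else n_fail
    n_ambiguous <- if (is.null(n_ambiguous)) 0L else n_ambiguous
    hit <- sample(n, n_fail + n_ambiguous)
    status[hit[seq_len(n_fail)]] <- "failed"
    if (n_ambiguous > 0)
      status[hit[n_fail + seq_len(n_ambiguous)]] <- "ambiguous"
  } else {
    u <- stats::runif(n)
    status[u < fail_rate] <- "failed"
    status[u >= fail_rate & u < fail_rate + ambiguous_rate] <- "ambiguous"
  }
  call <- ifelse(status == "called", true_calls[tab$sample], NA_character_)
  if (discordance_rate > 0) {
    flip <- status == "called" & stats::runif(n) < discordance_rate
    call[flip] <- ifelse(call[flip] == alleles[1], alleles[2], alleles[1])
  }
  tab$status <- status
  tab$call <- unname(call)
  tab
}

#' Score a classification against a simulation truth ledger
#'
#' Maps each recovered group to its majority truth founder and counts the
#' group members whose truth founder differs (recombinants inside a group
#' always count as misassigned). The misassignment fraction is taken over
#' samples placed in numbered groups.
#'
#' @param classification A `hap_classification`.
#' @param ledger Truth ledger from [simulate_panel()].
#' @return List: `n_classified`, `n_misassigned`, `misassignment`,
#'   `mapping` (data frame `group`, `founder`, `n`, `n_wrong`),
#'   `n_rare`, `n_unclassified`.
#' @export
score_recovery <- function(classification, ledger) {
  truth <- stats::setNames(ledger$founder, ledger$sample_id)
  rows <- lapply(classification$groups, function(g) {
    f <- truth[g$members]
    tab <- sort(table(f, useNA = "no"), decreasing = TRUE)
    modal <- if (length(tab)) as.integer(names(tab)[1L]) else NA_integer_
    n_wrong <- sum(is.na(f) | f != modal)
    data.frame(group = g$group_id, founder = modal,
               n = length(g$members), n_wrong = n_wrong)
  })
  mapping <- do.call(rbind, rows)
  n_classified <- sum(mapping$n)
  n_mis <- sum(mapping$n_wrong)
  list(n_classified = n_classified,
       n_misassigned = n_mis,
       misassignment = if (n_classified) n_mis / n_classified else NA_real_,
       mapping = mapping,
       n_rare = length(classification$rare),
       n_unclassified = length(classification$unclassified))
}
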