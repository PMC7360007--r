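# Build a genotype matrix from haplotype strings ("." = missing, "H" = het)
make_gm <- function(vectors, pos = NULL, chrom = "Chr1",
                    ids = names(vectors)) {
  m <- do.call(rbind, strsplit(vectors, ""))
  m[m == "."] <- NA_character_
  if (is.null(ids)) ids <- paste0("s", seq_along(vectors))
  rownames(m) <- ids
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 10L
  genotype_matrix(m, chrom, pos)
}

# Random biallelic genotype matrix for property tests
rand_gm <- function(seed, n_samples = 20, n_sites = 12,
                    missing_rate = 0.1, het_rate = 0.05) {
  set.seed(seed)
  alleles <- replicate(n_sites, sample(c("A", "C", "G", "T"), 2),
                       simplify = FALSE)
  calls <- vapply(alleles, function(a)
    sample(a, n_samples, replace = TRUE), character(n_samples))
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = n_samples)
  calls[matrix(runif(n_samples * n_sites) < het_rate,
               n_samples)] <- "H"
  calls[matrix(runif(n_samples * n_sites) < missing_rate,
               n_samples)] <- NA_character_
  rownames(calls) <- sprintf("s%03d", seq_len(n_samples))
  genotype_matrix(calls, "Chr1", sort(sample(1e6, n_sites)),
                  alleles = vapply(alleles, paste, "", collapse = ","))
}

# Small, fast simulation world: 3 founders, one subpopulation
tiny_config <- function(..., freqs = matrix(c(0.5, 0.3, 0.15), 3, 1,
                                            dimnames = list(NULL, "pop"))) {
  simulation_config(n_sites = 40, flank_sites = 5, flank_span = 2000,
                    founder_frequencies = freqs,
                    subpop_sizes = c(pop = 200),
                    indel_haplotype = 3,
                    gene_start = 50000, gene_length = 1000,
                    diagnostic_offset_bp = 500, ...)
}

extdata <- function(f) system.file("extdata", f, package = "badhap")

# minimal tag_set over a fixed site list (bypasses selection)
new_tag_set_for_test <- function(cm, sites) {
  structure(list(selected_sites = sites,
                 codes = apply(cm[, sites, drop = FALSE], 1, paste,
                               collapse = ""),
                 resolved_pairs = NULL, unresolved_pairs = NULL),
            class = "tag_set")
}

# independent per-pair separation check used against the tag-set oracle
verify_separation <- function(cm, sites) {
  n <- nrow(cm)
  ok <- TRUE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    full_diff <- any(cm[i, ] != cm[j, ], na.rm = TRUE)
    sub_diff <- length(sites) > 0 &&
      any(cm[i, sites] != cm[j, sites], na.rm = TRUE)
    if (full_diff && !sub_diff) ok <- FALSE
  }
  ok
}
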