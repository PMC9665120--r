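# fixtures shared across the suite; everything is built in code

# small count matrix with explicit counts and equal library sizes so that
# CPM values can be enumerated by hand (library 1e6 -> CPM == count)
make_counts <- function(counts, groups, lib = NULL, sites = NULL) {
  counts <- as.matrix(counts)
  n_loci <- nrow(counts); n_samples <- ncol(counts)
  loci <- data.frame(scaffold = "scaf_01",
                     position = seq_len(n_loci) * 100L,
                     strand = "+", stringsAsFactors = FALSE)
  if (is.null(lib)) lib <- rep(1e6, n_samples)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    group = groups,
    site = if (is.null(sites)) "GUA" else sites,
    library_size = lib, stringsAsFactors = FALSE)
  count_matrix(counts, loci, samples)
}

# NB null matrix: all groups share the per-locus mean; used for calibration
make_null_counts <- function(n_loci, n_per_group, dispersion, seed,
                             groups = c("parent1", "parent2"),
                             meanlog = log(10), sdlog = 1) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  base <- rlnorm(n_loci, meanlog, sdlog)
  lib <- rlnorm(n, log(1e6), 0.25)
  counts <- sapply(seq_len(n), function(j) {
    mu <- base * lib[j] / 1e6
    if (dispersion > 0) rnbinom(n_loci, size = 1 / dispersion, mu = mu)
    else rpois(n_loci, mu)
  })
  make_counts(counts, rep(groups, each = n_per_group),
              lib = pmax(round(lib), colSums(counts) + 1))
}

# minimal dmc_set with given significant ids, for intersection tests
fake_dmc_set <- function(focal, other, sig_ids, all_ids = sig_ids) {
  pos <- as.integer(sub(".*:(\\d+):.*", "\\1", all_ids))
  res <- data.frame(locus_id = all_ids,
                    scaffold = sub(":.*", "", all_ids),
                    position = pos, strand = "+",
                    logFC = 1, p_value = 0.001, q_value = 0.001,
                    significant = all_ids %in% sig_ids,
                    direction = "hypo_in_focal", stringsAsFactors = FALSE)
  structure(list(comparison = c(focal, other), results = res,
                 fdr_threshold = 0.01, n_filter = 1,
                 n_loci_in = length(all_ids), n_loci_tested = length(all_ids)),
            class = "dmc_set")
}
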