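#' Parameters for the msGBS experiment simulator
#'
#' Defaults mirror the design of a two-species hybrid-zone msGBS study:
#' 22 parent-1, 17 parent-2 and 5 F1-hybrid individuals.  Methylation is
#' represented directly on the expected-count scale: methylation blocks the
#' methylation-sensitive cut, so a more methylated site yields a lower
#' expected CPM.  Divergent loci split the two species symmetrically by
#' `effect_log2fc` on the log2 scale; hybrids at those loci are additive
#' (log2-midpoint of the parents), overdominant (above the higher parent by
#' `transgressive_log2fc`) or underdominant (below the lower parent by the
#' same amount) with probabilities `inheritance_mix`.
#'
#' @param n_loci number of cut-site loci.
#' @param n_p1,n_p2,n_hybrid samples per group (defaults 22, 17, 5).
#' @param frac_divergent fraction of loci with species-divergent
#'   methylation (default 0.2).
#' @param inheritance_mix named probabilities (additive, overdominant,
#'   underdominant) for divergent loci; must sum to 1.  Default
#'   c(0.9, 0.06, 0.04), reflecting the predominance of additive
#'   inheritance.
#' @param effect_log2fc log2 fold difference between the species at
#'   divergent loci (default 3, i.e. 8-fold).
#' @param transgressive_log2fc log2 shift beyond the nearer parent for
#'   transgressive loci (default 1, i.e. 2-fold beyond the parental range).
#' @param dispersion negative-binomial dispersion of counts (default 0.2).
#' @param library_size_mean,library_size_cv log-normal library-size model
#'   (defaults 1e6 and 0.3).
#' @param baseline_cpm_meanlog,baseline_cpm_sdlog log-normal baseline
#'   expected CPM per locus (defaults log(10) and 1: a long-tailed
#'   abundance distribution).
#' @param n_markers number of species-diagnostic SNP markers (default 200).
#' @param n_scaffolds scaffolds over which loci are spread (default 20).
#' @param frac_annotated_scaffolds fraction of scaffolds carrying gene
#'   annotation (default 0.75).
#' @param seed integer seed; one global seed drives independent sub-streams
#'   for counts, library sizes and genotypes.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_loci = 2000, n_p1 = 22, n_p2 = 17,
                              n_hybrid = 5, frac_divergent = 0.2,
                              inheritance_mix = c(additive = 0.9,
                                                  overdominant = 0.06,
                                                  underdominant = 0.04),
                              effect_log2fc = 3, transgressive_log2fc = 1,
                              dispersion = 0.2,
                              library_size_mean = 1e6, library_size_cv = 0.3,
                              baseline_cpm_meanlog = log(10),
                              baseline_cpm_sdlog = 1,
                              n_markers = 200, n_scaffolds = 20,
                              frac_annotated_scaffolds = 0.75, seed = 1) {
  p <- as.list(environment())
  if (abs(sum(p$inheritance_mix) - 1) > 1e-8 || any(p$inheritance_mix < 0))
    eh_stop("inheritance_mix must be non-negative and sum to 1",
            "eh_bad_params")
  if (p$frac_divergent < 0 || p$frac_divergent > 1)
    eh_stop("frac_divergent must be in [0, 1]", "eh_bad_params")
  if (p$effect_log2fc <= 0 || p$transgressive_log2fc <= 0 || p$dispersion < 0)
    eh_stop("effect sizes must be positive and dispersion non-negative",
            "eh_bad_params")
  structure(p, class = "simulation_params")
}

# derive independent sub-seeds (< 2^31) from the global seed so that, e.g.,
# changing n_markers leaves the count stream untouched
sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + k

#' Simulate a complete msGBS experiment with known truth
#'
#' Generates a locus x sample count matrix (negative-binomial counts with
#' log-normal library sizes), SNP dosages mixing fixed species-diagnostic
#' markers (parent1 = 0, parent2 = 2, hybrids = 1) with shared polymorphic
#' markers, gene models tiling a fraction of the
#' scaffolds so that every context category is populated, and a truth table
#' carrying the per-locus expected group CPMs, divergence flags and
#' inheritance modes.  Fully reproducible from `params$seed`.
#'
#' @param params a [simulation_params()] list.
#' @return list of class `msgbs_simulation` with elements `counts`
#'   ([count_matrix()]), `genotypes` ([genotype_matrix()]), `genes`
#'   (data.frame of gene models), `truth` (list: `loci` truth table,
#'   `samples`, `params`, `seed`).
#' @export
simulate_experiment <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params

  # --- locus geometry (count stream) -------------------------------------
  set.seed(sub_seed(p$seed, 1L))
  scaffolds <- sprintf("scaf_%02d", seq_len(p$n_scaffolds))
  scaf <- sample(scaffolds, p$n_loci, replace = TRUE)
  pos <- integer(p$n_loci)
  for (s in scaffolds) {
    i <- which(scaf == s)
    pos[i] <- sort(sample.int(2e6, length(i)))
  }
  strand <- sample(c("+", "-"), p$n_loci, replace = TRUE)
  loci <- data.frame(scaffold = scaf, position = pos, strand = strand,
                     stringsAsFactors = FALSE)
  loci$locus_id <- locus_ids(scaf, pos, strand)

  # --- true group means on the CPM scale ---------------------------------
  base <- rlnorm(p$n_loci, p$baseline_cpm_meanlog, p$baseline_cpm_sdlog)
  divergent <- runif(p$n_loci) < p$frac_divergent
  sign_dir <- sample(c(-1, 1), p$n_loci, replace = TRUE)
  half <- p$effect_log2fc / 2
  mu_p1 <- ifelse(divergent, base * 2^(sign_dir * half), base)
  mu_p2 <- ifelse(divergent, base * 2^(-sign_dir * half), base)
  mode <- rep(NA_character_, p$n_loci)
  mode[divergent] <- sample(names(p$inheritance_mix), sum(divergent),
                            replace = TRUE, prob = p$inheritance_mix)
  mu_h <- base  # non-divergent loci: all groups share the baseline
  mid <- sqrt(mu_p1 * mu_p2)            # log2-scale midpoint
  hi <- pmax(mu_p1, mu_p2); lo <- pmin(mu_p1, mu_p2)
  mu_h[divergent] <- mid[divergent]
  over <- divergent & mode == "overdominant"
  under <- divergent & mode == "underdominant"
  mu_h[over] <- hi[over] * 2^p$transgressive_log2fc
  mu_h[under] <- lo[under] * 2^(-p$transgressive_log2fc)

  # --- samples and library sizes (library stream) ------------------------
  set.seed(sub_seed(p$seed, 2L))
  groups <- rep(c("parent1", "parent2", "hybrid"),
                c(p$n_p1, p$n_p2, p$n_hybrid))
  n_samples <- length(groups)
  sdlog <- sqrt(log(1 + p$library_size_cv^2))
  lib <- rlnorm(n_samples, log(p$library_size_mean) - sdlog^2 / 2, sdlog)
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", groups, stats::ave(seq_len(n_samples),
                                                      groups, FUN = seq_along)),
    group = groups,
    site = rep_len(c("GUA", "FUN"), n_samples),
    stringsAsFactors = FALSE)

  # --- counts (count stream, continued) ----------------------------------
  set.seed(sub_seed(p$seed, 3L))
  mu_group <- cbind(parent1 = mu_p1, parent2 = mu_p2, hybrid = mu_h)
  counts <- matrix(0L, p$n_loci, n_samples)
  size <- if (p$dispersion > 0) 1 / p$dispersion else Inf
  for (j in seq_len(n_samples)) {
    mu_j <- mu_group[, groups[j]] * lib[j] / 1e6
    counts[, j] <- if (is.finite(size)) rnbinom(p$n_loci, size = size, mu = mu_j)
                   else stats::rpois(p$n_loci, mu_j)
  }
  # the sheet's library size is the full sequenced library; ensure it always
  # dominates the on-target total even in extreme draws
  samples$library_size <- pmax(round(lib), colSums(counts) + 1)
  cm <- count_matrix(counts, loci, samples)

  # --- genotypes (genotype stream) ---------------------------------------
  # half the markers are fixed species-diagnostic (parent1 = 0, parent2 = 2,
  # F1 hybrids heterozygous = 1); the rest segregate in all groups at
  # intermediate frequency, as in real SNP panels, so that Bray-Curtis
  # dosage distances place hybrids between the parental clusters
  set.seed(sub_seed(p$seed, 4L))
  n_diag <- ceiling(p$n_markers / 2)
  dos <- matrix(NA_real_, p$n_markers, n_samples)
  dos[seq_len(n_diag), groups == "parent1"] <- 0
  dos[seq_len(n_diag), groups == "parent2"] <- 2
  dos[seq_len(n_diag), groups == "hybrid"] <- 1
  if (p$n_markers > n_diag) {
    shared <- (n_diag + 1):p$n_markers
    freq <- runif(length(shared), 0.2, 0.8)
    dos[shared, ] <- rbinom(length(shared) * n_samples, 2, rep(freq, n_samples))
  }
  rownames(dos) <- sprintf("snp_%04d", seq_len(p$n_markers))
  colnames(dos) <- samples$sample_id
  gm <- genotype_matrix(dos)

  # --- gene models tiling annotated scaffolds ----------------------------
  n_annot <- max(1, round(p$frac_annotated_scaffolds * p$n_scaffolds))
  annot_scaffolds <- scaffolds[seq_len(n_annot)]
  genes <- do.call(rbind, lapply(annot_scaffolds, function(s) {
    starts <- seq(5000L, 2e6L, by = 25000L)  # ~5 kb genes every 25 kb
    data.frame(gene_id = sprintf("gene_%s_%03d", s, seq_along(starts)),
               scaffold = s, start = starts, end = starts + 4999L,
               strand = rep_len(c("+", "-"), length(starts)),
               stringsAsFactors = FALSE)
  }))

  truth_loci <- data.frame(loci,
                           true_cpm_p1 = mu_p1, true_cpm_p2 = mu_p2,
                           true_cpm_hybrid = mu_h, divergent = divergent,
                           mode = mode, stringsAsFactors = FALSE)
  structure(list(counts = cm, genotypes = gm, genes = genes,
                 truth = list(loci = truth_loci, samples = samples,
                              params = p, seed = p$seed)),
            class = "msgbs_simulation")
}

#' @exportS3Method base::print
print.msgbs_simulation <- function(x, ...) {
  cat(sprintf("simulated msGBS experiment (seed %d): %d loci, %d samples, %d markers\n",
              x$truth$seed, nrow(x$counts$counts), ncol(x$counts$counts),
              nrow(x$genotypes$genotypes)))
  cat(sprintf("  divergent loci: %d (%.1f%%)\n", sum(x$truth$loci$divergent),
              100 * mean(x$truth$loci$divergent)))
  invisible(x)
}

#' Write a simulated experiment to disk as plain-text fixtures
#'
#' Writes the counts TSV + sample sheet, a GFF3 of the gene models, the
#' dosage TSV and the truth table, all directly readable by the package's
#' input functions.
#'
#' @param sim an `msgbs_simulation` from [simulate_experiment()].
#' @param directory output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
export_fixture <- function(sim, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             samples = file.path(directory, "samples.tsv"),
             genes = file.path(directory, "genes.gff3"),
             genotypes = file.path(directory, "genotypes.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_count_matrix(sim$counts, paths["counts"], paths["samples"])
  write_gff3(sim$genes, paths["genes"])
  write_genotypes(sim$genotypes, paths["genotypes"])
  write.table(sim$truth$loci, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame of gene models (as from [read_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$scaffold,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "epihybrid"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate pairwise epigenetic distances from the MLPE model
#'
#' Draws individuals on a 2-D "genetic" plane, takes their Euclidean
#' distances as the genetic distance matrix, and generates epigenetic
#' pairwise values from the pairwise mixed model itself:
#' epi_ij = intercept + beta * gen_ij + a_i + a_j + e_ij, with individual
#' effects a ~ N(0, sd_id^2) and noise e ~ N(0, sd_resid^2).  Used for
#' parameter-recovery validation of [fit_pairwise_mixed_model()].
#'
#' @param n_individuals number of individuals (default 30).
#' @param beta true slope on genetic distance (default 0.5).
#' @param sd_id individual random-effect SD (default 0.2).
#' @param sd_resid residual SD (default 0.1).
#' @param intercept baseline distance (default 0.5).
#' @param seed integer seed.
#' @return list with `epi_d`, `gen_d` (matrices), `samples` (data.frame),
#'   and the true parameters.
#' @export
simulate_pairwise_distances <- function(n_individuals = 30, beta = 0.5,
                                        sd_id = 0.2, sd_resid = 0.1,
                                        intercept = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("ind_%02d", seq_len(n_individuals))
  xy <- matrix(runif(2 * n_individuals), ncol = 2)
  gen_d <- as.matrix(dist(xy))
  a <- rnorm(n_individuals, 0, sd_id)
  epi_d <- matrix(0, n_individuals, n_individuals)
  for (i in seq_len(n_individuals - 1)) {
    for (j in (i + 1):n_individuals) {
      v <- intercept + beta * gen_d[i, j] + a[i] + a[j] + rnorm(1, 0, sd_resid)
      epi_d[i, j] <- epi_d[j, i] <- v
    }
  }
  dimnames(gen_d) <- dimnames(epi_d) <- list(ids, ids)
  samples <- data.frame(sample_id = ids,
                        group = rep_len(c("parent1", "parent2", "hybrid"),
                                        n_individuals),
                        site = rep_len(c("GUA", "FUN"), n_individuals),
                        stringsAsFactors = FALSE)
  list(epi_d = epi_d, gen_d = gen_d, samples = samples,
       beta = beta, sd_id = sd_id, sd_resid = sd_resid, seed = seed)
}
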