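#' Configuration for the full msGBS hybrid-methylation pipeline
#'
#' @param counts a [count_matrix()] or path to a counts TSV.
#' @param samples sample sheet path (required when `counts` is a path).
#' @param genes gene models data.frame or GFF3 path (optional; context
#'   stage is skipped without it).
#' @param genotypes a [genotype_matrix()] or dosage TSV / VCF path
#'   (optional; Mantel and mixed-model stages are skipped without it).
#' @param output_dir directory for all stage outputs.
#' @param fdr_threshold DMC significance threshold (default 0.01).
#' @param cpm_threshold occupancy-filter CPM threshold (default 1).
#' @param promoter_window promoter window in bp (default 2000).
#' @param n_permutations Mantel permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param mds_k MDS dimensions (default 2).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples = NULL, genes = NULL,
                            genotypes = NULL, output_dir,
                            fdr_threshold = 0.01, cpm_threshold = 1,
                            promoter_window = 2000, n_permutations = 999,
                            seed = 1, mds_k = 2) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    eh_stop("fdr_threshold must be in (0, 1]", "eh_bad_config")
  if (cpm_threshold <= 0) eh_stop("cpm_threshold must be > 0", "eh_bad_config")
  if (promoter_window < 0) eh_stop("promoter_window must be >= 0", "eh_bad_config")
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full hybrid-methylation analysis pipeline
#'
#' Orchestrates the complete analysis on one dataset: the three pairwise
#' DMC comparisons (parent1 vs parent2, hybrid vs each parent, each with
#' its own occupancy filter), the common-DMC intersection, inheritance
#' classification of the parental and common DMC sets, genomic-context
#' tabulation, MDS of the parental DMCs and of all loci, hierarchical
#' clustering of scaled common-DMC profiles, Bray-Curtis genetic and
#' epigenetic distances with a Mantel test, and the pairwise mixed model.
#' All stage outputs are written as TSV (plus Newick for the dendrogram)
#' under `config$output_dir`, together with a JSON-lines manifest recording
#' per-stage row counts and the seed; given identical inputs and seed the
#' stage outputs are byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `epihybrid_pipeline`: list with `manifest`
#'   (data.frame of stages), `paths` (named output files), and the
#'   in-memory stage `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list()
  paths <- character()
  note_stage <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      eh_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)), "eh_stage_failure")
    })
  }

  # 1. inputs -------------------------------------------------------------
  m <- run_stage("load_inputs", {
    if (inherits(config$counts, "count_matrix")) config$counts
    else read_count_matrix(config$counts, config$samples)
  })
  genes <- if (is.null(config$genes)) NULL
           else if (is.data.frame(config$genes)) config$genes
           else read_gene_models(config$genes)
  geno <- if (is.null(config$genotypes)) NULL
          else if (inherits(config$genotypes, "genotype_matrix")) config$genotypes
          else read_genotypes(config$genotypes)
  note_stage("load_inputs", nrow(m$counts), nrow(m$counts))

  # 2-4. the three DMC comparisons ----------------------------------------
  comparisons <- list(
    parent1_vs_parent2 = c("parent1", "parent2"),
    hybrid_vs_parent1 = c("hybrid", "parent1"),
    hybrid_vs_parent2 = c("hybrid", "parent2"))
  dmc_sets <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    ds <- run_stage(paste0("dmc_", nm),
                    call_dmcs(m, cmp[1], cmp[2],
                              fdr_threshold = config$fdr_threshold,
                              cpm_threshold = config$cpm_threshold))
    dmc_sets[[nm]] <- ds
    paths[paste0("dmc_", nm)] <- write_tsv(ds$results, out(paste0("dmc_", nm, ".tsv")))
    note_stage(paste0("dmc_", nm), ds$n_loci_in, sum(ds$results$significant))
  }

  # 5. common DMCs ---------------------------------------------------------
  common <- run_stage("common_dmcs",
                      intersect_dmcs(dmc_sets$hybrid_vs_parent1,
                                     dmc_sets$hybrid_vs_parent2))
  paths["common_dmcs"] <- write_tsv(data.frame(locus_id = common),
                                    out("common_dmcs.tsv"))
  note_stage("common_dmcs",
             sum(dmc_sets$hybrid_vs_parent1$results$significant),
             length(common))

  # 6. inheritance ---------------------------------------------------------
  parental_dmcs <- with(dmc_sets$parent1_vs_parent2$results,
                        locus_id[significant])
  inh <- run_stage("inheritance", {
    res <- list()
    for (set_nm in c("parental", "common")) {
      ids <- if (set_nm == "parental") parental_dmcs else common
      if (length(ids) == 0) {
        res[[set_nm]] <- NULL
        next
      }
      calls <- classify_inheritance(m, ids)
      res[[set_nm]] <- list(calls = calls, summary = summarize_inheritance(calls))
    }
    res
  })
  for (set_nm in names(inh)) {
    paths[paste0("inheritance_", set_nm)] <-
      write_tsv(inh[[set_nm]]$calls, out(paste0("inheritance_", set_nm, ".tsv")))
    paths[paste0("inheritance_", set_nm, "_summary")] <-
      write_tsv(as.data.frame(inh[[set_nm]]$summary),
                out(paste0("inheritance_", set_nm, "_summary.tsv")))
  }
  note_stage("inheritance",
             length(parental_dmcs) + length(common),
             sum(vapply(inh, function(x) nrow(x$calls), integer(1))))

  # 7. genomic context of the common DMCs ----------------------------------
  context_tab <- NULL
  if (!is.null(genes) && length(common) > 0) {
    ann <- run_stage("context", {
      loci_tab <- m$loci[match(common, m$loci$locus_id), , drop = FALSE]
      annotate_context(loci_tab, genes,
                       promoter_window = config$promoter_window)
    })
    context_tab <- tabulate_context(ann)
    paths["context"] <- write_tsv(ann, out("context.tsv"))
    paths["context_summary"] <- write_tsv(context_tab, out("context_summary.tsv"))
    note_stage("context", length(common), nrow(ann))
  } else note_stage("context", length(common), 0L)

  # 8. ordination and clustering -------------------------------------------
  cpm <- cpm_normalize(m)
  ord <- run_stage("ordination", {
    res <- list()
    if (length(parental_dmcs) >= 2) {
      d <- euclidean_distances(t(cpm[parental_dmcs, , drop = FALSE]))
      res$mds_parental <- classical_mds(d, k = config$mds_k)
    }
    res$mds_all <- classical_mds(euclidean_distances(t(cpm)), k = config$mds_k)
    if (length(common) >= 2) {
      scaled <- scale_profiles(cpm, common)
      res$dendrogram <- hierarchical_cluster(scaled)
    }
    res
  })
  if (!is.null(ord$mds_parental))
    paths["mds_parental"] <- write_tsv(
      data.frame(sample_id = rownames(ord$mds_parental$points),
                 ord$mds_parental$points, check.names = FALSE),
      out("mds_parental.tsv"))
  paths["mds_all"] <- write_tsv(
    data.frame(sample_id = rownames(ord$mds_all$points),
               ord$mds_all$points, check.names = FALSE),
    out("mds_all.tsv"))
  if (!is.null(ord$dendrogram)) {
    paths["dendrogram"] <- out("dendrogram.nwk")
    writeLines(cluster_newick(ord$dendrogram), paths["dendrogram"])
  }
  note_stage("ordination", ncol(cpm), ncol(cpm))

  # 9. distances, Mantel, mixed model --------------------------------------
  mantel <- NULL; mlpe <- NULL
  if (!is.null(geno) && length(common) >= 2) {
    res9 <- run_stage("distance_models", {
      epi_d <- bray_curtis_distances(t(cpm[common, , drop = FALSE]))
      gen_d <- bray_curtis_distances(t(geno$genotypes), pairwise_deletion = TRUE)
      stopifnot(identical(rownames(epi_d), rownames(gen_d)))
      mt <- mantel_test(epi_d, gen_d, n_permutations = config$n_permutations,
                        seed = config$seed)
      fit <- fit_pairwise_mixed_model(epi_d, gen_d, m$samples)
      list(mantel = mt, mlpe = fit)
    })
    mantel <- res9$mantel; mlpe <- res9$mlpe
    paths["mantel"] <- write_tsv(
      data.frame(r = mantel$r, p_value = mantel$p_value,
                 n_permutations = mantel$n_permutations, seed = mantel$seed),
      out("mantel.tsv"))
    paths["mlpe"] <- write_tsv(
      data.frame(term = c(names(mlpe$coefficients),
                          paste0("var_", names(mlpe$variance_components)),
                          "aic", "aic_fixed_only", "delta_aic"),
                 estimate = c(unname(mlpe$coefficients),
                              unname(mlpe$variance_components),
                              mlpe$aic, mlpe$aic_fixed_only, mlpe$delta_aic)),
      out("mlpe.tsv"))
    note_stage("distance_models", length(common), 2L)
  } else note_stage("distance_models", length(common), 0L)

  manifest <- do.call(rbind, manifest)
  header <- jsonlite::toJSON(list(
    type = "run", package = "epihybrid",
    version = as.character(packageVersion("epihybrid")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, fdr_threshold = config$fdr_threshold,
    cpm_threshold = config$cpm_threshold,
    promoter_window = config$promoter_window,
    n_permutations = config$n_permutations), auto_unbox = TRUE)
  stage_lines <- vapply(seq_len(nrow(manifest)), function(i)
    as.character(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE)),
    character(1))
  paths["manifest"] <- out("manifest.jsonl")
  writeLines(c(as.character(header), stage_lines), paths["manifest"])

  structure(list(manifest = manifest, paths = paths,
                 results = list(dmc = dmc_sets, common_dmcs = common,
                                inheritance = inh, context = context_tab,
                                ordination = ord, mantel = mantel,
                                mlpe = mlpe)),
            class = "epihybrid_pipeline")
}

#' @exportS3Method base::print
print.epihybrid_pipeline <- function(x, ...) {
  cat("epihybrid pipeline run\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
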