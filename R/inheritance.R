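#' Classify hybrid methylation inheritance at DMC loci
#'
#' For each locus the group mean CPM is computed for the two parental
#' species and the hybrids.  A locus is `additive` when the hybrid mean lies
#' in the closed interval between the parental means (intermediate
#' methylation), `overdominant` when it is strictly above the larger
#' parental mean (more reads = less methylation than either parent), and
#' `underdominant` when strictly below the smaller.  Boundary equality is
#' additive: transgression is defined strictly, and with continuous CPMs
#' exact ties are measure-zero.  The classification is symmetric in the two
#' parental labels.
#'
#' @param m a [count_matrix()] containing parent1, parent2 and hybrid
#'   samples.
#' @param loci locus_ids to classify (typically a DMC set); `NULL` uses all
#'   loci in `m`.
#' @return data.frame with columns `locus_id`, `mean_cpm_p1`, `mean_cpm_p2`,
#'   `mean_cpm_hybrid`, `mode` (factor: additive / overdominant /
#'   underdominant).
#' @export
classify_inheritance <- function(m, loci = NULL) {
  for (g in c("parent1", "parent2", "hybrid")) samples_in_group(m, g)
  if (!is.null(loci)) {
    missing <- setdiff(loci, m$loci$locus_id)
    if (length(missing) > 0)
      eh_stop(paste("loci absent from count matrix:",
                    paste(head(missing, 5), collapse = ", ")),
              "eh_unknown_locus")
    m <- m[loci, ]
  }
  cpm <- cpm_normalize(m)
  mu <- function(g) rowMeans(cpm[, m$samples$group == g, drop = FALSE])
  p1 <- mu("parent1"); p2 <- mu("parent2"); h <- mu("hybrid")
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  mode <- ifelse(h > hi, "overdominant", ifelse(h < lo, "underdominant", "additive"))
  data.frame(locus_id = m$loci$locus_id,
             mean_cpm_p1 = p1, mean_cpm_p2 = p2, mean_cpm_hybrid = h,
             mode = factor(mode, levels = c("additive", "overdominant",
                                            "underdominant")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate inheritance-mode calls
#'
#' @param calls the data.frame returned by [classify_inheritance()], or a
#'   character/factor vector of modes.
#' @return object of class `inheritance_summary`: list with `n_total`,
#'   `n_additive`, `n_overdominant`, `n_underdominant` and the matching
#'   percentages rounded to one decimal.
#' @export
summarize_inheritance <- function(calls) {
  modes <- if (is.data.frame(calls)) calls$mode else calls
  if (length(modes) == 0) eh_stop("no inheritance calls", "eh_empty_calls")
  modes <- factor(as.character(modes),
                  levels = c("additive", "overdominant", "underdominant"))
  if (anyNA(modes)) eh_stop("unknown inheritance mode", "eh_bad_mode")
  n <- table(modes)
  total <- length(modes)
  structure(list(n_total = total,
                 n_additive = unname(n["additive"]),
                 n_overdominant = unname(n["overdominant"]),
                 n_underdominant = unname(n["underdominant"]),
                 pct_additive = round(100 * n[["additive"]] / total, 1),
                 pct_overdominant = round(100 * n[["overdominant"]] / total, 1),
                 pct_underdominant = round(100 * n[["underdominant"]] / total, 1)),
            class = "inheritance_summary")
}

#' @exportS3Method base::print
print.inheritance_summary <- function(x, ...) {
  cat(sprintf("inheritance of %d DMCs:\n", x$n_total))
  cat(sprintf("  additive      %6d (%.1f%%)\n", x$n_additive, x$pct_additive))
  cat(sprintf("  overdominant  %6d (%.1f%%)\n", x$n_overdominant, x$pct_overdominant))
  cat(sprintf("  underdominant %6d (%.1f%%)\n", x$n_underdominant, x$pct_underdominant))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.inheritance_summary <- function(x, ...) {
  data.frame(mode = c("additive", "overdominant", "underdominant"),
             n = c(x$n_additive, x$n_overdominant, x$n_underdominant),
             pct = c(x$pct_additive, x$pct_overdominant, x$pct_underdominant),
             stringsAsFactors = FALSE)
}

#' Scale per-locus profiles to z-scores across samples
#'
#' Each locus row is centred to mean 0 and scaled to unit (sample) standard
#' deviation across samples; zero-variance rows map to all-zero rows.
#'
#' @param cpm loci x samples numeric matrix (e.g. from [cpm_normalize()]).
#' @param loci optional row subset (locus_ids or indices).
#' @return matrix of z-scores, same orientation.
#' @export
scale_profiles <- function(cpm, loci = NULL) {
  if (!is.null(loci)) cpm <- cpm[loci, , drop = FALSE]
  ctr <- cpm - rowMeans(cpm)
  s <- apply(cpm, 1, sd)
  s[s == 0] <- Inf  # constant rows -> all zeros
  ctr / s
}

#' Hierarchical clustering of samples on scaled methylation profiles
#'
#' Agglomerative clustering of samples using Euclidean distance between
#' scaled per-locus profiles, with average (UPGMA) linkage by default.
#' Merge order is deterministic given the input; ties are resolved by
#' sample order as in [stats::hclust()].
#'
#' @param scaled loci x samples z-score matrix from [scale_profiles()].
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return an `hclust` object over the samples.
#' @export
hierarchical_cluster <- function(scaled, linkage = "average") {
  if (ncol(scaled) < 2) eh_stop("need at least 2 samples", "eh_too_few_samples")
  hclust(dist(t(scaled)), method = linkage)
}

#' Serialize a sample dendrogram as a Newick string
#'
#' @param hc an `hclust` object (e.g. from [hierarchical_cluster()]).
#' @return single-element character vector: the Newick tree.
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
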