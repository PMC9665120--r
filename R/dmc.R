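#' Estimate negative-binomial dispersion from grouped counts
#'
#' A common dispersion is estimated by maximizing the negative-binomial
#' conditional log-likelihood (conditioning on each group's locus total,
#' which removes the locus- and group-specific means) pooled over all loci
#' and groups, after scaling counts to a common effective library size.  A
#' per-locus estimate maximizes the same conditional likelihood locus by
#' locus and is then shrunk toward the common value by a fixed-weight
#' convex combination; with the few samples per group typical of msGBS
#' studies the default puts most weight (0.8) on the common value.
#'
#' @param m a [count_matrix()].
#' @param groups group labels defining the grouping; defaults to all groups
#'   present.
#' @param shrinkage_weight weight in \[0, 1\] on the common dispersion in the
#'   per-locus shrinkage (default 0.8).
#' @return object of class `dispersion_estimate`: list with `common`,
#'   `per_locus` (named by locus_id), `shrinkage_weight`.
#' @export
estimate_dispersion <- function(m, groups = NULL, shrinkage_weight = 0.8) {
  if (shrinkage_weight < 0 || shrinkage_weight > 1)
    eh_stop("shrinkage_weight must be in [0, 1]", "eh_bad_dispersion")
  if (is.null(groups)) groups <- unique(m$samples$group)
  if (ncol(m$counts) < 2) eh_stop("need at least 2 samples", "eh_bad_dispersion")
  if (all(m$counts == 0)) eh_stop("all counts are zero", "eh_all_zero")
  lib <- m$samples$library_size
  pseudo <- sweep(m$counts, 2, mean(lib) / lib, `*`)
  group_cols <- lapply(groups, function(g) which(m$samples$group == g))
  group_cols <- group_cols[lengths(group_cols) >= 2]  # singletons carry no information
  if (length(group_cols) == 0)
    eh_stop("no group with >= 2 samples", "eh_bad_dispersion")

  cond_ll <- function(phi, rows = NULL) {
    r <- 1 / phi
    tot <- 0
    for (cols in group_cols) {
      y <- pseudo[, cols, drop = FALSE]
      if (!is.null(rows)) y <- y[rows, , drop = FALSE]
      n <- length(cols)
      z <- rowSums(y)
      ll <- rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) -
        lgamma(n * r + z)
      tot <- tot + sum(ll[z > 0])
    }
    tot
  }
  lo <- log(1e-6); hi <- log(20)
  opt <- optimize(function(lp) cond_ll(exp(lp)), c(lo, hi), maximum = TRUE)
  common <- exp(opt$maximum)
  # boundary = effectively Poisson; floor at 0
  if (opt$maximum <= lo + 1e-3 || cond_ll(1e-6) >= opt$objective) common <- 0

  n_loci <- nrow(m$counts)
  per <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    has_var <- any(vapply(group_cols, function(cols)
      length(unique(pseudo[i, cols])) > 1, logical(1)))
    if (!has_var) { per[i] <- 0; next }
    oi <- optimize(function(lp) cond_ll(exp(lp), rows = i), c(lo, hi),
                   maximum = TRUE)
    per[i] <- if (oi$maximum <= lo + 1e-3) 0 else exp(oi$maximum)
  }
  per <- shrinkage_weight * common + (1 - shrinkage_weight) * per
  structure(list(common = common,
                 per_locus = setNames(per, m$loci$locus_id),
                 shrinkage_weight = shrinkage_weight),
            class = "dispersion_estimate")
}

#' @exportS3Method base::print
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("NB dispersion estimate: common = %.4g, %d loci, shrinkage weight %.2f\n",
              x$common, length(x$per_locus), x$shrinkage_weight))
  invisible(x)
}

# Exact conditional two-sided NB p-value for one locus.
# za, zb: integer group totals after library-size equalization;
# na, nb: group sizes; phi: per-sample NB dispersion.  Conditional on the
# grand total z, the group-A total follows the distribution of the split of
# z between NB(na/phi) and NB(nb/phi) components; at phi = 0 this is exactly
# Binomial(z, na/(na+nb)).  Two-sided p sums the probabilities of all splits
# no more likely than the observed one (minimum-likelihood rule, ties in).
exact_nb_pvalue <- function(za, zb, na, nb, phi) {
  z <- za + zb
  if (z == 0) return(1)
  a <- 0:z
  if (phi <= 0) {
    logp <- dbinom(a, z, na / (na + nb), log = TRUE)
  } else {
    r <- 1 / phi
    mu <- z / (na + nb)
    logp <- dnbinom(a, size = na * r, mu = na * mu, log = TRUE) +
      dnbinom(z - a, size = nb * r, mu = nb * mu, log = TRUE)
  }
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  p_obs <- w[za + 1]
  min(1, sum(w[w <= p_obs * (1 + 1e-7)]))
}

#' Exact conditional NB test for differential methylation, per locus
#'
#' Two-group exact test on read counts.  Counts are scaled to the mean
#' library size of the compared samples (equal effective libraries), group
#' totals are formed, and a two-sided exact p-value is computed for the
#' split of each locus total between the groups under a negative-binomial
#' model with the supplied dispersion; at dispersion 0 the test reduces
#' exactly to the conditional binomial test.  logFC is
#' log2((meanCPM_a + c) / (meanCPM_b + c)) with pseudo-count `c` in CPM
#' units, with `group_a` the focal group: positive logFC means more reads
#' (more cutting, i.e. hypomethylation) in `group_a`.
#'
#' @param m a [count_matrix()] (already filtered).
#' @param group_a,group_b group labels; `group_a` is focal.
#' @param dispersion a [estimate_dispersion()] result, or a numeric scalar /
#'   per-locus vector of NB dispersions.
#' @param pseudo_cpm pseudo-count added to mean CPM in the logFC (default 0.5).
#' @return data.frame with columns `locus_id`, `logFC`, `p_value`.
#' @export
dmc_test <- function(m, group_a, group_b, dispersion, pseudo_cpm = 0.5) {
  ia <- samples_in_group(m, group_a)
  ib <- samples_in_group(m, group_b)
  lib <- m$samples$library_size
  phi <- if (inherits(dispersion, "dispersion_estimate")) {
    dispersion$per_locus[m$loci$locus_id]
  } else dispersion
  phi <- rep_len(as.numeric(phi), nrow(m$counts))
  if (anyNA(phi) || any(phi < 0))
    eh_stop("dispersion must be non-negative for every tested locus",
            "eh_bad_dispersion")

  cols <- c(ia, ib)
  lbar <- mean(lib[cols])
  pseudo <- sweep(m$counts[, cols, drop = FALSE], 2, lbar / lib[cols], `*`)
  na <- length(ia); nb <- length(ib)
  za <- round(rowSums(pseudo[, seq_len(na), drop = FALSE]))
  zb <- round(rowSums(pseudo[, na + seq_len(nb), drop = FALSE]))
  p <- vapply(seq_along(za),
              function(i) exact_nb_pvalue(za[i], zb[i], na, nb, phi[i]),
              numeric(1))

  cpm <- cpm_normalize(m)
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  logfc <- log2((mean_a + pseudo_cpm) / (mean_b + pseudo_cpm))
  data.frame(locus_id = m$loci$locus_id, logFC = logfc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (monotone, capped at 1), via [stats::p.adjust()].
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    eh_stop("p-values must be in [0, 1]", "eh_bad_pvalues")
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated cytosines between two groups
#'
#' Runs the full per-comparison workflow: the occupancy filter
#' ([filter_loci()]) on the two compared groups, dispersion estimation on
#' the filtered counts, the exact conditional NB test ([dmc_test()]),
#' BH-FDR adjustment, and thresholding at `fdr_threshold`.  Direction is
#' taken from the sign of logFC: positive (more reads in the focal group)
#' is hypomethylation in the focal group.
#'
#' @param m an unfiltered [count_matrix()].
#' @param group_a,group_b group labels; `group_a` is focal (typically the
#'   hybrids in hybrid-vs-parent comparisons).
#' @param fdr_threshold q-value cut-off for significance (default 0.01).
#' @param cpm_threshold,n,strict passed to [filter_loci()].
#' @param dispersion optional pre-computed dispersion (see [dmc_test()]);
#'   estimated from the filtered matrix when `NULL`.
#' @param shrinkage_weight passed to [estimate_dispersion()].
#' @param pseudo_cpm passed to [dmc_test()].
#' @return object of class `dmc_set`: list with `comparison` (c(group_a,
#'   group_b)), `results` (data.frame: locus_id, scaffold, position, strand,
#'   logFC, p_value, q_value, significant, direction), `fdr_threshold`,
#'   `n_filter`, `n_loci_in`, `n_loci_tested`.
#' @export
call_dmcs <- function(m, group_a, group_b, fdr_threshold = 0.01,
                      cpm_threshold = 1, n = NULL, strict = TRUE,
                      dispersion = NULL, shrinkage_weight = 0.8,
                      pseudo_cpm = 0.5) {
  groups <- unique(c(group_a, group_b))
  n_used <- if (is.null(n)) min_group_size(m, groups) else n
  mf <- filter_loci(m, groups, cpm_threshold = cpm_threshold, n = n_used,
                    strict = strict)
  keep_samples <- which(m$samples$group %in% groups)
  mf <- mf[, keep_samples]
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(mf, groups = groups,
                                      shrinkage_weight = shrinkage_weight)
  res <- dmc_test(mf, group_a, group_b, dispersion, pseudo_cpm = pseudo_cpm)
  res$q_value <- bh_fdr(res$p_value)
  # threshold 1 is inclusive so that "keep everything" configurations keep
  # loci whose q-value is exactly 1
  res$significant <- if (fdr_threshold >= 1) rep(TRUE, nrow(res))
                     else res$q_value < fdr_threshold
  res$direction <- ifelse(res$logFC > 0, "hypo_in_focal",
                          ifelse(res$logFC < 0, "hyper_in_focal", NA))
  res <- cbind(res["locus_id"],
               mf$loci[, c("scaffold", "position", "strand")],
               res[, c("logFC", "p_value", "q_value", "significant", "direction")])
  rownames(res) <- NULL
  structure(list(comparison = c(group_a, group_b), results = res,
                 fdr_threshold = fdr_threshold, n_filter = n_used,
                 n_loci_in = nrow(m$counts), n_loci_tested = nrow(res),
                 dispersion = dispersion),
            class = "dmc_set")
}

#' @exportS3Method base::print
print.dmc_set <- function(x, ...) {
  r <- x$results
  nsig <- sum(r$significant)
  cat(sprintf("DMC comparison %s vs %s (focal: %s)\n",
              x$comparison[1], x$comparison[2], x$comparison[1]))
  cat(sprintf("  %d / %d loci tested after occupancy filter (n = %d)\n",
              x$n_loci_tested, x$n_loci_in, x$n_filter))
  cat(sprintf("  %d DMCs at FDR < %g (%d hypo, %d hyper in focal group)\n",
              nsig, x$fdr_threshold,
              sum(r$significant & r$logFC > 0),
              sum(r$significant & r$logFC < 0)))
  invisible(x)
}

#' @exportS3Method base::summary
summary.dmc_set <- function(object, ...) {
  r <- object$results
  data.frame(comparison = paste(object$comparison, collapse = "_vs_"),
             n_tested = nrow(r),
             n_significant = sum(r$significant),
             n_hypo_in_focal = sum(r$significant & r$logFC > 0),
             n_hyper_in_focal = sum(r$significant & r$logFC < 0),
             stringsAsFactors = FALSE)
}

#' Loci significant in both of two DMC comparisons
#'
#' The "common DMC" set: loci called significant both in hybrid vs parent 1
#' and hybrid vs parent 2.  Both sets must share the same focal group.
#'
#' @param a,b `dmc_set` objects with the same focal group.
#' @return character vector of locus_ids, ordered by scaffold then position
#'   then strand.
#' @export
intersect_dmcs <- function(a, b) {
  if (!identical(a$comparison[1], b$comparison[1]))
    eh_stop("DMC sets must share the same focal group", "eh_bad_intersection")
  sig_a <- a$results[a$results$significant, , drop = FALSE]
  common <- sig_a[sig_a$locus_id %in%
                    b$results$locus_id[b$results$significant], , drop = FALSE]
  common <- common[order(common$scaffold, common$position, common$strand), ]
  common$locus_id
}
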