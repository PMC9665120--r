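#' Euclidean distances between samples
#'
#' @param x samples x features numeric matrix without missing values.
#' @return symmetric sample x sample distance matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
euclidean_distances <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) eh_stop("missing values not allowed in Euclidean distances",
                        "eh_missing_values")
  as.matrix(dist(x))
}

#' Bray-Curtis dissimilarities between samples
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i), over features observed in
#' both samples when `pairwise_deletion = TRUE` (missing entries are
#' excluded pair by pair, never imputed).  A pair whose shared features are
#' all zero gets distance 0.
#'
#' @param x samples x features non-negative matrix (CPM profiles, SNP
#'   dosages, ...); NA allowed only with `pairwise_deletion`.
#' @param pairwise_deletion drop features missing in either member of a
#'   pair (default FALSE).
#' @return symmetric distance matrix in \[0, 1\].
#' @export
bray_curtis_distances <- function(x, pairwise_deletion = FALSE) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE))
    eh_stop("Bray-Curtis requires non-negative features", "eh_negative_values")
  if (anyNA(x) && !pairwise_deletion)
    eh_stop("missing values require pairwise_deletion = TRUE",
            "eh_missing_values")
  # vegdist warns on all-zero rows; their distances are defined as 0 below
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(x, method = "bray", na.rm = pairwise_deletion)))
  d[is.nan(d)] <- 0  # both-zero (or no shared feature) pairs
  diag(d) <- 0
  d
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centred Gram-matrix eigendecomposition via [stats::cmdscale()].
#' Axes are ordered by descending eigenvalue, and the sign of each axis is
#' fixed so that its largest-magnitude coordinate is positive, making the
#' embedding deterministic.  If fewer than `k` positive eigenvalues exist,
#' the remaining axes are zero-padded and flagged.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of dimensions requested (>= 1).
#' @return list with `points` (samples x k), `eig` (all eigenvalues),
#'   `padded` (logical: were axes zero-padded?).
#' @export
classical_mds <- function(d, k = 2) {
  if (k < 1) eh_stop("k must be >= 1", "eh_bad_k")
  d <- as.matrix(d)
  n <- nrow(d)
  k_eff <- min(k, n - 1)
  fit <- suppressWarnings(cmdscale(as.dist(d), k = k_eff, eig = TRUE))
  pts <- fit$points
  # axes whose eigenvalue is numerically zero carry no geometry; zero them
  rank <- sum(fit$eig > max(fit$eig, 0) * 1e-8)
  if (ncol(pts) > rank) pts[, (rank + 1):ncol(pts)] <- 0
  got <- min(ncol(pts), rank)
  if (ncol(pts) < k) pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig, padded = got < k)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from joint row/column permutations of the second matrix
#' (one-tailed, positive association: p = (1 + #\{r_perm >= r_obs\}) /
#' (1 + n_permutations)), computed with [vegan::mantel()] under a fixed
#' seed.
#'
#' @param d1,d2 distance matrices over the same samples in the same order.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed making the permutation stream reproducible.
#' @return object of class `mantel_result`: list with `r`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)) ||
      !identical(rownames(d1), rownames(d2)))
    eh_stop("distance matrices must cover the same samples in the same order",
            "eh_mismatched_samples")
  set.seed(seed)
  fit <- vegan::mantel(as.dist(d1), as.dist(d2), method = "pearson",
                       permutations = n_permutations)
  structure(list(r = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = n_permutations, seed = seed),
            class = "mantel_result")
}

#' @exportS3Method base::print
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$r, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Mixed model of pairwise epigenetic distance (MLPE-style)
#'
#' Each unordered sample pair contributes one observation: its epigenetic
#' distance is modelled as a Gaussian linear mixed model with genetic
#' distance, the sampling sites and the species (groups) of the two pair
#' members as fixed effects, and crossed random intercepts for the identity
#' of each pair member, accounting for the non-independence of pairwise
#' observations.  The two "slots" of each pair are filled in a fixed
#' order (the sample ordering of the distance matrices), and fixed factors
#' with a single level are dropped from the formula.  Both the mixed model
#' and the fixed-effects-only linear model are fitted by maximum likelihood
#' so their AICs and likelihood ratios are comparable.
#'
#' @param epi_d epigenetic (methylation) distance matrix.
#' @param gen_d genetic (SNP) distance matrix, same samples, same order.
#' @param samples sample table with `sample_id`, `group`, `site` matching
#'   the distance matrices.
#' @return object of class `pairwise_mlpe`: list with `coefficients` (fixed
#'   effects), `variance_components` (id1, id2, residual), `log_likelihood`,
#'   `aic`, `aic_fixed_only`, `delta_aic` (fixed-only minus mixed; positive
#'   favours the random effects), `converged`, and the underlying fits
#'   `fit` / `fit_fixed`.
#' @export
fit_pairwise_mixed_model <- function(epi_d, gen_d, samples) {
  epi_d <- as.matrix(epi_d); gen_d <- as.matrix(gen_d)
  ids <- samples$sample_id
  if (!identical(rownames(epi_d), ids) || !identical(rownames(gen_d), ids))
    eh_stop("distance matrices and sample table must align", "eh_mismatched_samples")
  n <- length(ids)
  pairs <- which(upper.tri(epi_d), arr.ind = TRUE)
  df <- data.frame(
    epi = epi_d[pairs], gen = gen_d[pairs],
    site1 = samples$site[pairs[, 1]], site2 = samples$site[pairs[, 2]],
    species1 = samples$group[pairs[, 1]], species2 = samples$group[pairs[, 2]],
    id1 = factor(ids[pairs[, 1]], levels = ids),
    id2 = factor(ids[pairs[, 2]], levels = ids),
    stringsAsFactors = FALSE)
  if (sd(df$gen) == 0)
    eh_stop("genetic distances are constant; slope is not identifiable",
            "eh_degenerate_design")
  fixed <- "gen"
  for (term in c("site1", "site2", "species1", "species2"))
    if (length(unique(df[[term]])) > 1) fixed <- c(fixed, term)
  f_mixed <- as.formula(paste("epi ~", paste(fixed, collapse = " + "),
                              "+ (1 | id1) + (1 | id2)"))
  f_fixed <- as.formula(paste("epi ~", paste(fixed, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(f_mixed, data = df, REML = FALSE),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  fit_fixed <- lm(f_fixed, data = df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- setNames(vc$vcov, vc$grp)
  structure(list(
    coefficients = lme4::fixef(fit),
    variance_components = c(id1 = unname(vcomp["id1"]),
                            id2 = unname(vcomp["id2"]),
                            residual = unname(vcomp["Residual"])),
    log_likelihood = as.numeric(logLik(fit)),
    aic = AIC(fit), aic_fixed_only = AIC(fit_fixed),
    delta_aic = AIC(fit_fixed) - AIC(fit),
    converged = converged, n_pairs = nrow(df),
    fit = fit, fit_fixed = fit_fixed), class = "pairwise_mlpe")
}

#' @exportS3Method base::print
print.pairwise_mlpe <- function(x, ...) {
  cat(sprintf("pairwise mixed model (%d pairs)%s\n", x$n_pairs,
              if (x$converged) "" else "  [did not converge]"))
  cat(sprintf("  slope on genetic distance: %.4f\n", x$coefficients[["gen"]]))
  cat(sprintf("  variance components: id1 %.4g, id2 %.4g, residual %.4g\n",
              x$variance_components["id1"], x$variance_components["id2"],
              x$variance_components["residual"]))
  cat(sprintf("  AIC %.1f (fixed-only %.1f, delta %.1f)\n",
              x$aic, x$aic_fixed_only, x$delta_aic))
  invisible(x)
}
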