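#' Counts-per-million normalization
#'
#' CPM\[i, j\] = counts\[i, j\] * 1e6 / library_size\[j\].  Library sizes are
#' the total sequenced reads per sample (from the sample sheet), not the
#' on-target column sums, so the transform is exactly invertible.
#'
#' @param m a [count_matrix()].
#' @return numeric matrix of the same shape (loci x samples) in CPM units.
#' @export
cpm_normalize <- function(m) {
  lib <- m$samples$library_size
  if (any(lib <= 0)) eh_stop("library sizes must be positive", "eh_zero_library")
  sweep(m$counts, 2, 1e6 / lib, `*`)
}

#' Size of the smallest group in a comparison
#'
#' The occupancy filter requires a locus to be covered in at least `n`
#' individuals of each compared group, with `n` the size of the smallest
#' group in the comparison.
#'
#' @param samples sample table (data.frame with a `group` column) or a
#'   `count_matrix`.
#' @param groups character vector of group labels (usually two).
#' @return integer, the minimum group size.
#' @export
min_group_size <- function(samples, groups) {
  if (inherits(samples, "count_matrix")) samples <- samples$samples
  sizes <- vapply(groups, function(g) sum(samples$group == g), integer(1))
  if (any(sizes == 0))
    eh_stop(paste("empty group:", paste(groups[sizes == 0], collapse = ", ")),
            "eh_empty_group")
  min(sizes)
}

#' Occupancy filter on CPM-normalized counts
#'
#' Keeps exactly the loci with CPM strictly greater than `cpm_threshold` in
#' at least `n` individuals of *each* listed group; the order of surviving
#' loci is preserved.  By default `n` is the smallest group size among
#' `groups` (see [min_group_size()]); an explicit `n` overrides it.  The
#' filter is normally applied per pairwise comparison; passing all three
#' group labels gives the joint filter used for the all-group ordination.
#'
#' @param m a [count_matrix()].
#' @param groups character vector of group labels (two for a comparison).
#' @param cpm_threshold CPM cut-off (default 1, i.e. "more than one count
#'   per million").
#' @param n minimum number of individuals per group; `NULL` resolves to the
#'   smallest group size.
#' @param strict logical; `TRUE` (default) uses CPM > threshold, `FALSE`
#'   uses >= (sensitivity analysis only).
#' @return a `count_matrix` containing the surviving loci (all samples kept).
#' @export
filter_loci <- function(m, groups, cpm_threshold = 1, n = NULL, strict = TRUE) {
  if (cpm_threshold <= 0) eh_stop("cpm_threshold must be > 0", "eh_bad_filter")
  n_min <- min_group_size(m, groups)
  if (is.null(n)) n <- n_min
  if (n < 1) eh_stop("n must be >= 1", "eh_bad_filter")
  sizes <- vapply(groups, function(g) sum(m$samples$group == g), integer(1))
  if (any(n > sizes))
    eh_stop("n exceeds the size of a compared group", "eh_bad_filter")
  cpm <- cpm_normalize(m)
  keep <- rep(TRUE, nrow(cpm))
  for (g in groups) {
    cols <- m$samples$group == g
    hits <- if (strict) cpm[, cols, drop = FALSE] > cpm_threshold
            else cpm[, cols, drop = FALSE] >= cpm_threshold
    keep <- keep & (rowSums(hits) >= n)
  }
  m[which(keep), ]
}
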