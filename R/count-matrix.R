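#' Construct a locus-by-sample msGBS count matrix
#'
#' The central container of the package: non-negative integer read counts at
#' restriction cut-site loci (rows) for a set of samples (columns), plus the
#' locus coordinates and the per-sample metadata (group, sampling site,
#' library size).  Library sizes come from the sample sheet rather than the
#' column sums because normalization is by the total sequenced library of
#' each sample, which includes reads at loci that are later filtered out.
#'
#' @param counts numeric matrix, loci x samples, non-negative integers.
#' @param loci data.frame with columns `scaffold`, `position` (1-based
#'   cut-site coordinate), `strand` (one of `+`, `-`, `.`); a `locus_id`
#'   column (`"scaffold:position:strand"`) is added if absent.
#' @param samples data.frame with columns `sample_id`, `group` (one of
#'   `parent1`, `parent2`, `hybrid`), `site`, `library_size`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `loci`, `samples`.
#' @export
count_matrix <- function(counts, loci, samples) {
  counts <- as.matrix(counts)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(loci$locus_id)) {
    loci$locus_id <- locus_ids(loci$scaffold, loci$position, loci$strand)
  }
  rownames(counts) <- loci$locus_id
  colnames(counts) <- samples$sample_id
  obj <- structure(list(counts = counts, loci = loci, samples = samples),
                   class = "count_matrix")
  validate_count_matrix(obj)
  obj
}

#' Build locus identifiers from coordinates
#'
#' @param scaffold,position,strand coordinate vectors.
#' @return character vector `"scaffold:position:strand"`.
#' @export
locus_ids <- function(scaffold, position, strand) {
  paste(scaffold, position, strand, sep = ":")
}

validate_count_matrix <- function(m) {
  counts <- m$counts; loci <- m$loci; samples <- m$samples
  req_l <- c("scaffold", "position", "strand", "locus_id")
  if (!all(req_l %in% names(loci)))
    eh_stop("loci table must have columns scaffold, position, strand, locus_id",
            "eh_invalid_loci")
  req_s <- c("sample_id", "group", "site", "library_size")
  if (!all(req_s %in% names(samples)))
    eh_stop("sample table must have columns sample_id, group, site, library_size",
            "eh_invalid_samples")
  if (nrow(counts) != nrow(loci) || ncol(counts) != nrow(samples))
    eh_stop("count matrix dimensions do not match loci/sample tables",
            "eh_dim_mismatch")
  if (anyDuplicated(loci$locus_id))
    eh_stop("duplicate locus_id in count matrix", "eh_duplicate_locus")
  if (anyDuplicated(samples$sample_id))
    eh_stop("duplicate sample_id in count matrix", "eh_duplicate_sample")
  if (any(loci$position < 1))
    eh_stop("locus positions must be >= 1", "eh_invalid_loci")
  if (!all(loci$strand %in% c("+", "-", ".")))
    eh_stop("locus strand must be one of '+', '-', '.'", "eh_invalid_loci")
  if (!all(samples$group %in% c("parent1", "parent2", "hybrid")))
    eh_stop("sample group must be one of parent1, parent2, hybrid",
            "eh_invalid_samples")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    eh_stop("counts must be non-negative integers without missing values",
            "eh_invalid_counts")
  if (any(samples$library_size <= 0))
    eh_stop("library sizes must be positive", "eh_invalid_samples")
  if (nrow(counts) > 0 && any(samples$library_size < colSums(counts)))
    eh_stop("library_size smaller than the column sum of counts for a sample",
            "eh_invalid_samples")
  invisible(m)
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("msGBS count matrix: %d loci x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  library sizes: %.3g - %.3g\n",
              min(x$samples$library_size), max(x$samples$library_size)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by loci and/or samples
#'
#' @param x a `count_matrix`.
#' @param i locus index (integer, logical, or locus_id character vector).
#' @param j sample index (integer, logical, or sample_id character vector).
#' @param ... ignored.
#' @return a `count_matrix` restricted to the selected loci and samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$loci$locus_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  if (anyNA(i)) eh_stop("unknown locus_id in subset", "eh_unknown_locus")
  if (anyNA(j)) eh_stop("unknown sample_id in subset", "eh_unknown_sample")
  count_matrix(x$counts[i, j, drop = FALSE],
               x$loci[i, , drop = FALSE],
               x$samples[j, , drop = FALSE])
}

samples_in_group <- function(m, group) {
  idx <- which(m$samples$group == group)
  if (length(idx) == 0)
    eh_stop(sprintf("no samples in group '%s'", group), "eh_empty_group")
  idx
}

#' Read an msGBS count matrix and sample sheet from TSV files
#'
#' The counts file is tab-separated with columns `scaffold`, `position`,
#' `strand` followed by one column per sample; the sample sheet has columns
#' `sample_id`, `group`, `site` and (normally) `library_size`.
#'
#' @param path counts TSV.
#' @param sample_sheet sample sheet TSV.
#' @param library_size_from `"sheet"` (default) uses the sheet's
#'   `library_size` column; `"colsums"` falls back to per-sample count
#'   totals when the sheet omits the column.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, sample_sheet,
                              library_size_from = c("sheet", "colsums")) {
  library_size_from <- match.arg(library_size_from)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4 || !identical(names(raw)[1:3], c("scaffold", "position", "strand")))
    eh_stop("counts file must start with columns scaffold, position, strand",
            "eh_bad_counts_file")
  sample_names <- names(raw)[-(1:3)]
  if (anyDuplicated(sample_names))
    eh_stop("duplicate sample in counts file header", "eh_duplicate_sample")
  sheet <- read.delim(sample_sheet, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "site") %in% names(sheet)))
    eh_stop("sample sheet must have columns sample_id, group, site",
            "eh_bad_sample_sheet")
  if (anyDuplicated(sheet$sample_id))
    eh_stop("duplicate sample_id in sample sheet", "eh_duplicate_sample")
  missing_in_sheet <- setdiff(sample_names, sheet$sample_id)
  if (length(missing_in_sheet) > 0)
    eh_stop(paste("samples in counts file absent from sample sheet:",
                  paste(missing_in_sheet, collapse = ", ")),
            "eh_unknown_sample")
  missing_in_counts <- setdiff(sheet$sample_id, sample_names)
  if (length(missing_in_counts) > 0)
    eh_stop(paste("samples in sheet absent from counts file:",
                  paste(missing_in_counts, collapse = ", ")),
            "eh_unknown_sample")
  counts <- as.matrix(raw[, sheet$sample_id, drop = FALSE])
  if (!is.numeric(counts))
    eh_stop("counts must be numeric", "eh_invalid_counts")
  if (is.null(sheet$library_size)) {
    if (library_size_from == "sheet")
      eh_stop("sample sheet has no library_size column (set library_size_from = 'colsums' to use count totals)",
              "eh_bad_sample_sheet")
    sheet$library_size <- colSums(counts)
  }
  count_matrix(counts, raw[, 1:3], sheet)
}

#' Write a count matrix (and its sample sheet) to TSV
#'
#' @param m a `count_matrix`.
#' @param path counts TSV output path.
#' @param sample_sheet optional path for the sample sheet TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, sample_sheet = NULL) {
  out <- cbind(m$loci[, c("scaffold", "position", "strand")],
               as.data.frame(m$counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet))
    write.table(m$samples, sample_sheet, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` feature rows only; coordinates are 1-based inclusive as in
#' the GFF3 standard and are kept that way throughout the package.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` (one row per gene; zero rows for an annotation with no genes).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (!all(strand %in% c("+", "-")))
    eh_stop("gene strand must be '+' or '-'", "eh_bad_strand")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$gene_id %||% gr$Name
    ids <- if (is.null(ids)) alt else ifelse(is.na(ids), alt, ids)
  }
  if (is.null(ids) || anyNA(ids))
    eh_stop("gene rows must carry an ID attribute", "eh_bad_gff")
  data.frame(gene_id = as.character(ids),
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a genotype (alt-allele dosage) matrix
#'
#' Accepts either a TSV dosage matrix (first column `marker_id`, one column
#' per sample, entries in \{0, 1, 2\} or NA) or a minimal VCF whose GT field
#' is converted to dosages (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2, `./.` -> NA).
#' Missing genotypes are kept as NA, never imputed; downstream distances use
#' pairwise deletion.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return object of class `genotype_matrix`: list with `markers`,
#'   `samples`, and a markers x samples integer matrix `genotypes`.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    markers <- as.character(raw[[1]])
    g <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(g) <- "double"
    bad <- !is.na(g) & !(g %in% c(0, 1, 2))
    if (any(bad))
      eh_stop("genotype dosages must be 0, 1, 2 or missing", "eh_bad_dosage")
    rownames(g) <- markers
    genotype_matrix(g)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    conv <- function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_real_, length(x))
      out[x %in% c("0/0")] <- 0
      out[x %in% c("0/1", "1/0")] <- 1
      out[x %in% c("1/1")] <- 2
      bad <- !is.na(x) & !(x %in% c("0/0", "0/1", "1/0", "1/1", "./."))
      if (any(bad))
        eh_stop("unsupported genotype call (only biallelic 0/0, 0/1, 1/1, ./.)",
                "eh_bad_dosage")
      out
    }
    g <- apply(gt, 2, conv)
    if (is.null(dim(g))) g <- matrix(g, nrow = nrow(gt), dimnames = dimnames(gt))
    rownames(g) <- rownames(gt)
    genotype_matrix(g)
  }
}

#' Construct a genotype matrix object
#'
#' @param genotypes markers x samples matrix with entries in \{0,1,2\} or NA.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1, 2))
  if (any(bad))
    eh_stop("genotype dosages must be 0, 1, 2 or missing", "eh_bad_dosage")
  structure(list(markers = rownames(genotypes),
                 samples = colnames(genotypes),
                 genotypes = genotypes),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d markers x %d samples (%.1f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Write a genotype dosage matrix to TSV
#'
#' @param g a `genotype_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  out <- data.frame(marker_id = x_or_seq(g$markers, nrow(g$genotypes)),
                    g$genotypes, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

x_or_seq <- function(x, n) if (is.null(x)) paste0("m", seq_len(n)) else x
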