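#' Assign msGBS loci to genomic-context categories
#'
#' Each cut-site locus is placed in exactly one of four categories:
#' `unannotated` when its scaffold carries no annotation at all,
#' `promoter` when it lies within `promoter_window` bp upstream of a gene's
#' strand-aware start (upstream of `start` for `+` genes, of `end` for `-`
#' genes; the window excludes the gene body itself), `gene_body` when it
#' falls inside a gene, and `intergenic` otherwise.  Precedence is
#' promoter > gene_body > intergenic, so categories partition the loci.
#' When several genes compete for the same locus the gene with the nearest
#' strand-aware start wins, with gene_id as the final tie-break.
#'
#' @param loci data.frame with `locus_id`, `scaffold`, `position` (and
#'   optionally `strand`), e.g. the `loci` table of a [count_matrix()].
#' @param genes gene models from [read_gene_models()].
#' @param annotated_scaffolds scaffolds considered annotated; defaults to
#'   the scaffolds carrying at least one gene.
#' @param promoter_window upstream window in bp defining putative promoters
#'   (default 2000).
#' @return data.frame with columns `locus_id`, `category` (factor:
#'   promoter / gene_body / intergenic / unannotated), `gene_id` (NA for
#'   intergenic and unannotated loci).
#' @export
annotate_context <- function(loci, genes, annotated_scaffolds = NULL,
                             promoter_window = 2000) {
  if (promoter_window < 0)
    eh_stop("promoter_window must be >= 0", "eh_bad_window")
  if (is.null(annotated_scaffolds)) annotated_scaffolds <- unique(genes$scaffold)
  n <- nrow(loci)
  category <- rep("unannotated", n)
  gene_hit <- rep(NA_character_, n)
  annotated <- loci$scaffold %in% annotated_scaffolds
  category[annotated] <- "intergenic"

  if (nrow(genes) > 0 && any(annotated)) {
    levels <- unique(c(loci$scaffold, genes$scaffold))
    gene_gr <- GenomicRanges::GRanges(
      factor(genes$scaffold, levels),
      IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand)
    loci_gr <- GenomicRanges::GRanges(
      factor(loci$scaffold, levels),
      IRanges::IRanges(loci$position, width = 1))
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)

    assign_best <- function(hits, cat) {
      if (length(hits) == 0) return()
      h <- as.data.frame(hits)
      h$dist <- abs(loci$position[h$queryHits] - tss[h$subjectHits])
      h$gene <- genes$gene_id[h$subjectHits]
      h <- h[order(h$queryHits, h$dist, h$gene), ]
      h <- h[!duplicated(h$queryHits), ]
      sel <- annotated[h$queryHits]
      category[h$queryHits[sel]] <<- cat
      gene_hit[h$queryHits[sel]] <<- h$gene[sel]
    }

    body_hits <- GenomicRanges::findOverlaps(loci_gr, gene_gr,
                                             ignore.strand = TRUE)
    assign_best(body_hits, "gene_body")
    if (promoter_window > 0) {
      prom_gr <- suppressWarnings(GenomicRanges::trim(
        GenomicRanges::promoters(gene_gr, upstream = promoter_window,
                                 downstream = 0)))
      prom_hits <- GenomicRanges::findOverlaps(loci_gr, prom_gr,
                                               ignore.strand = TRUE)
      assign_best(prom_hits, "promoter")
    }
  }
  data.frame(locus_id = loci$locus_id,
             category = factor(category, levels = c("promoter", "gene_body",
                                                    "intergenic", "unannotated")),
             gene_id = gene_hit, row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate the genomic-context partition
#'
#' @param annotations data.frame from [annotate_context()], or a
#'   character/factor vector of categories.
#' @return data.frame with one row per category: `category`, `n`, `pct`
#'   (percent of all loci, rounded to 2 decimals); counts always sum to the
#'   number of input loci.
#' @export
tabulate_context <- function(annotations) {
  cats <- if (is.data.frame(annotations)) annotations$category else annotations
  if (length(cats) == 0) eh_stop("no annotations", "eh_empty_annotations")
  cats <- factor(as.character(cats),
                 levels = c("promoter", "gene_body", "intergenic", "unannotated"))
  if (anyNA(cats)) eh_stop("unknown context category", "eh_bad_category")
  n <- table(cats)
  data.frame(category = names(n), n = as.integer(n),
             pct = round(100 * as.integer(n) / length(cats), 2),
             stringsAsFactors = FALSE)
}
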