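test_that("count matrix TSVs round-trip through write and read", {
  m <- make_counts(matrix(c(0, 5, 12, 3, 0, 7), nrow = 3),
                   groups = c("parent1", "parent2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, tsv, sheet)
  m2 <- read_count_matrix(tsv, sheet)
  expect_identical(dim(m2), c(3L, 2L))
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$loci, m$loci)
  expect_equal(m2$samples, m$samples)
})

test_that("count matrix readers reject malformed input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tsite\tlibrary_size",
               "a\tparent1\tGUA\t1000000",
               "b\tparent2\tGUA\t1000000"), sheet)
  # duplicate sample column
  writeLines(c("scaffold\tposition\tstrand\ta\ta",
               "s1\t100\t+\t1\t2"), tsv)
  expect_error(read_count_matrix(tsv, sheet), class = "eh_duplicate_sample")
  # sample missing from sheet
  writeLines(c("scaffold\tposition\tstrand\ta\tc",
               "s1\t100\t+\t1\t2"), tsv)
  expect_error(read_count_matrix(tsv, sheet), class = "eh_unknown_sample")
  # negative count
  writeLines(c("scaffold\tposition\tstrand\ta\tb",
               "s1\t100\t+\t-1\t2"), tsv)
  expect_error(read_count_matrix(tsv, sheet), class = "eh_invalid_counts")
  # non-integer count
  writeLines(c("scaffold\tposition\tstrand\ta\tb",
               "s1\t100\t+\t1.5\t2"), tsv)
  expect_error(read_count_matrix(tsv, sheet), class = "eh_invalid_counts")
})

test_that("count matrix invariants are enforced at construction", {
  counts <- matrix(1, 2, 2)
  loci <- data.frame(scaffold = "s1", position = c(100L, 100L), strand = "+")
  samples <- data.frame(sample_id = c("a", "b"), group = "parent1",
                        site = "GUA", library_size = 1e6)
  expect_error(count_matrix(counts, loci, samples),
               class = "eh_duplicate_locus")
  loci$position <- c(100L, 200L)
  samples$group <- "not_a_group"
  expect_error(count_matrix(counts, loci, samples),
               class = "eh_invalid_samples")
  samples$group <- "parent1"
  samples$library_size <- 1  # smaller than the column sums
  expect_error(count_matrix(counts, loci, samples),
               class = "eh_invalid_samples")
})

test_that("GFF3 reader keeps gene rows only and validates coordinates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
               "s1\ttest\texon\t100\t200\t.\t+\t.\tID=g1.e1;Parent=g1",
               "s1\ttest\texon\t250\t500\t.\t+\t.\tID=g1.e2;Parent=g1",
               "s2\ttest\tgene\t1000\t2000\t.\t-\t.\tID=g2",
               "s2\ttest\texon\t1000\t1200\t.\t-\t.\tID=g2.e1;Parent=g2",
               "s2\ttest\texon\t1300\t1500\t.\t-\t.\tID=g2.e2;Parent=g2",
               "s2\ttest\texon\t1600\t2000\t.\t-\t.\tID=g2.e3;Parent=g2"), gff)
  genes <- read_gene_models(gff)
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$strand, c("+", "-"))
  expect_equal(genes$start, c(100L, 1000L))

  writeLines("##gff-version 3", gff)
  expect_equal(nrow(read_gene_models(gff)), 0L)

  writeLines(c("##gff-version 3",
               "s1\ttest\tgene\t500\t100\t.\t+\t.\tID=g1"), gff)
  expect_error(read_gene_models(gff))

  writeLines(c("##gff-version 3",
               "s1\ttest\tgene\t100\t500\t.\t.\t.\tID=g1"), gff)
  expect_error(read_gene_models(gff), class = "eh_bad_strand")
})

test_that("genotype readers convert TSV dosages and VCF GT calls", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\ta\tb\tc",
               "m1\t0\t1\t2",
               "m2\t2\t2\t0",
               "m3\t1\tNA\t1",
               "m4\t0\t0\t0"), tsv)
  g <- read_genotypes(tsv)
  expect_identical(dim(g$genotypes), c(4L, 3L))
  expect_true(is.na(g$genotypes["m3", "b"]))

  writeLines(c("marker_id\ta\tb", "m1\t3\t0"), tsv)
  expect_error(read_genotypes(tsv), class = "eh_bad_dosage")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
               "s1\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
               "s1\t200\tv2\tG\tC\t.\tPASS\t.\tGT\t0/0\t./."), vcf)
  gv <- read_genotypes(vcf)
  expect_equal(unname(gv$genotypes[1, ]), c(1, 2))
  expect_equal(unname(gv$genotypes[2, 1]), 0)
  expect_true(is.na(gv$genotypes[2, 2]))
})

test_that("count matrix subsetting keeps tables aligned", {
  m <- make_counts(matrix(1:12, nrow = 3), rep(c("parent1", "parent2"), each = 2))
  sub <- m[c(3, 1), c("s01", "s03")]
  expect_equal(sub$counts, m$counts[c(3, 1), c(1, 3)])
  expect_equal(sub$loci$locus_id, m$loci$locus_id[c(3, 1)])
  expect_error(m["no:such:locus", ], class = "eh_unknown_locus")
})
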