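test_that("read_fasta parses records, wraps, and normalises case", {
  fa <- write_temp_fasta(c(chr1 = "ACGT"))
  writeLines(c(">chr1", "ACGT", "ACGT", ">chr2 some description", "acgt"), fa)
  got <- read_fasta(fa)
  expect_equal(got$name, c("chr1", "chr2"))
  expect_equal(got$sequence, c("ACGTACGT", "ACGT"))
})

test_that("read_fasta rejects empty records and foreign residues", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">empty"), fa)
  expect_error(read_fasta(fa), "empty")
  writeLines(c(">bad", "ACRT"), fa)
  expect_error(read_fasta(fa), "alphabet")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("translate_dna follows the standard code, N and stop rules", {
  expect_equal(translate_dna("ATGAAATGA"), "MK*")
  expect_equal(translate_dna("ATGAAATGA", frame = 1), "*N")
  expect_equal(translate_dna("ANA"), "X")
  expect_equal(translate_dna("AT"), "")
  expect_equal(translate_dna(""), "")
})

test_that("revcomp matches an independent complement-and-reverse oracle", {
  withr::local_seed(11)
  for (i in 1:20) {
    s <- random_dna_str(sample(1:80, 1))
    expect_equal(revcomp(s), oracle_revcomp(s))
  }
  expect_equal(revcomp("ATGAAA"), "TTTCAT")
})

test_that("read_gff3 converts coordinates and synthesises missing exons", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t301\t500\t.\t+\t.\tID=g2",
    "chr1\tsrc\texon\t301\t330\t.\t+\t.\tParent=g2",
    "chr1\tsrc\texon\t401\t460\t.\t+\t.\tParent=g2"
  ), gff)
  ann <- read_gff3(gff, "v1")
  g1 <- ann[ann$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100L, 200L))
  g2 <- ann[ann$gene_id == "g2", ]
  expect_equal(g2$start, c(300L, 400L))
  expect_equal(g2$end, c(330L, 460L))
  expect_equal(unique(ann$source_version), "v1")
})

test_that("read_gff3 resolves exon parents through mRNA and errors otherwise", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t-\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t101\t160\t.\t-\t.\tParent=m1",
    "chr1\tsrc\texon\t301\t400\t.\t-\t.\tParent=m1"
  ), gff)
  ann <- read_gff3(gff, "v")
  expect_equal(nrow(ann), 2)
  expect_equal(ann$gene_id, c("g1", "g1"))

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t101\t160\t.\t+\t.\tParent=ghost"
  ), gff)
  expect_error(read_gff3(gff, "v"), "does not resolve")
})

test_that("overlapping exons within a gene are rejected", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1",
    "chr1\tsrc\texon\t150\t300\t.\t+\t.\tParent=g1"
  ), gff)
  expect_error(read_gff3(gff, "v"), "overlapping")
})

test_that("write_gff3 then read_gff3 reproduces coordinates bit-exactly", {
  ann <- default_bundle()$annotations$new
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff3(path, "new")
  cols <- c("gene_id", "chrom", "strand", "start", "end")
  expect_equal(
    as.data.frame(dplyr::arrange(back[, cols], gene_id, start)),
    as.data.frame(dplyr::arrange(ann[, cols], gene_id, start))
  )
})

test_that("spliced_sequences concatenates exons and honours strand", {
  genome <- tibble::tibble(name = "c", sequence = "ATGCCCAAA")
  ann <- tibble::tibble(
    gene_id = c("g", "g", "h"), chrom = "c", strand = c("+", "+", "+"),
    start = c(0L, 6L, 0L), end = c(3L, 9L, 9L)
  )
  sp <- spliced_sequences(ann, genome)
  expect_equal(sp$sequence[sp$gene_id == "g"], "ATGAAA")
  expect_equal(sp$sequence[sp$gene_id == "h"], "ATGCCCAAA")
  ann$strand <- "-"
  sp_neg <- spliced_sequences(ann, genome)
  expect_equal(sp_neg$sequence[sp_neg$gene_id == "g"],
               oracle_revcomp("ATGAAA"))
  ann$end[2] <- 50L
  expect_error(spliced_sequences(ann, genome), "outside")
})

test_that("read_peptides accepts bare lists and TSVs", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PEPTIDEK", "ANOTHERR", "PEPTIDEK"), p)
  expect_equal(read_peptides(p)$peptide, c("PEPTIDEK", "ANOTHERR"))
  writeLines(c("peptide\tintensity", "PEPTIDEK\t100"), p)
  expect_equal(read_peptides(p)$peptide, "PEPTIDEK")
})
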