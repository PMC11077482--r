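# A 3 kb genome with a planted 2-exon gene; the contig is its spliced
# transcript, so alignment truth is known by construction.
planted_two_exon <- function(seed = 31, e1 = c(1000L, 1030L),
                             e2 = c(1200L, 1260L)) {
  withr::with_seed(seed, {
    g <- random_dna_str(3000)
    list(
      genome = tibble::tibble(name = "chr1", sequence = g),
      contig = paste0(substr(g, e1[1] + 1, e1[2]), substr(g, e2[1] + 1, e2[2])),
      exons = tibble::tibble(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
    )
  })
}

test_that("an exact spliced transcript aligns block-for-block", {
  fx <- planted_two_exon()
  aln <- align_contigs(fx$contig, fx$genome, align_params(),
                       contig_id = "tx1")
  expect_equal(nrow(aln), 1)
  expect_equal(aln$strand, "+")
  expect_equal(aln$matches, 90L)
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$score, 450L)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$coverage_pct, 100)
  bl <- aln$blocks[[1]]
  expect_equal(bl$tstart, fx$exons$start)
  expect_equal(bl$tend, fx$exons$end)
  expect_equal(bl$qstart, c(0L, 30L))
})

test_that("a single substitution costs one mismatch", {
  fx <- planted_two_exon()
  mutated <- fx$contig
  ref <- substr(mutated, 45, 45)
  substr(mutated, 45, 45) <- setdiff(c("A", "C", "G", "T"), ref)[1]
  aln <- align_contigs(mutated, fx$genome, align_params(), contig_id = "mut")
  expect_equal(nrow(aln), 1)
  expect_equal(aln$matches, 89L)
  expect_equal(aln$mismatches, 1L)
  expect_equal(aln$score, 5L * 89L - 4L)
  expect_equal(aln$coverage_pct, 100)
})

test_that("a k-mer-disjoint contig yields no alignment", {
  withr::local_seed(17)
  genome <- tibble::tibble(name = "chr1", sequence = random_dna_str(10000))
  repeat {
    ctg <- random_dna_str(100)
    gk <- substring(genome$sequence, 1:(10000 - 14), 15:10000)
    ck <- c(substring(ctg, 1:86, 15:100),
            substring(oracle_revcomp(ctg), 1:86, 15:100))
    if (!any(ck %in% gk)) break
  }
  aln <- align_contigs(ctg, genome, align_params(), contig_id = "absent")
  expect_equal(nrow(aln), 0)
})

test_that("reverse-complementing a contig flips strand, not statistics", {
  fx <- planted_two_exon()
  fwd <- align_contigs(fx$contig, fx$genome, align_params(), contig_id = "f")
  rev <- align_contigs(oracle_revcomp(fx$contig), fx$genome, align_params(),
                       contig_id = "r")
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  for (col in c("score", "matches", "mismatches", "identity_pct",
                "coverage_pct", "t_start", "t_end")) {
    expect_equal(rev[[col]], fwd[[col]])
  }
  # genomic footprint identical; query blocks mirrored
  expect_equal(sort(rev$blocks[[1]]$tstart), sort(fwd$blocks[[1]]$tstart))
})

test_that("stored statistics agree with a naive column-walk oracle", {
  b <- default_bundle()
  run <- default_run()
  aln <- run$alignments
  gseq <- stats::setNames(b$genome$sequence, b$genome$name)
  cseq <- stats::setNames(b$contigs$sequence, b$contigs$name)
  expect_gt(nrow(aln), 10)
  for (i in seq_len(nrow(aln))) {
    o <- oracle_alignment_stats(aln[i, ], cseq[[aln$contig_id[i]]],
                                gseq[[aln$chrom[i]]])
    expect_equal(aln$matches[i], o$matches)
    expect_equal(aln$mismatches[i], o$mismatches)
    expect_equal(aln$aligned_cols[i], o$aligned_cols)
    expect_equal(aln$coverage_pct[i], o$coverage_pct)
    expect_equal(aln$score[i], 5L * o$matches - 4L * o$mismatches)
  }
})

test_that("retention filter applies the score/identity/coverage thresholds", {
  mk <- function(score, id, cov) {
    tibble::tibble(alignment_id = "a", contig_id = "c", chrom = "chr1",
                   strand = "+", score = score, identity_pct = id,
                   coverage_pct = cov)
  }
  p <- align_params()
  expect_true(filter_alignments(mk(2500, 96, 60), p)$kept)
  f1 <- filter_alignments(mk(1900, 99, 99), p)
  expect_false(f1$kept); expect_equal(f1$reject_reason, "score")
  f2 <- filter_alignments(mk(2500, 94.9, 99), p)
  expect_false(f2$kept); expect_equal(f2$reject_reason, "identity")
  f3 <- filter_alignments(mk(2500, 96, 49), p)
  expect_false(f3$kept); expect_equal(f3$reject_reason, "coverage")
  # a score of exactly 2000 is not "above 2000"
  expect_false(filter_alignments(mk(2000, 100, 100), p)$kept)
  # boundary identity/coverage are inclusive
  expect_true(filter_alignments(mk(2001, 95, 50), p)$kept)
})

test_that("kept and rejected alignments partition the input", {
  run <- default_run()
  filt <- run$alignments
  expect_equal(sum(filt$kept) + sum(!filt$kept), nrow(filt))
  expect_true(all(is.na(filt$reject_reason[filt$kept])))
  expect_true(all(!is.na(filt$reject_reason[!filt$kept])))
})

test_that("est2genome-style GFF import reconstructs blocks and statistics", {
  fx <- planted_two_exon()
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "# --- START OF GFF DUMP ---",
    "chr1\texonerate:est2genome\tgene\t1001\t1260\t450\t+\t.\tgene_id 1 ; sequence tx1",
    "chr1\texonerate:est2genome\texon\t1001\t1030\t.\t+\t.\tinsertions 0",
    "chr1\texonerate:est2genome\texon\t1201\t1260\t.\t+\t.\tinsertions 0"
  ), gff)
  contigs <- tibble::tibble(name = "tx1", sequence = fx$contig)
  aln <- read_exonerate_gff(gff, contigs = contigs, genome = fx$genome)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$contig_id, "tx1")
  expect_equal(aln$matches, 90L)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$coverage_pct, 100)
  expect_equal(aln$blocks[[1]]$tstart, c(1000L, 1200L))
  # without sequences the statistics stay NA and pass the filter on score
  aln2 <- read_exonerate_gff(gff)
  expect_true(is.na(aln2$identity_pct))
  expect_true(filter_alignments(aln2, align_params(min_score = 400))$kept)
})
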