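# Minimal hand-built inputs: one ORF per contig, one novel peptide each.
mk_obs <- function(peptides, orf_ids) {
  tibble::tibble(
    peptide = peptides,
    parents = purrr::map(orf_ids, function(o) list(transcript = o))
  )
}

mk_orfs <- function(contig_ids, proteins, start = 0L, strand = "+") {
  tibble::tibble(
    orf_id = paste0(contig_ids, ":orf"), contig_id = contig_ids,
    strand = strand, start = start,
    end = start + 3L * nchar(proteins) + 3L, frame = 0L,
    protein = proteins, length_aa = nchar(proteins),
    complete_5p = TRUE, complete_3p = TRUE
  )
}

mk_aln <- function(contig_id, t_start, t_end, chrom = "chr1", strand = "+") {
  tibble::tibble(
    alignment_id = paste0(contig_id, "|", chrom), contig_id = contig_id,
    chrom = chrom, strand = strand, t_start = t_start, t_end = t_end,
    kept = TRUE,
    blocks = list(tibble::tibble(qstart = 0L, qend = t_end - t_start,
                                 tstart = t_start, tend = t_end))
  )
}

ann1 <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                       start = 600L, end = 900L, source_version = "v")

test_that("gene-span overlap separates refined from novel from unaligned", {
  orfs <- mk_orfs(c("c1", "c2", "c3"), c("AAAA", "CCCC", "DDDD"))
  obs <- mk_obs(c("PEPA", "PEPB", "PEPC"), orfs$orf_id)
  aln <- dplyr::bind_rows(mk_aln("c1", 500L, 800L), mk_aln("c2", 5000L, 5300L))
  cl <- classify_contigs(obs, orfs, aln, ann1)
  cl <- cl[order(cl$contig_id), ]
  expect_equal(cl$category, c("refined_gene_structure",
                              "putative_novel_gene", "unaligned"))
  expect_equal(cl$overlapping_genes[[1]], "g1")
  expect_equal(cl$overlapping_genes[[2]], character())
  expect_equal(cl$n_alignments, c(1L, 1L, 0L))
  expect_equal(cl$supporting_peptides[[3]], "PEPC")
})

test_that("one shared base suffices and gene overlap dominates", {
  orfs <- mk_orfs("c1", "AAAA")
  obs <- mk_obs("PEP", orfs$orf_id)
  # alignment ends exactly at the gene start + 1 shared base
  touch <- classify_contigs(obs, orfs, mk_aln("c1", 400L, 601L), ann1)
  expect_equal(touch$category, "refined_gene_structure")
  miss <- classify_contigs(obs, orfs, mk_aln("c1", 400L, 600L), ann1)
  expect_equal(miss$category, "putative_novel_gene")
  # two alignments, one overlapping: overlap dominates
  both <- classify_contigs(
    obs, orfs, dplyr::bind_rows(mk_aln("c1", 650L, 700L),
                                mk_aln("c1", 9000L, 9050L)),
    ann1
  )
  expect_equal(both$category, "refined_gene_structure")
})

test_that("strand-blind overlap is the default; strict strand is optional", {
  orfs <- mk_orfs("c1", "AAAA")
  obs <- mk_obs("PEP", orfs$orf_id)
  aln <- mk_aln("c1", 650L, 700L, strand = "-")
  expect_equal(classify_contigs(obs, orfs, aln, ann1)$category,
               "refined_gene_structure")
  expect_equal(classify_contigs(obs, orfs, aln, ann1,
                                strand_mode = "match")$category,
               "putative_novel_gene")
})

test_that("classification is invariant to gene and contig order", {
  b <- default_bundle()
  run <- default_run()
  kept <- run$alignments[run$alignments$kept, ]
  obs <- run$membership[run$membership$transcript & !run$membership$old, ]
  ann <- b$annotations$old
  base <- classify_contigs(obs, run$orfs, kept, ann)
  perm <- withr::with_seed(3, {
    classify_contigs(obs[sample.int(nrow(obs)), ],
                     run$orfs[sample.int(nrow(run$orfs)), ],
                     kept[sample.int(nrow(kept)), ],
                     ann[sample.int(nrow(ann)), ])
  })
  expect_equal(as.data.frame(base[, c("contig_id", "category")]),
               as.data.frame(perm[, c("contig_id", "category")]))
})

test_that("missing parent ORFs are an error", {
  orfs <- mk_orfs("c1", "AAAA")
  obs <- mk_obs("PEP", "ghost:orf")
  expect_error(classify_contigs(obs, orfs, mk_aln("c1", 0L, 10L), ann1),
               "missing from the ORF set")
})

test_that("peptides project through ORF and alignment to genomic blocks", {
  protein <- paste0("AAAAA", "WCMNH", strrep("G", 20))
  orfs <- mk_orfs("c1", protein, start = 10L)
  aln <- tibble::tibble(
    alignment_id = "a1", contig_id = "c1", chrom = "chr1", strand = "+",
    kept = TRUE,
    blocks = list(tibble::tibble(qstart = c(0L, 30L), qend = c(30L, 90L),
                                 tstart = c(100L, 200L), tend = c(130L, 260L)))
  )
  loci <- project_peptides(mk_obs("WCMNH", orfs$orf_id), orfs, aln)
  expect_equal(nrow(loci), 1)
  bl <- loci$blocks[[1]]
  expect_equal(bl$start, c(125L, 200L))   # contig nt [25,40) across the splice
  expect_equal(bl$end, c(130L, 210L))
  expect_false(loci$clipped)

  loci0 <- project_peptides(mk_obs("AAAAA", orfs$orf_id), orfs, aln)
  expect_equal(loci0$blocks[[1]]$start, 110L)
  expect_equal(loci0$blocks[[1]]$end, 125L)

  # a peptide occurring twice in the protein yields two loci
  protein2 <- paste0("EFWKV", strrep("A", 10), "EFWKV", strrep("G", 10))
  orfs2 <- mk_orfs("c1", protein2, start = 0L)
  loci2 <- project_peptides(mk_obs("EFWKV", orfs2$orf_id), orfs2, aln)
  expect_equal(nrow(loci2), 2)

  expect_error(
    project_peptides(mk_obs("NOTTHERE", orfs$orf_id), orfs, aln),
    "not a substring"
  )
})

test_that("projection round-trips through the genome on real runs", {
  run <- default_run()
  mc <- default_bundle()$manifest$contigs
  loci <- dplyr::bind_rows(run$loci)
  expect_gt(nrow(loci), 20)
  expect_equal(sum(loci$clipped), 0)
  sav_ids <- mc$contig_id[mc$class == "sav"]
  # loci inconsistent with the reference genome are exactly the planted
  # variant-covering peptides of SAV contigs
  expect_true(all(loci$frame_consistent[!loci$contig_id %in% sav_ids]))
  bad <- loci[!loci$frame_consistent, ]
  expect_true(all(bad$contig_id %in% sav_ids))
})

test_that("to_bed12 emits bit-exact track lines", {
  loci <- tibble::tibble(
    peptide = "NAME", chrom = "chr1", strand = "+",
    blocks = list(tibble::tibble(start = c(125L, 200L), end = c(130L, 210L)))
  )
  expect_equal(to_bed12(loci),
               "chr1\t125\t210\tNAME\t0\t+\t125\t210\t0\t2\t5,10\t0,75")
  single <- tibble::tibble(
    peptide = "N", chrom = "chr1", strand = "-",
    blocks = list(tibble::tibble(start = 100L, end = 130L))
  )
  expect_equal(to_bed12(single),
               "chr1\t100\t130\tN\t0\t-\t100\t130\t0\t1\t30\t0")
  bad <- tibble::tibble(
    peptide = "B", chrom = "chr1", strand = "+",
    blocks = list(tibble::tibble(start = c(200L, 100L), end = c(210L, 130L)))
  )
  expect_error(to_bed12(bad), "out of ascending order")
  empty <- tibble::tibble(peptide = "E", chrom = "chr1", strand = "+",
                          blocks = list(tibble::tibble(start = integer(),
                                                       end = integer())))
  expect_error(to_bed12(empty), "empty block list")
})
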