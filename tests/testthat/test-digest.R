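test_that("digest reproduces the worked tryptic examples", {
  cfg <- digestion_config(max_missed_cleavages = 2, min_len = 6)
  expect_setequal(digest("MKRPDEKR", cfg),
                  c("MKRPDEK", "RPDEKR", "MKRPDEKR"))
  cfgP <- digestion_config(enzyme = "trypsin/P", max_missed_cleavages = 0,
                           min_len = 1)
  expect_setequal(digest("MKRPDEKR", cfgP), c("MK", "R", "PDEK"))
  cfg1 <- digestion_config(min_len = 3)
  expect_equal(digest("MADEQPF", cfg1), "MADEQPF")   # no cleavage site
  expect_error(digest("MKZR", cfg), "invalid residue")
})

test_that("X-containing peptides are excluded", {
  cfg <- digestion_config(min_len = 1, max_missed_cleavages = 0)
  expect_setequal(digest("MKXPEPTIDER", cfg), c("MK", "XPEPTIDER")[1])
})

test_that("digest equals brute-force enumeration on random proteins", {
  withr::local_seed(21)
  enzymes <- c("trypsin", "trypsin/P", "lysC+trypsin")
  for (rep in 1:60) {
    prot <- random_protein(sample(6:60, 1))
    enz <- sample(enzymes, 1)
    mm <- sample(0:2, 1)
    cfg <- digestion_config(enzyme = enz, max_missed_cleavages = mm,
                            min_len = 6)
    expect_setequal(digest(prot, cfg),
                    oracle_digest(prot, enz, mm, 6, 50))
  }
})

test_that("peptide index records parents and folds I/L", {
  cfg <- digestion_config(min_len = 6, il_equivalence = TRUE)
  prots <- tibble::tibble(
    id = c("p1", "p2"),
    protein = c("MMMKTIDEIKGGG", "CCCKTLDELKDDD")
  )
  idx <- build_peptide_index(prots, cfg)
  shared <- idx[idx$key == "TLDELK", ]
  expect_setequal(shared$protein_id, c("p1", "p2"))
  expect_setequal(shared$peptide, c("TIDEIK", "TLDELK"))
  expect_equal(nrow(build_peptide_index(prots[0, ], cfg)), 0)
  dup <- prots; dup$id <- c("p1", "p1")
  expect_error(build_peptide_index(dup, cfg), "duplicate protein id")
})

test_that("membership assignment implements plain set logic", {
  cfg <- digestion_config(min_len = 2, max_missed_cleavages = 0,
                          il_equivalence = FALSE)
  mk_idx <- function(peps, id) {
    structure(tibble::tibble(key = peps, peptide = peps, protein_id = id),
              cfg = cfg, class = c("pg_peptide_index", "tbl_df", "tbl",
                                   "data.frame"))
  }
  indexes <- list(
    A = mk_idx(c("PA", "PB", "PC"), "a1"),
    B = mk_idx(c("PB", "PC"), "b1"),
    C = mk_idx("PC", "c1")
  )
  obs <- assign_membership(c("PA", "PB", "PC", "QQ"), indexes)
  expect_equal(obs$A, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(obs$B, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(obs$C, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(obs$unmatched, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(obs$parents[[3]]$C, "c1")

  vc <- venn_counts(obs)
  expect_equal(vc$count[vc$region == "A"], 1L)
  expect_equal(vc$count[vc$region == "A&B"], 1L)
  expect_equal(vc$count[vc$region == "A&B&C"], 1L)
  expect_equal(vc$count[vc$region == "unmatched"], 1L)
  expect_equal(sum(vc$count), nrow(obs))

  nov <- novel_peptides(obs, "A")
  expect_equal(nov$peptide, "PA")
  expect_equal(nrow(novel_peptides(obs, "C")), 0)
  expect_error(novel_peptides(obs, "Z"), "unknown target")

  empty <- assign_membership(character(), indexes)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(venn_counts(empty)$count), 0)
})

test_that("venn regions always sum to the observation count", {
  withr::local_seed(5)
  cfg <- digestion_config(min_len = 2, il_equivalence = FALSE)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    universe <- replicate(30, random_protein(6))
    indexes <- lapply(seq_len(k), function(i) {
      peps <- sample(universe, sample(5:25, 1))
      structure(tibble::tibble(key = peps, peptide = peps, protein_id = "p"),
                cfg = cfg, class = c("pg_peptide_index", "tbl_df", "tbl",
                                     "data.frame"))
    })
    names(indexes) <- LETTERS[seq_len(k)]
    obs <- assign_membership(sample(universe, 20), indexes)
    vc <- venn_counts(obs)
    expect_equal(nrow(vc), 2^k)          # 2^k - 1 regions + unmatched
    expect_equal(sum(vc$count), 20L)
  }
})

test_that("zero-contamination bundles have no unmatched observed peptide", {
  run <- default_run()
  expect_equal(sum(run$membership$unmatched), 0)
})

test_that("novel peptides recover planted novel-gene peptides exactly", {
  b <- default_bundle()
  run <- default_run()
  mc <- b$manifest$contigs
  mp <- b$manifest$peptides
  # peptides sampled exclusively from planted novel (hidden) genes are
  # exactly the transcript-AND-NOT-old novel set restricted to those contigs
  hidden_ids <- mc$contig_id[mc$class == "hidden"]
  hidden_peps <- mp$peptide[mp$source %in% hidden_ids]
  v_novel <- run$membership[run$membership$transcript &
                              !run$membership$old, ]
  expect_true(all(hidden_peps %in% v_novel$peptide))   # recall 1.0
  # precision: every old-novel peptide traces to a contig planted as
  # missing from the old annotation (hidden, refined extension, sav, noise)
  src <- mp$source[match(v_novel$peptide, mp$peptide)]
  cls <- mc$class[match(src, mc$contig_id)]
  expect_true(all(cls %in% c("hidden", "refined", "sav", "noise")))
})
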