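test_that("tabular hits parse with query coverage arithmetic", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "85.0", "95", "14", "0", "1", "95", "10",
                   "104", "1e-30", "190", sep = "\t"), f)
  hits <- parse_tabular_hits(f, "plantdb",
                             tibble::tibble(query_id = "q1", length = 100))
  expect_equal(hits$query_cov_pct, 95)
  expect_equal(hits$identity_pct, 85)
  expect_equal(hits$subject_db, "plantdb")

  writeLines(character(), f)
  expect_equal(nrow(parse_tabular_hits(f, "d", c(q1 = 100))), 0)

  writeLines(paste(rep("x", 11), collapse = "\t"), f)
  expect_error(parse_tabular_hits(f, "d", c(q1 = 100)), "line 1.*11 columns")
})

test_that("local_align scores BLOSUM62 identities and is symmetric", {
  mkr <- local_align("MKR", "MKR")
  expect_equal(mkr$score, 15)
  expect_equal(mkr$aln_len, 3L)
  withr::local_seed(8)
  p <- random_protein(100)
  self <- local_align(p, p)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$query_cov_pct, 100)
  expect_gt(self$evalue, 0)
  a <- random_protein(40); b <- random_protein(40)
  expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  expect_error(local_align("", "MKR"), "non-empty")
})

test_that("local_align equals a quadratic affine-gap matrix oracle", {
  withr::local_seed(13)
  for (rep in 1:25) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    expect_equal(local_align(a, b)$score, oracle_sw_score(a, b))
  }
})

test_that("hit filtering uses strict thresholds in fixed order", {
  mk <- function(e, id, cov) {
    tibble::tibble(query_id = "q", subject_id = "s", evalue = e,
                   identity_pct = id, query_cov_pct = cov)
  }
  expect_true(filter_hits(mk(1e-15, 85, 95))$kept)
  r1 <- filter_hits(mk(1e-10, 99, 99))
  expect_false(r1$kept); expect_equal(r1$reject_reason, "evalue")
  r2 <- filter_hits(mk(1e-20, 70.0, 99))
  expect_false(r2$kept); expect_equal(r2$reject_reason, "identity")
  r3 <- filter_hits(mk(1e-20, 90, 90.0))
  expect_false(r3$kept); expect_equal(r3$reject_reason, "coverage")
})

test_that("filtering partitions hits and is monotone in each threshold", {
  withr::local_seed(44)
  hits <- tibble::tibble(
    query_id = paste0("q", 1:200), subject_id = "s",
    evalue = 10^stats::runif(200, -40, 0),
    identity_pct = stats::runif(200, 0, 100),
    query_cov_pct = stats::runif(200, 0, 100)
  )
  base <- filter_hits(hits)
  expect_equal(sum(base$kept) + sum(!base$kept), nrow(hits))
  relaxed <- list(
    filter_hits(hits, max_evalue = 1e-6),
    filter_hits(hits, min_identity = 50),
    filter_hits(hits, min_coverage = 70)
  )
  for (r in relaxed) {
    expect_true(all(base$query_id[base$kept] %in% r$query_id[r$kept]))
  }
})

test_that("SAV screening fires the published rules", {
  mk <- function(id, mism, aln_len, qlen, contig = "c1", score = 1000) {
    tibble::tibble(query_id = contig, subject_id = "s", identity_pct = id,
                   mismatches = mism, aln_len = aln_len,
                   query_length = qlen, bitscore = score)
  }
  one <- sav_candidates(mk(99.7, 1L, 300L, 300L))
  expect_equal(one$rule_fired, "single_mismatch")
  short <- sav_candidates(mk(100, 0L, 299L, 300L))
  expect_equal(short$rule_fired, "one_base_short")
  expect_equal(short$length_deficit, 1L)
  expect_equal(nrow(sav_candidates(mk(99.0, 3L, 300L, 300L))), 0)
  expect_equal(nrow(sav_candidates(mk(99.0, 3L, 300L, 300L),
                                   permissive = TRUE)), 0)
  two <- sav_candidates(mk(99.3, 2L, 300L, 300L), permissive = TRUE)
  expect_equal(two$rule_fired, "two_mismatch_permissive")
  expect_equal(nrow(sav_candidates(mk(99.3, 2L, 300L, 300L))), 0)
  # outside the identity band: no call even with one mismatch
  expect_equal(nrow(sav_candidates(mk(95, 1L, 300L, 300L))), 0)
  # one call per contig, on the best-scoring hit
  h <- dplyr::bind_rows(mk(99.7, 1L, 300L, 300L, score = 500),
                        mk(99.9, 2L, 300L, 300L, score = 900))
  expect_equal(nrow(sav_candidates(h, permissive = TRUE)), 1)
  expect_equal(sav_candidates(h, permissive = TRUE)$rule_fired,
               "two_mismatch_permissive")
})

test_that("strict SAV calls are a subset of permissive calls", {
  withr::local_seed(55)
  hits <- tibble::tibble(
    query_id = paste0("c", 1:100), subject_id = "s",
    identity_pct = stats::runif(100, 98.5, 100),
    mismatches = sample(0:3, 100, replace = TRUE),
    aln_len = 300L - sample(0:2, 100, replace = TRUE),
    query_length = 300L, bitscore = 1000
  )
  strict <- sav_candidates(hits)
  perm <- sav_candidates(hits, permissive = TRUE)
  expect_true(all(strict$contig_id %in% perm$contig_id))
})

test_that("planted SAV contigs are recalled and exact copies are not called", {
  b <- default_bundle()
  run <- default_run()
  mc <- b$manifest$contigs
  planted <- sort(mc$contig_id[mc$class == "sav"])
  called <- sort(run$sav$strict$contig_id)
  expect_equal(called, planted)
  exact_ids <- mc$contig_id[mc$class %in% c("exact", "hidden", "refined")]
  expect_equal(intersect(run$sav$permissive$contig_id, exact_ids),
               character())
  # the located amino-acid effect matches the planted one
  eff <- run$sav$strict
  for (i in seq_len(nrow(eff))) {
    planted_row <- mc[mc$contig_id == eff$contig_id[i], ]
    expect_equal(eff$aa_pos[i], planted_row$snv_aa_pos)
    expect_equal(eff$ref_aa[i], planted_row$snv_ref_aa)
    expect_equal(eff$alt_aa[i], planted_row$snv_alt_aa)
    expect_true(eff$nonsynonymous[i])
  }
})

test_that("homology support is attached per contig and database", {
  cl <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                       category = "unaligned", homology_supported = NA)
  hits <- tibble::tibble(
    query_id = c("c1", "c1", "c2"), subject_db = c("rice", "maize", "rice"),
    kept = c(TRUE, TRUE, FALSE)
  )
  out <- homology_flag(cl, hits)
  expect_equal(out$homology_supported, c(TRUE, FALSE, FALSE))
  expect_equal(out$homology_dbs[[1]], c("maize", "rice"))
  expect_equal(out$homology_dbs[[3]], character())
})
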