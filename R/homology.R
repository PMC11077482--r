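#' Parse 12-column tabular homology hits
#'
#' Reads the standard 12-column tab-separated alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`) and computes query coverage from the supplied
#' query lengths as `100 * (qend - qstart + 1) / query_length`.
#'
#' @param path Path to the tabular file.
#' @param subject_db Label recorded for the subject database (e.g. the
#'   proteome searched).
#' @param query_lengths A tibble with columns `query_id` and `length`,
#'   or a named numeric vector.
#' @return A hits tibble: `query_id`, `subject_id`, `subject_db`,
#'   `identity_pct`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `query_length`,
#'   `query_cov_pct`.
#' @export
parse_tabular_hits <- function(path, subject_db, query_lengths) {
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(query_lengths$length,
                                     query_lengths$query_id)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits_tbl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort(paste0("line ", which(nf != 12)[1],
                 " has ", nf[nf != 12][1], " columns; expected 12"))
  }
  m <- do.call(rbind, fields)
  qid <- m[, 1]
  if (any(!qid %in% names(query_lengths))) {
    abort(paste0("no query length supplied for '",
                 qid[!qid %in% names(query_lengths)][1], "'"))
  }
  qlen <- as.numeric(query_lengths[qid])
  tibble(
    query_id = qid, subject_id = m[, 2], subject_db = subject_db,
    identity_pct = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    query_length = as.integer(qlen),
    query_cov_pct = 100 * (as.integer(m[, 8]) - as.integer(m[, 7]) + 1) / qlen
  )
}

empty_hits_tbl <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    subject_db = character(), identity_pct = numeric(),
    aln_len = integer(), mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), evalue = numeric(), bitscore = numeric(),
    query_length = integer(), query_cov_pct = numeric()
  )
}

#' Local protein alignment with an e-value estimate
#'
#' Optimal Smith-Waterman local alignment under BLOSUM62 with affine gap
#' costs (a gap of length L costs `gap_open + L * gap_extend`). The
#' reported e-value is the Karlin-Altschul estimate
#' `K * m * n * exp(-lambda * score)` with fixed constants `K = 0.041`,
#' `lambda = 0.267`; it is an approximation intended for thresholding
#' synthetic comparisons, not a database-calibrated statistic.
#'
#' @param query,subject Protein sequences.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A one-row tibble: `score`, `aln_len`, `matches`,
#'   `identity_pct`, `query_cov_pct`, `evalue`, plus the aligned
#'   `q_aligned`/`s_aligned` strings.
#' @export
local_align <- function(query, subject, gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) {
    abort("local_align requires non-empty sequences")
  }
  pa <- Biostrings::pairwiseAlignment(
    query, subject, type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(pa)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  matches <- Biostrings::nmatch(pa)
  qcov <- 100 * (Biostrings::width(Biostrings::pattern(pa))) / nchar(query)
  tibble(
    score = sc, aln_len = as.integer(aln_len),
    matches = as.integer(matches),
    identity_pct = 100 * matches / aln_len,
    query_cov_pct = qcov,
    evalue = 0.041 * nchar(query) * nchar(subject) * exp(-0.267 * sc),
    q_aligned = as.character(Biostrings::alignedPattern(pa)),
    s_aligned = as.character(Biostrings::alignedSubject(pa))
  )
}

#' Filter homology hits on significance thresholds
#'
#' A hit is kept when its e-value is below `max_evalue`, its identity
#' strictly exceeds `min_identity`, and its query coverage strictly
#' exceeds `min_coverage` (all strict inequalities). Rejected hits carry
#' the first failing criterion, checked in that order.
#'
#' @param hits A hits tibble (see [parse_tabular_hits()]).
#' @param max_evalue,min_identity,min_coverage Thresholds.
#' @return The hits with added `kept` and `reject_reason` columns; kept
#'   and rejected rows partition the input.
#' @export
filter_hits <- function(hits, max_evalue = 1e-12, min_identity = 70,
                        min_coverage = 90) {
  fail_e <- !(hits$evalue < max_evalue)
  fail_i <- !(hits$identity_pct > min_identity)
  fail_c <- !(hits$query_cov_pct > min_coverage)
  reason <- rep(NA_character_, nrow(hits))
  reason[fail_c] <- "coverage"
  reason[fail_i] <- "identity"
  reason[fail_e] <- "evalue"
  hits$kept <- is.na(reason)
  hits$reject_reason <- reason
  hits
}

#' Convert retained genomic alignments to SAV-screenable hits
#'
#' Adapts the spliced aligner's output to the hit schema used by
#' [sav_candidates()]: the subject is the chromosome, the alignment
#' length is the number of aligned query bases, and the score doubles as
#' the bitscore for best-hit selection.
#'
#' @param alignments An alignment tibble (kept rows of
#'   [filter_alignments()] output).
#' @return A hits-like tibble.
#' @export
alignment_hits <- function(alignments) {
  aln <- alignments
  if ("kept" %in% names(aln)) aln <- aln[aln$kept, , drop = FALSE]
  tibble(
    query_id = aln$contig_id, subject_id = aln$chrom,
    subject_db = "genome", identity_pct = aln$identity_pct,
    aln_len = aln$query_aligned, mismatches = aln$mismatches,
    query_length = aln$contig_length, bitscore = aln$score
  )
}

#' Screen near-perfect hits for single-variant candidates
#'
#' Within the `100--99%` identity band, a contig is a single-amino-acid
#' variant (SAV) candidate when its best alignment carries exactly one
#' mismatch, or no mismatch but an alignment one base short of the full
#' contig length; the permissive mode additionally admits two
#' mismatches. One call is made per contig, on its highest-scoring hit
#' in the band.
#'
#' @param hits A hits tibble with `query_id`, `identity_pct`,
#'   `mismatches`, `aln_len`, `query_length` and `bitscore` columns
#'   (see [alignment_hits()] or [parse_tabular_hits()]).
#' @param band Identity band screened, as `c(low, high)` percent.
#' @param permissive Also call two-mismatch cases.
#' @return A SAV-call tibble: `contig_id`, `subject_id`, `rule_fired`
#'   (`single_mismatch`, `one_base_short`, or
#'   `two_mismatch_permissive`), `mismatches`, `length_deficit`,
#'   `identity_pct`, `bitscore`.
#' @export
sav_candidates <- function(hits, band = c(99, 100), permissive = FALSE) {
  h <- hits[!is.na(hits$identity_pct) &
              hits$identity_pct >= band[1] & hits$identity_pct <= band[2], ,
            drop = FALSE]
  if (nrow(h) == 0) return(empty_sav_tbl())
  h <- h %>%
    group_by(.data$query_id) %>%
    slice_max(.data$bitscore, n = 1, with_ties = FALSE) %>%
    ungroup()
  deficit <- h$query_length - h$aln_len
  rule <- rep(NA_character_, nrow(h))
  rule[h$mismatches == 1] <- "single_mismatch"
  rule[h$mismatches == 0 & deficit == 1] <- "one_base_short"
  if (permissive) rule[h$mismatches == 2] <- "two_mismatch_permissive"
  keep <- !is.na(rule)
  if (!any(keep)) return(empty_sav_tbl())
  tibble(
    contig_id = h$query_id[keep], subject_id = h$subject_id[keep],
    rule_fired = rule[keep], mismatches = h$mismatches[keep],
    length_deficit = as.integer(deficit[keep]),
    identity_pct = h$identity_pct[keep], bitscore = h$bitscore[keep]
  ) %>%
    arrange(.data$contig_id)
}

empty_sav_tbl <- function() {
  tibble(
    contig_id = character(), subject_id = character(),
    rule_fired = character(), mismatches = integer(),
    length_deficit = integer(), identity_pct = numeric(),
    bitscore = numeric()
  )
}

#' Annotate single-mismatch SAV calls with their amino-acid effect
#'
#' For each `single_mismatch` call, locates the mismatching contig base
#' by column walk over the retained alignment, and reports the affected
#' ORF codon and residue change when the mismatch falls inside a
#' predicted ORF. A nucleotide mismatch outside any ORF, or one that
#' does not change the residue, is reported with `nonsynonymous =
#' FALSE`/`NA` accordingly.
#'
#' @param sav_calls Output of [sav_candidates()].
#' @param contigs,genome Sequence tibbles.
#' @param alignments Retained alignments of the contigs.
#' @param orfs ORF tibble for the contigs.
#' @return The calls with added `contig_pos` (0-based), `contig_base`,
#'   `genome_base`, `aa_pos` (1-based residue in the ORF protein),
#'   `ref_aa`, `alt_aa`, `nonsynonymous`.
#' @export
sav_effects <- function(sav_calls, contigs, genome, alignments, orfs) {
  aln <- alignments
  if ("kept" %in% names(aln)) aln <- aln[aln$kept, , drop = FALSE]
  cseq <- stats::setNames(contigs$sequence, contigs$name)
  gseq <- stats::setNames(genome$sequence, genome$name)
  out <- sav_calls
  out$contig_pos <- NA_integer_
  out$contig_base <- NA_character_
  out$genome_base <- NA_character_
  out$aa_pos <- NA_integer_
  out$ref_aa <- NA_character_
  out$alt_aa <- NA_character_
  out$nonsynonymous <- NA
  for (i in seq_len(nrow(out))) {
    if (out$rule_fired[i] != "single_mismatch") next
    my <- aln[aln$contig_id == out$contig_id[i], , drop = FALSE]
    my <- my[order(-my$score), , drop = FALSE]
    if (nrow(my) == 0) next
    a <- my[1, ]
    qs_full <- cseq[[a$contig_id]]
    bl <- a$blocks[[1]]
    pos <- NA_integer_; gb <- NA_character_
    for (b in seq_len(nrow(bl))) {
      qsub <- substr(qs_full, bl$qstart[b] + 1L, bl$qend[b])
      if (a$strand == "-") qsub <- revcomp(qsub)
      tsub <- substr(gseq[[a$chrom]], bl$tstart[b] + 1L, bl$tend[b])
      diffs <- which(utf8ToInt(qsub) != utf8ToInt(tsub))
      if (length(diffs) > 0) {
        d <- diffs[1]
        pos <- if (a$strand == "+") bl$qstart[b] + d - 1L
               else bl$qend[b] - d            # 0-based contig coordinate
        gb <- substr(tsub, d, d)
        break
      }
    }
    if (is.na(pos)) next
    out$contig_pos[i] <- pos
    out$contig_base[i] <- substr(qs_full, pos + 1L, pos + 1L)
    out$genome_base[i] <- gb
    my_orfs <- orfs[orfs$contig_id == a$contig_id &
                      orfs$start <= pos & orfs$end > pos, , drop = FALSE]
    if (nrow(my_orfs) == 0) next
    orf <- my_orfs[order(-my_orfs$length_aa), ][1, ]
    off <- if (orf$strand == "+") pos - orf$start else orf$end - 1L - pos
    aa_pos <- off %/% 3L + 1L
    orf_nt <- substr(qs_full, orf$start + 1L, orf$end)
    if (orf$strand == "-") orf_nt <- revcomp(orf_nt)
    codon_start <- (aa_pos - 1L) * 3L + 1L
    alt_codon <- substr(orf_nt, codon_start, codon_start + 2L)
    within <- off %% 3L + 1L
    # genome base -> contig-forward base (alignment strand), then ->
    # transcript orientation (ORF strand)
    ref_base <- if (a$strand == "-") revcomp(gb) else gb
    if (orf$strand == "-") ref_base <- revcomp(ref_base)
    ref_codon <- alt_codon
    substr(ref_codon, within, within) <- ref_base
    out$aa_pos[i] <- aa_pos
    out$ref_aa[i] <- translate_dna(ref_codon)
    out$alt_aa[i] <- translate_dna(alt_codon)
    out$nonsynonymous[i] <- out$ref_aa[i] != out$alt_aa[i]
  }
  out
}

#' Attach homology support to a classification
#'
#' Marks each classified contig as homology-supported when it has at
#' least one retained hit in any subject proteome, and records which
#' databases support it. Unaligned and putative-novel contigs with
#' homology support are the externally validated novel candidates.
#'
#' @param classification Output of [classify_contigs()].
#' @param kept_hits A hits tibble restricted to retained hits (rows of
#'   [filter_hits()] output with `kept = TRUE`), with a `subject_db`
#'   column.
#' @return The classification with `homology_supported` filled in and a
#'   `homology_dbs` list column added.
#' @export
homology_flag <- function(classification, kept_hits) {
  h <- kept_hits
  if ("kept" %in% names(h)) h <- h[h$kept, , drop = FALSE]
  by_contig <- split(h$subject_db, h$query_id)
  classification$homology_supported <-
    classification$contig_id %in% names(by_contig)
  classification$homology_dbs <- purrr::map(classification$contig_id,
    function(cid) sort(unique(by_contig[[cid]])) %||% character())
  classification
}

`%||%` <- function(x, y) if (is.null(x)) y else x
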