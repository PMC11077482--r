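#' Spliced-alignment parameters and retention thresholds
#'
#' The aligner seeds exact k-mer anchors, chains them collinearly
#' (target-side gaps up to `max_intron` are treated as introns), resolves
#' the remaining gaps column-wise, and scores columns `match`/`mismatch`.
#' The `+5`/`-4` scheme gives est2genome-like score magnitudes, so the
#' conventional `score > 2000` retention threshold corresponds to roughly
#' 400 matched bases. Retention thresholds follow the usual
#' transcript-to-genome filtering practice: score above `min_score`, at
#' least `min_identity_pct` percent identity, and at least
#' `min_coverage_pct` percent of the contig aligned.
#'
#' @param match,mismatch Per-column scores.
#' @param k Anchor seed length (>= 8).
#' @param max_intron Maximum target-side gap interpreted as an intron, bp.
#' @param min_exon Minimum exon length the aligner is expected to resolve, bp.
#' @param min_score Retention: score must exceed this.
#' @param min_identity_pct Retention: identity must be at least this (%).
#' @param min_coverage_pct Retention: query coverage must be at least this (%).
#' @return A `pg_align_params` list.
#' @export
align_params <- function(match = 5L, mismatch = -4L, k = 15L,
                         max_intron = 10000L, min_exon = 20L,
                         min_score = 2000, min_identity_pct = 95,
                         min_coverage_pct = 50) {
  stopifnot(k >= 8, match > 0, mismatch < 0, max_intron >= 0,
            min_score >= 0, min_identity_pct >= 0, min_coverage_pct >= 0)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         k = as.integer(k), max_intron = as.integer(max_intron),
         min_exon = as.integer(min_exon), min_score = min_score,
         min_identity_pct = min_identity_pct,
         min_coverage_pct = min_coverage_pct),
    class = "pg_align_params"
  )
}

#' Precompute a genome k-mer index
#'
#' Indexes every forward k-mer of every chromosome for exact anchor
#' seeding. Build once and reuse across contigs.
#'
#' @param genome A genome tibble (see [read_fasta()]).
#' @param k Seed length.
#' @return A `pg_genome_index` object.
#' @export
genome_kmer_index <- function(genome, k = 15L) {
  if (nrow(genome) == 0) abort("genome is empty")
  chroms <- purrr::map(seq_len(nrow(genome)), function(i) {
    s <- genome$sequence[i]
    L <- nchar(s)
    if (L < k) {
      return(list(seq = s, length = L, levels = character(), pos = list()))
    }
    kms <- substring(s, 1:(L - k + 1L), k:L)
    f <- factor(kms)
    list(seq = s, length = L, levels = levels(f),
         pos = split(0:(L - k), f))
  })
  names(chroms) <- genome$name
  structure(list(k = as.integer(k), chroms = chroms),
            class = "pg_genome_index")
}

utf8_mismatch_count <- function(a, b) {
  # column-wise mismatch count of two equal-length strings
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# cumulative-score-maximal ungapped extension length; qv/tv are equal-length
# character strings ordered from the alignment edge outward
best_extension <- function(qv, tv, match, mismatch) {
  n <- nchar(qv)
  if (n == 0) return(list(len = 0L, matches = 0L, mismatches = 0L))
  eq <- utf8ToInt(qv) == utf8ToInt(tv)
  cum <- cumsum(ifelse(eq, match, mismatch))
  best <- max(cum)
  if (best <= 0) return(list(len = 0L, matches = 0L, mismatches = 0L))
  len <- max(which(cum == best))
  list(len = as.integer(len), matches = sum(eq[seq_len(len)]),
       mismatches = as.integer(len - sum(eq[seq_len(len)])))
}

# collinear chaining DP over exact-match segments (qs,qe,ts,te 0-based).
# Anchors spanning an exon junction can extend a base or two past the true
# boundary on the wrong diagonal, so segments may overlap by up to k-1;
# such overlaps are allowed here and trimmed during block construction.
chain_segments <- function(seg, max_intron, k, max_qgap = 200L) {
  n <- nrow(seg)
  ord <- order(seg$qs, seg$ts)
  seg <- seg[ord, , drop = FALSE]
  len <- seg$qe - seg$qs
  dp <- len
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      qgap <- seg$qs[i] - seg$qe[j]
      tgap <- seg$ts[i] - seg$te[j]
      if (qgap < -(k - 1L) || tgap < -(k - 1L)) next
      if (seg$qe[i] <= seg$qe[j] || seg$te[i] <= seg$te[j]) next
      if (qgap > max_qgap) next
      if (tgap - max(qgap, 0L) > max_intron) next
      cand <- dp[j] + len[i] - max(0L, -qgap) - max(0L, -tgap)
      if (cand > dp[i]) {
        dp[i] <- cand
        prev[i] <- j
      }
    }
  }
  i <- which.max(dp)
  chain <- integer()
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  seg[chain, , drop = FALSE]
}

align_one_orientation <- function(q, chrom_name, chrom, params) {
  k <- params$k
  Lq <- nchar(q)
  Lt <- chrom$length
  if (Lq < k || length(chrom$levels) == 0) return(list())
  qk <- substring(q, 1:(Lq - k + 1L), k:Lq)
  lev <- match(qk, chrom$levels)
  hit_q <- which(!is.na(lev))
  if (length(hit_q) == 0) return(list())
  tpos_list <- chrom$pos[lev[hit_q]]
  qpos <- rep.int(hit_q - 1L, lengths(tpos_list))
  tpos <- unlist(tpos_list, use.names = FALSE)

  # merge same-diagonal anchor runs into maximal exact segments
  d <- tpos - qpos
  o <- order(d, qpos)
  d <- d[o]; qpos <- qpos[o]
  run_break <- c(TRUE, diff(d) != 0 | diff(qpos) > k)
  run_id <- cumsum(run_break)
  seg <- tibble(
    qs = tapply(qpos, run_id, min)[unique(run_id)] |> as.integer(),
    qe = (tapply(qpos, run_id, max)[unique(run_id)] + k) |> as.integer(),
    diag = tapply(d, run_id, function(x) x[1])[unique(run_id)] |> as.integer()
  )
  seg$ts <- seg$qs + seg$diag
  seg$te <- seg$qe + seg$diag

  # cluster segments into candidate loci by target-side proximity
  seg <- seg[order(seg$ts), , drop = FALSE]
  locus_break <- c(TRUE, seg$ts[-1] > cummax(seg$te)[-nrow(seg)] + params$max_intron)
  locus_id <- cumsum(locus_break)

  out <- list()
  for (lid in unique(locus_id)) {
    sl <- seg[locus_id == lid, , drop = FALSE]
    chain <- chain_segments(sl, params$max_intron, k)
    if (nrow(chain) == 0) next

    # resolve inter-segment gaps into blocks
    blocks <- list()
    cur <- c(chain$qs[1], chain$qe[1], chain$ts[1], chain$te[1])
    if (nrow(chain) > 1) {
      for (i in 2:nrow(chain)) {
        # trim any small overlap (junction-spanning anchors) off the
        # incoming segment so gaps are non-negative
        ov <- max(0L, cur[2] - chain$qs[i])
        ov <- max(ov, cur[4] - chain$ts[i])
        if (ov > 0) {
          chain$qs[i] <- chain$qs[i] + ov
          chain$ts[i] <- chain$ts[i] + ov
          if (chain$qs[i] >= chain$qe[i]) next
        }
        qgap <- chain$qs[i] - cur[2]
        tgap <- chain$ts[i] - cur[4]
        if (qgap == tgap) {
          cur[2] <- chain$qe[i]; cur[4] <- chain$te[i]
        } else if (tgap > qgap) {
          if (qgap > 0) {
            # unanchored query bases straddling an intron: place them on
            # whichever side of the junction matches best (optimal split)
            gap_q <- substr(q, cur[2] + 1L, cur[2] + qgap)
            left_t <- substr(chrom$seq, cur[4] + 1L, cur[4] + qgap)
            right_t <- substr(chrom$seq, chain$ts[i] - qgap + 1L, chain$ts[i])
            le <- cumsum(utf8ToInt(gap_q) == utf8ToInt(left_t))
            re <- utf8ToInt(gap_q) == utf8ToInt(right_t)
            sc <- c(0L, le) + (sum(re) - c(0L, cumsum(re)))
            s <- which.max(sc) - 1L
            cur[2] <- cur[2] + s; cur[4] <- cur[4] + s
            chain$qs[i] <- chain$qs[i] - (qgap - s)
            chain$ts[i] <- chain$ts[i] - (qgap - s)
          }
          blocks[[length(blocks) + 1L]] <- cur
          cur <- c(chain$qs[i], chain$qe[i], chain$ts[i], chain$te[i])
        } else {
          if (tgap > 0) { cur[2] <- cur[2] + tgap; cur[4] <- cur[4] + tgap }
          blocks[[length(blocks) + 1L]] <- cur
          cur <- c(chain$qs[i], chain$qe[i], chain$ts[i], chain$te[i])
        }
      }
    }
    blocks[[length(blocks) + 1L]] <- cur
    bl <- do.call(rbind, blocks)
    colnames(bl) <- c("qstart", "qend", "tstart", "tend")
    bl <- as_tibble(bl)

    # ungapped edge extension, trimmed at the cumulative-score maximum
    ext_n <- min(bl$qstart[1], bl$tstart[1])
    if (ext_n > 0) {
      qv <- rev_chars(substr(q, bl$qstart[1] - ext_n + 1L, bl$qstart[1]))
      tv <- rev_chars(substr(chrom$seq, bl$tstart[1] - ext_n + 1L, bl$tstart[1]))
      e <- best_extension(qv, tv, params$match, params$mismatch)
      bl$qstart[1] <- bl$qstart[1] - e$len
      bl$tstart[1] <- bl$tstart[1] - e$len
    }
    nlast <- nrow(bl)
    ext_n <- min(Lq - bl$qend[nlast], Lt - bl$tend[nlast])
    if (ext_n > 0) {
      qv <- substr(q, bl$qend[nlast] + 1L, bl$qend[nlast] + ext_n)
      tv <- substr(chrom$seq, bl$tend[nlast] + 1L, bl$tend[nlast] + ext_n)
      e <- best_extension(qv, tv, params$match, params$mismatch)
      bl$qend[nlast] <- bl$qend[nlast] + e$len
      bl$tend[nlast] <- bl$tend[nlast] + e$len
    }

    # column-walk statistics over the final blocks
    mm <- 0L
    cols <- 0L
    for (i in seq_len(nrow(bl))) {
      qs_sub <- substr(q, bl$qstart[i] + 1L, bl$qend[i])
      ts_sub <- substr(chrom$seq, bl$tstart[i] + 1L, bl$tend[i])
      mm <- mm + utf8_mismatch_count(qs_sub, ts_sub)
      cols <- cols + nchar(qs_sub)
    }
    matches <- cols - mm
    if (matches < k) next
    out[[length(out) + 1L]] <- list(blocks = bl, matches = matches,
                                    mismatches = mm, aligned_cols = cols)
  }
  out
}

rev_chars <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

#' Align transcript contigs to a genome (splice-aware)
#'
#' Seeds exact `k`-mer anchors against each chromosome and each contig
#' orientation, chains them collinearly, treats target-side gaps up to
#' `max_intron` as introns, resolves substitution regions column-wise,
#' and extends ungapped to the contig ends trimming at the
#' cumulative-score maximum. A contig may align at several loci; every
#' locus is reported. Alignment blocks are given on the contig's forward
#' coordinates; on the `-` strand, ascending contig coordinates pair with
#' descending genomic blocks (the orientation recorded in `strand`).
#'
#' This aligner targets the high-identity regime the retention filter
#' keeps (about 95% identity and above); it does not model gapped
#' low-identity homology.
#'
#' @param contigs A tibble with columns `name` and `sequence`, or a
#'   single sequence string with `name` supplied via `contig_id`.
#' @param genome A genome tibble, or a prebuilt [genome_kmer_index()].
#' @param params An [align_params()] object.
#' @param contig_id Name used when `contigs` is a bare string.
#' @return An alignment tibble: `alignment_id`, `contig_id`, `chrom`,
#'   `strand`, `score`, `matches`, `mismatches`, `aligned_cols`,
#'   `identity_pct`, `coverage_pct`, `query_aligned`, `contig_length`,
#'   `t_start`, `t_end`, `n_blocks`, and a `blocks` list column of
#'   per-block tibbles (`qstart`, `qend`, `tstart`, `tend`). Loci are
#'   ordered per contig by score (descending), then chromosome, then
#'   genomic start.
#' @export
align_contigs <- function(contigs, genome, params = align_params(),
                          contig_id = "contig") {
  if (is.character(contigs)) {
    contigs <- tibble(name = contig_id, sequence = contigs)
  }
  index <- if (inherits(genome, "pg_genome_index")) {
    if (genome$k != params$k) abort("genome index k does not match params$k")
    genome
  } else {
    genome_kmer_index(genome, k = params$k)
  }
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    qid <- contigs$name[ci]
    qseq <- contigs$sequence[ci]
    Lq <- nchar(qseq)
    for (chrom_name in names(index$chroms)) {
      chrom <- index$chroms[[chrom_name]]
      for (orient in c("+", "-")) {
        q <- if (orient == "+") qseq else revcomp(qseq)
        loci <- align_one_orientation(q, chrom_name, chrom, params)
        for (loc in loci) {
          bl <- loc$blocks
          if (orient == "-") {
            bl <- tibble(
              qstart = Lq - rev(bl$qend), qend = Lq - rev(bl$qstart),
              tstart = rev(bl$tstart), tend = rev(bl$tend)
            )
          }
          score <- params$match * loc$matches + params$mismatch * loc$mismatches
          query_aligned <- sum(bl$qend - bl$qstart)
          rows[[length(rows) + 1L]] <- tibble(
            contig_id = qid, chrom = chrom_name, strand = orient,
            score = score, matches = loc$matches,
            mismatches = loc$mismatches, aligned_cols = loc$aligned_cols,
            identity_pct = 100 * loc$matches / loc$aligned_cols,
            coverage_pct = 100 * query_aligned / Lq,
            query_aligned = as.integer(query_aligned),
            contig_length = as.integer(Lq),
            t_start = min(bl$tstart), t_end = max(bl$tend),
            n_blocks = nrow(bl), blocks = list(bl)
          )
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_alignment_tbl())
  out <- bind_rows(rows) %>%
    arrange(.data$contig_id, dplyr::desc(.data$score), .data$chrom,
            .data$t_start)
  out$alignment_id <- sprintf("%s|%s:%d-%d(%s)", out$contig_id, out$chrom,
                              out$t_start, out$t_end, out$strand)
  select(out, "alignment_id", dplyr::everything())
}

empty_alignment_tbl <- function() {
  tibble(
    alignment_id = character(), contig_id = character(), chrom = character(),
    strand = character(), score = numeric(), matches = integer(),
    mismatches = integer(), aligned_cols = integer(),
    identity_pct = numeric(), coverage_pct = numeric(),
    query_aligned = integer(), contig_length = integer(),
    t_start = integer(), t_end = integer(), n_blocks = integer(),
    blocks = list()
  )
}

#' Apply the alignment retention filter
#'
#' An alignment is kept when its score exceeds `min_score`, its identity
#' is at least `min_identity_pct`, and its query coverage is at least
#' `min_coverage_pct`. Rejected alignments carry the first failing
#' criterion (checked in that order). `NA` statistics (e.g. from imported
#' alignments lacking them) pass their criterion.
#'
#' @param alignments An alignment tibble (see [align_contigs()]).
#' @param params An [align_params()] carrying the thresholds.
#' @return The alignments with added columns `kept` (logical) and
#'   `reject_reason` (`"score"`, `"identity"`, `"coverage"`, or `NA`);
#'   kept and rejected rows partition the input.
#' @export
filter_alignments <- function(alignments, params = align_params()) {
  fail_score <- !is.na(alignments$score) & alignments$score <= params$min_score
  fail_id <- !is.na(alignments$identity_pct) &
    alignments$identity_pct < params$min_identity_pct
  fail_cov <- !is.na(alignments$coverage_pct) &
    alignments$coverage_pct < params$min_coverage_pct
  reason <- rep(NA_character_, nrow(alignments))
  reason[fail_cov] <- "coverage"
  reason[fail_id] <- "identity"
  reason[fail_score] <- "score"
  alignments$kept <- is.na(reason)
  alignments$reject_reason <- reason
  alignments
}

#' Recompute alignment statistics from blocks by column walk
#'
#' Walks every block column by column against the contig and genome
#' sequences and recomputes matches, mismatches, score, identity and
#' coverage. Used to fill in statistics for imported alignments and to
#' cross-check the aligner's bookkeeping.
#'
#' @param alignments An alignment tibble with a `blocks` list column.
#' @param contigs,genome Sequence tibbles (see [read_fasta()]).
#' @param params An [align_params()] supplying the scoring scheme.
#' @return The alignments with refreshed statistic columns.
#' @export
recompute_alignment_stats <- function(alignments, contigs, genome,
                                      params = align_params()) {
  cseq <- stats::setNames(contigs$sequence, contigs$name)
  gseq <- stats::setNames(genome$sequence, genome$name)
  for (i in seq_len(nrow(alignments))) {
    if (!alignments$contig_id[i] %in% names(cseq) ||
        !alignments$chrom[i] %in% names(gseq)) {
      abort(paste0("missing sequence for alignment of contig '",
                   alignments$contig_id[i], "'"))
    }
    qs <- cseq[[alignments$contig_id[i]]]
    ts <- gseq[[alignments$chrom[i]]]
    bl <- alignments$blocks[[i]]
    mm <- 0L; cols <- 0L
    for (b in seq_len(nrow(bl))) {
      qsub <- substr(qs, bl$qstart[b] + 1L, bl$qend[b])
      if (alignments$strand[i] == "-") qsub <- revcomp(qsub)
      tsub <- substr(ts, bl$tstart[b] + 1L, bl$tend[b])
      mm <- mm + utf8_mismatch_count(qsub, tsub)
      cols <- cols + nchar(qsub)
    }
    qa <- sum(bl$qend - bl$qstart)
    alignments$matches[i] <- cols - mm
    alignments$mismatches[i] <- mm
    alignments$aligned_cols[i] <- cols
    alignments$score[i] <- params$match * (cols - mm) + params$mismatch * mm
    alignments$identity_pct[i] <- 100 * (cols - mm) / cols
    alignments$query_aligned[i] <- as.integer(qa)
    alignments$contig_length[i] <- nchar(qs)
    alignments$coverage_pct[i] <- 100 * qa / nchar(qs)
  }
  alignments
}

#' Import est2genome-style GFF2 alignment output
#'
#' Reads the documented subset of an EXONERATE est2genome GFF dump: tab
#' separated lines whose feature column is `gene` (one per alignment,
#' with a `sequence <contig_id>` attribute and the alignment score) or
#' `exon` (one per aligned block), with genomic coordinates in columns
#' 4--5 and the strand in column 7. Query-side block coordinates are
#' reconstructed from the block lengths in transcript order. When contig
#' and genome sequences are supplied, identity and coverage are
#' recomputed by column walk; otherwise they are `NA` and pass the
#' retention filter's identity/coverage criteria.
#'
#' @param path Path to the GFF2 file.
#' @param contigs,genome Optional sequence tibbles for statistic
#'   recomputation.
#' @param params An [align_params()].
#' @return An alignment tibble (see [align_contigs()]).
#' @export
read_exonerate_gff <- function(path, contigs = NULL, genome = NULL,
                               params = align_params()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 8 && f[3] %in% c("gene", "exon"),
                 logical(1))
  fields <- fields[keep]
  rows <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur$exons) == 0) return(NULL)
    ex <- do.call(rbind, cur$exons)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    w <- ex[, 2] - ex[, 1]
    torder <- if (cur$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    qend <- cumsum(w[torder])
    bl <- tibble(qstart = qend - w[torder], qend = qend,
                 tstart = ex[torder, 1], tend = ex[torder, 2])
    # store blocks in ascending query order (contig-forward convention)
    bl <- bl[order(bl$qstart), ]
    tibble(
      contig_id = cur$contig_id, chrom = cur$chrom, strand = cur$strand,
      score = cur$score, matches = NA_integer_, mismatches = NA_integer_,
      aligned_cols = NA_integer_, identity_pct = NA_real_,
      coverage_pct = NA_real_, query_aligned = as.integer(sum(w)),
      contig_length = NA_integer_, t_start = min(bl$tstart),
      t_end = max(bl$tend), n_blocks = nrow(bl), blocks = list(bl)
    )
  }
  for (f in fields) {
    if (f[3] == "gene") {
      rows[[length(rows) + 1L]] <- flush(cur)
      m <- regmatches(f[9], regexec("sequence\\s+([^ ;]+)", f[9]))[[1]]
      cur <- list(
        chrom = f[1],
        contig_id = if (length(m) == 2) m[2] else paste0("query", length(rows) + 1L),
        score = suppressWarnings(as.numeric(f[6])),
        strand = f[7], exons = list()
      )
    } else if (!is.null(cur)) {
      cur$exons[[length(cur$exons) + 1L]] <-
        c(as.integer(f[4]) - 1L, as.integer(f[5]))
    }
  }
  rows[[length(rows) + 1L]] <- flush(cur)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_alignment_tbl())
  out <- bind_rows(rows)
  if (!is.null(contigs) && !is.null(genome)) {
    out <- recompute_alignment_stats(out, contigs, genome, params)
  } else if (!is.null(contigs)) {
    cl <- stats::setNames(nchar(contigs$sequence), contigs$name)
    out$contig_length <- as.integer(cl[out$contig_id])
    out$coverage_pct <- 100 * out$query_aligned / out$contig_length
  }
  out$alignment_id <- sprintf("%s|%s:%d-%d(%s)", out$contig_id, out$chrom,
                              out$t_start, out$t_end, out$strand)
  select(out, "alignment_id", dplyr::everything())
}
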