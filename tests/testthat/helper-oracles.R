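# Independent oracles, deliberately coded without reusing package internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# per-base transcript -> genome lookup table for a coordinate map
oracle_map_table <- function(blocks, strand) {
  unlist(lapply(seq_len(nrow(blocks)), function(i) {
    qs <- blocks$qstart[i]; qe <- blocks$qend[i]
    if (strand == "+") {
      blocks$tstart[i] + (qs:(qe - 1L)) - qs
    } else {
      blocks$tend[i] - 1L - ((qs:(qe - 1L)) - qs)
    }
  }))
}

# brute-force digestion: every substring bounded by cleavage sites with a
# bounded number of internal sites
oracle_digest <- function(protein, enzyme, max_missed, min_len, max_len) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  if (n == 0) return(character())
  is_site <- vapply(seq_len(max(n - 1L, 0L)), function(i) {
    kr <- res[i] == "K" || res[i] == "R"
    if (enzyme == "trypsin/P") return(kr)
    if (enzyme == "lysC+trypsin") {
      return(res[i] == "K" || (res[i] == "R" && res[i + 1L] != "P"))
    }
    kr && res[i + 1L] != "P"
  }, logical(1))
  boundary <- c(TRUE, is_site)          # boundary[i]: position i can start
  end_ok <- c(is_site, TRUE)            # end_ok[j]: position j can end
  out <- character()
  for (i in seq_len(n)) {
    if (!boundary[i]) next
    for (j in i:n) {
      if (!end_ok[j]) next
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      internal <- if (j > i) sum(is_site[i:(j - 1L)]) else 0L
      if (internal > max_missed) next
      pep <- paste(res[i:j], collapse = "")
      if (!grepl("X", pep, fixed = TRUE)) out <- c(out, pep)
    }
  }
  unique(out)
}

# quadratic-time affine-gap Smith-Waterman (gap of length L costs
# open + L * extend), scored with BLOSUM62
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# column-walk recomputation of alignment statistics from blocks
oracle_alignment_stats <- function(aln_row, contig_seq, genome_seq) {
  bl <- aln_row$blocks[[1]]
  matches <- 0L; cols <- 0L
  for (b in seq_len(nrow(bl))) {
    qsub <- substr(contig_seq, bl$qstart[b] + 1L, bl$qend[b])
    if (aln_row$strand == "-") qsub <- oracle_revcomp(qsub)
    tsub <- substr(genome_seq, bl$tstart[b] + 1L, bl$tend[b])
    qc <- strsplit(qsub, "")[[1]]; tc <- strsplit(tsub, "")[[1]]
    matches <- matches + sum(qc == tc)
    cols <- cols + length(qc)
  }
  list(matches = matches, mismatches = cols - matches, aligned_cols = cols,
       coverage_pct = 100 * sum(bl$qend - bl$qstart) / nchar(contig_seq))
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
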