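#' Predict open reading frames in assembled contigs
#'
#' Scans all six frames (three per strand) of each contig. An ORF runs
#' from a start codon (`ATG`) -- or, when `allow_partial = TRUE`, from the
#' frame's first codon when no upstream in-frame stop exists -- to the
#' next in-frame stop codon (included in the coordinates) or the contig
#' end. Nested ORFs sharing a stop are reported once, at their longest
#' extent (first `ATG` per stop-delimited segment). Coordinates are on the
#' contig's forward strand, 0-based half-open.
#'
#' @param contigs A tibble with columns `name` and `sequence` (see
#'   [read_fasta()]).
#' @param min_aa Minimum protein length in residues (stop excluded).
#' @param allow_partial Report 5'-incomplete ORFs that begin at the
#'   frame's first codon.
#' @return A tibble of ORF records sorted longest-first (ties by
#'   `contig_id`, `+` strand first, then start): `orf_id`, `contig_id`,
#'   `strand`, `start`, `end`, `frame`, `protein`, `length_aa`,
#'   `complete_5p`, `complete_3p`.
#' @export
find_orfs <- function(contigs, min_aa = 100L, allow_partial = TRUE) {
  stopifnot(min_aa >= 1)
  stopifnot(all(c("name", "sequence") %in% names(contigs)))
  res <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    find_orfs_one(contigs$name[i], contigs$sequence[i], min_aa, allow_partial)
  })
  if (nrow(res) == 0) return(empty_orf_tbl())
  res %>%
    arrange(dplyr::desc(.data$length_aa), .data$contig_id,
            .data$strand, .data$start)
}

empty_orf_tbl <- function() {
  tibble(
    orf_id = character(), contig_id = character(), strand = character(),
    start = integer(), end = integer(), frame = integer(),
    protein = character(), length_aa = integer(),
    complete_5p = logical(), complete_3p = logical()
  )
}

find_orfs_one <- function(contig_id, seq, min_aa, allow_partial) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3L
      if (n_codon < 1) next
      starts1 <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
      codons <- substring(s, starts1, starts1 + 2L)
      stop_idx <- which(codons %in% stops)
      seg_bounds <- c(0L, stop_idx, n_codon + 1L)
      for (si in seq_len(length(seg_bounds) - 1L)) {
        first <- seg_bounds[si] + 1L            # first codon index in segment
        stop_at <- seg_bounds[si + 1L]          # index of stop codon, or n_codon+1
        has_stop <- stop_at <= n_codon
        last_coding <- stop_at - 1L
        if (last_coding < first) next
        atg <- which(codons[first:last_coding] == "ATG")
        if (length(atg) > 0) {
          orf_first <- first + atg[1] - 1L
          complete_5p <- TRUE
        } else if (allow_partial && si == 1L) {
          orf_first <- first
          complete_5p <- FALSE
        } else {
          next
        }
        if (last_coding - orf_first + 1L < min_aa) next
        prot <- paste0(codons[orf_first:last_coding], collapse = "")
        protein <- translate_dna(prot)
        if (nchar(protein) < min_aa) next
        s_start <- frame + 3L * (orf_first - 1L)               # 0-based on scanned strand
        s_end <- frame + 3L * (if (has_stop) stop_at else last_coding)
        if (strand == "+") {
          start <- s_start; end <- s_end
        } else {
          start <- L - s_end; end <- L - s_start
        }
        out[[length(out) + 1L]] <- tibble(
          orf_id = sprintf("%s:%s:f%d:%d", contig_id, strand, frame, start),
          contig_id = contig_id, strand = strand,
          start = as.integer(start), end = as.integer(end),
          frame = as.integer(frame), protein = protein,
          length_aa = nchar(protein),
          complete_5p = complete_5p, complete_3p = has_stop
        )
      }
    }
  }
  if (length(out) == 0) empty_orf_tbl() else bind_rows(out)
}

#' Build a protein database from contig ORFs
#'
#' Runs [find_orfs()] over a contig set and assembles the protein search
#' database, either with all qualifying ORFs or reduced to the single
#' longest ORF per contig (ties broken by `+` strand first, then lowest
#' start), emulating a one-protein-per-transcript reduction.
#'
#' @inheritParams find_orfs
#' @param mode `"all"` or `"longest_per_contig"`.
#' @return An ORF tibble as in [find_orfs()].
#' @export
build_protein_db <- function(contigs, min_aa = 100L,
                             mode = c("all", "longest_per_contig"),
                             allow_partial = TRUE) {
  mode <- match.arg(mode)
  if (anyDuplicated(contigs$name) > 0) {
    abort(paste0("duplicate contig id: ",
                 contigs$name[duplicated(contigs$name)][1]))
  }
  orfs <- find_orfs(contigs, min_aa = min_aa, allow_partial = allow_partial)
  if (mode == "longest_per_contig" && nrow(orfs) > 0) {
    orfs <- orfs %>%
      arrange(dplyr::desc(.data$length_aa), .data$strand, .data$start) %>%
      group_by(.data$contig_id) %>%
      slice(1) %>%
      ungroup() %>%
      arrange(dplyr::desc(.data$length_aa), .data$contig_id,
              .data$strand, .data$start)
  }
  orfs
}

#' Write predicted proteins to FASTA with coordinate provenance
#'
#' Headers follow the grammar
#' `orf_id contig_id:start-end(strand)frame`, e.g.
#' `ctg1:+:f2:2 ctg1:2-11(+)2`, so downstream peptide projection can
#' recover the ORF's position on its contig from the header alone.
#'
#' @param orfs An ORF tibble (see [find_orfs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(orfs, path) {
  headers <- sprintf("%s %s:%d-%d(%s)%d", orfs$orf_id, orfs$contig_id,
                     orfs$start, orfs$end, orfs$strand, orfs$frame)
  lines <- as.vector(rbind(paste0(">", headers), orfs$protein))
  writeLines(lines, path)
  invisible(path)
}
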