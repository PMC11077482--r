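# Resolve novel observations to their parent ORFs and contigs via the
# transcript database's parent lists.
novel_support <- function(novel_obs, orfs, transcript_db) {
  if (nrow(novel_obs) == 0) {
    return(tibble(peptide = character(), orf_id = character(),
                  contig_id = character()))
  }
  rows <- purrr::map_dfr(seq_len(nrow(novel_obs)), function(i) {
    par <- novel_obs$parents[[i]][[transcript_db]]
    if (is.null(par) || length(par) == 0) {
      abort(paste0("novel peptide '", novel_obs$peptide[i],
                   "' has no parent in database '", transcript_db, "'"))
    }
    tibble(peptide = novel_obs$peptide[i], orf_id = par)
  })
  idx <- match(rows$orf_id, orfs$orf_id)
  if (anyNA(idx)) {
    abort(paste0("parent ORF '", rows$orf_id[is.na(idx)][1],
                 "' missing from the ORF set"))
  }
  rows$contig_id <- orfs$contig_id[idx]
  rows
}

#' Classify peptide-supported contigs against an annotation
#'
#' Implements the decision flow for contigs carrying at least one novel
#' peptide. A contig with at least one retained genomic alignment whose
#' span shares at least one base with an annotated gene's span is a
#' *refined gene structure* (the most likely explanation of novel
#' peptides over an annotated gene is that the annotation should be
#' revised). A contig whose retained alignments overlap no gene is a
#' *putative novel gene*. A contig with no retained alignment is
#' *unaligned*; homology evidence for those is attached later by
#' [homology_flag()]. Each contig is classified exactly once, and gene
#' overlap dominates when a contig has both overlapping and
#' non-overlapping alignments.
#'
#' @param novel_obs Novel peptide observations (see [novel_peptides()];
#'   more generally, any membership rows whose peptides are absent from
#'   the annotation under study).
#' @param orfs The ORF tibble the transcript database was built from.
#' @param kept_alignments Retained alignments (rows of
#'   [filter_alignments()] output with `kept = TRUE`).
#' @param annotation Annotation tibble of the version under study.
#' @param overlap `"span"` compares against gene spans (min exon start to
#'   max exon end); `"exon"` requires overlap with an exon.
#' @param strand_mode `"either"` ignores strand when testing overlap
#'   (alignment strand need not match the gene's); `"match"` requires it.
#' @param transcript_db Name of the transcript database in the
#'   observations' parent lists.
#' @return A classification tibble: `contig_id`, `category`,
#'   `n_alignments`, `alignments_used` (list), `overlapping_genes`
#'   (list), `supporting_peptides` (list), `n_peptides`,
#'   `homology_supported` (initialised `NA`).
#' @export
classify_contigs <- function(novel_obs, orfs, kept_alignments, annotation,
                             overlap = c("span", "exon"),
                             strand_mode = c("either", "match"),
                             transcript_db = "transcript") {
  overlap <- match.arg(overlap)
  strand_mode <- match.arg(strand_mode)
  validate_annotation(annotation)
  support <- novel_support(novel_obs, orfs, transcript_db)
  contig_ids <- sort(unique(support$contig_id))
  targets <- if (overlap == "span") gene_spans(annotation) else annotation
  aln <- kept_alignments
  if ("kept" %in% names(aln)) aln <- aln[aln$kept, , drop = FALSE]

  res <- purrr::map_dfr(contig_ids, function(cid) {
    my_aln <- aln[aln$contig_id == cid, , drop = FALSE]
    peps <- sort(unique(support$peptide[support$contig_id == cid]))
    if (nrow(my_aln) == 0) {
      return(tibble(
        contig_id = cid, category = "unaligned", n_alignments = 0L,
        alignments_used = list(character()),
        overlapping_genes = list(character()),
        supporting_peptides = list(peps), n_peptides = length(peps),
        homology_supported = NA
      ))
    }
    genes_hit <- character()
    for (i in seq_len(nrow(my_aln))) {
      cand <- targets[targets$chrom == my_aln$chrom[i], , drop = FALSE]
      if (strand_mode == "match") {
        cand <- cand[cand$strand == my_aln$strand[i], , drop = FALSE]
      }
      hit <- cand$start < my_aln$t_end[i] & cand$end > my_aln$t_start[i]
      genes_hit <- c(genes_hit, cand$gene_id[hit])
    }
    genes_hit <- sort(unique(genes_hit))
    tibble(
      contig_id = cid,
      category = if (length(genes_hit) > 0) "refined_gene_structure"
                 else "putative_novel_gene",
      n_alignments = nrow(my_aln),
      alignments_used = list(my_aln$alignment_id),
      overlapping_genes = list(genes_hit),
      supporting_peptides = list(peps), n_peptides = length(peps),
      homology_supported = NA
    )
  })
  if (nrow(res) == 0) {
    res <- tibble(
      contig_id = character(), category = character(),
      n_alignments = integer(), alignments_used = list(),
      overlapping_genes = list(), supporting_peptides = list(),
      n_peptides = integer(), homology_supported = logical()
    )
  }
  res
}

#' Project novel peptides to genomic coordinates
#'
#' Lifts each novel peptide from its position in the parent protein to an
#' ORF-relative nucleotide interval, to contig coordinates
#' (strand-adjusted through the ORF's strand), and finally to genomic
#' blocks through each retained alignment of the parent contig. Peptides
#' extending beyond the aligned portion of the contig are clipped and
#' flagged. When the genome is supplied, a `frame_consistent` flag
#' records whether translating the extracted genomic blocks (spliced,
#' strand-adjusted) reproduces the peptide exactly.
#'
#' @inheritParams classify_contigs
#' @param genome Optional genome tibble for the translation round-trip
#'   check.
#' @return A peptide-locus tibble: `peptide`, `contig_id`, `orf_id`,
#'   `alignment_id`, `chrom`, `strand` (of the peptide locus), `blocks`
#'   (list of ascending genomic `start`/`end` tibbles), `n_blocks`,
#'   `clipped`, `frame_consistent` (`NA` when clipped or no genome
#'   given). Peptides occurring several times in a protein, or contigs
#'   aligned at several loci, yield one row per occurrence and locus.
#' @export
project_peptides <- function(novel_obs, orfs, kept_alignments,
                             genome = NULL, transcript_db = "transcript") {
  support <- novel_support(novel_obs, orfs, transcript_db)
  aln <- kept_alignments
  if ("kept" %in% names(aln)) aln <- aln[aln$kept, , drop = FALSE]
  gseq <- if (!is.null(genome)) stats::setNames(genome$sequence, genome$name)

  rows <- list()
  for (i in seq_len(nrow(support))) {
    orf <- orfs[orfs$orf_id == support$orf_id[i], ]
    pep <- support$peptide[i]
    hits <- gregexpr(pep, orf$protein, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      abort(paste0("peptide '", pep, "' is not a substring of ORF '",
                   orf$orf_id, "'"))
    }
    my_aln <- aln[aln$contig_id == orf$contig_id, , drop = FALSE]
    for (p0 in as.integer(hits) - 1L) {          # 0-based protein offset
      plen <- nchar(pep)
      if (orf$strand == "+") {
        nt_a <- orf$start + 3L * p0
        nt_b <- nt_a + 3L * plen
      } else {
        nt_b <- orf$end - 3L * p0
        nt_a <- nt_b - 3L * plen
      }
      for (j in seq_len(nrow(my_aln))) {
        bl <- my_aln$blocks[[j]]
        qlo <- min(bl$qstart); qhi <- max(bl$qend)
        a <- max(nt_a, qlo); b <- min(nt_b, qhi)
        if (b <= a) next
        pieces <- project_interval_blocks(bl, my_aln$strand[j], a, b)
        mapped <- sum(pieces$end - pieces$start)
        clipped <- mapped < 3L * plen
        locus_strand <- if (orf$strand == my_aln$strand[j]) "+" else "-"
        frame_ok <- NA
        if (!clipped && !is.null(gseq)) {
          s <- paste0(substring(gseq[[my_aln$chrom[j]]],
                                pieces$start + 1L, pieces$end),
                      collapse = "")
          if (locus_strand == "-") s <- revcomp(s)
          frame_ok <- identical(translate_dna(s), pep)
        }
        rows[[length(rows) + 1L]] <- tibble(
          peptide = pep, contig_id = orf$contig_id, orf_id = orf$orf_id,
          alignment_id = my_aln$alignment_id[j], chrom = my_aln$chrom[j],
          strand = locus_strand, blocks = list(pieces),
          n_blocks = nrow(pieces), clipped = clipped,
          frame_consistent = frame_ok
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      peptide = character(), contig_id = character(), orf_id = character(),
      alignment_id = character(), chrom = character(), strand = character(),
      blocks = list(), n_blocks = integer(), clipped = logical(),
      frame_consistent = logical()
    ))
  }
  out <- bind_rows(rows)
  # identical loci can arise via several parent ORFs; collapse exact dupes
  out$.key <- vapply(seq_len(nrow(out)), function(i) {
    paste(out$peptide[i], out$alignment_id[i], out$strand[i],
          paste(out$blocks[[i]]$start, out$blocks[[i]]$end, collapse = ";"))
  }, character(1))
  out <- out[!duplicated(out$.key), , drop = FALSE]
  out$.key <- NULL
  arrange(out, .data$peptide, .data$chrom)
}

#' Format loci as BED12 genome-browser track lines
#'
#' Emits one BED12 line per locus (peptide locus or alignment), with
#' 0-based half-open coordinates, score 0, thick range equal to the full
#' range, and blockSizes/blockStarts derived from the genomic blocks.
#' Output is bit-exact tab-separated text suitable for a custom track.
#'
#' @param loci A peptide-locus tibble (see [project_peptides()]) or an
#'   alignment tibble (see [align_contigs()]); any tibble with `chrom`,
#'   `strand`, a `blocks` list column and a name column works.
#' @param name_col Column used for the BED name field (defaults to
#'   `peptide` when present, else `contig_id`).
#' @param rgb The itemRgb field.
#' @return A character vector of BED12 lines.
#' @export
#' @examples
#' loci <- tibble::tibble(
#'   peptide = "PEPTIDE", chrom = "chr1", strand = "+",
#'   blocks = list(tibble::tibble(start = c(125, 200), end = c(130, 210)))
#' )
#' to_bed12(loci)
to_bed12 <- function(loci, name_col = NULL, rgb = "0") {
  if (is.null(name_col)) {
    name_col <- if ("peptide" %in% names(loci)) "peptide" else "contig_id"
  }
  vapply(seq_len(nrow(loci)), function(i) {
    bl <- loci$blocks[[i]]
    if (is.null(bl) || nrow(bl) == 0) {
      abort(paste0("locus ", i, " has an empty block list"))
    }
    if ("tstart" %in% names(bl)) {
      bl <- tibble(start = bl$tstart, end = bl$tend)
      bl <- bl[order(bl$start), ]
    }
    if (any(diff(bl$start) <= 0) && nrow(bl) > 1) {
      abort(paste0("locus ", i, " has blocks out of ascending order"))
    }
    if (nrow(bl) > 1 && any(bl$start[-1] < bl$end[-nrow(bl)])) {
      abort(paste0("locus ", i, " has overlapping blocks"))
    }
    chrom_start <- bl$start[1]
    chrom_end <- bl$end[nrow(bl)]
    paste(
      loci$chrom[i], chrom_start, chrom_end, loci[[name_col]][i], 0,
      loci$strand[i], chrom_start, chrom_end, rgb, nrow(bl),
      paste0(bl$end - bl$start, collapse = ","),
      paste0(bl$start - chrom_start, collapse = ","),
      sep = "\t"
    )
  }, character(1))
}

#' @rdname to_bed12
#' @param path Output path.
#' @return `write_bed()` returns `path` invisibly.
#' @export
write_bed <- function(loci, path, name_col = NULL, rgb = "0") {
  writeLines(to_bed12(loci, name_col = name_col, rgb = rgb), path)
  invisible(path)
}
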