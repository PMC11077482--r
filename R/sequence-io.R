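#' Read a nucleotide FASTA file into a tibble
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file. Sequences are
#' upper-cased and restricted to the alphabet `A`, `C`, `G`, `T`, `N`;
#' any other residue is a parse error. Record names are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`, one row per record,
#'   in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "ACGT", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) {
    abort(paste0("no FASTA records in '", path, "'"))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) {
    abort("FASTA record with empty header name")
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("empty FASTA record: ", names(seqs)[!nzchar(seqs)][1]))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(
      "sequence '", names(seqs)[bad][1],
      "' contains residues outside the A/C/G/T/N alphabet"
    ))
  }
  tibble(name = unname(names(seqs)), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `name` and `sequence` (nucleotide or
#'   protein), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) {
    seqs <- tibble(name = names(seqs), sequence = unname(seqs))
  }
  stopifnot(all(c("name", "sequence") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of sequences over `A`/`C`/`G`/`T`/`N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide sequence to protein
#'
#' Translates with the standard genetic code. Codons containing `N` become
#' `X`, stop codons are rendered as `*`, and a trailing partial codon is
#' dropped. The first codon is not given initiator treatment (`ATG` still
#' translates to `M`, but alternative initiators are translated literally).
#'
#' @param nt Character vector of nucleotide sequences over `A`/`C`/`G`/`T`/`N`.
#' @param frame Reading-frame offset, 0--2: the number of leading bases
#'   skipped before the first codon.
#' @return Character vector of amino-acid sequences.
#' @export
#' @examples
#' translate_dna("ATGAAATGA")           # "MK*"
#' translate_dna("ATGAAATGA", frame = 1) # "*N"
translate_dna <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  code <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    s <- substr(s, frame + 1L, nchar(s))
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return("")
    starts <- seq.int(1L, n, by = 3L)
    aa <- unname(code[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"          # codons containing N (or other ambiguity)
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `exon` features. Exon `Parent` attributes are
#' resolved to genes (directly or through one `mRNA` level). Genes without
#' exon children receive a single exon spanning the whole gene. GFF3
#' 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention at this boundary.
#'
#' @param path Path to a GFF3 file.
#' @param version_label Label recorded in the `source_version` column,
#'   identifying the annotation version (e.g. `"old"`, `"new"`).
#' @return An annotation tibble with one row per exon and columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open) and
#'   `source_version`, sorted by gene then exon start.
#' @export
read_gff3 <- function(path, version_label = "annotation") {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file not found: ", path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("failed to parse GFF3 '", path, "': ", conditionMessage(e)))
  )
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x) == 0) NA_character_ else as.character(x[[1]]),
           character(1))
  }
  df$parent1 <- if ("Parent" %in% names(df)) first_parent(df$Parent) else NA_character_

  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) {
    abort(paste0("no gene features in '", path, "'"))
  }
  if (anyNA(genes$ID) || anyDuplicated(genes$ID) > 0) {
    abort("gene features must carry unique ID attributes")
  }
  mrna <- df[df$type == "mRNA", ]
  mrna_to_gene <- stats::setNames(mrna$parent1, mrna$ID)
  exons <- df[df$type == "exon", ]
  if (nrow(exons) > 0) {
    gene_of <- ifelse(exons$parent1 %in% genes$ID,
                      exons$parent1,
                      unname(mrna_to_gene[exons$parent1]))
    if (anyNA(gene_of)) {
      bad <- exons$parent1[is.na(gene_of)][1]
      abort(paste0("exon Parent '", bad, "' does not resolve to a gene"))
    }
    exons$gene_id <- gene_of
  }

  gene_tbl <- tibble(
    gene_id = genes$ID, chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    g_start = genes$start - 1L, g_end = genes$end
  )
  if (any(!gene_tbl$strand %in% c("+", "-"))) {
    abort("gene features must be stranded (+/-)")
  }

  out <- purrr::map_dfr(seq_len(nrow(gene_tbl)), function(i) {
    g <- gene_tbl[i, ]
    ex <- if (nrow(exons) > 0) exons[exons$gene_id == g$gene_id, ] else exons
    if (nrow(ex) == 0) {
      tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = g$g_start, end = g$g_end)
    } else {
      if (any(as.character(ex$seqnames) != g$chrom)) {
        abort(paste0("exons of gene '", g$gene_id, "' on a different chromosome"))
      }
      tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = ex$start - 1L, end = ex$end) %>%
        distinct() %>%
        arrange(.data$start)
    }
  })
  out$source_version <- version_label
  validate_annotation(out)
  out
}

#' Validate an annotation tibble
#'
#' Checks the gene-model invariants: positive-width exons, at least one
#' exon per gene, exons sorted and pairwise non-overlapping within a gene,
#' one chromosome and strand per gene.
#'
#' @param annotation An annotation tibble as returned by [read_gff3()].
#' @return The annotation, invisibly; errors on violation.
#' @export
validate_annotation <- function(annotation) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(annotation))) {
    abort(paste0("annotation must have columns ", paste(req, collapse = ", ")))
  }
  if (any(annotation$end <= annotation$start)) {
    bad <- annotation$gene_id[annotation$end <= annotation$start][1]
    abort(paste0("gene '", bad, "' has an exon with end <= start"))
  }
  split_idx <- split(seq_len(nrow(annotation)), annotation$gene_id)
  for (idx in split_idx) {
    s <- sort(annotation$start[idx])
    e <- annotation$end[idx][order(annotation$start[idx])]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)])) {
      abort(paste0("gene '", annotation$gene_id[idx[1]], "' has overlapping exons"))
    }
    if (length(unique(annotation$chrom[idx])) > 1 ||
        length(unique(annotation$strand[idx])) > 1) {
      abort(paste0("gene '", annotation$gene_id[idx[1]],
                   "' mixes chromosomes or strands"))
    }
  }
  invisible(annotation)
}

#' Write an annotation tibble to GFF3
#'
#' Emits one `gene` feature per gene (spanning its exons) and one `exon`
#' feature per exon with a `Parent` attribute, converting back to GFF3
#' 1-based inclusive coordinates. [read_gff3()] on the output reproduces
#' the input coordinates exactly.
#'
#' @param annotation An annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  validate_annotation(annotation)
  spans <- gene_spans(annotation)
  fmt <- function(chrom, src, type, start0, end0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start0 + 1L, end0, strand, attrs)
  }
  lines <- character(0)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    ex <- annotation[annotation$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    lines <- c(
      lines,
      fmt(g$chrom, "proteorefine", "gene", g$start, g$end, g$strand,
          paste0("ID=", g$gene_id)),
      fmt(ex$chrom, "proteorefine", "exon", ex$start, ex$end, ex$strand,
          paste0("ID=", g$gene_id, ".exon", seq_len(nrow(ex)),
                 ";Parent=", g$gene_id))
    )
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Gene spans of an annotation
#'
#' The span of a gene is the interval from its minimum exon start to its
#' maximum exon end; this is the "range of an annotated gene" used for
#' overlap classification.
#'
#' @param annotation An annotation tibble.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
gene_spans <- function(annotation) {
  annotation %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    )
}

#' Read an observed-peptide list
#'
#' Accepts either a headerless one-peptide-per-line text file or a TSV
#' whose header contains a `peptide` (or `sequence`) column; any other
#' columns (e.g. intensities) are ignored.
#'
#' @param path Path to the peptide list.
#' @return A tibble with a single `peptide` column of unique upper-case
#'   peptide sequences, in first-seen order.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) abort(paste0("peptide file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(tibble(peptide = character()))
  if (grepl("\t", first) ||
      grepl("^(peptide|sequence)$", trimws(first), ignore.case = TRUE)) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    col <- intersect(c("peptide", "sequence"), tolower(names(tbl)))
    if (length(col) == 0) {
      abort("peptide TSV must contain a 'peptide' or 'sequence' column")
    }
    names(tbl) <- tolower(names(tbl))
    peps <- tbl[[col[1]]]
  } else {
    peps <- readLines(path)
    peps <- peps[nzchar(peps)]
  }
  tibble(peptide = unique(toupper(peps)))
}
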