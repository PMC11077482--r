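#' Build a transcript-to-genome coordinate map
#'
#' A coordinate map pairs query (transcript) intervals with genomic
#' intervals of equal length. Query intervals must partition
#' `[0, transcript length)` contiguously; genomic intervals must be
#' disjoint. On the `-` strand the genomic order of the blocks is the
#' reverse of the query order, and within each block query position `q`
#' maps to genomic position `tend - 1 - (q - qstart)`. All coordinates are
#' 0-based half-open.
#'
#' @param blocks A data frame with columns `qstart`, `qend`, `tstart`,
#'   `tend` (one row per block, in query order).
#' @param strand `"+"` or `"-"`.
#' @param chrom Optional chromosome name attached as an attribute.
#' @return A `pg_coord_map` tibble.
#' @export
coord_map <- function(blocks, strand = "+", chrom = NA_character_) {
  blocks <- as_tibble(blocks)[, c("qstart", "qend", "tstart", "tend")]
  map <- structure(blocks, strand = strand, chrom = chrom,
                   class = c("pg_coord_map", class(blocks)))
  validate_coord_map(map)
  map
}

#' @rdname coord_map
#' @param map A `pg_coord_map`.
#' @export
validate_coord_map <- function(map) {
  strand <- attr(map, "strand")
  if (!strand %in% c("+", "-")) abort("coord map strand must be '+' or '-'")
  if (nrow(map) == 0) abort("coord map must have at least one block")
  qlen <- map$qend - map$qstart
  tlen <- map$tend - map$tstart
  if (any(qlen <= 0) || any(tlen <= 0)) abort("coord map blocks must have positive width")
  if (any(qlen != tlen)) abort("paired intervals must have equal lengths")
  if (map$qstart[1] != 0) abort("query intervals must start at 0")
  if (nrow(map) > 1) {
    if (any(map$qstart[-1] != map$qend[-nrow(map)])) {
      abort("query intervals must partition the transcript contiguously")
    }
    tb <- if (strand == "+") map else map[rev(seq_len(nrow(map))), ]
    if (any(tb$tstart[-1] < tb$tend[-nrow(tb)])) {
      abort("genomic intervals must be disjoint and ordered consistently with strand")
    }
  }
  invisible(map)
}

#' Map a transcript interval to genomic intervals
#'
#' Projects a query (transcript) interval through a coordinate map to the
#' minimal list of genomic intervals covering it base for base. The result
#' is returned in ascending genomic order regardless of strand; the map's
#' strand is recorded in the `strand` column as the orientation flag.
#'
#' @param map A `pg_coord_map` (see [coord_map()]).
#' @param qstart,qend Query interval, 0-based half-open, within
#'   `[0, transcript length)`.
#' @return A tibble of genomic intervals with columns `start`, `end`,
#'   `strand`, sorted by `start`; adjacent abutting intervals are merged.
#' @export
#' @examples
#' m <- coord_map(data.frame(qstart = c(0, 30), qend = c(30, 90),
#'                           tstart = c(100, 200), tend = c(130, 260)))
#' map_to_genome(m, 25, 40)
map_to_genome <- function(map, qstart, qend) {
  validate_coord_map(map)
  qlen_total <- map$qend[nrow(map)]
  if (qstart < 0 || qend > qlen_total || qend <= qstart) {
    abort(paste0("query interval [", qstart, ",", qend,
                 ") escapes the map's query range [0,", qlen_total, ")"))
  }
  strand <- attr(map, "strand")
  pieces <- project_interval_blocks(map, strand, qstart, qend)
  stopifnot(sum(pieces$end - pieces$start) == qend - qstart)
  pieces$strand <- strand
  pieces
}

# Tolerant projection shared with alignment-based peptide projection:
# blocks need not cover the whole interval (clipping is the caller's
# concern); returns merged ascending genomic intervals.
project_interval_blocks <- function(blocks, strand, qstart, qend) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    a <- max(qstart, blocks$qstart[i])
    b <- min(qend, blocks$qend[i])
    if (b <= a) next
    if (strand == "+") {
      gs <- blocks$tstart[i] + (a - blocks$qstart[i])
      ge <- blocks$tstart[i] + (b - blocks$qstart[i])
    } else {
      gs <- blocks$tend[i] - (b - blocks$qstart[i])
      ge <- blocks$tend[i] - (a - blocks$qstart[i])
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge abutting pieces into a minimal interval list
  starts <- m[1, 1]; ends <- m[1, 2]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] == ends[length(ends)]) {
        ends[length(ends)] <- m[i, 2]
      } else {
        starts <- c(starts, m[i, 1]); ends <- c(ends, m[i, 2])
      }
    }
  }
  tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Spliced transcript sequences of annotated genes
#'
#' Concatenates each gene's exon substrings in genomic order and
#' reverse-complements the result for `-`-strand genes, yielding the
#' 5'-to-3' transcript sequence.
#'
#' @param annotation An annotation tibble (see [read_gff3()]).
#' @param genome A genome tibble (see [read_fasta()]).
#' @return A tibble with columns `gene_id` and `sequence`.
#' @export
spliced_sequences <- function(annotation, genome) {
  validate_annotation(annotation)
  seqs <- stats::setNames(genome$sequence, genome$name)
  spans <- gene_spans(annotation)
  missing_chrom <- setdiff(unique(spans$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome '", missing_chrom[1], "' not in genome"))
  }
  res <- purrr::map_chr(spans$gene_id, function(gid) {
    ex <- annotation[annotation$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    chrom_seq <- seqs[[ex$chrom[1]]]
    if (any(ex$end > nchar(chrom_seq)) || any(ex$start < 0)) {
      abort(paste0("gene '", gid, "' has an exon outside '", ex$chrom[1], "'"))
    }
    s <- paste0(substring(chrom_seq, ex$start + 1L, ex$end), collapse = "")
    if (ex$strand[1] == "-") revcomp(s) else s
  })
  tibble(gene_id = spans$gene_id, sequence = res)
}

#' Coordinate map of an annotated gene
#'
#' Builds the transcript-to-genome [coord_map()] implied by a gene's exon
#' structure: transcript coordinates run 5' to 3' of the transcript.
#'
#' @param annotation An annotation tibble.
#' @param gene_id Gene to map.
#' @return A `pg_coord_map`.
#' @export
gene_coord_map <- function(annotation, gene_id) {
  ex <- annotation[annotation$gene_id == gene_id, ]
  if (nrow(ex) == 0) abort(paste0("gene '", gene_id, "' not in annotation"))
  ex <- ex[order(ex$start), ]
  w <- ex$end - ex$start
  if (ex$strand[1] == "-") {
    ex <- ex[rev(seq_len(nrow(ex))), ]
    w <- rev(w)
  }
  qend <- cumsum(w)
  coord_map(
    tibble(qstart = qend - w, qend = qend, tstart = ex$start, tend = ex$end),
    strand = ex$strand[1], chrom = ex$chrom[1]
  )
}
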