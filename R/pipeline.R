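#' Configure an end-to-end pipeline run from files on disk
#'
#' Collects the input paths and stage options for [run_pipeline()]. All
#' referenced inputs must exist; annotation versions are named (the
#' names become the `source_version` labels and the per-version output
#' names).
#'
#' @param genome Path to the genome FASTA.
#' @param annotations Named character vector of GFF3 paths, one per
#'   annotation version (e.g. `c(old = ..., new = ...)`).
#' @param contigs Path to the contig FASTA.
#' @param peptides Path to the observed-peptide list (see
#'   [read_peptides()]).
#' @param hits Optional named character vector of 12-column tabular
#'   homology hit files; names label the subject databases.
#' @param digestion A [digestion_config()].
#' @param align A [align_params()].
#' @param orf ORF options: `min_aa`, `mode`, `allow_partial` (see
#'   [build_protein_db()]).
#' @param overlap,strand_mode Classification options (see
#'   [classify_contigs()]).
#' @param transcript_db Label of the transcript-derived database.
#' @param out_dir If non-`NULL`, stage artifacts (TSV/BED/FASTA/JSON)
#'   are written here.
#' @return A `pg_pipeline_config` list.
#' @export
pipeline_config <- function(genome, annotations, contigs, peptides,
                            hits = NULL,
                            digestion = digestion_config(),
                            align = align_params(),
                            orf = list(min_aa = 100L, mode = "all",
                                       allow_partial = TRUE),
                            overlap = "span", strand_mode = "either",
                            transcript_db = "transcript",
                            out_dir = NULL) {
  paths <- c(genome, annotations, contigs, peptides, hits)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file not found: ", missing[1]))
  }
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))) ||
      anyDuplicated(names(annotations)) > 0) {
    abort("annotation versions must have unique names")
  }
  structure(
    list(genome = genome, annotations = annotations, contigs = contigs,
         peptides = peptides, hits = hits, digestion = digestion,
         align = align, orf = orf, overlap = overlap,
         strand_mode = strand_mode, transcript_db = transcript_db,
         out_dir = out_dir),
    class = "pg_pipeline_config"
  )
}

#' Run the proteogenomic validation pipeline
#'
#' Executes the full workflow: ORF prediction over the contigs, in-silico
#' digestion and peptide indexing of the transcript-derived and
#' annotation-derived protein databases, observed-peptide membership and
#' Venn analysis, spliced alignment of the contigs to the genome with
#' retention filtering, per-annotation-version classification of
#' novel-peptide-supported contigs, peptide-to-genome projection, SAV
#' screening of the retained alignments, and (when hit tables are
#' supplied) homology flagging.
#'
#' Novelty is assessed per annotation version: for version `v`, the
#' novel peptides are those present in the transcript database and
#' absent from `v`'s database, and only contigs carrying such peptides
#' enter `v`'s classification. The strictly-exclusive set (peptides in
#' the transcript database and no other) is also reported.
#'
#' @param x A `pg_pipeline_config` (inputs on disk) or a `pg_bundle`
#'   from [simulate_study()] (inputs in memory).
#' @param ... For a bundle: optional overrides among `digestion`,
#'   `align`, `orf`, `overlap`, `strand_mode`, `hits` (a named list of
#'   hit tibbles), and `out_dir`.
#' @param quiet Suppress the per-stage progress messages (written to
#'   standard error).
#' @return A `pg_run` object; see [glance.pg_run()], [tidy.pg_run()],
#'   [autoplot.pg_run()]. Components include `databases` (per-database
#'   peptide/protein counts), `venn`, `membership`, `alignments`,
#'   `classification` and `loci` (named by annotation version),
#'   `category_counts`, `sav` (strict and permissive calls with
#'   amino-acid effects), and `files` (artifact inventory).
#' @export
run_pipeline <- function(x, ..., quiet = FALSE) {
  UseMethod("run_pipeline")
}

#' @export
run_pipeline.pg_pipeline_config <- function(x, ..., quiet = FALSE) {
  inputs <- list(
    genome = read_fasta(x$genome),
    annotations = purrr::imap(x$annotations, function(p, v) read_gff3(p, v)),
    contigs = read_fasta(x$contigs),
    observed = read_peptides(x$peptides)
  )
  hits <- NULL
  if (!is.null(x$hits)) {
    qlen <- tibble(query_id = inputs$contigs$name,
                   length = nchar(inputs$contigs$sequence))
    hits <- purrr::imap(x$hits, function(p, db) {
      parse_tabular_hits(p, db, qlen)
    })
  }
  run_pipeline_impl(inputs, x, hits, quiet = quiet)
}

#' @export
run_pipeline.pg_bundle <- function(x, ..., quiet = FALSE) {
  dots <- list(...)
  cfg <- pipeline_defaults(dots)
  inputs <- list(genome = x$genome, annotations = x$annotations,
                 contigs = x$contigs, observed = x$observed)
  run_pipeline_impl(inputs, cfg, dots$hits, quiet = quiet)
}

pipeline_defaults <- function(dots = list()) {
  cfg <- list(
    digestion = dots$digestion %||% digestion_config(),
    align = dots$align %||% align_params(),
    orf = dots$orf %||% list(min_aa = 100L, mode = "all", allow_partial = TRUE),
    overlap = dots$overlap %||% "span",
    strand_mode = dots$strand_mode %||% "either",
    transcript_db = dots$transcript_db %||% "transcript",
    out_dir = dots$out_dir
  )
  class(cfg) <- "pg_pipeline_config"
  cfg
}

stage_msg <- function(quiet, ...) {
  if (!quiet) message("[proteorefine] ", ...)
}

run_pipeline_impl <- function(inputs, cfg, hits = NULL, quiet = FALSE) {
  versions <- names(inputs$annotations)
  tdb <- cfg$transcript_db
  if (tdb %in% versions) {
    abort("transcript_db label clashes with an annotation version name")
  }

  # 1. ORF prediction
  orfs <- build_protein_db(inputs$contigs, min_aa = cfg$orf$min_aa,
                           mode = cfg$orf$mode,
                           allow_partial = cfg$orf$allow_partial)
  stage_msg(quiet, "orf: ", nrow(orfs), " ORFs from ",
            nrow(inputs$contigs), " contigs")

  # 2. protein databases and peptide indexes
  ann_proteins <- purrr::map(inputs$annotations, function(ann) {
    sp <- spliced_sequences(ann, inputs$genome)
    tibble(id = sp$gene_id,
           protein = sub("\\*$", "", translate_dna(sp$sequence)))
  })
  indexes <- c(
    purrr::map(ann_proteins, build_peptide_index, cfg = cfg$digestion),
    stats::setNames(
      list(build_peptide_index(
        tibble(id = orfs$orf_id, protein = orfs$protein), cfg$digestion
      )),
      tdb
    )
  )
  stage_msg(quiet, "digest: indexes over ",
            paste(names(indexes), collapse = ", "))

  # 3. membership, Venn, novelty
  membership <- assign_membership(inputs$observed, indexes)
  venn <- venn_counts(membership)
  stopifnot(sum(venn$count) == nrow(membership))
  exclusive <- novel_peptides(membership, tdb)
  stage_msg(quiet, "match: ", nrow(membership), " observed peptides, ",
            sum(membership$unmatched), " unmatched, ",
            nrow(exclusive), " exclusive to ", tdb)

  databases <- purrr::map_dfr(names(indexes), function(db) {
    rows <- membership[membership[[db]], , drop = FALSE]
    parents <- unlist(purrr::map(rows$parents, function(p) p[[db]]))
    tibble(database = db, n_peptides = nrow(rows),
           n_proteins = length(unique(parents)))
  })

  # 4. spliced alignment + retention filter
  alignments <- align_contigs(inputs$contigs, inputs$genome, cfg$align)
  filtered <- filter_alignments(alignments, cfg$align)
  kept <- filtered[filtered$kept, , drop = FALSE]
  stage_msg(quiet, "align: ", nrow(alignments), " loci, ", nrow(kept),
            " kept from ", length(unique(kept$contig_id)), " contigs")

  # 5. per-version classification and projection
  classification <- list()
  loci <- list()
  for (v in versions) {
    v_novel <- membership[membership[[tdb]] & !membership[[v]], , drop = FALSE]
    cl <- classify_contigs(v_novel, orfs, kept, inputs$annotations[[v]],
                           overlap = cfg$overlap,
                           strand_mode = cfg$strand_mode,
                           transcript_db = tdb)
    lc <- project_peptides(v_novel, orfs, kept, genome = inputs$genome,
                           transcript_db = tdb)
    if (!is.null(hits)) {
      kept_hits <- bind_rows(purrr::map(hits, filter_hits))
      cl <- homology_flag(cl, kept_hits)
    }
    classification[[v]] <- cl
    loci[[v]] <- lc
    stage_msg(quiet, "classify[", v, "]: ", nrow(cl),
              " novel-supported contigs (",
              paste(names(table(cl$category)), table(cl$category),
                    sep = "=", collapse = ", "), ")")
  }

  category_counts <- purrr::imap_dfr(classification, function(cl, v) {
    lv <- c("refined_gene_structure", "putative_novel_gene", "unaligned")
    tibble(version = v, category = lv,
           count = as.integer(table(factor(cl$category, levels = lv))))
  })
  for (v in versions) {
    stopifnot(sum(category_counts$count[category_counts$version == v]) ==
                nrow(classification[[v]]))
  }

  # 6. SAV screening on retained alignments
  ah <- alignment_hits(kept)
  sav_strict <- sav_candidates(ah, permissive = FALSE)
  sav_perm <- sav_candidates(ah, permissive = TRUE)
  sav_strict <- sav_effects(sav_strict, inputs$contigs, inputs$genome,
                            kept, orfs)
  stage_msg(quiet, "sav: ", nrow(sav_strict), " strict, ",
            nrow(sav_perm), " permissive calls")

  files <- character()
  if (!is.null(cfg$out_dir)) {
    files <- write_run_artifacts(cfg$out_dir, orfs, membership, venn,
                                 filtered, classification, loci,
                                 sav_strict, sav_perm, databases,
                                 category_counts)
  }

  structure(
    list(
      databases = databases, venn = venn, membership = membership,
      exclusive_novel = exclusive, orfs = orfs,
      alignments = filtered, classification = classification,
      loci = loci, category_counts = category_counts,
      sav = list(strict = sav_strict, permissive = sav_perm),
      transcript_db = tdb, versions = versions, files = files
    ),
    class = "pg_run"
  )
}

write_run_artifacts <- function(dir, orfs, membership, venn, filtered,
                                classification, loci, sav_strict,
                                sav_perm, databases, category_counts) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(name) {
    p <- file.path(dir, name)
    paths[length(paths) + 1L] <<- p
    p
  }
  write_protein_fasta(orfs, put("orf_proteins.fasta"))
  mem_flat <- membership
  mem_flat$parents <- NULL
  readr::write_tsv(mem_flat, put("peptide_membership.tsv"), progress = FALSE)
  readr::write_tsv(venn, put("venn_counts.tsv"), progress = FALSE)
  aln_flat <- filtered
  aln_flat$blocks <- NULL
  readr::write_tsv(aln_flat, put("alignments.tsv"), progress = FALSE)
  for (v in names(classification)) {
    cl <- classification[[v]]
    flat <- tibble(
      contig_id = cl$contig_id, category = cl$category,
      n_alignments = cl$n_alignments,
      genes = purrr::map_chr(cl$overlapping_genes, paste, collapse = ","),
      n_peptides = cl$n_peptides,
      homology_supported = cl$homology_supported
    )
    readr::write_tsv(flat, put(paste0("classification_", v, ".tsv")),
                     progress = FALSE)
    lc <- loci[[v]]
    ok <- lc[!lc$clipped, , drop = FALSE]
    if (nrow(ok) > 0) {
      writeLines(to_bed12(ok), put(paste0("peptide_loci_", v, ".bed")))
    }
  }
  readr::write_tsv(sav_strict, put("sav_calls_strict.tsv"), progress = FALSE)
  readr::write_tsv(sav_perm, put("sav_calls_permissive.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(databases = databases, venn = venn,
         category_counts = category_counts),
    put("run_summary.json"), dataframe = "rows", pretty = TRUE, digits = NA
  )
  paths
}

#' Recompute summary tables from a completed run directory
#'
#' Reads the artifacts written by [run_pipeline()] (with `out_dir` set)
#' and rebuilds the headline tables, so a finished run can be summarised
#' without re-executing the stages.
#'
#' @param dir The run's output directory.
#' @return A list with `databases`, `venn`, and `category_counts`
#'   tibbles matching the corresponding `pg_run` components.
#' @export
summarize_run <- function(dir) {
  need <- file.path(dir, c("venn_counts.tsv", "run_summary.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("missing run artifact: ", missing[1],
                 " (run the pipeline with out_dir set)"))
  }
  venn <- readr::read_tsv(file.path(dir, "venn_counts.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  cls_files <- list.files(dir, pattern = "^classification_.*\\.tsv$",
                          full.names = TRUE)
  lv <- c("refined_gene_structure", "putative_novel_gene", "unaligned")
  category_counts <- purrr::map_dfr(cls_files, function(p) {
    v <- sub("^classification_(.*)\\.tsv$", "\\1", basename(p))
    cl <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    tibble(version = v, category = lv,
           count = as.integer(table(factor(cl$category, levels = lv))))
  })
  js <- jsonlite::read_json(file.path(dir, "run_summary.json"),
                            simplifyVector = TRUE)
  list(databases = as_tibble(js$databases), venn = as_tibble(venn),
       category_counts = category_counts)
}

#' @export
print.pg_run <- function(x, ...) {
  cat("<pg_run> proteogenomic validation run\n")
  cat("  observed peptides:", nrow(x$membership),
      "| unmatched:", sum(x$membership$unmatched),
      "| exclusive to", paste0(x$transcript_db, ":"),
      nrow(x$exclusive_novel), "\n")
  cat("  databases:\n")
  for (i in seq_len(nrow(x$databases))) {
    cat(sprintf("    %-12s %5d peptides  %5d proteins\n",
                x$databases$database[i], x$databases$n_peptides[i],
                x$databases$n_proteins[i]))
  }
  kept <- sum(x$alignments$kept)
  cat("  alignments:", nrow(x$alignments), "loci,", kept, "retained\n")
  for (v in x$versions) {
    cc <- x$category_counts[x$category_counts$version == v, ]
    cat(sprintf("  vs %-6s refined=%d novel=%d unaligned=%d\n", v,
                cc$count[cc$category == "refined_gene_structure"],
                cc$count[cc$category == "putative_novel_gene"],
                cc$count[cc$category == "unaligned"]))
  }
  cat("  SAV calls:", nrow(x$sav$strict), "strict /",
      nrow(x$sav$permissive), "permissive\n")
  invisible(x)
}

#' Tidy the per-version classification counts of a run
#'
#' @param x A `pg_run`.
#' @param ... Unused.
#' @return A tibble with columns `version`, `category`, `count`.
#' @method tidy pg_run
#' @export
tidy.pg_run <- function(x, ...) {
  x$category_counts
}

#' One-row summary of a pipeline run
#'
#' @param x A `pg_run`.
#' @param ... Unused.
#' @return A one-row tibble: observed/unmatched/exclusive peptide
#'   counts, alignment and retention counts, SAV call counts.
#' @method glance pg_run
#' @export
glance.pg_run <- function(x, ...) {
  tibble(
    n_observed = nrow(x$membership),
    n_unmatched = sum(x$membership$unmatched),
    n_exclusive_novel = nrow(x$exclusive_novel),
    n_alignments = nrow(x$alignments),
    n_alignments_kept = sum(x$alignments$kept),
    n_contigs_aligned = length(unique(x$alignments$contig_id[x$alignments$kept])),
    n_sav_strict = nrow(x$sav$strict),
    n_sav_permissive = nrow(x$sav$permissive)
  )
}
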