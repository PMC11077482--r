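STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sense_codons <- function() setdiff(all_codons(), STOP_CODONS)

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

random_cds <- function(n_codons) {
  paste0(c("ATG", sample(sense_codons(), n_codons - 2L, replace = TRUE),
           sample(STOP_CODONS, 1L)), collapse = "")
}

#' Configure the synthetic proteogenomics study
#'
#' The generator plants a toy study with the statistical structure the
#' pipeline assumes: a random genome carrying multi-exon protein-coding
#' genes on both strands; two annotation versions (the "old" one missing
#' the hidden genes, and both truncating the refined genes' terminal
#' exons); a contig set of exact transcripts, structure-extending
#' transcripts, single-SNV transcripts and genome-absent noise; and an
#' observed-peptide list sampled from the contigs' tryptic digests with
#' optional contaminant noise. Defaults are sized to exercise every
#' branch of the classification flow in seconds: genes carry CDSs of at
#' least `min_cds_len` bp so that exact transcripts clear the default
#' score-over-2000 retention threshold the way real high-identity
#' contigs do.
#'
#' @param seed Integer seed; identical configs reproduce the bundle
#'   byte-identically.
#' @param genome_length Genome size in bp (one chromosome).
#' @param gc_content GC fraction of the intergenic background.
#' @param n_genes Total planted genes (includes the hidden ones).
#' @param exons_per_gene Inclusive range of exon counts.
#' @param exon_len,intron_len Inclusive bp ranges for exon and intron
#'   lengths.
#' @param min_cds_len Minimum total CDS length per gene, bp.
#' @param n_hidden_genes Genes present in the genome and the "new"
#'   annotation but absent from the "old" one.
#' @param n_refined Genes whose terminal exon is truncated in both
#'   annotation versions while their contig carries the full CDS.
#' @param n_sav Contigs carrying exactly one planted nonsynonymous SNV.
#' @param n_noise Contigs sharing no 15-mer with the genome.
#' @param refined_extension Inclusive bp range of the terminal-exon
#'   truncation (rounded to a codon multiple).
#' @param peptides_per_contig Inclusive range of observed peptides
#'   sampled per contig.
#' @param contamination_rate Fraction of the observed-peptide list drawn
#'   as random decoy-like tryptic strings matching no database.
#' @param digestion The [digestion_config()] used for peptide sampling.
#' @param intergenic_gap Minimum bp between gene footprints.
#' @return A `pg_simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, genome_length = 200000L,
                              gc_content = 0.42, n_genes = 40L,
                              exons_per_gene = c(1L, 4L),
                              exon_len = c(90L, 450L),
                              intron_len = c(60L, 300L),
                              min_cds_len = 510L,
                              n_hidden_genes = 5L, n_refined = 5L,
                              n_sav = 5L, n_noise = 3L,
                              refined_extension = c(30L, 90L),
                              peptides_per_contig = c(2L, 5L),
                              contamination_rate = 0,
                              digestion = digestion_config(),
                              intergenic_gap = 300L) {
  stopifnot(
    n_genes >= 1, n_hidden_genes >= 0, n_refined >= 0, n_sav >= 0,
    n_noise >= 0, n_hidden_genes + n_refined + n_sav <= n_genes,
    contamination_rate >= 0, contamination_rate < 1,
    gc_content >= 0, gc_content <= 1, min_cds_len >= 60
  )
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         exon_len = as.integer(exon_len),
         intron_len = as.integer(intron_len),
         min_cds_len = as.integer(min_cds_len),
         n_hidden_genes = as.integer(n_hidden_genes),
         n_refined = as.integer(n_refined), n_sav = as.integer(n_sav),
         n_noise = as.integer(n_noise),
         refined_extension = as.integer(refined_extension),
         peptides_per_contig = as.integer(peptides_per_contig),
         contamination_rate = contamination_rate, digestion = digestion,
         intergenic_gap = as.integer(intergenic_gap)),
    class = "pg_simulation_config"
  )
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] >= rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
}

#' Generate a synthetic proteogenomics study bundle
#'
#' Builds the study described by a [simulation_config()]: genome,
#' two annotation versions, contigs, an observed-peptide list, and a
#' truth manifest recording each contig's origin class and expected
#' classification under each annotation version. The same config (seed
#' included) reproduces the bundle byte-identically.
#'
#' @param config A [simulation_config()].
#' @param dir If non-`NULL`, the bundle is also written to this
#'   directory via [write_bundle()].
#' @return A `pg_bundle` list with elements `config`, `genome`,
#'   `annotations` (named list `old`/`new` of annotation tibbles),
#'   `contigs`, `observed` (tibble with a `peptide` column), and
#'   `manifest` (list with `contigs` and `peptides` tibbles).
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL) {
  withr::local_seed(config$seed)
  cfg <- config
  digestion <- cfg$digestion

  roles <- rep("exact", cfg$n_genes)
  special <- sample.int(cfg$n_genes, cfg$n_hidden_genes + cfg$n_refined + cfg$n_sav)
  roles[special[seq_len(cfg$n_hidden_genes)]] <- "hidden"
  roles[special[cfg$n_hidden_genes + seq_len(cfg$n_refined)]] <- "refined"
  roles[special[cfg$n_hidden_genes + cfg$n_refined + seq_len(cfg$n_sav)]] <- "sav"

  # --- gene structures -----------------------------------------------------
  genes <- purrr::map(seq_len(cfg$n_genes), function(i) {
    n_ex <- sample_range(cfg$exons_per_gene)
    ex_len <- sample_range(cfg$exon_len, n_ex)
    total <- sum(ex_len)
    if (total < cfg$min_cds_len) {
      ex_len[which.max(ex_len)] <- ex_len[which.max(ex_len)] +
        (cfg$min_cds_len - total)
    }
    rem <- (3L - sum(ex_len) %% 3L) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] + rem
    trim <- 0L
    if (roles[i] == "refined") {
      trim <- 3L * (sample_range(cfg$refined_extension) %/% 3L)
      trim <- max(trim, 30L)
      # terminal transcript exon must survive truncation of stop + trim
      if (ex_len[n_ex] < trim + 3L + 30L) {
        ex_len[n_ex] <- ex_len[n_ex] + (trim + 3L + 30L - ex_len[n_ex]) %/% 3L * 3L + 3L
      }
    }
    in_len <- if (n_ex > 1) sample_range(cfg$intron_len, n_ex - 1L) else integer()
    strand <- sample(c("+", "-"), 1L)
    cds <- random_cds(sum(ex_len) %/% 3L)
    if (roles[i] == "refined") {
      # the truncated annotation must be missing at least one observable
      # peptide of the full protein, else the extension is undetectable
      for (tr in seq_len(50L)) {
        full <- sub("\\*$", "", translate_dna(cds))
        trunc <- sub("\\*$", "", translate_dna(substr(cds, 1L, nchar(cds) - trim - 3L)))
        gain <- setdiff(fold_il(digest(full, cfg$digestion), cfg$digestion),
                        fold_il(digest(trunc, cfg$digestion), cfg$digestion))
        if (length(gain) > 0) break
        cds <- random_cds(sum(ex_len) %/% 3L)
      }
    }
    list(gene_id = sprintf("gene%03d", i), role = roles[i], strand = strand,
         ex_len = ex_len, in_len = in_len, cds = cds, trim = trim,
         footprint = sum(ex_len) + sum(in_len))
  })

  # --- placement -----------------------------------------------------------
  order_idx <- sample.int(cfg$n_genes)
  footprints <- vapply(genes, `[[`, integer(1), "footprint")
  total_fp <- sum(footprints)
  n_gaps <- cfg$n_genes + 1L
  extra <- cfg$genome_length - total_fp - n_gaps * cfg$intergenic_gap
  if (extra < 0) {
    abort("gene footprints do not fit: increase genome_length")
  }
  w <- stats::runif(n_gaps)
  gaps <- cfg$intergenic_gap + floor(extra * w / sum(w))
  pos <- 0L
  starts <- integer(cfg$n_genes)
  for (j in seq_len(cfg$n_genes)) {
    pos <- pos + gaps[j]
    starts[order_idx[j]] <- as.integer(pos)
    pos <- pos + footprints[order_idx[j]]
  }

  # --- genome assembly -----------------------------------------------------
  bg <- strsplit(random_dna(cfg$genome_length, cfg$gc_content), "")[[1]]
  exon_tbl <- list()
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[[i]]
    n_ex <- length(g$ex_len)
    # ex_len is in transcript order; genomic (ascending) layout reverses it
    # on the minus strand
    lay_len <- if (g$strand == "-") rev(g$ex_len) else g$ex_len
    ex_start <- starts[i] + c(0L, cumsum(lay_len[-n_ex] + g$in_len))
    ex_end <- ex_start + lay_len
    # split the CDS into transcript-order chunks, then lay them on the genome
    chunk_end <- cumsum(g$ex_len)
    chunks <- substring(g$cds, chunk_end - g$ex_len + 1L, chunk_end)
    genomic_chunks <- if (g$strand == "+") chunks else rev(revcomp(chunks))
    for (e in seq_len(n_ex)) {
      bg[(ex_start[e] + 1L):ex_end[e]] <- strsplit(genomic_chunks[e], "")[[1]]
    }
    # keep splice junctions unambiguous: with no splice-site signal in the
    # random introns, a junction whose intron edge repeats the adjacent
    # exon edge base has two equal-scoring placements, so the generator
    # excludes that degenerate case (cf. the k-mer-disjoint noise contigs)
    bases <- c("A", "C", "G", "T")
    for (e in seq_len(max(n_ex - 1L, 0L))) {
      if (bg[ex_end[e] + 1L] == bg[ex_start[e + 1L] + 1L]) {
        bg[ex_end[e] + 1L] <- sample(setdiff(bases, bg[ex_start[e + 1L] + 1L]), 1L)
      }
      if (bg[ex_start[e + 1L]] == bg[ex_end[e]]) {
        bg[ex_start[e + 1L]] <- sample(setdiff(bases, bg[ex_end[e]]), 1L)
      }
    }
    genes[[i]]$ex_start <- ex_start
    genes[[i]]$ex_end <- ex_end
    exon_tbl[[i]] <- tibble(
      gene_id = g$gene_id, chrom = "chr1", strand = g$strand,
      start = ex_start, end = ex_end
    )
  }
  genome <- tibble(name = "chr1", sequence = paste0(bg, collapse = ""))

  # --- annotations (refined genes truncated in both versions) --------------
  annotate <- function(keep_roles, label) {
    rows <- purrr::map_dfr(seq_len(cfg$n_genes), function(i) {
      g <- genes[[i]]
      if (!g$role %in% keep_roles) return(NULL)
      ex <- exon_tbl[[i]]
      if (g$role == "refined") {
        cut <- g$trim + 3L
        n_ex <- nrow(ex)
        if (g$strand == "+") ex$end[n_ex] <- ex$end[n_ex] - cut
        else ex$start[1] <- ex$start[1] + cut
      }
      ex
    })
    rows$source_version <- label
    rows
  }
  ann_new <- annotate(c("exact", "refined", "sav", "hidden"), "new")
  ann_old <- annotate(c("exact", "refined", "sav"), "old")

  # digest keys of everything the annotation databases can yield
  ann_protein <- function(g) {
    cds <- if (g$role == "refined") substr(g$cds, 1L, nchar(g$cds) - g$trim - 3L) else g$cds
    sub("\\*$", "", translate_dna(cds))
  }
  db_keys <- unique(fold_il(
    unlist(purrr::map(genes, function(g) digest(ann_protein(g), digestion))),
    digestion
  ))

  # --- contigs -------------------------------------------------------------
  contig_plan <- list()
  add_contig <- function(class, seq, g = NULL, extra = list()) {
    contig_plan[[length(contig_plan) + 1L]] <<- c(
      list(class = class, sequence = seq,
           source_gene = if (is.null(g)) NA_character_ else g$gene_id,
           gene_strand = if (is.null(g)) NA_character_ else g$strand),
      extra
    )
  }
  genome_kmers <- NULL
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[[i]]
    full_protein <- sub("\\*$", "", translate_dna(g$cds))
    if (g$role %in% c("exact", "hidden")) {
      add_contig(g$role, g$cds, g, list(protein = full_protein))
    } else if (g$role == "refined") {
      novel <- setdiff(
        fold_il(digest(full_protein, digestion), digestion),
        fold_il(digest(ann_protein(g), digestion), digestion)
      )
      novel <- setdiff(novel, db_keys)
      if (length(novel) == 0) {
        abort(paste0("refined gene ", g$gene_id,
                     " yields no annotation-exclusive peptide; reseed or widen refined_extension"))
      }
      add_contig("refined", g$cds, g,
                 list(protein = full_protein, extension_bp = g$trim,
                      forced_keys = novel))
    } else if (g$role == "sav") {
      planted <- plant_snv(g$cds, digestion, db_keys)
      add_contig("sav", planted$seq, g, planted[names(planted) != "seq"])
    }
  }
  if (cfg$n_noise > 0) {
    gk <- genome_kmer_index(genome, k = 15L)$chroms[["chr1"]]$levels
    for (j in seq_len(cfg$n_noise)) {
      repeat {
        cds <- random_cds(sample(170:300, 1L))
        L <- nchar(cds)
        km <- c(substring(cds, 1:(L - 14L), 15:L),
                substring(revcomp(cds), 1:(L - 14L), 15:L))
        if (!any(km %in% gk)) break
      }
      add_contig("noise", cds, NULL,
                 list(protein = sub("\\*$", "", translate_dna(cds))))
    }
  }

  shuffle <- sample.int(length(contig_plan))
  contig_plan <- contig_plan[shuffle]
  for (j in seq_along(contig_plan)) {
    contig_plan[[j]]$contig_id <- sprintf("ctg%03d", j)
  }

  # --- observed peptides ---------------------------------------------------
  pep_rows <- list()
  for (cp in contig_plan) {
    peps <- digest(cp$protein, digestion)
    n_take <- min(sample_range(cfg$peptides_per_contig), length(peps))
    forced <- character()
    if (!is.null(cp$forced_keys)) {
      pool <- peps[fold_il(peps, digestion) %in% cp$forced_keys]
      forced <- pool[sample.int(length(pool), 1L)]
    }
    rest_pool <- setdiff(peps, forced)
    n_rest <- max(n_take - length(forced), 1L)
    rest <- rest_pool[sample.int(length(rest_pool), min(n_rest, length(rest_pool)))]
    pep_rows[[length(pep_rows) + 1L]] <-
      tibble(peptide = c(forced, rest), source = cp$contig_id)
  }
  peps <- bind_rows(pep_rows)
  peps <- peps[!duplicated(peps$peptide), , drop = FALSE]
  if (cfg$contamination_rate > 0) {
    n_cont <- round(cfg$contamination_rate * nrow(peps) /
                      (1 - cfg$contamination_rate))
    all_keys <- unique(c(db_keys, fold_il(peps$peptide, digestion)))
    cont <- character(n_cont)
    for (j in seq_len(n_cont)) {
      repeat {
        p <- paste0(c(sample(setdiff(AA20, c("K", "R")),
                             sample(6:19, 1L), replace = TRUE),
                      sample(c("K", "R"), 1L)), collapse = "")
        if (!fold_il(p, digestion) %in% all_keys && !p %in% cont) break
      }
      cont[j] <- p
    }
    peps <- bind_rows(peps, tibble(peptide = cont, source = "contaminant"))
  }
  peps <- peps[sample.int(nrow(peps)), , drop = FALSE]

  # --- manifest ------------------------------------------------------------
  expected <- function(class, version) {
    switch(class,
      exact = "annotated",
      hidden = if (version == "old") "putative_novel_gene" else "annotated",
      refined = "refined_gene_structure",
      sav = "refined_gene_structure",
      noise = "unaligned"
    )
  }
  manifest_contigs <- purrr::map_dfr(contig_plan, function(cp) {
    tibble(
      contig_id = cp$contig_id, class = cp$class,
      source_gene = cp$source_gene,
      gene_strand = cp$gene_strand,
      length = nchar(cp$sequence),
      protein = cp$protein,
      extension_bp = cp$extension_bp %||% NA_integer_,
      snv_cds_pos = cp$snv_cds_pos %||% NA_integer_,
      snv_ref_base = cp$snv_ref_base %||% NA_character_,
      snv_alt_base = cp$snv_alt_base %||% NA_character_,
      snv_aa_pos = cp$snv_aa_pos %||% NA_integer_,
      snv_ref_aa = cp$snv_ref_aa %||% NA_character_,
      snv_alt_aa = cp$snv_alt_aa %||% NA_character_,
      expected_old = expected(cp$class, "old"),
      expected_new = expected(cp$class, "new")
    )
  }) %>% arrange(.data$contig_id)

  contigs <- tibble(
    name = vapply(contig_plan, `[[`, character(1), "contig_id"),
    sequence = vapply(contig_plan, `[[`, character(1), "sequence")
  ) %>% arrange(.data$name)

  bundle <- structure(
    list(
      config = cfg, genome = genome,
      annotations = list(old = ann_old, new = ann_new),
      contigs = contigs,
      observed = tibble(peptide = peps$peptide),
      manifest = list(contigs = manifest_contigs,
                      peptides = as_tibble(peps))
    ),
    class = "pg_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

# plant one nonsynonymous SNV (sense -> sense, residue change robust to I/L
# folding) whose variant peptide is observable and database-exclusive
plant_snv <- function(cds, digestion, db_keys, max_tries = 500L) {
  n_codon <- nchar(cds) %/% 3L
  for (try in seq_len(max_tries)) {
    ci <- sample(2:(n_codon - 1L), 1L)
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    within <- sample(1:3, 1L)
    ref <- substr(codon, within, within)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    new_codon <- codon
    substr(new_codon, within, within) <- alt
    if (new_codon %in% STOP_CODONS) next
    ref_aa <- translate_dna(codon)
    alt_aa <- translate_dna(new_codon)
    if (chartr("I", "L", ref_aa) == chartr("I", "L", alt_aa)) next
    seq <- cds
    pos <- 3L * (ci - 1L) + within - 1L          # 0-based CDS position
    substr(seq, pos + 1L, pos + 1L) <- alt
    protein <- sub("\\*$", "", translate_dna(seq))
    peps <- digest(protein, digestion)
    # peptides covering the variant residue, absent from annotation DBs
    starts <- purrr::map_int(peps, function(p) {
      as.integer(regexpr(p, protein, fixed = TRUE)) - 1L
    })
    covers <- starts <= (ci - 1L) & (starts + nchar(peps)) > (ci - 1L)
    pool_keys <- setdiff(fold_il(peps[covers], digestion), db_keys)
    if (length(pool_keys) == 0) next
    return(list(
      seq = seq, protein = protein, forced_keys = pool_keys,
      snv_cds_pos = pos, snv_ref_base = ref, snv_alt_base = alt,
      snv_aa_pos = ci, snv_ref_aa = ref_aa, snv_alt_aa = alt_aa
    ))
  }
  abort("could not plant a nonsynonymous SNV; reseed")
}

#' Write a simulation bundle to disk
#'
#' Writes `genome.fasta`, `annotation_old.gff3`, `annotation_new.gff3`,
#' `contigs.fasta`, `peptides.tsv` (a `peptide` column only -- sources
#' stay in the manifest), `truth_manifest.json` and `sim_config.json`.
#'
#' @param bundle A `pg_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$genome, file.path(dir, "genome.fasta"))
  write_gff3(bundle$annotations$old, file.path(dir, "annotation_old.gff3"))
  write_gff3(bundle$annotations$new, file.path(dir, "annotation_new.gff3"))
  write_fasta(bundle$contigs, file.path(dir, "contigs.fasta"))
  readr::write_tsv(bundle$observed, file.path(dir, "peptides.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(contigs = bundle$manifest$contigs,
         peptides = bundle$manifest$peptides),
    file.path(dir, "truth_manifest.json"),
    dataframe = "rows", na = "null", digits = NA, pretty = TRUE
  )
  cfg <- bundle$config
  cfg$digestion <- unclass(cfg$digestion)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation bundle back from disk
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `pg_bundle` (without the original config object's class).
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "truth_manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(
      config = jsonlite::read_json(file.path(dir, "sim_config.json"),
                                   simplifyVector = TRUE),
      genome = read_fasta(file.path(dir, "genome.fasta")),
      annotations = list(
        old = read_gff3(file.path(dir, "annotation_old.gff3"), "old"),
        new = read_gff3(file.path(dir, "annotation_new.gff3"), "new")
      ),
      contigs = read_fasta(file.path(dir, "contigs.fasta")),
      observed = read_peptides(file.path(dir, "peptides.tsv")),
      manifest = list(contigs = as_tibble(manifest$contigs),
                      peptides = as_tibble(manifest$peptides))
    ),
    class = "pg_bundle"
  )
}

#' Validate a simulation bundle against its truth manifest
#'
#' Asserts the manifest invariants: every contig appears exactly once in
#' the manifest and vice versa; every observed peptide has exactly one
#' manifest source (a contig or `"contaminant"`); exact/hidden contigs
#' equal the spliced transcript of their source gene; each SAV contig's
#' protein differs from its source gene's protein at exactly one
#' residue; noise contigs share no 15-mer with the genome (either
#' orientation); expected categories come from the classification
#' vocabulary.
#'
#' @param bundle A `pg_bundle`.
#' @return A tibble of checks (`check`, `pass`), invisibly `TRUE`-only;
#'   any violated assertion raises an error naming the offending contig.
#' @export
validate_bundle <- function(bundle) {
  mc <- bundle$manifest$contigs
  checks <- list()
  note <- function(name) checks[[length(checks) + 1L]] <<- name

  if (!setequal(mc$contig_id, bundle$contigs$name) ||
      anyDuplicated(mc$contig_id) > 0) {
    abort("manifest contigs and emitted contigs do not match one-to-one")
  }
  note("contigs one-to-one with manifest")

  mp <- bundle$manifest$peptides
  if (!setequal(mp$peptide, bundle$observed$peptide) ||
      anyDuplicated(mp$peptide) > 0) {
    abort("manifest peptides and observed peptides do not match one-to-one")
  }
  if (!all(mp$source %in% c(mc$contig_id, "contaminant"))) {
    abort("manifest peptide with unknown source")
  }
  note("peptides one-to-one with manifest")

  cseq <- stats::setNames(bundle$contigs$sequence, bundle$contigs$name)
  spliced <- spliced_sequences(bundle$annotations$new, bundle$genome)
  spl <- stats::setNames(spliced$sequence, spliced$gene_id)
  for (i in seq_len(nrow(mc))) {
    row <- mc[i, ]
    if (row$class %in% c("exact", "hidden") &&
        !identical(cseq[[row$contig_id]], spl[[row$source_gene]])) {
      abort(paste0("contig ", row$contig_id,
                   " is not the spliced transcript of ", row$source_gene))
    }
    if (row$class == "sav") {
      ref_prot <- sub("\\*$", "", translate_dna(spl[[row$source_gene]]))
      alt_prot <- row$protein
      if (nchar(ref_prot) != nchar(alt_prot)) {
        abort(paste0("SAV contig ", row$contig_id, " changes protein length"))
      }
      ndiff <- utf8_mismatch_count(ref_prot, alt_prot)
      if (ndiff != 1) {
        abort(paste0("SAV contig ", row$contig_id, " differs at ", ndiff,
                     " residues; expected exactly 1"))
      }
    }
  }
  note("exact/hidden transcripts and SAV single-residue effects")

  gk <- genome_kmer_index(bundle$genome, k = 15L)
  all_gk <- unlist(purrr::map(gk$chroms, `[[`, "levels"), use.names = FALSE)
  for (cid in mc$contig_id[mc$class == "noise"]) {
    s <- cseq[[cid]]
    L <- nchar(s)
    km <- c(substring(s, 1:(L - 14L), 15:L),
            substring(revcomp(s), 1:(L - 14L), 15:L))
    if (any(km %in% all_gk)) {
      abort(paste0("noise contig ", cid, " shares a 15-mer with the genome"))
    }
  }
  note("noise contigs k-mer-disjoint from genome")

  allowed <- c("annotated", "refined_gene_structure", "putative_novel_gene",
               "unaligned")
  if (!all(mc$expected_old %in% allowed) || !all(mc$expected_new %in% allowed)) {
    abort("manifest expected category outside the classification vocabulary")
  }
  note("expected categories in vocabulary")

  invisible(tibble(check = unlist(checks), pass = TRUE))
}
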