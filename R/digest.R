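#' In-silico digestion settings
#'
#' Defaults mirror a standard shotgun-proteomics search: tryptic cleavage
#' with proline suppression, up to two missed cleavages, peptide length
#' 6--50 residues, and isoleucine/leucine treated as equivalent when
#' keying peptides (the residues are isobaric and indistinguishable by
#' MS).
#'
#' @param enzyme `"trypsin"` (cleave after K/R, not before P),
#'   `"trypsin/P"` (ignore the proline rule), or `"lysC+trypsin"`
#'   (sequential digest: K sites are never suppressed by proline).
#' @param max_missed_cleavages Maximum internal uncleaved sites per
#'   peptide.
#' @param min_len,max_len Peptide length bounds in residues.
#' @param il_equivalence Fold I/L to a common symbol when keying peptides
#'   for database membership.
#' @return A `pg_digestion_config` list.
#' @export
digestion_config <- function(enzyme = c("trypsin", "trypsin/P", "lysC+trypsin"),
                             max_missed_cleavages = 2L, min_len = 6L,
                             max_len = 50L, il_equivalence = TRUE) {
  enzyme <- match.arg(enzyme)
  stopifnot(max_missed_cleavages >= 0, min_len >= 1, min_len <= max_len)
  structure(
    list(enzyme = enzyme,
         max_missed_cleavages = as.integer(max_missed_cleavages),
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         il_equivalence = isTRUE(il_equivalence)),
    class = "pg_digestion_config"
  )
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

fold_il <- function(x, cfg) {
  if (isTRUE(cfg$il_equivalence)) chartr("I", "L", x) else x
}

# 1-based positions i such that cleavage occurs between residue i and i+1
cleavage_sites <- function(residues, enzyme) {
  n <- length(residues)
  if (n < 2) return(integer())
  i <- seq_len(n - 1L)
  is_kr <- residues[i] %in% c("K", "R")
  next_p <- residues[i + 1L] == "P"
  keep <- switch(enzyme,
    "trypsin" = is_kr & !next_p,
    "trypsin/P" = is_kr,
    "lysC+trypsin" = (residues[i] == "K") | (residues[i] == "R" & !next_p)
  )
  i[keep]
}

#' Digest a protein in silico
#'
#' Cleaves the protein at the configured enzyme's sites and returns all
#' peptides formed by runs of up to `max_missed_cleavages + 1` consecutive
#' fragments whose length is within the configured bounds. Peptides
#' containing `X` (from ambiguous codons) are excluded.
#'
#' @param protein A single protein sequence over the 20 amino acids
#'   plus `X`.
#' @param cfg A [digestion_config()].
#' @return A character vector of unique peptides (order: by position,
#'   then span).
#' @export
#' @examples
#' digest("MKRPDEKR", digestion_config())
digest <- function(protein, cfg = digestion_config()) {
  stopifnot(is.character(protein), length(protein) == 1)
  residues <- strsplit(protein, "")[[1]]
  bad <- setdiff(residues, c(AA20, "X"))
  if (length(bad) > 0) {
    abort(paste0("invalid residue '", bad[1], "' in protein"))
  }
  n <- length(residues)
  if (n == 0) return(character())
  sites <- cleavage_sites(residues, cfg$enzyme)
  bounds <- c(0L, sites, n)          # fragment k spans (bounds[k], bounds[k+1]]
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (a in seq_len(nfrag)) {
    b_max <- min(nfrag, a + cfg$max_missed_cleavages)
    for (b in a:b_max) {
      len <- bounds[b + 1L] - bounds[a]
      if (len > cfg$max_len) break
      if (len < cfg$min_len) next
      peps <- c(peps, substr(protein, bounds[a] + 1L, bounds[b + 1L]))
    }
  }
  peps <- unique(peps)
  peps[!grepl("X", peps, fixed = TRUE)]
}

#' Build a peptide-to-parent index over a protein database
#'
#' Digests every protein and indexes the union of peptides by their
#' (optionally I/L-folded) key, recording each peptide's parent proteins.
#'
#' @param proteins A tibble with an id column (`id`, `orf_id` or
#'   `gene_id`) and a `protein` column.
#' @param cfg A [digestion_config()].
#' @return A `pg_peptide_index` tibble with columns `key` (folded
#'   membership key), `peptide` (original sequence) and `protein_id`, one
#'   row per distinct (peptide, parent) pair; the digestion config is
#'   attached as an attribute.
#' @export
build_peptide_index <- function(proteins, cfg = digestion_config()) {
  id_col <- intersect(c("id", "orf_id", "gene_id"), names(proteins))
  if (length(id_col) == 0 || !"protein" %in% names(proteins)) {
    abort("proteins must have an id column (id/orf_id/gene_id) and a 'protein' column")
  }
  ids <- proteins[[id_col[1]]]
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicate protein id: ", ids[duplicated(ids)][1]))
  }
  rows <- purrr::map_dfr(seq_along(ids), function(i) {
    peps <- digest(proteins$protein[i], cfg)
    if (length(peps) == 0) return(NULL)
    tibble(key = fold_il(peps, cfg), peptide = peps, protein_id = ids[i])
  })
  if (nrow(rows) == 0) {
    rows <- tibble(key = character(), peptide = character(),
                   protein_id = character())
  }
  structure(distinct(rows), cfg = cfg,
            class = c("pg_peptide_index", class(rows)))
}

#' Annotate observed peptides with database membership
#'
#' Looks each observed peptide up in one or more peptide indexes (built
#' with [build_peptide_index()], typically one per searched database) and
#' records, per database, whether the peptide is present and which parent
#' proteins carry it. Peptides absent from every database are retained
#' and flagged `unmatched`.
#'
#' @param observed A character vector of peptide sequences, or a tibble
#'   with a `peptide` column.
#' @param indexes A named list of `pg_peptide_index` objects; the names
#'   are the database labels.
#' @return A membership tibble with columns `peptide`, one logical column
#'   per database, `unmatched`, and `parents` (a list column of named
#'   lists mapping database to parent-id vectors). The database names are
#'   attached as the `databases` attribute.
#' @export
assign_membership <- function(observed, indexes) {
  if (is.data.frame(observed)) observed <- observed$peptide
  if (length(indexes) < 1 || is.null(names(indexes)) ||
      any(!nzchar(names(indexes)))) {
    abort("indexes must be a non-empty named list")
  }
  dbs <- names(indexes)
  out <- tibble(peptide = as.character(observed))
  member <- matrix(FALSE, nrow = nrow(out), ncol = length(dbs),
                   dimnames = list(NULL, dbs))
  parent_lists <- rep(list(stats::setNames(list(), character())), nrow(out))
  for (db in dbs) {
    idx <- indexes[[db]]
    cfg <- attr(idx, "cfg")
    keys <- fold_il(out$peptide, cfg)
    by_key <- split(idx$protein_id, idx$key)
    hit <- keys %in% names(by_key)
    member[, db] <- hit
    for (i in which(hit)) {
      parent_lists[[i]][[db]] <- sort(unique(by_key[[keys[i]]]))
    }
  }
  for (db in dbs) out[[db]] <- unname(member[, db])
  out$unmatched <- rowSums(member) == 0
  out$parents <- parent_lists
  structure(out, databases = dbs, class = class(out))
}

membership_databases <- function(observations) {
  dbs <- attr(observations, "databases")
  if (is.null(dbs)) {
    dbs <- setdiff(names(observations), c("peptide", "unmatched", "parents"))
    dbs <- dbs[vapply(observations[dbs], is.logical, logical(1))]
  }
  if (length(dbs) == 0 || !all(dbs %in% names(observations))) {
    abort("observations do not carry a consistent database membership vector")
  }
  dbs
}

#' Venn region counts of peptide membership
#'
#' Counts observed peptides in each of the `2^k - 1` non-empty membership
#' regions over the `k` searched databases (region labels join database
#' names with `&`), plus the `unmatched` region. Regions always sum to
#' the number of observations.
#'
#' @param observations A membership tibble from [assign_membership()].
#' @return A tibble with columns `region` and `count`, zero-count regions
#'   included.
#' @export
venn_counts <- function(observations) {
  dbs <- membership_databases(observations)
  k <- length(dbs)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- dbs
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  region_of <- function(flags) paste(dbs[flags], collapse = "&")
  labels <- apply(combos, 1, function(r) region_of(as.logical(r)))
  mem <- as.matrix(observations[, dbs, drop = FALSE])
  if (nrow(mem) > 0 && any(is.na(mem))) abort("membership flags must not be NA")
  obs_region <- apply(mem, 1, function(r) {
    if (!any(r)) "unmatched" else region_of(as.logical(r))
  })
  counts <- table(factor(obs_region, levels = c(labels, "unmatched")))
  tibble(region = names(counts), count = as.integer(counts))
}

#' Peptides exclusive to one database
#'
#' Returns the observed peptides whose membership is exactly the target
#' database -- present there and absent from every other searched
#' database. These are the "novel" peptides when the target is the
#' transcript-derived database.
#'
#' @param observations A membership tibble from [assign_membership()].
#' @param target_db Database name.
#' @return The subset of `observations` exclusive to `target_db`.
#' @export
novel_peptides <- function(observations, target_db) {
  dbs <- membership_databases(observations)
  if (!target_db %in% dbs) {
    abort(paste0("unknown target database '", target_db, "'"))
  }
  others <- setdiff(dbs, target_db)
  keep <- observations[[target_db]]
  for (db in others) keep <- keep & !observations[[db]]
  observations[keep, , drop = FALSE]
}
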