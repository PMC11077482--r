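# Shared fixtures. The default study bundle and its pipeline run are
# computed once per test session and reused.

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function(seed = 7) {
  key <- paste0("bundle", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(simulation_config(seed = seed))
  }
  .fixture_env[[key]]
}

default_run <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      suppressMessages(run_pipeline(default_bundle(seed), quiet = TRUE))
  }
  .fixture_env[[key]]
}

# expected category per contig/version, treating absence from the
# classification as "annotated" (all its peptides explained by the version)
observed_categories <- function(run, version, manifest_contigs) {
  cl <- run$classification[[version]]
  got <- stats::setNames(cl$category, cl$contig_id)
  ifelse(manifest_contigs$contig_id %in% names(got),
         got[manifest_contigs$contig_id], "annotated")
}

write_temp_fasta <- function(named_seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(named_seqs)),
                             unname(named_seqs))), path)
  path
}
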