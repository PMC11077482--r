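---
title: "Validating genome annotation with transcript-derived peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating genome annotation with transcript-derived peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteorefine)
```

## The inference

Annotation pipelines predict gene models computationally, and the
models inherit the blind spots of the predictors: genes can be missed
entirely, and exon boundaries can be truncated or misplaced. A
transcriptome assembled de novo from the same organism is an
independent witness. If its contigs are translated into a protein
database and confidently identified peptides (a 1% FDR search result)
are compared across that database and the databases derived from the
genome annotations, three situations carry information:

* a peptide found in both the transcript database and an annotation
  database *validates* the annotated gene;
* a peptide found only in the transcript database, whose parent contig
  aligns to the genome **overlapping an annotated gene**, indicates the
  annotation should be revised — a *refined gene structure*;
* the same situation with **no gene overlap** indicates a *putative
  novel gene*; and a contig that does not align at all, yet has
  protein-level homology elsewhere, may be a gene missing from the
  assembly itself (*unaligned*, homology-supported).

`proteorefine` implements this decision flow as composable stages
(`build_protein_db()` → `build_peptide_index()` /
`assign_membership()` → `novel_peptides()` → `align_contigs()` /
`filter_alignments()` → `classify_contigs()` → `project_peptides()` /
`to_bed12()`, with `sav_candidates()` and `filter_hits()` on the
side), and `run_pipeline()` chains them.

The pipeline deliberately consumes an observed-peptide *list*, not
spectra. Search-engine scoring and FDR control are upstream concerns;
every downstream step here is search-engine-agnostic. The simulator's
`contamination_rate` stands in for residual false identifications when
robustness is being probed.

### Novelty is relative to a database set

"Novel" is always relative. Two notions are exposed:

* `novel_peptides(obs, target)` returns peptides whose membership is
  *exactly* the target database — the strict, publication-style count
  of peptides unexplained by every genome annotation searched.
* `run_pipeline()` classifies per annotation version `v` using the
  peptides present in the transcript database and absent from `v`.
  This is what an annotator revising version `v` needs: a gene present
  in a newer annotation but missing from `v` should surface as a
  putative novel gene *for `v`* even though the newer annotation
  explains it.

A contig whose peptides are all explained by version `v` is simply not
classified against `v`; summaries treat it as "annotated". Both
notions are reported in a `pg_run`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_aa` (ORF) | 100 | residues | conventional minimum ORF length for transcript translation; short spurious ORFs mostly encode unobservable peptides |
| `allow_partial` | `TRUE` | – | assembled contigs are frequently 5'-incomplete; a frame-leading ORF without an upstream stop is kept |
| enzyme | trypsin | – | cleavage C-terminal to K/R, suppressed before proline; `trypsin/P` and sequential `lysC+trypsin` (K never suppressed) available |
| `max_missed_cleavages` | 2 | sites | standard shotgun search setting |
| `min_len`, `max_len` | 6, 50 | residues | the practically observable peptide range; 6 matches the usual search minimum |
| `il_equivalence` | `TRUE` | – | isobaric I/L are indistinguishable by MS; folding them when keying membership prevents false exclusivity calls |
| `match`, `mismatch` | +5, −4 | score | est2genome-like magnitudes, so the customary score threshold (next row) corresponds to ≈400 matched bases |
| `min_score` | 2000 (strict >) | score | retention threshold for spliced alignments |
| `min_identity_pct` | 95 (≥) | % | only near-identical alignments are biologically interpretable as the same locus |
| `min_coverage_pct` | 50 (≥) | % of contig | at least half the contig must be explained by the locus |
| `k` | 15 | bp | anchor seed length; long enough that random 15-mer collisions are rare at the genome sizes targeted |
| `max_intron` | 10,000 | bp | target-side gaps up to this are introns |
| homology filter | e < 1e-12, id > 70%, cov > 90% | – | strict inequalities; coverage is *query* coverage (an interpretation — the convention is not universal, so it is configurable) |
| SAV band | identity ∈ [99, 100] | % | "near-perfect" band screened for variants |

## The aligner

`align_contigs()` is a bespoke splice-aware aligner for the
high-identity regime the retention filter keeps (≈95% identity and
above): exact `k`-mer anchors are merged into maximal exact segments
per diagonal, segments are chained collinearly by dynamic programming
(target gaps ≤ `max_intron` are introns), substitution regions between
same-diagonal segments are resolved column by column, unanchored bases
straddling an intron are placed on whichever side of the junction
scores better (an optimal split), and alignment ends are extended
ungapped, trimmed at the cumulative-score maximum. Identity is
computed over aligned columns excluding intron gaps; coverage over the
full contig length. It does not model gapped low-identity homology —
that is what the homology-hit import is for — and it records splice
orientation when present but does not enforce GT–AG.

Numerical corner cases worth stating:

* **Junction ambiguity.** When an intron's edge base equals the
  adjacent exon's edge base, two placements of the junction score
  identically and no sequence-only aligner can prefer one. The
  synthetic generator excludes this degenerate case by construction
  (see below), and on real data the reported boundary is the
  arbitrary-but-deterministic one of equal score.
* **Ties in chaining** are broken toward the first-seen chain in a
  fixed segment order, making output independent of input order.
* **Multiple loci** per contig are all reported (transposon-like
  contigs legitimately align at several places), ordered by score,
  chromosome, then start.

## The SAV screen

Within the 99–100% identity band, the best retained alignment per
contig is called a single-amino-acid-variant candidate when it has
exactly one mismatch, or zero mismatches with an alignment one base
short of the contig; permissive mode adds two-mismatch cases.
`sav_effects()` then locates the mismatching base by column walk and
reports the codon-level effect when it lands in a predicted ORF. The
screen operates at the nucleotide level; a candidate is *potential*
until the residue change is confirmed, which is why the effect
annotation carries an explicit `nonsynonymous` flag. The e-value
reported by the built-in protein aligner uses fixed Karlin–Altschul
constants (K = 0.041, λ = 0.267) and is an estimate for thresholding
synthetic comparisons, not a database-calibrated statistic.

## What the simulator emulates — and what it does not

`simulate_study()` plants, on one random chromosome (200 kb by
default): 40 multi-exon genes (1–4 exons, CDS ≥ 510 bp) on both
strands; a complete "new" annotation and an "old" one missing 5
*hidden* genes; 5 *refined* genes whose terminal exon is truncated in
**both** annotations while the contig carries the full CDS (persistent
terminal-exon misannotation — this is what makes a structure-extension
contig classify as refined under either version); 5 *SAV* contigs with
one planted nonsynonymous SNV (rejection-sampled so the residue change
survives I/L folding and a covering tryptic peptide exists); 3 *noise*
contigs sharing no 15-mer with the genome in either orientation
(rejection-sampled, so "unaligned" is deterministic); exact transcripts
for the remaining genes; and 2–5 observed peptides per contig sampled
from the planted protein's digest, with structure-informative peptides
(extension-covering, variant-covering) guaranteed present. The truth
manifest records every contig's origin and expected classification per
annotation version, and every peptide's source.

Deliberate idealisations, which bound what passing tests show about
real data:

* CDSs are uniform random sense codons — no codon bias, no paralog
  families, no repeats beyond chance; real genomes produce more
  ambiguous alignments.
* Transcripts are exact CDS copies (no UTRs, no assembly errors other
  than the planted classes); contigs carry no indels.
* Default CDS length (≥ 510 bp) is chosen so exact transcripts clear
  the score-over-2000 retention threshold, as real retained contigs
  did; shorter genes would be filtered into the unaligned class, which
  is a property of the filter, not a defect.
* Splice junctions are made unambiguous (intron edge ≠ exon edge
  base), because without a splice-site model the ambiguous case is
  undecidable (above).
* The observed-peptide list is sampled directly from digests; spectra,
  retention times, modifications and match-between-runs effects are
  out of scope.
* Planted SAV peptides covering the variant cannot translate back from
  the *reference* genome — the projection's `frame_consistent` flag
  identifies exactly those loci, and the round-trip invariant is
  asserted over all others.

Determinism is part of the contract: the same configuration (seed
included) regenerates the bundle byte-identically, and re-running the
pipeline on identical inputs rewrites byte-identical artifacts.

## Problem sizes

The shipped tests run the full pipeline on the default 200 kb / 40-gene
study (seconds on one core), verify digestion against brute-force
enumeration on 1,000 random proteins for every enzyme ×
missed-cleavage combination, exercise the aligner's exact block
recovery on 100 planted multi-exon transcripts in a 400 kb genome, and
check the coordinate-map projection against a per-base oracle on over
1,000 random intervals. These sizes exercise every branch of the
decision flow while keeping the suite fast; nothing in the
implementation is specific to them.

## Known limitations

* `N` is the only ambiguity code accepted; other IUPAC codes are
  rejected at parse time.
* GFF3 handling covers `gene`/`mRNA`/`exon` features only; the
  classifier's gene "range" is the span from first to last exon (an
  exon-level overlap mode is available via `overlap = "exon"`).
* Overlap classification is strand-blind by default (`strand_mode =
  "match"` for strict behaviour) because annotation conventions differ
  on antisense evidence.
* The aligner assumes the high-identity regime; it will fragment or
  drop genuinely divergent alignments rather than model them.
* Annotation rewriting (emitting revised GFF3 gene models) is out of
  scope; the outputs are classifications, tables and browser tracks.
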