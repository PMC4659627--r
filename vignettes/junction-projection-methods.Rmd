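---
title: "Projecting splice junctions onto transcripts without a reference genome"
author: "spliceproj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting splice junctions onto transcripts without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceproj)
options(spliceproj.verbose = FALSE)
```

## The problem and the model

De novo assembled transcriptomes of non-model organisms carry no record of
where their introns were. Yet exon/intron boundary positions are strongly
conserved between orthologous genes across vertebrates, and the last bases
of exons carry a donor-site signal (a strong preference for G at the final
exonic position). `spliceproj` exploits both observations to place
exon-exon junctions on mRNA sequences with no same-species genome:

1. **Reference database.** For one or more well-annotated species we store
   each non-redundant protein together with its junction records in protein
   coordinates: the index of the codon downstream of each junction and the
   junction's *phase* (CDS offset mod 3). Phase-0 junctions fall cleanly
   between codons; phase-1/2 junctions split a codon and are invisible at
   amino-acid resolution.
2. **Best-hit projection.** Each query transcript is translated in all six
   frames (frames split at stop codons) and every stop-free segment is
   locally aligned against every reference protein (BLOSUM62, affine gaps
   11/1). The single highest-scoring hit, gated at e-value `1e-5`
   (Karlin–Altschul statistics), carries the reference junctions onto the
   transcript: walking the alignment columns converts each junction's codon
   index into a transcript nucleotide position.
3. **Donor-motif resolution.** A phase-0 junction projects to a single
   exact position. A codon-split junction projects to two adjacent
   candidate positions (the two intra-codon offsets). The package learns a
   base-frequency model of the last `L` exonic bases from all *unambiguous*
   (phase-0) projected junctions of the run, pooled across transcripts, and
   resolves each split junction to its higher-scoring candidate
   (log-likelihood under the per-position frequencies, pseudocount 1).
4. **Filtering.** Predictions closer together than a minimum exon length
   are thinned (the lower-scoring one is dropped; ties drop the downstream
   one). First/last exon fragments are not filtered against transcript
   ends, because transcript ends are assembly artifacts, not junctions.
5. **Consensus.** With several reference databases, per-database
   predictions are pooled per transcript and clustered by single linkage
   (window 2 nt, which spans the 1-nt split-codon ambiguity plus the 1-nt
   evaluation tolerance). A cluster's consensus position is the member
   position supported by most databases (ties: higher motif score, then
   smaller position); union semantics (minimum support 1) are the default
   because multi-reference runs are meant to *increase* coverage.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `evalue_max` | 1e-5 | best-hit gate; larger values analyze more nucleotides at some precision cost |
| `motif_length` (L) | 1 | donor-motif width in bases, 1–5; a single base already carries most of the usable signal |
| `min_exon_len` | 10 | minimum spacing (nt) between predicted junctions, 1–20 |
| `cluster_window` | 2 | consensus single-linkage window (nt) |
| `min_support` | 1 | union semantics for multi-reference merging |
| `tolerance` | 1 | evaluation: a prediction within 1 nt of a true junction counts as correct |
| `use_reference_phase` | FALSE | resolve split codons from the stored phase instead of the motif |

The defaults for L and the minimum exon length sit at the precision-gain /
sensitivity-loss optimum that [`sweep_parameters()`] explores: the sweep
reruns the resolution and filtering stages over the L x min-exon grid and
reports each cell's ratio of precision gained to sensitivity lost relative
to the no-motif baseline (split codons resolved by the deterministic
smaller-position tie-break). Cells indistinguishable from their baseline
report an infinite ratio.

Phase is stored in the reference databases but **not** used at prediction
time by default: motif-based resolution is the published behavior, and
phase conservation across distant species is exactly what a cautious user
should not assume. `use_reference_phase = TRUE` exists because the
information is there; it also powers the package's strongest self-check
(below).

## What the synthetic data emulates — and what it does not

`simulate_reference()` builds a deterministic toy species: 20 genes (by
default) of 3–6 exons on both strands of one chromosome, GT..AG introns,
ATG-initiated stop-terminated CDSs free of internal stops, 10–30 nt UTRs
confined to the terminal exons, and exon bodies of 30–90 nt so junction
phases are mixed. The donor signal is planted directly: the last base of
each internal exon is G with probability 0.8 (roughly the vertebrate
donor-site frequency), otherwise uniform over the remaining bases. A
clean-motif mode (`donor_G_prob = 1`, `suppress_background_G = TRUE`)
removes G from all non-donor positions — giving a signal of strength 1.0
for isolating the motif machinery.

`evolve_transcripts()` derives a sister-species transcriptome by i.i.d.
per-site substitutions. By default substitutions that would create a
premature in-frame stop are redirected to another base: real coding
sequences evolve under purifying selection against nonsense mutations, and
without this the simulated divergence would fragment the six-frame
translation in a way real orthologs do not. The site still counts as
substituted, so substitution counts keep their binomial distribution.
`evolve_reference()` applies the same process to a whole reference species
(CDS, UTRs, intron interiors; gene structure, ATG, stop and GT..AG kept) to
build sister references from a common ancestor for multi-reference
experiments.

The generator does **not** model: indels (an exon-structure-preserving
indel mode is deliberately left out of the defaults because indels confound
the projection signal under test), codon-usage bias, dN/dS structure,
acceptor-side or branch-point signals, alternative splicing, paralogy, or
assembly errors. Passing tests on this generator therefore demonstrate the
correctness of the projection/resolution machinery under its stated
assumptions — not performance on real diverged transcriptomes, where
alignment quality and junction conservation are the binding constraints.

## Numerical and design choices

* **Coordinates.** Everything internal is 0-based half-open; genePred/GTF
  converters live at the boundary. A junction position is the transcript
  index of the first base of the downstream exon, making phase = CDS offset
  mod 3 exactly.
* **Aligner.** Local alignment is Smith–Waterman with affine gaps via
  `Biostrings::pairwiseAlignment` (a gap of length *k* costs
  `gap_open + k * gap_extend`, the classic 11 + k). The empty alignment is
  always admissible, so all-nonpositive pairings score 0. The test suite
  holds the aligner to an independent brute-force DP oracle. Alignment
  tie-breaks among co-optimal tracebacks are the engine's (deterministic);
  best-hit tie-breaks are ours: higher raw score, then smaller subject id,
  then strand/frame order.
* **Search pruning.** Segments too short to reach the e-value gate even as
  perfect matches (length x max matrix score < gate score) are skipped;
  this cannot change any post-gate result.
* **E-values.** Karlin–Altschul `E = K m n exp(-lambda S)` with fixed
  gapped-BLOSUM62 constants (K = 0.041, lambda = 0.267); an approximation
  of external translated-search statistics, adequate for gating.
* **Matching for evaluation.** Predicted and true junctions are matched
  1-to-1 under the tolerance by an exact non-crossing dynamic program that
  maximizes the number of matches, then minimizes total distance. A greedy
  nearest-first pairing was considered and rejected: it is not
  cardinality-optimal (preds {4,5} vs truths {5,6} at tolerance 1 is a
  two-match instance where nearest-first finds only one). The test suite
  checks the DP against exhaustive assignment.
* **Annotation quality.** Fraction of transcript ids whose provided
  protein equals the genome-derived translation, over the *union* of ids
  (ids present on one side only count as failures). Transcripts failing
  the check are excluded from the database.
* **Degenerate inputs.** Empty motif training sets degrade to the uniform
  model (resolution falls back to the smaller-position tie-break) with a
  warning; 0/0 metric ratios are reported as `NA`/null with a warning;
  junctions whose flanking reference residues are clipped by the local
  alignment are dropped, not extrapolated.
* **Known sensitivity ceilings.** Junctions in UTRs are not representable
  in protein space and never enter the database; one best hit is taken per
  transcript per database (no HSP stitching), so junctions outside the
  best local alignment are unrecoverable. Both are documented consequences
  of the protein-based design.

## Problem sizes

The packaged checks run the full pipeline on the 20-gene standard fixture
(about 5-6 kb of transcript per run): self-projection and motif-resolution
runs once each, the divergence band at {0, 0.05, 0.10, 0.20} with five
replicate query evolutions per level, a three-reference consensus
experiment, and a 2 x 2 corner of the L x min-exon sweep grid. These sizes
exercise every code path with junction counts in the dozens; scaling the
generator up changes runtimes, not code paths.

## A worked self-check

The strongest identity the package asserts about itself: projecting a
reference's own mRNAs against its own database with phase-based resolution
must recover every database junction exactly.

```{r selfcheck, eval = FALSE}
ref <- simulate_reference(sim_params(seed = 1), db_name = "ref")
db  <- build_reference_db(ref$genome, ref$models, ref$proteins, "ref")
res <- predict_junctions(ref$transcripts, db,
                         config = predict_config(use_reference_phase = TRUE))
compute_metrics(match_predictions(res$predictions, ref$truth, tolerance = 0))
#> eval_report (tau=0): P=57 TP=57 FP=0 FN=0  sens=1 prec=1 fdr=0
```
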