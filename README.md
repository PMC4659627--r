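# spliceproj

Splice-junction prediction for transcripts of organisms **without a
reference genome**.

De novo assembled transcriptomes carry no record of intron positions, which
blocks everything downstream that needs exon boundaries: intra-exon PCR
primer design, exome-capture probe design, population-genetic markers.
`spliceproj` places exon–exon junctions on mRNA sequences by exploiting two
facts about vertebrate gene evolution: exon/intron boundary *positions* are
conserved between orthologs far beyond sequence identity, and the 3' end of
an exon carries a donor-site base signal (G-rich at the final exonic
position).

## Method

For a reference species with a well-annotated genome, each non-redundant
protein is stored with its junctions in protein coordinates: the codon
index *c* downstream of the junction and the phase *p* = (CDS offset mod
3). A query transcript is translated in six frames and locally aligned
(Smith–Waterman, BLOSUM62, affine gaps 11/1) against all reference
proteins; the best hit, gated at Karlin–Altschul e-value E = K·m·n·e^(−λS)
≤ 10⁻⁵, projects each junction onto the transcript by walking the
alignment columns.

A phase-0 junction lands between codons — one exact position. A
codon-split junction (p ∈ {1,2}) has two possible intra-codon positions.
These are resolved with a position-frequency model of the last L exonic
bases (default L = 1), learned from the run's own unambiguous junctions
with pseudocount 1, scoring each candidate by Σ log f. Predictions closer
than a minimum exon length (default 10 nt) are thinned; with several
reference databases, per-database sets are merged by single-linkage
clustering (window 2 nt) with support-count consensus.

Evaluation follows the standard confusion-count scheme with a distance
tolerance τ (default 1 nt): sensitivity = TP/(TP+FN), precision =
TP/(TP+FP), FDR = 1 − precision, with exact 1-to-1 matching of predictions
to true junctions.

## Worked example

Everything below is computed, not curated — a simulated reference species,
a diverged (10% per-site) query transcriptome, and a round trip through the
whole pipeline:

```r
library(spliceproj)

ref <- simulate_reference(sim_params(seed = 1), db_name = "ref")
db  <- build_reference_db(ref$genome, ref$models, ref$proteins, "ref")
db
#> junction_db 'ref': 20 proteins, 57 junctions, annotation quality 1

## self-projection sanity check: exact recovery of every junction
res <- predict_junctions(ref$transcripts, db,
                         config = predict_config(use_reference_phase = TRUE))
compute_metrics(match_predictions(res$predictions, ref$truth, tolerance = 0))
#> eval_report (tau=0): P=57 TP=57 FP=0 FN=0  sens=1 prec=1 fdr=0

## a sister species at 10% divergence, motif-based resolution
q    <- evolve_transcripts(ref, divergence = 0.10, seed = 2)
res2 <- predict_junctions(q$transcripts, db, config = predict_config())
compute_metrics(match_predictions(res2$predictions, q$truth, tolerance = 1))
#> eval_report (tau=1): P=57 TP=57 FP=0 FN=0  sens=1 prec=1 fdr=0
round(res2$similarity$similarity, 3)   # fraction of nucleotides analyzed
#> [1] 0.826

head(res2$predictions, 3)
#>   transcript_id position     resolution motif_score db_name subject_id      e_value
#> 1          g001       48          exact  -0.2876821     ref       g001 1.548499e-17
#> 2          g001      116 motif_resolved  -0.2876821     ref       g001 1.548499e-17
#> 3          g002       69 motif_resolved  -0.2876821     ref       g002 7.642808e-19
```

`position` is the 0-based transcript index of the first base of the
downstream exon; `resolution` records whether the junction fell between
codons (`exact`) or was a codon-split junction placed by the donor motif
(`motif_resolved`); `motif_score` is the log-likelihood of the preceding
bases under the learned motif. `write_predictions()` emits the same table
as TSV or BED6 (`--one-based` style shifting available for primer design).

A thin command-line surface over these functions ships in
`inst/cli/spliceproj.R` with subcommands `build-db`, `predict`, `evaluate`,
`simulate`, `fixtures` and `sweep`.

## Scope and limitations

Junctions inside UTRs are invisible to a protein-coordinate database, and
only the single best local alignment per transcript per database is
projected — both are documented sensitivity ceilings of the protein-based
design. The simulator is substitution-only by default and models no
acceptor-side signal, codon bias, alternative splicing or assembly error;
see the methods vignette (`vignettes/junction-projection-methods.Rmd`) for
the full account of assumptions, parameters and numerical choices.
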