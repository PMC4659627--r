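#' Prediction configuration
#'
#' Defaults reproduce the published pipeline settings: donor-side motif of a
#' single base, minimum exon length 10 bp, e-value cutoff 1e-5, evaluation
#' tolerance 1 nt, consensus cluster window 2 nt with union (min support 1)
#' semantics. `use_reference_phase = FALSE` resolves split-codon junctions
#' with the learned motif; `TRUE` uses the phase stored in the reference
#' database instead (exact resolution, useful for self-tests).
#'
#' @param motif_length Donor motif length L, 1..5.
#' @param min_exon_len Minimum allowed spacing between predicted junctions,
#'   1..20 nt.
#' @param evalue_max Best-hit e-value cutoff.
#' @param use_reference_phase Resolve split-codon junctions from stored
#'   phase instead of the motif.
#' @param pseudocount Motif pseudocount.
#' @param cluster_window Consensus clustering window (nt).
#' @param min_support Minimum supporting databases for a consensus junction.
#' @param tolerance Evaluation tolerance tau (nt).
#' @return List of class `predict_config`.
#' @export
predict_config <- function(motif_length = 1L, min_exon_len = 10L,
                           evalue_max = 1e-5, use_reference_phase = FALSE,
                           pseudocount = 1.0, cluster_window = 2L,
                           min_support = 1L, tolerance = 1L) {
  stopifnot(motif_length >= 1L, motif_length <= 5L,
            min_exon_len >= 1L, min_exon_len <= 20L,
            evalue_max > 0, pseudocount > 0,
            cluster_window >= 0L, min_support >= 1L, tolerance >= 0L)
  structure(list(motif_length = as.integer(motif_length),
                 min_exon_len = as.integer(min_exon_len),
                 evalue_max = evalue_max,
                 use_reference_phase = isTRUE(use_reference_phase),
                 pseudocount = pseudocount,
                 cluster_window = as.integer(cluster_window),
                 min_support = as.integer(min_support),
                 tolerance = as.integer(tolerance)),
            class = "predict_config")
}

# map an oriented transcript position to input orientation
map_oriented <- function(pos, frame, q_len) {
  if (frame > 0L) pos else q_len - pos
}

#' Project reference junctions through a translated alignment
#'
#' For each junction record of the aligned reference protein, finds the
#' query nucleotide position of the first base of the codon downstream of
#' the junction by walking the alignment columns. Phase-0 junctions yield a
#' single exact candidate at that position; split-codon junctions yield the
#' two intra-codon candidates (position + 1, position + 2), to be resolved
#' later. Junctions whose flanking subject residues fall in a subject gap
#' or outside the local alignment are dropped.
#'
#' @param aln A `translated_alignment`.
#' @param junctions Data frame (codon_index, phase) for `aln$subject_id`.
#' @param transcript Query nucleotide sequence (supplies length for
#'   negative-frame coordinate reflection).
#' @return Data frame of candidates: transcript_id, pos1, pos2 (`NA` for
#'   exact), pos_phase (phase-resolved position, always defined),
#'   resolution ("exact"/"ambiguous"), phase, codon_index, db_name,
#'   subject_id, e_value.
#' @export
project_junctions <- function(aln, junctions, transcript) {
  stopifnot(inherits(aln, "translated_alignment"))
  q_len <- nchar(transcript)
  or_start <- if (aln$frame > 0L) aln$q_nt_start else q_len - aln$q_nt_end
  cols <- aln$columns
  empty <- data.frame(transcript_id = character(), pos1 = integer(),
                      pos2 = integer(), pos_phase = integer(),
                      resolution = character(), phase = integer(),
                      codon_index = integer(), db_name = character(),
                      subject_id = character(), e_value = numeric())
  if (nrow(junctions) == 0L || nrow(cols) == 0L) return(empty)
  s_idx <- cols[, "s"]
  q_gap <- is.na(cols[, "q"])
  # cumulative count of non-gap query columns strictly before each column
  q_before <- cumsum(!q_gap) - as.integer(!q_gap)
  out <- vector("list", nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    j <- junctions$codon_index[i]
    ph <- junctions$phase[i]
    if (j < aln$s_aa_start || j >= aln$s_aa_end) next
    cj <- which(!is.na(s_idx) & s_idx == j)
    if (length(cj) != 1L || q_gap[cj]) next           # downstream residue
    if (j - 1L >= aln$s_aa_start) {                   # upstream, clip at edge
      cp <- which(!is.na(s_idx) & s_idx == j - 1L)
      if (length(cp) != 1L || q_gap[cp]) next
    }
    q_nt_or <- or_start + 3L * q_before[cj]           # oriented codon start
    mapped <- function(p) map_oriented(p, aln$frame, q_len)
    pos_phase <- mapped(q_nt_or + ph)
    if (ph == 0L) {
      p1 <- mapped(q_nt_or); p2 <- NA_integer_
      resolution <- "exact"
    } else {
      ps <- sort(c(mapped(q_nt_or + 1L), mapped(q_nt_or + 2L)))
      p1 <- ps[1]; p2 <- ps[2]
      resolution <- "ambiguous"
    }
    if (p1 <= 0L || (if (is.na(p2)) p1 else p2) >= q_len) next
    out[[i]] <- data.frame(transcript_id = aln$query_id, pos1 = p1, pos2 = p2,
                           pos_phase = pos_phase, resolution = resolution,
                           phase = ph, codon_index = j,
                           db_name = aln$db_name, subject_id = aln$subject_id,
                           e_value = aln$e_value)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# ---- donor-side motif -------------------------------------------------------

MOTIF_BASES <- c("A", "C", "G", "T")

#' Learn the donor-side (3' exon end) base motif from exact candidates
#'
#' The last L exonic bases before every unambiguous (phase-0) projected
#' junction are tallied into a per-position base-count model. Frequencies
#' are computed with a pseudocount, so an empty training set degenerates to
#' the uniform model (with a warning); motif resolution then reduces to the
#' deterministic tie-break.
#'
#' @param exact_candidates Candidate data frame (rows with resolution
#'   "exact" are used).
#' @param transcripts Named character vector of query sequences.
#' @param L Motif length.
#' @param pseudocount Added to every cell at frequency computation.
#' @return List of class `motif_model` with `L`, `counts` (4 x L),
#'   `pseudocount`, `n_sites`.
#' @export
learn_motif <- function(exact_candidates, transcripts, L = 1L,
                        pseudocount = 1.0) {
  stopifnot(L >= 1L)
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(MOTIF_BASES, NULL))
  n_sites <- 0L
  ex <- exact_candidates[exact_candidates$resolution == "exact", , drop = FALSE]
  for (i in seq_len(nrow(ex))) {
    tr <- transcripts[[ex$transcript_id[i]]]
    p <- ex$pos1[i]
    if (is.null(tr) || p < L) next
    win <- strsplit(substr(tr, p - L + 1L, p), "")[[1]]  # 0-based p-L..p-1
    for (k in seq_len(L)) {
      b <- win[k]
      if (b %in% MOTIF_BASES) counts[b, k] <- counts[b, k] + 1L
    }
    n_sites <- n_sites + 1L
  }
  if (n_sites == 0L) {
    warning("no usable junction sites for motif training; uniform model",
            call. = FALSE)
  }
  structure(list(L = as.integer(L), counts = counts,
                 pseudocount = pseudocount, n_sites = n_sites),
            class = "motif_model")
}

#' Per-position base frequencies of a motif model (pseudocount applied)
#' @param motif A `motif_model`.
#' @return 4 x L matrix; columns sum to 1.
#' @export
motif_frequencies <- function(motif) {
  pc <- motif$pseudocount
  sweep(motif$counts + pc, 2L, colSums(motif$counts) + 4 * pc, "/")
}

#' Log-likelihood motif score of the L bases ending at a position
#'
#' Scores the window `transcript[position - L .. position)` (0-based) under
#' the motif's per-position frequencies; higher is better. Positions closer
#' than L to the transcript start score `-Inf` (deprioritized). Non-ACGT
#' letters take the pseudocount share of the position's frequency mass.
#'
#' @param motif A `motif_model` (or `NULL` for the no-motif baseline: score
#'   0 everywhere).
#' @param transcript Nucleotide sequence.
#' @param position 0-based junction position.
#' @return Log-scale score.
#' @export
score_with_motif <- function(motif, transcript, position) {
  if (is.null(motif)) return(0)
  L <- motif$L
  if (position < L) return(-Inf)
  fr <- motif_frequencies(motif)
  denom <- colSums(motif$counts) + 4 * motif$pseudocount
  win <- strsplit(substr(transcript, position - L + 1L, position), "")[[1]]
  s <- 0
  for (k in seq_len(L)) {
    b <- win[k]
    f <- if (b %in% MOTIF_BASES) fr[b, k] else motif$pseudocount / denom[k]
    s <- s + log(unname(f))
  }
  s
}

# ---- finalization -----------------------------------------------------------

# iteratively drop the lower-scoring member of adjacent pairs closer than
# min_exon_len (tie: drop the downstream one); positions must be sorted
enforce_min_exon <- function(df, min_exon_len) {
  while (nrow(df) > 1L) {
    gaps <- diff(df$position)
    v <- which(gaps < min_exon_len)
    if (!length(v)) break
    i <- v[1]
    drop <- if (df$motif_score[i] < df$motif_score[i + 1L]) i else i + 1L
    df <- df[-drop, , drop = FALSE]
  }
  df
}

#' Resolve candidates into final junction predictions
#'
#' Split-codon (ambiguous) candidates are resolved to the higher-scoring of
#' their two positions (tie: the smaller position), or from the stored
#' reference phase when `config$use_reference_phase`. Predictions are then
#' sorted and the minimum-exon-length filter applied: while any two
#' adjacent predictions are closer than `min_exon_len`, the one with the
#' lower motif score is dropped (tie: the downstream one). The first and
#' last predicted exon fragments are not length-filtered against the
#' transcript ends.
#'
#' @param candidates Candidate data frame from [project_junctions()]
#'   (single transcript, single database best hit).
#' @param motif A `motif_model`, or `NULL` for motif-free resolution.
#' @param transcript Query nucleotide sequence.
#' @param config [predict_config()].
#' @return Prediction data frame: transcript_id, position, resolution
#'   ("exact"/"motif_resolved"), motif_score, db_name, subject_id, e_value.
#' @export
finalize_predictions <- function(candidates, motif, transcript,
                                 config = predict_config()) {
  empty <- data.frame(transcript_id = character(), position = integer(),
                      resolution = character(), motif_score = numeric(),
                      db_name = character(), subject_id = character(),
                      e_value = numeric())
  if (nrow(candidates) == 0L) return(empty)
  n <- nrow(candidates)
  position <- integer(n); resolution <- character(n); msc <- numeric(n)
  for (i in seq_len(n)) {
    if (candidates$resolution[i] == "exact") {
      position[i] <- candidates$pos1[i]
      resolution[i] <- "exact"
      msc[i] <- score_with_motif(motif, transcript, position[i])
    } else if (config$use_reference_phase) {
      position[i] <- candidates$pos_phase[i]
      resolution[i] <- "exact"
      msc[i] <- score_with_motif(motif, transcript, position[i])
    } else {
      p1 <- candidates$pos1[i]; p2 <- candidates$pos2[i]
      s1 <- score_with_motif(motif, transcript, p1)
      s2 <- score_with_motif(motif, transcript, p2)
      if (s2 > s1) { position[i] <- p2; msc[i] <- s2 }
      else { position[i] <- p1; msc[i] <- s1 }     # tie -> smaller position
      resolution[i] <- "motif_resolved"
    }
  }
  df <- data.frame(transcript_id = candidates$transcript_id,
                   position = position, resolution = resolution,
                   motif_score = msc, db_name = candidates$db_name,
                   subject_id = candidates$subject_id,
                   e_value = candidates$e_value)
  df <- df[order(df$position), , drop = FALSE]
  df <- df[!duplicated(df$position), , drop = FALSE]
  df <- enforce_min_exon(df, config$min_exon_len)
  rownames(df) <- NULL
  df
}

# ---- whole-pipeline driver --------------------------------------------------

#' Predict splice junctions on query transcripts
#'
#' Runs the full pipeline: per reference database, find each transcript's
#' best translated hit and project the reference junctions; learn the
#' donor-side motif from the pooled unambiguous candidates of the run;
#' resolve and filter per transcript; and, when several databases are
#' given, merge the per-database sets into a consensus (see
#' [merge_references()]).
#'
#' @param transcripts Named character vector of query sequences, or FASTA
#'   path.
#' @param dbs A `junction_db` or list of them (or paths to saved DBs).
#' @param config [predict_config()].
#' @param align [align_params()]; its `evalue_max` is overridden by
#'   `config$evalue_max`.
#' @param hits Optional list of precomputed `translated_alignment` objects
#'   (e.g. from [parse_tabular_hits()]) keyed implicitly by their query and
#'   db names; when supplied, the built-in aligner is skipped for those
#'   databases.
#' @return List with `predictions` (consensus when multiple DBs, else the
#'   single DB's set), `per_db` (named list of per-database prediction data
#'   frames), `motif` (the learned `motif_model`), `alignments` (retained
#'   best hits), `similarity` (see [compute_similarity()]).
#' @export
predict_junctions <- function(transcripts, dbs, config = predict_config(),
                              align = align_params(), hits = NULL) {
  if (is.character(transcripts) && length(transcripts) == 1L) {
    transcripts <- read_fasta(transcripts, alphabet = "dna")
  }
  if (inherits(dbs, "junction_db")) dbs <- list(dbs)
  dbs <- lapply(dbs, function(d) {
    if (is.character(d)) load_db(d) else d
  })
  align$evalue_max <- config$evalue_max
  cand_by_db <- list()
  aln_all <- list()
  for (db in dbs) {
    cands <- list()
    for (tid in names(transcripts)) {
      aln <- NULL
      if (!is.null(hits)) {
        for (h in hits) {
          if (identical(h$query_id, tid) && identical(h$db_name, db$db_name) &&
              h$e_value <= config$evalue_max &&
              (is.null(aln) || h$raw_score > aln$raw_score)) aln <- h
        }
      } else {
        aln <- translated_search(tid, transcripts[[tid]], db, align)
      }
      if (is.null(aln)) next
      aln_all[[length(aln_all) + 1L]] <- aln
      jn <- db$junctions[db$junctions$protein_id == aln$subject_id, ,
                         drop = FALSE]
      cc <- project_junctions(aln, jn, transcripts[[tid]])
      if (nrow(cc)) cands[[tid]] <- cc
    }
    cand_by_db[[db$db_name]] <-
      if (length(cands)) do.call(rbind, unname(cands)) else NULL
  }
  pooled <- do.call(rbind, unname(cand_by_db[!vapply(cand_by_db, is.null,
                                                     logical(1))]))
  motif <- if (is.null(pooled)) {
    suppressWarnings(learn_motif(
      data.frame(transcript_id = character(), pos1 = integer(),
                 resolution = character()), transcripts,
      config$motif_length, config$pseudocount))
  } else {
    learn_motif(pooled, transcripts, config$motif_length, config$pseudocount)
  }
  per_db <- list()
  for (dbn in names(cand_by_db)) {
    cc <- cand_by_db[[dbn]]
    if (is.null(cc)) {
      per_db[[dbn]] <- finalize_predictions(
        data.frame(transcript_id = character(), pos1 = integer(),
                   pos2 = integer(), pos_phase = integer(),
                   resolution = character(), phase = integer(),
                   codon_index = integer(), db_name = character(),
                   subject_id = character(), e_value = numeric()),
        motif, "", config)
      next
    }
    parts <- lapply(split(cc, cc$transcript_id), function(one) {
      finalize_predictions(one, motif, transcripts[[one$transcript_id[1]]],
                           config)
    })
    per_db[[dbn]] <- do.call(rbind, unname(parts))
  }
  predictions <- if (length(per_db) > 1L) {
    merge_references(per_db, motif, transcripts, config)
  } else if (length(per_db) == 1L) {
    per_db[[1]]
  } else {
    data.frame(transcript_id = character(), position = integer(),
               resolution = character(), motif_score = numeric(),
               db_name = character(), subject_id = character(),
               e_value = numeric())
  }
  sim <- compute_similarity(aln_all, transcripts)
  list(predictions = predictions, per_db = per_db, motif = motif,
       alignments = aln_all, similarity = sim)
}
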