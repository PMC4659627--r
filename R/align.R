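#' Alignment parameters
#'
#' Defaults follow the classic translated-search setup: BLOSUM62 with affine
#' gap penalties 11/1 (a gap of length k costs 11 + k), an e-value cutoff of
#' 1e-5, and standard gapped Karlin-Altschul constants K = 0.041,
#' lambda = 0.267 used to convert raw scores into e-values and bit scores.
#'
#' @param substitution_matrix Scoring matrix name (shipped with Biostrings).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param evalue_max Retain hits only with e-value below this.
#' @param karlin_k,karlin_lambda Karlin-Altschul constants.
#' @return List of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         evalue_max = 1e-5,
                         karlin_k = 0.041, karlin_lambda = 0.267) {
  stopifnot(gap_open > 0, gap_extend > 0, evalue_max > 0,
            karlin_k > 0, karlin_lambda > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 evalue_max = evalue_max,
                 karlin_k = karlin_k, karlin_lambda = karlin_lambda),
            class = "align_params")
}

# Replace letters absent from the scoring matrix by X
sanitize_aa <- function(x, mat) {
  letters_ok <- rownames(mat)
  chars <- strsplit(x, "")[[1]]
  chars[!chars %in% letters_ok] <- "X"
  paste(chars, collapse = "")
}

#' Optimal local protein alignment with affine gaps
#'
#' Smith-Waterman semantics: the empty alignment (score 0) is always
#' admissible, so if every residue pairing scores non-positively the result
#' is an empty alignment with score 0.
#'
#' @param q_aa,s_aa Amino-acid strings (query, subject).
#' @param params [align_params()].
#' @return List with `columns` (two-column integer matrix of 0-based
#'   query/subject residue indices, `NA` for a gap), `raw_score`,
#'   `q_aa_start`, `q_aa_end`, `s_aa_start`, `s_aa_end` (0-based half-open).
#' @export
local_align_protein <- function(q_aa, s_aa, params = align_params()) {
  empty <- list(columns = matrix(integer(), ncol = 2,
                                 dimnames = list(NULL, c("q", "s"))),
                raw_score = 0L, q_aa_start = 0L, q_aa_end = 0L,
                s_aa_start = 0L, s_aa_end = 0L)
  if (nchar(q_aa) == 0L || nchar(s_aa) == 0L) return(empty)
  mat <- get_submatrix(params$substitution_matrix)
  q_aa <- sanitize_aa(q_aa, mat); s_aa <- sanitize_aa(s_aa, mat)
  pa <- Biostrings::pairwiseAlignment(
    pattern = q_aa, subject = s_aa, type = "local",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(empty)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  si <- Biostrings::start(Biostrings::subject(pa)) - 1L
  n <- length(ap)
  qcol <- scol <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    if (ap[k] != "-") { qcol[k] <- qi; qi <- qi + 1L }
    if (as_[k] != "-") { scol[k] <- si; si <- si + 1L }
  }
  cols <- cbind(q = qcol, s = scol)
  list(columns = cols, raw_score = as.integer(round(sc)),
       q_aa_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       q_aa_end = Biostrings::end(Biostrings::pattern(pa)),
       s_aa_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       s_aa_end = Biostrings::end(Biostrings::subject(pa)))
}

#' Karlin-Altschul e-value for a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score at least S between a query of m residues and a
#' database of n residues.
#'
#' @param raw_score Raw alignment score S.
#' @param m Query length in residues.
#' @param n Total database residues.
#' @param params [align_params()] supplying K and lambda.
#' @export
estimate_evalue <- function(raw_score, m, n, params = align_params()) {
  stopifnot(m > 0, n > 0)
  params$karlin_k * m * n * exp(-params$karlin_lambda * raw_score)
}

bit_score <- function(raw_score, params) {
  (params$karlin_lambda * raw_score - log(params$karlin_k)) / log(2)
}

# Split a translated frame into stop-free segments with their aa offsets
frame_segments <- function(aa) {
  if (nchar(aa) == 0L) return(data.frame(offset = integer(), seq = character()))
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) > 0L
  data.frame(offset = as.integer(offs[keep]), seq = parts[keep],
             stringsAsFactors = FALSE)
}

# All six-frame stop-free segments of a transcript; coordinates are aa
# offsets within the (oriented) frame.
six_frame_segments <- function(nt) {
  L <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    seq_or <- if (strand == "+") nt else revcomp(nt)
    for (f in 1:3) {
      n_cod <- (L - f + 1L) %/% 3L
      if (n_cod < 1L) next
      aa <- translate_nt(substr(seq_or, f, f + 3L * n_cod - 1L))
      segs <- frame_segments(aa)
      if (nrow(segs)) {
        segs$strand <- strand
        segs$frame <- f
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(), seq = character(),
                      strand = character(), frame = integer()))
  }
  do.call(rbind, out)
}

#' Best translated (six-frame) hit of a transcript against a reference DB
#'
#' The transcript is translated in all six frames, frames are split into
#' stop-free segments, and every segment is locally aligned against every
#' database protein. The single best hit (highest raw score; ties broken by
#' smaller subject id, then strand/frame/segment order) is returned with
#' nucleotide coordinates mapped back to the input orientation, or `NULL`
#' if the best e-value exceeds `params$evalue_max`.
#'
#' @param transcript_id Query id (recorded in the result).
#' @param transcript Nucleotide sequence.
#' @param db A `junction_db`.
#' @param params [align_params()].
#' @return A `translated_alignment` list or `NULL`. Fields: query_id,
#'   subject_id, db_name, frame (+1..+3 forward, -1..-3 reverse), q_len,
#'   q_nt_start/q_nt_end (0-based half-open, input orientation),
#'   q_or_nt_start (coding orientation), s_aa_start/s_aa_end, columns
#'   (query indices are frame-local aa offsets), raw_score, bit_score,
#'   e_value.
#' @export
translated_search <- function(transcript_id, transcript, db,
                              params = align_params()) {
  nt <- chartr("U", "T", toupper(transcript))
  L <- nchar(nt)
  if (L < 3L) return(NULL)
  segs <- six_frame_segments(nt)
  if (!nrow(segs)) return(NULL)
  mat <- get_submatrix(params$substitution_matrix)
  # prune segments that cannot reach the e-value gate even as perfect
  # matches: their best possible score is length * max(matrix), and only
  # scores >= s_gate survive the gate, so dropping them never changes the
  # post-gate result
  m_res0 <- max(1L, L %/% 3L)
  n_res0 <- sum(nchar(db$proteins))
  s_gate <- (log(params$karlin_k * m_res0 * n_res0) -
               log(params$evalue_max)) / params$karlin_lambda
  segs <- segs[nchar(segs$seq) * max(mat) >= s_gate, , drop = FALSE]
  if (!nrow(segs)) return(NULL)
  seg_seqs <- vapply(segs$seq, sanitize_aa, character(1), mat = mat,
                     USE.NAMES = FALSE)
  pat <- Biostrings::AAStringSet(seg_seqs)
  subj_ids <- sort(names(db$proteins))
  best <- NULL
  for (sid in subj_ids) {
    s_aa <- sanitize_aa(db$proteins[[sid]], mat)
    scores <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = s_aa, type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
    k <- which.max(scores)  # first (strand/frame/segment order) on ties
    if (is.null(best) || scores[k] > best$score + 1e-9) {
      best <- list(score = scores[k], sid = sid, seg = k)
    }
  }
  if (is.null(best) || best$score <= 0) return(NULL)
  m_res <- max(1L, L %/% 3L)
  n_res <- sum(nchar(db$proteins))
  ev <- estimate_evalue(best$score, m_res, n_res, params)
  if (ev > params$evalue_max) return(NULL)
  seg <- segs[best$seg, ]
  aln <- local_align_protein(seg_seqs[best$seg], db$proteins[[best$sid]], params)
  # lift segment-local query aa indices to frame-local
  cols <- aln$columns
  cols[, "q"] <- cols[, "q"] + seg$offset
  q_aa_start <- aln$q_aa_start + seg$offset
  q_aa_end <- aln$q_aa_end + seg$offset
  or_start <- (seg$frame - 1L) + 3L * q_aa_start   # oriented nt coords
  or_end <- (seg$frame - 1L) + 3L * q_aa_end
  if (seg$strand == "+") {
    q_nt_start <- or_start; q_nt_end <- or_end
    frame <- seg$frame
  } else {
    q_nt_start <- L - or_end; q_nt_end <- L - or_start
    frame <- -seg$frame
  }
  structure(list(query_id = transcript_id, subject_id = best$sid,
                 db_name = db$db_name, frame = as.integer(frame), q_len = L,
                 q_nt_start = as.integer(q_nt_start),
                 q_nt_end = as.integer(q_nt_end),
                 q_or_nt_start = as.integer(or_start),
                 s_aa_start = aln$s_aa_start, s_aa_end = aln$s_aa_end,
                 columns = cols,
                 raw_score = as.integer(round(best$score)),
                 bit_score = bit_score(best$score, params),
                 e_value = ev),
            class = "translated_alignment")
}

# ---- external tabular hits --------------------------------------------------

HIT_FIELDS <- c("qseqid", "sseqid", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore", "score", "qframe", "btop")

expand_btop <- function(btop) {
  if (!grepl("^([0-9]+|[A-Z*-]{2})*$", btop)) {
    sp_stop("malformed btop string: '", btop, "'")
  }
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Z*-]{2}", btop))[[1]]
  qcol <- integer(); scol <- integer()
  qi <- 0L; si <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      n <- as.integer(t)
      if (n > 0L) {
        qcol <- c(qcol, qi + seq_len(n) - 1L)
        scol <- c(scol, si + seq_len(n) - 1L)
        qi <- qi + n; si <- si + n
      }
    } else {
      qc <- substr(t, 1, 1); sc <- substr(t, 2, 2)
      if (qc == "-" && sc == "-") sp_stop("malformed btop token '--'")
      qcol <- c(qcol, if (qc == "-") NA_integer_ else qi)
      scol <- c(scol, if (sc == "-") NA_integer_ else si)
      if (qc != "-") qi <- qi + 1L
      if (sc != "-") si <- si + 1L
    }
  }
  cbind(q = qcol, s = scol)
}

#' Parse external translated-search tabular hits (with btop traceback)
#'
#' Reads tab-separated rows in the 11-field layout
#' `qseqid sseqid qstart qend sstart send evalue bitscore score qframe btop`
#' (i.e. outfmt "6 ..." of the common translated-search tools) and expands
#' each btop traceback into a per-column correspondence. Input coordinates
#' are 1-based inclusive and converted to the internal 0-based half-open
#' convention. Rows whose subject is absent from the database are dropped
#' with a warning; rows with malformed btop raise a row-level error.
#'
#' @param path Tab-separated hits file (no header).
#' @param db A `junction_db`; query lengths for coordinate reflection of
#'   negative frames are inferred from qstart/qend.
#' @return List of `translated_alignment` objects.
#' @export
parse_tabular_hits <- function(path, db) {
  tab <- read.delim(path, header = FALSE, col.names = HIT_FIELDS,
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "integer",
                                   "numeric", "numeric", "integer",
                                   "integer", "character"))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$sseqid %in% names(db$proteins)) {
      warning("hit row ", i, ": subject '", r$sseqid,
              "' not in database; dropped", call. = FALSE)
      next
    }
    cols <- tryCatch(expand_btop(r$btop), error = function(e) {
      sp_stop("hit row ", i, ": ", conditionMessage(e))
    })
    cols[, "s"] <- cols[, "s"] + (r$sstart - 1L)
    q_nt_start <- min(r$qstart, r$qend) - 1L
    q_nt_end <- max(r$qstart, r$qend)
    out[[length(out) + 1L]] <- structure(list(
      query_id = r$qseqid, subject_id = r$sseqid, db_name = db$db_name,
      frame = as.integer(r$qframe), q_len = NA_integer_,
      q_nt_start = as.integer(q_nt_start), q_nt_end = as.integer(q_nt_end),
      q_or_nt_start = NA_integer_,
      s_aa_start = r$sstart - 1L, s_aa_end = r$send,
      columns = cols, raw_score = as.integer(r$score),
      bit_score = r$bitscore, e_value = r$evalue),
      class = "translated_alignment")
  }
  out
}
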