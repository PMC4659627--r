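#' Distance-tolerant confusion counts for junction predictions
#'
#' Matches predicted to true junction positions per transcript under a
#' 1-to-1 constraint: a prediction may account for at most one true
#' junction and vice versa, and a pair may match only if its distance is at
#' most `tolerance` nt. The matching is exact (maximum number of pairs;
#' among maximum matchings, minimum total distance), computed by a
#' non-crossing dynamic program on the sorted positions. Unmatched
#' predictions count as FP, unmatched truths as FN; matched distances fill
#' the distance histogram.
#'
#' @param predicted Data frame (transcript_id, position) of predictions.
#' @param truth Data frame (transcript_id, position) of true junctions.
#' @param tolerance Maximum matching distance tau (nt), default 1.
#' @param fp_nearest Also record, in `fp_nearest_distances`, the distance of
#'   each FP to its nearest truth (within `fp_report_range`).
#' @param fp_report_range Reporting range for `fp_nearest`.
#' @return List of class `eval_report`: P, TP, FP, FN, tolerance,
#'   `distance_histogram` (named count vector over matched distances), and
#'   optionally `fp_nearest_distances`. Pass to [compute_metrics()] for
#'   sensitivity/precision/FDR.
#' @export
match_predictions <- function(predicted, truth, tolerance = 1L,
                              fp_nearest = FALSE, fp_report_range = 10L) {
  stopifnot(tolerance >= 0L)
  pred_split <- split(as.integer(predicted$position), predicted$transcript_id)
  truth_split <- split(as.integer(truth$position), truth$transcript_id)
  ids <- union(names(pred_split), names(truth_split))
  orphan <- setdiff(names(pred_split), names(truth_split))
  if (length(orphan)) {
    sp_log("transcript(s) with predictions but no truth entries (all FP): ",
           paste(head(orphan, 3), collapse = ", "))
  }
  TP <- 0L; FP <- 0L; FN <- 0L; P <- 0L
  hist_d <- integer(tolerance + 1L)
  fp_near <- integer(0)
  for (tid in ids) {
    p <- sort(pred_split[[tid]] %||% integer())
    t <- sort(truth_split[[tid]] %||% integer())
    P <- P + length(t)
    m <- match_positions_1to1(p, t, tolerance)
    TP <- TP + nrow(m$pairs)
    FP <- FP + (length(p) - nrow(m$pairs))
    FN <- FN + (length(t) - nrow(m$pairs))
    if (nrow(m$pairs)) {
      d <- abs(m$pairs[, 1] - m$pairs[, 2])
      for (dd in d) hist_d[dd + 1L] <- hist_d[dd + 1L] + 1L
    }
    if (fp_nearest && length(p) > nrow(m$pairs) && length(t)) {
      un <- setdiff(p, m$pairs[, 1])
      nd <- vapply(un, function(x) min(abs(x - t)), numeric(1))
      fp_near <- c(fp_near, as.integer(nd[nd <= fp_report_range]))
    }
  }
  names(hist_d) <- as.character(seq_len(tolerance + 1L) - 1L)
  rep <- list(P = P, TP = TP, FP = FP, FN = FN,
              tolerance = as.integer(tolerance),
              distance_histogram = hist_d)
  if (fp_nearest) rep$fp_nearest_distances <- fp_near
  structure(rep, class = "eval_report")
}

# exact max-cardinality (then min total distance) 1-to-1 matching between
# two sorted position vectors with |p - t| <= tau; non-crossing DP
match_positions_1to1 <- function(p, t, tau) {
  np <- length(p); nt <- length(t)
  if (np == 0L || nt == 0L) {
    return(list(pairs = matrix(integer(), ncol = 2)))
  }
  # cnt[i, j], dst[i, j]: best over p[i..], t[j..] (1-based, size +1 border)
  cnt <- matrix(0L, np + 1L, nt + 1L)
  dst <- matrix(0, np + 1L, nt + 1L)
  for (i in np:1) {
    for (j in nt:1) {
      best_c <- cnt[i + 1L, j]; best_d <- dst[i + 1L, j]   # skip pred i
      if (cnt[i, j + 1L] > best_c ||
          (cnt[i, j + 1L] == best_c && dst[i, j + 1L] < best_d)) {
        best_c <- cnt[i, j + 1L]; best_d <- dst[i, j + 1L] # skip truth j
      }
      d <- abs(p[i] - t[j])
      if (d <= tau) {
        cc <- cnt[i + 1L, j + 1L] + 1L
        dd <- dst[i + 1L, j + 1L] + d
        if (cc > best_c || (cc == best_c && dd < best_d)) {
          best_c <- cc; best_d <- dd
        }
      }
      cnt[i, j] <- best_c; dst[i, j] <- best_d
    }
  }
  pairs <- matrix(integer(), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= np && j <= nt) {
    d <- abs(p[i] - t[j])
    if (d <= tau && cnt[i, j] == cnt[i + 1L, j + 1L] + 1L &&
        dst[i, j] == dst[i + 1L, j + 1L] + d) {
      pairs <- rbind(pairs, c(p[i], t[j]))
      i <- i + 1L; j <- j + 1L
    } else if (cnt[i, j] == cnt[i + 1L, j] && dst[i, j] == dst[i + 1L, j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(pairs = pairs)
}

#' Fill sensitivity, precision and FDR into an evaluation report
#'
#' sensitivity = TP / (TP + FN), precision = TP / (TP + FP),
#' FDR = FP / (TP + FP) = 1 - precision. Undefined ratios (0/0) are
#' reported as `NA` with a warning (serialized as null).
#'
#' @param report An `eval_report` from [match_predictions()].
#' @return The report with `sensitivity`, `precision`, `fdr` added.
#' @export
compute_metrics <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  if (report$TP + report$FN != report$P) {
    sp_stop("inconsistent counts: TP + FN != P")
  }
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined (0/0)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  report$sensitivity <- ratio(report$TP, report$TP + report$FN, "sensitivity")
  report$precision <- ratio(report$TP, report$TP + report$FP, "precision")
  report$fdr <- ratio(report$FP, report$TP + report$FP, "fdr")
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (tau=", x$tolerance, "): P=", x$P, " TP=", x$TP,
      " FP=", x$FP, " FN=", x$FN, sep = "")
  if (!is.null(x$sensitivity)) {
    cat("  sens=", format(x$sensitivity, digits = 4),
        " prec=", format(x$precision, digits = 4),
        " fdr=", format(x$fdr, digits = 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Similarity: fraction of query nucleotides covered by retained hits
#'
#' `analyzed_nt` is the union of aligned query spans of the retained best
#' hits (per transcript, across databases); `total_nt` sums the lengths of
#' all input transcripts, including those without any hit.
#'
#' @param alignments List of retained `translated_alignment` objects.
#' @param transcripts Named character vector of all query sequences.
#' @return List: total_nt, analyzed_nt, similarity.
#' @export
compute_similarity <- function(alignments, transcripts) {
  total_nt <- sum(nchar(transcripts))
  by_tid <- split(alignments,
                  vapply(alignments, `[[`, character(1), "query_id"))
  analyzed <- 0L
  for (alns in by_tid) {
    s <- vapply(alns, `[[`, integer(1), "q_nt_start")
    e <- vapply(alns, `[[`, integer(1), "q_nt_end")
    analyzed <- analyzed + union_width(s, e)
  }
  list(total_nt = total_nt, analyzed_nt = analyzed,
       similarity = if (total_nt > 0) analyzed / total_nt else 0)
}

#' Motif-length by minimum-exon-length parameter sweep
#'
#' Re-runs the resolution/filter stage of the pipeline over a grid of motif
#' lengths and minimum exon lengths and reports, per cell, sensitivity and
#' precision at the configured tolerance plus the precision-gain to
#' sensitivity-loss ratio relative to the no-motif baseline (the same run
#' with motif resolution disabled: split-codon candidates fall back to the
#' deterministic smaller-position tie-break). A cell whose sensitivity loss
#' is zero or negative reports `Inf`. Alignments and projections are
#' computed once and shared across the grid (they do not depend on L or the
#' exon-length filter).
#'
#' @param transcripts Named character vector or FASTA path.
#' @param truth Truth data frame (transcript_id, position).
#' @param dbs A `junction_db` or list of them.
#' @param L_values Motif lengths to sweep (subset of 1..5).
#' @param min_exon_values Minimum exon lengths to sweep (subset of 1..20).
#' @param config Base [predict_config()] (tolerance, e-value, consensus
#'   settings).
#' @param align [align_params()].
#' @return Data frame: L, min_exon_len, sensitivity, precision,
#'   baseline_sensitivity, baseline_precision, ratio.
#' @export
sweep_parameters <- function(transcripts, truth, dbs,
                             L_values = 1:5, min_exon_values = 1:20,
                             config = predict_config(),
                             align = align_params()) {
  stopifnot(all(L_values >= 1L & L_values <= 5L),
            all(min_exon_values >= 1L & min_exon_values <= 20L))
  if (is.character(transcripts) && length(transcripts) == 1L) {
    transcripts <- read_fasta(transcripts, alphabet = "dna")
  }
  if (inherits(dbs, "junction_db")) dbs <- list(dbs)
  align$evalue_max <- config$evalue_max
  # alignment + projection once
  cand_by_db <- list()
  for (db in dbs) {
    cands <- list()
    for (tid in names(transcripts)) {
      aln <- translated_search(tid, transcripts[[tid]], db, align)
      if (is.null(aln)) next
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
  run_cell <- function(motif, min_exon) {
    cfg <- config
    cfg$min_exon_len <- as.integer(min_exon)
    per_db <- list()
    for (dbn in names(cand_by_db)) {
      cc <- cand_by_db[[dbn]]
      if (is.null(cc)) next
      parts <- lapply(split(cc, cc$transcript_id), function(one) {
        finalize_predictions(one, motif,
                             transcripts[[one$transcript_id[1]]], cfg)
      })
      per_db[[dbn]] <- do.call(rbind, unname(parts))
    }
    preds <- if (length(per_db) > 1L) {
      merge_references(per_db, motif, transcripts, cfg)
    } else if (length(per_db) == 1L) per_db[[1]] else {
      data.frame(transcript_id = character(), position = integer())
    }
    rep <- suppressWarnings(compute_metrics(
      match_predictions(preds, truth, config$tolerance)))
    c(sens = rep$sensitivity, prec = rep$precision)
  }
  grid <- expand.grid(L = as.integer(L_values),
                      min_exon_len = as.integer(min_exon_values))
  res <- vector("list", nrow(grid))
  base_cache <- list()
  for (r in seq_len(nrow(grid))) {
    L <- grid$L[r]; me <- grid$min_exon_len[r]
    motif <- if (is.null(pooled)) NULL else
      learn_motif(pooled, transcripts, L, config$pseudocount)
    cell <- run_cell(motif, me)
    bkey <- as.character(me)
    if (is.null(base_cache[[bkey]])) {
      base_cache[[bkey]] <- run_cell(NULL, me)
    }
    base <- base_cache[[bkey]]
    gain <- cell["prec"] - base["prec"]
    loss <- base["sens"] - cell["sens"]
    ratio <- if (!is.finite(loss) || loss <= 0) Inf else gain / loss
    res[[r]] <- data.frame(L = L, min_exon_len = me,
                           sensitivity = unname(cell["sens"]),
                           precision = unname(cell["prec"]),
                           baseline_sensitivity = unname(base["sens"]),
                           baseline_precision = unname(base["prec"]),
                           ratio = unname(ratio))
  }
  do.call(rbind, res)
}
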