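#' Single-linkage clustering of per-database junction predictions
#'
#' Predictions for one transcript, pooled across reference databases, are
#' clustered by position with single linkage: adjacent (sorted) positions
#' at most `cluster_window` nt apart join the same cluster. Within a
#' cluster, each database contributes at most one prediction (its
#' higher-motif-score one; tie: the smaller position).
#'
#' @param pooled Prediction data frame for a single transcript with a
#'   `db_name` column.
#' @param cluster_window Maximum gap (nt) for single linkage.
#' @return The input rows (deduplicated per DB per cluster) with an
#'   integer `cluster` column added.
#' @export
cluster_predictions <- function(pooled, cluster_window = 2L) {
  if (nrow(pooled) == 0L) {
    pooled$cluster <- integer(0)
    return(pooled)
  }
  stopifnot(length(unique(pooled$transcript_id)) == 1L)
  pooled <- pooled[order(pooled$position), , drop = FALSE]
  gaps <- diff(pooled$position)
  pooled$cluster <- cumsum(c(1L, as.integer(gaps > cluster_window)))
  keep <- unlist(lapply(split(seq_len(nrow(pooled)), pooled$cluster),
                        function(idx) {
    sub <- pooled[idx, , drop = FALSE]
    sel <- integer(0)
    for (dbn in unique(sub$db_name)) {
      rows <- which(sub$db_name == dbn)
      if (length(rows) > 1L) {
        o <- order(-sub$motif_score[rows], sub$position[rows])
        rows <- rows[o[1]]
      }
      sel <- c(sel, rows)
    }
    idx[sort(sel)]
  }), use.names = FALSE)
  out <- pooled[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-reference prediction sets into a consensus
#'
#' Mirrors the multi-reference mode: per transcript, predictions from all
#' databases are clustered ([cluster_predictions()]); each cluster's
#' consensus position is the member position supported by the most
#' databases (ties: higher motif score, then smaller position); its support
#' is the union of contributing (db, subject) pairs. Clusters supported by
#' fewer than `min_support` databases are dropped, and the minimum-exon
#' spacing filter is re-applied to the merged set.
#'
#' @param per_db Named list of per-database prediction data frames.
#' @param motif The run's `motif_model` (used only for re-scoring ties; may
#'   be `NULL`).
#' @param transcripts Named character vector of query sequences.
#' @param config [predict_config()].
#' @return Consensus prediction data frame with `support_count` and
#'   `supporting_dbs` columns.
#' @export
merge_references <- function(per_db, motif, transcripts,
                             config = predict_config()) {
  pooled <- do.call(rbind, unname(per_db))
  empty <- data.frame(transcript_id = character(), position = integer(),
                      resolution = character(), motif_score = numeric(),
                      db_name = character(), subject_id = character(),
                      e_value = numeric(), support_count = integer(),
                      supporting_dbs = character())
  if (is.null(pooled) || nrow(pooled) == 0L) return(empty)
  out <- list()
  for (tid in sort(unique(pooled$transcript_id))) {
    sub <- pooled[pooled$transcript_id == tid, , drop = FALSE]
    cl <- cluster_predictions(sub, config$cluster_window)
    rows <- lapply(split(cl, cl$cluster), function(members) {
      support_count <- length(unique(members$db_name))
      if (support_count < config$min_support) return(NULL)
      tab <- table(members$position)
      best_n <- max(tab)
      cand_pos <- as.integer(names(tab)[tab == best_n])
      if (length(cand_pos) > 1L) {
        sc <- vapply(cand_pos, function(p) {
          max(members$motif_score[members$position == p])
        }, numeric(1))
        cand_pos <- cand_pos[order(-sc, cand_pos)]
      }
      pos <- cand_pos[1]
      rep_row <- members[members$position == pos, , drop = FALSE][1, ]
      dbs <- sort(unique(members$db_name))
      data.frame(transcript_id = tid, position = pos,
                 resolution = rep_row$resolution,
                 motif_score = max(members$motif_score[members$position == pos]),
                 db_name = rep_row$db_name, subject_id = rep_row$subject_id,
                 e_value = min(members$e_value),
                 support_count = support_count,
                 supporting_dbs = paste(dbs, collapse = ","))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df <- df[order(df$position), , drop = FALSE]
    df <- enforce_min_exon(df, config$min_exon_len)
    out[[tid]] <- df
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
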