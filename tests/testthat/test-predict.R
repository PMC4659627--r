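# a minimal hand-built alignment object for projection tests
mk_aln <- function(columns, q_nt_start, s_aa_start, s_aa_end, frame = 1L,
                   q_len = 1000L, query_id = "q1") {
  structure(list(query_id = query_id, subject_id = "p1", db_name = "db1",
                 frame = frame, q_len = q_len,
                 q_nt_start = q_nt_start,
                 q_nt_end = q_nt_start + 3L * sum(!is.na(columns[, "q"])),
                 q_or_nt_start = q_nt_start,
                 s_aa_start = s_aa_start, s_aa_end = s_aa_end,
                 columns = columns, raw_score = 100L, bit_score = 50,
                 e_value = 1e-20),
            class = "translated_alignment")
}

ungapped_cols <- function(n, q0 = 0L, s0 = 0L) {
  cbind(q = q0 + seq_len(n) - 1L, s = s0 + seq_len(n) - 1L)
}

test_that("phase-0 junctions project to exact positions", {
  aln <- mk_aln(ungapped_cols(10), q_nt_start = 12L, s_aa_start = 0L,
                s_aa_end = 10L)
  tx <- strrep("A", 100)
  cc <- project_junctions(aln, data.frame(codon_index = 4L, phase = 0L), tx)
  expect_equal(cc$pos1, 24L)           # 12 + 3*4
  expect_equal(cc$resolution, "exact")
  expect_true(is.na(cc$pos2))
})

test_that("split-codon junctions yield the two intra-codon candidates", {
  aln <- mk_aln(ungapped_cols(10), q_nt_start = 12L, s_aa_start = 0L,
                s_aa_end = 10L)
  tx <- strrep("A", 100)
  cc <- project_junctions(aln, data.frame(codon_index = 4L, phase = 2L), tx)
  expect_equal(c(cc$pos1, cc$pos2), c(25L, 26L))
  expect_equal(cc$resolution, "ambiguous")
  expect_equal(cc$pos_phase, 26L)
})

test_that("query insertions upstream of the junction shift the projection", {
  # 2-residue query insertion (subject gaps) before subject residue 4
  cols <- rbind(cbind(q = 0:1, s = 0:1),
                cbind(q = 2:3, s = NA_integer_),
                cbind(q = 4:9, s = 2:7))
  aln <- mk_aln(cols, q_nt_start = 12L, s_aa_start = 0L, s_aa_end = 8L)
  tx <- strrep("A", 100)
  cc <- project_junctions(aln, data.frame(codon_index = 4L, phase = 0L), tx)
  # oracle: walk the columns -- 6 non-gap query cols before subject residue 4
  expect_equal(cc$pos1, 12L + 3L * 6L)
})

test_that("junctions in subject gaps or outside the alignment are dropped", {
  cols <- rbind(cbind(q = 0:2, s = 0:2),
                cbind(q = NA_integer_, s = 3L),     # query gap at residue 3
                cbind(q = 3:5, s = 4:6))
  aln <- mk_aln(cols, q_nt_start = 0L, s_aa_start = 0L, s_aa_end = 7L)
  tx <- strrep("A", 100)
  jn <- data.frame(codon_index = c(3L, 4L, 20L), phase = c(0L, 0L, 0L))
  cc <- project_junctions(aln, jn, tx)
  expect_equal(nrow(cc), 0)  # 3: query gap; 4: upstream in gap; 20: outside
})

test_that("motif counts and pseudocount frequencies follow the definitions", {
  txs <- c(t1 = paste0(strrep("A", 50), "G", strrep("A", 49)))
  cand <- data.frame(transcript_id = rep("t1", 10), pos1 = rep(51L, 10),
                     resolution = rep("exact", 10))
  m <- learn_motif(cand, txs, L = 1)
  fr <- motif_frequencies(m)
  expect_equal(unname(fr["G", 1]), 11 / 14)    # (10+1)/(10+4)
  expect_equal(sum(fr[, 1]), 1)

  # no training sites -> uniform with warning
  expect_warning(m0 <- learn_motif(cand[0, ], txs, L = 1), "uniform")
  expect_equal(unname(motif_frequencies(m0)[, 1]), rep(0.25, 4))

  # L = 2 on sites AG, AG, CG
  txs2 <- c(a = paste0(strrep("T", 10), "AG", strrep("T", 10)),
            b = paste0(strrep("T", 10), "CG", strrep("T", 10)))
  cand2 <- data.frame(transcript_id = c("a", "a", "b"),
                      pos1 = c(12L, 12L, 12L),
                      resolution = "exact")
  m2 <- learn_motif(cand2, txs2, L = 2)
  fr2 <- motif_frequencies(m2)
  expect_equal(unname(fr2["A", 1]), 3 / 7)     # (2+1)/(3+4)
  expect_equal(unname(fr2["C", 1]), 2 / 7)
  expect_equal(unname(fr2["G", 2]), 4 / 7)
})

test_that("motif scoring is log frequency; short/non-ACGT handled", {
  txs <- c(t1 = paste0(strrep("A", 50), "G", strrep("A", 49)))
  cand <- data.frame(transcript_id = rep("t1", 10), pos1 = rep(51L, 10),
                     resolution = rep("exact", 10))
  m <- learn_motif(cand, txs, L = 1)
  expect_equal(score_with_motif(m, txs[["t1"]], 51L), log(11 / 14))
  expect_equal(score_with_motif(m, txs[["t1"]], 1L), log(1 / 14))  # A
  expect_equal(score_with_motif(m, txs[["t1"]], 0L), -Inf)
  # N takes the pseudocount share
  txN <- paste0("N", strrep("A", 20))
  expect_equal(score_with_motif(m, txN, 1L), log(1 / 14))
  # uniform model scores all candidates identically
  expect_warning(m0 <- learn_motif(cand[0, ], txs, L = 1))
  expect_equal(score_with_motif(m0, txs[["t1"]], 51L),
               score_with_motif(m0, txs[["t1"]], 50L))
})

test_that("ambiguous candidates resolve by motif score, then position", {
  tx <- paste0(strrep("A", 25), "G", strrep("A", 74))  # G at 0-based 25
  cand <- data.frame(transcript_id = "q1", pos1 = 25L, pos2 = 26L,
                     pos_phase = 26L, resolution = "ambiguous", phase = 2L,
                     codon_index = 4L, db_name = "db1", subject_id = "p1",
                     e_value = 1e-20)
  gmot <- structure(list(L = 1L,
                         counts = matrix(c(0L, 0L, 100L, 0L), 4, 1,
                                         dimnames = list(c("A", "C", "G", "T"),
                                                         NULL)),
                         pseudocount = 1, n_sites = 100L),
                    class = "motif_model")
  got <- finalize_predictions(cand, gmot, tx, predict_config())
  expect_equal(got$position, 26L)      # G precedes 26
  expect_equal(got$resolution, "motif_resolved")
  # tie (uniform) -> smaller position
  expect_warning(m0 <- learn_motif(cand[0, ], c(q1 = tx), L = 1))
  got0 <- finalize_predictions(cand, m0, tx, predict_config())
  expect_equal(got0$position, 25L)
  # reference phase overrides the motif
  gotp <- finalize_predictions(cand, gmot, tx,
                               predict_config(use_reference_phase = TRUE))
  expect_equal(gotp$position, 26L)
  expect_equal(gotp$resolution, "exact")
})

test_that("min-exon filter drops lower-scoring close predictions", {
  tx <- strrep("A", 200)
  mk <- function(pos, score) {
    data.frame(transcript_id = "q1", position = pos, resolution = "exact",
               motif_score = score, db_name = "db1", subject_id = "p1",
               e_value = 1e-20)
  }
  # equal scores at 100 and 104 -> downstream dropped
  df <- rbind(mk(100L, 0.5), mk(104L, 0.5))
  got <- spliceproj:::enforce_min_exon(df, 10L)
  expect_equal(got$position, 100L)
  # scores 0.9, 0.1, 0.5 at 100, 104, 113 -> keep 100 and 113
  df2 <- rbind(mk(100L, 0.9), mk(104L, 0.1), mk(113L, 0.5))
  got2 <- spliceproj:::enforce_min_exon(df2, 10L)
  expect_equal(got2$position, c(100L, 113L))
  # oracle on that instance: exhaustive search over drop sets, maximizing
  # total kept score subject to the spacing constraint
  best <- NULL
  for (keepmask in 0:7) {
    keep <- which(bitwAnd(keepmask, 2^(0:2)) > 0)
    pos <- df2$position[keep]
    if (length(pos) > 1 && any(diff(pos) < 10)) next
    sc <- sum(df2$motif_score[keep])
    if (is.null(best) || sc > best$sc) best <- list(sc = sc, keep = keep)
  }
  expect_equal(got2$position, df2$position[best$keep])
})

test_that("predictions are sorted, spaced, and positions are interior", {
  ref <- simulate_reference(sim_params(n_genes = 8, seed = 31), "sp")
  db <- build_reference_db(ref$genome, ref$models, ref$proteins, "sp")
  q <- evolve_transcripts(ref, divergence = 0.05, seed = 32)
  res <- predict_junctions(q$transcripts, db, config = predict_config())
  pr <- res$predictions
  expect_gt(nrow(pr), 0)
  for (tid in unique(pr$transcript_id)) {
    pos <- pr$position[pr$transcript_id == tid]
    expect_false(is.unsorted(pos, strictly = TRUE))
    if (length(pos) > 1) expect_true(all(diff(pos) >= 10))
    expect_true(all(pos > 0 & pos < nchar(q$transcripts[[tid]])))
  }
})

test_that("self-projection with reference phase recovers every junction", {
  ref <- simulate_reference(sim_params(n_genes = 6, seed = 13), "self")
  db <- build_reference_db(ref$genome, ref$models, ref$proteins, "self")
  res <- predict_junctions(ref$transcripts, db,
                           config = predict_config(use_reference_phase = TRUE))
  rep <- compute_metrics(match_predictions(res$predictions, ref$truth,
                                           tolerance = 0))
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$precision, 1.0)
})
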