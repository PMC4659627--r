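# Independent oracles used by the property tests. These deliberately share
# no code with the package internals.

# Brute-force affine-gap Smith-Waterman score (gap of length k costs
# go + k * ge), straightforward three-matrix DP with a zero floor.
brute_force_sw <- function(q, s, mat, go = 11, ge = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in query (consuming subject)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consuming query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(H[i, j - 1] - (go + ge), X[i, j - 1] - ge)
      Y[i, j] <- max(H[i - 1, j] - (go + ge), Y[i - 1, j] - ge)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     X[i, j], Y[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Exhaustive optimal 1-to-1 matching between positions p and t under
# tolerance tau: maximizes matched count, then minimizes total distance.
# Bitmask DP over used truths; returns c(count, total_distance).
exhaustive_match <- function(p, t, tau) {
  np <- length(p); nt <- length(t)
  if (np == 0L || nt == 0L) return(c(0L, 0))
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > np) return(c(0L, 0))
    key <- paste0(i, "_", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, mask)                      # leave p[i] unmatched
    for (j in seq_len(nt)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) next
      d <- abs(p[i] - t[j])
      if (d > tau) next
      sub <- rec(i + 1L, bitwOr(mask, bitwShiftL(1L, j - 1L)))
      cand <- c(sub[1] + 1L, sub[2] + d)
      if (cand[1] > best[1] || (cand[1] == best[1] && cand[2] < best[2])) {
        best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

# Hand-built two-exon toy gene on a plus strand: utr5 | exon1-core |
# intron | exon2-core | utr3, with the CDS boundaries aligned to the cores.
toy_two_exon <- function(core1, core2, utr5 = "", utr3 = "",
                         intron = "GTAAAAAG", chrom = "chrT") {
  exon1 <- paste0(utr5, core1)
  exon2 <- paste0(core2, utr3)
  genome_seq <- paste0(exon1, intron, exon2)
  e1s <- 0L; e1e <- nchar(exon1)
  e2s <- e1e + nchar(intron); e2e <- e2s + nchar(exon2)
  model <- list(gene_id = "t1", transcript_id = "t1", chrom = chrom,
                strand = "+",
                exon_starts = c(e1s, e2s), exon_ends = c(e1e, e2e),
                cds_start = nchar(utr5),
                cds_end = e2e - nchar(utr3))
  list(genome = stats::setNames(genome_seq, chrom), model = model)
}

# Mirror a toy genome + model to the opposite strand (coordinates reflected)
mirror_to_minus <- function(genome, model) {
  L <- nchar(genome[[model$chrom]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome[[model$chrom]])))
  m2 <- model
  m2$strand <- "-"
  m2$exon_starts <- rev(L - model$exon_ends)
  m2$exon_ends <- rev(L - model$exon_starts)
  m2$cds_start <- L - model$cds_end
  m2$cds_end <- L - model$cds_start
  list(genome = stats::setNames(rc, model$chrom), model = m2)
}
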