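STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Parameters for the synthetic reference/query generator
#'
#' The generator emulates the structure the projection method assumes:
#' multi-exon protein-coding genes with GT..AG introns, a donor-side signal
#' at the last base of each internal exon (G with probability
#' `donor_G_prob`), CDS-consistent proteins, and a diverged sister-species
#' transcriptome with known junction truth. Defaults describe a compact but
#' realistic desk-scale locus set: 20 genes of 3-6 exons, exon bodies of
#' 30-90 nt (so junction phases are mixed), short introns and UTRs, the
#' empirical mammalian-like 0.8 donor-G frequency, and both strands.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Range (lo, hi) of exon counts.
#' @param exon_len Range of coding exon-body lengths (>= 3 nt).
#' @param intron_len Range of intron lengths (>= 4 nt, for GT..AG).
#' @param donor_G_prob Probability the last exonic base of an internal exon
#'   is G (otherwise uniform over the remaining background bases).
#' @param utr5_len,utr3_len UTR length ranges.
#' @param divergence Default per-site substitution probability for
#'   [evolve_transcripts()].
#' @param minus_strand_prob Probability a gene is placed on the minus
#'   strand.
#' @param suppress_background_G If `TRUE`, non-donor positions are drawn
#'   from {A, C, T} only (clean-motif mode for donor-signal tests).
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 20L, exons_per_gene = c(3L, 6L),
                       exon_len = c(30L, 90L), intron_len = c(20L, 60L),
                       donor_G_prob = 0.8, utr5_len = c(10L, 30L),
                       utr3_len = c(10L, 30L), divergence = 0,
                       minus_strand_prob = 0.5,
                       suppress_background_G = FALSE, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            exons_per_gene = as_range(exons_per_gene, "exons_per_gene"),
            exon_len = as_range(exon_len, "exon_len"),
            intron_len = as_range(intron_len, "intron_len"),
            donor_G_prob = donor_G_prob,
            utr5_len = as_range(utr5_len, "utr5_len"),
            utr3_len = as_range(utr3_len, "utr3_len"),
            divergence = divergence,
            minus_strand_prob = minus_strand_prob,
            suppress_background_G = isTRUE(suppress_background_G),
            seed = as.integer(seed))
  if (p$n_genes < 1L) sp_stop("n_genes must be >= 1")
  if (p$exon_len[1] < 3L) sp_stop("exon_len must be >= 3")
  if (p$intron_len[1] < 4L) sp_stop("intron_len must be >= 4 (GT..AG)")
  if (p$donor_G_prob < 0 || p$donor_G_prob > 1) sp_stop("donor_G_prob in [0,1]")
  if (p$divergence < 0 || p$divergence > 0.5) sp_stop("divergence in [0, 0.5]")
  structure(p, class = "sim_params")
}

sim_alphabet <- function(params) {
  if (params$suppress_background_G) c("A", "C", "T") else c("A", "C", "G", "T")
}

sample_bases <- function(n, alphabet) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random non-stop codons over the background alphabet
sample_codons <- function(n, alphabet) {
  if (n == 0L) return(character())
  pool <- apply(expand.grid(alphabet, alphabet, alphabet), 1, paste,
                collapse = "")
  pool <- setdiff(pool, STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

# Build one gene's CDS (codon vector) with the donor signal planted at the
# last base of each internal coding exon; junction offsets are the
# cumulative coding-exon lengths.
build_cds_codons <- function(n_codons, junction_offsets, params) {
  alphabet <- sim_alphabet(params)
  codons <- c("ATG", sample_codons(n_codons - 2L, alphabet),
              if (params$suppress_background_G) "TAA" else
                sample(STOP_CODONS, 1L))
  for (off in junction_offsets) {
    bpos <- off - 1L                      # 0-based CDS index of donor base
    ci <- bpos %/% 3L + 1L                # codon holding it (1-based)
    if (ci <= 1L || ci >= n_codons) next  # never touch start/stop codons
    within <- bpos %% 3L + 1L
    base <- if (stats::runif(1) < params$donor_G_prob) "G" else
      sample(setdiff(alphabet, "G"), 1L)
    cod <- strsplit(codons[ci], "")[[1]]
    cod[within] <- base
    # repair if the donor base created a stop codon: resample the free
    # positions (donor base stays fixed)
    while (paste(cod, collapse = "") %in% STOP_CODONS) {
      free <- setdiff(1:3, within)
      cod[free] <- sample(alphabet, length(free), replace = TRUE)
    }
    codons[ci] <- paste(cod, collapse = "")
  }
  codons
}

assemble_gene <- function(comp) {
  # genomic (plus-layout) sequence and coordinates from components
  n_ex <- length(comp$exon_seqs)
  parts <- character(0)
  exon_starts <- integer(n_ex); exon_ends <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    exon_starts[i] <- pos
    parts <- c(parts, comp$exon_seqs[i])
    pos <- pos + nchar(comp$exon_seqs[i])
    exon_ends[i] <- pos
    if (i < n_ex) {
      parts <- c(parts, comp$intron_seqs[i])
      pos <- pos + nchar(comp$intron_seqs[i])
    }
  }
  list(seq = paste(parts, collapse = ""), exon_starts = exon_starts,
       exon_ends = exon_ends, glen = pos)
}

build_gene <- function(gid, params) {
  alphabet <- sim_alphabet(params)
  n_ex <- sample_range(params$exons_per_gene)
  cores <- sample_range(params$exon_len, n_ex)
  rem <- sum(cores) %% 3L
  if (rem > 0L) {                        # make the spliced CDS a codon whole
    if (cores[n_ex] - rem >= 3L) cores[n_ex] <- cores[n_ex] - rem
    else cores[n_ex] <- cores[n_ex] + (3L - rem)
  }
  cds_len <- sum(cores)
  n_codons <- cds_len %/% 3L
  offsets <- head(cumsum(cores), -1L)    # CDS offsets of the junctions
  codons <- build_cds_codons(n_codons, offsets, params)
  cds <- paste(codons, collapse = "")
  utr5 <- sample_bases(sample_range(params$utr5_len), alphabet)
  utr3 <- sample_bases(sample_range(params$utr3_len), alphabet)
  # split the CDS back into per-exon bodies
  stops <- cumsum(cores)
  starts <- c(0L, head(stops, -1L))
  bodies <- substring(cds, starts + 1L, stops)
  exon_seqs <- bodies
  exon_seqs[1] <- paste0(utr5, exon_seqs[1])
  exon_seqs[n_ex] <- paste0(exon_seqs[n_ex], utr3)
  introns <- vapply(seq_len(n_ex - 1L), function(i) {
    len <- sample_range(params$intron_len)
    paste0("GT", sample_bases(len - 4L, alphabet), "AG")
  }, character(1))
  strand <- if (stats::runif(1) < params$minus_strand_prob) "-" else "+"
  list(gene_id = gid, strand = strand, utr5 = utr5, utr3 = utr3,
       cores = cores, cds = cds, exon_seqs = exon_seqs,
       intron_seqs = introns, offsets = offsets)
}

finish_reference <- function(components, params, db_name) {
  spacer_len <- 50L
  genome_parts <- character(0)
  models <- list(); proteins <- character(); transcripts <- character()
  truth <- list()
  pos <- 0L
  alphabet <- sim_alphabet(params)
  for (comp in components) {
    asm <- assemble_gene(comp)
    spacer <- sample_bases(spacer_len, alphabet)
    genome_parts <- c(genome_parts, spacer)
    pos <- pos + spacer_len
    gstart <- pos
    utr5n <- nchar(comp$utr5); utr3n <- nchar(comp$utr3)
    if (comp$strand == "+") {
      gseq <- asm$seq
      ex_s <- gstart + asm$exon_starts
      ex_e <- gstart + asm$exon_ends
      cds_start <- gstart + utr5n
      cds_end <- gstart + asm$glen - utr3n
    } else {
      gseq <- revcomp(asm$seq)
      ex_s <- gstart + (asm$glen - rev(asm$exon_ends))
      ex_e <- gstart + (asm$glen - rev(asm$exon_starts))
      cds_start <- gstart + utr3n
      cds_end <- gstart + asm$glen - utr5n
    }
    genome_parts <- c(genome_parts, gseq)
    pos <- pos + asm$glen
    models[[comp$gene_id]] <- new_gene_model(
      gene_id = comp$gene_id, transcript_id = comp$gene_id,
      chrom = "chr1", strand = comp$strand,
      exon_starts = ex_s, exon_ends = ex_e,
      cds_start = cds_start, cds_end = cds_end)
    aa <- translate_nt(comp$cds)
    proteins[comp$gene_id] <- substr(aa, 1L, nchar(aa) - 1L)  # strip stop
    transcripts[comp$gene_id] <- paste0(comp$utr5, comp$cds, comp$utr3)
    truth[[comp$gene_id]] <- data.frame(
      transcript_id = comp$gene_id,
      position = utr5n + comp$offsets,
      cds_offset = comp$offsets,
      phase = comp$offsets %% 3L)
  }
  genome <- c(chr1 = paste(genome_parts, collapse = ""))
  truth_df <- do.call(rbind, unname(truth))
  rownames(truth_df) <- NULL
  structure(list(db_name = db_name, genome = genome, models = unname(models),
                 proteins = proteins, transcripts = transcripts,
                 truth = truth_df, components = components, params = params),
            class = "sim_reference")
}

#' Simulate a toy annotated reference species
#'
#' Generates a single-chromosome genome with `n_genes` multi-exon genes
#' (GT..AG introns, ATG-initiated stop-terminated CDS free of internal
#' stops, donor-G signal at internal exon ends), the matching gene models,
#' the encoded proteins, the mature mRNAs, and the junction truth table
#' (transcript coordinates, with CDS offset and phase per junction). Fully
#' deterministic given `params$seed`.
#'
#' @param params [sim_params()].
#' @param db_name Name recorded on the reference (used as the database name
#'   downstream).
#' @return List of class `sim_reference`: genome, models, proteins,
#'   transcripts, truth, params.
#' @export
simulate_reference <- function(params = sim_params(), db_name = "simref") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  comps <- lapply(seq_len(params$n_genes), function(i) {
    build_gene(sprintf("g%03d", i), params)
  })
  finish_reference(comps, params, db_name)
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference '", x$db_name, "': ", length(x$models), " genes, ",
      nrow(x$truth), " junctions, genome ", nchar(x$genome), " nt\n", sep = "")
  invisible(x)
}

# substitute bases i.i.d. at `rate`; targets uniform over the other bases of
# `alphabet`; positions in `protect` (1-based) are never touched
mutate_seq <- function(seq, rate, alphabet, protect = integer()) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in hit) {
    alt <- setdiff(alphabet, chars[i])
    if (!length(alt)) next
    chars[i] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  }
  paste(chars, collapse = "")
}

# redirect any substitution that created a premature in-frame stop; the site
# stays substituted (different base, non-stop codon)
repair_orf <- function(cds, original_cds, alphabet) {
  n_cod <- nchar(cds) %/% 3L
  if (n_cod < 2L) return(cds)
  chars <- strsplit(cds, "")[[1]]
  for (ci in seq_len(n_cod - 1L)) {       # last codon is the real stop
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    cod <- paste(chars[idx], collapse = "")
    if (!cod %in% STOP_CODONS) next
    orig <- substr(original_cds, idx[1], idx[3])
    changed <- idx[chars[idx] != strsplit(orig, "")[[1]]]
    for (i in changed) {
      alts <- setdiff(alphabet, c(chars[i], substr(original_cds, i, i)))
      for (a in c(alts, substr(original_cds, i, i))) {
        chars[i] <- a
        if (!paste(chars[idx], collapse = "") %in% STOP_CODONS) break
      }
      if (!paste(chars[idx], collapse = "") %in% STOP_CODONS) break
    }
  }
  paste(chars, collapse = "")
}

#' Evolve the reference mRNAs into a diverged query transcriptome
#'
#' Applies i.i.d. substitutions at the given per-site rate to every mature
#' transcript. Junction positions are unchanged (substitution-only; an
#' exon-structure-preserving indel mode is deliberately not the default).
#' With `preserve_orf` (default), substitutions that would create a
#' premature in-frame stop within the CDS are redirected to another base —
#' the footprint of purifying selection against nonsense mutations; the
#' site still counts as substituted.
#'
#' @param ref A `sim_reference`.
#' @param divergence Per-site substitution probability (defaults to
#'   `ref$params$divergence`).
#' @param seed RNG seed.
#' @param preserve_orf Redirect nonsense substitutions within the CDS.
#' @return List of class `sim_query`: transcripts (named character vector),
#'   truth (same positions as the reference truth), divergence, seed.
#' @export
evolve_transcripts <- function(ref, divergence = NULL, seed = 1L,
                               preserve_orf = TRUE) {
  stopifnot(inherits(ref, "sim_reference"))
  divergence <- divergence %||% ref$params$divergence
  if (divergence < 0 || divergence > 0.5) sp_stop("divergence in [0, 0.5]")
  set.seed(as.integer(seed))
  alphabet <- sim_alphabet(ref$params)
  out <- character(length(ref$transcripts))
  names(out) <- names(ref$transcripts)
  for (tid in names(ref$transcripts)) {
    comp <- NULL
    for (c0 in ref$components) if (c0$gene_id == tid) { comp <- c0; break }
    tr <- ref$transcripts[[tid]]
    mut <- mutate_seq(tr, divergence, alphabet)
    if (preserve_orf && !is.null(comp)) {
      u5 <- nchar(comp$utr5); cl <- nchar(comp$cds)
      cds_mut <- substr(mut, u5 + 1L, u5 + cl)
      cds_fix <- repair_orf(cds_mut, comp$cds, alphabet)
      mut <- paste0(substr(mut, 1L, u5), cds_fix,
                    substr(mut, u5 + cl + 1L, nchar(mut)))
    }
    out[tid] <- mut
  }
  structure(list(transcripts = out,
                 truth = ref$truth[, c("transcript_id", "position",
                                       "cds_offset", "phase")],
                 divergence = divergence, seed = as.integer(seed)),
            class = "sim_query")
}

#' Evolve a whole reference species (for multi-reference simulations)
#'
#' Derives a sister reference species from a common ancestor: every gene's
#' CDS (ORF-preserving, start/stop codons kept), UTRs and intron interiors
#' (GT..AG dinucleotides kept) are substituted i.i.d. at `divergence`, and
#' the genome, annotation, proteins, transcripts and truth are reassembled
#' with unchanged gene structure.
#'
#' @param ref A `sim_reference` (the ancestor).
#' @param divergence Per-site substitution probability.
#' @param seed RNG seed.
#' @param db_name Name of the derived reference.
#' @return A new `sim_reference`.
#' @export
evolve_reference <- function(ref, divergence, seed, db_name) {
  stopifnot(inherits(ref, "sim_reference"))
  set.seed(as.integer(seed))
  alphabet <- sim_alphabet(ref$params)
  comps <- lapply(ref$components, function(comp) {
    cl <- nchar(comp$cds)
    protect <- c(1:3, (cl - 2L):cl)        # keep ATG and the stop codon
    cds_mut <- mutate_seq(comp$cds, divergence, alphabet, protect = protect)
    cds_mut <- repair_orf(cds_mut, comp$cds, alphabet)
    comp$cds <- cds_mut
    comp$utr5 <- mutate_seq(comp$utr5, divergence, alphabet)
    comp$utr3 <- mutate_seq(comp$utr3, divergence, alphabet)
    comp$intron_seqs <- vapply(comp$intron_seqs, function(s) {
      inner <- mutate_seq(substr(s, 3L, nchar(s) - 2L), divergence, alphabet)
      paste0("GT", inner, "AG")
    }, character(1), USE.NAMES = FALSE)
    # rebuild exon bodies from the mutated CDS
    stops <- cumsum(comp$cores)
    starts <- c(0L, head(stops, -1L))
    bodies <- substring(comp$cds, starts + 1L, stops)
    bodies[1] <- paste0(comp$utr5, bodies[1])
    bodies[length(bodies)] <- paste0(bodies[length(bodies)], comp$utr3)
    comp$exon_seqs <- bodies
    comp
  })
  finish_reference(comps, ref$params, db_name)
}

#' Write a simulated reference to disk in pipeline formats
#'
#' Emits `genome.fa`, `annotation.genePred`, `proteins.faa`,
#' `transcripts.fa` and `truth.tsv` under `dir` — exactly the formats
#' [build_reference_db()] and [predict_junctions()] consume.
#'
#' @param ref A `sim_reference`.
#' @param dir Output directory.
#' @export
write_sim_reference <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_fasta(ref$proteins, file.path(dir, "proteins.faa"))
  write_fasta(ref$transcripts, file.path(dir, "transcripts.fa"))
  lines <- vapply(ref$models, function(m) {
    paste(m$transcript_id, m$chrom, m$strand, min(m$exon_starts),
          max(m$exon_ends), m$cds_start, m$cds_end, length(m$exon_starts),
          paste0(paste(m$exon_starts, collapse = ","), ","),
          paste0(paste(m$exon_ends, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, file.path(dir, "annotation.genePred"))
  write_truth(ref$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Materialize the standard named fixture set used by the test suite
#'
#' @param dir Output directory.
#' @param seed Base seed.
#' @return Invisibly, the list of written subdirectories.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  ref <- simulate_reference(sim_params(seed = seed), db_name = "simref")
  write_sim_reference(ref, file.path(dir, "reference"))
  q <- evolve_transcripts(ref, divergence = 0.05, seed = seed + 1L)
  dir.create(file.path(dir, "query"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(q$transcripts, file.path(dir, "query", "transcripts.fa"))
  write_truth(q$truth, file.path(dir, "query", "truth.tsv"))
  invisible(file.path(dir, c("reference", "query")))
}
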