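test_that("codon/phase arithmetic maps CDS offsets correctly", {
  cp <- cds_offset_to_codon_phase(c(9L, 7L, 0L))
  expect_equal(cp$codon_index, c(3L, 2L, 0L))
  expect_equal(cp$phase, c(0L, 1L, 0L))
  expect_error(cds_offset_to_codon_phase(-1L), "non-negative")
})

test_that("genePred and GTF parses of the same gene are identical", {
  gp <- "t1\tchrT\t+\t0\t118\t0\t118\t2\t0,109,\t9,118,"
  f1 <- withr::local_tempfile(fileext = ".genePred")
  writeLines(gp, f1)
  m1 <- parse_gene_models(f1, dialect = "genepred")
  expect_length(m1, 1)
  expect_equal(m1[[1]]$exon_starts, c(0L, 109L))
  expect_equal(m1[[1]]$exon_ends, c(9L, 118L))

  gtf <- c(
    paste0("chrT\ttoy\texon\t1\t9\t.\t+\t.\t",
           'gene_id "t1"; transcript_id "t1";'),
    paste0("chrT\ttoy\texon\t110\t118\t.\t+\t.\t",
           'gene_id "t1"; transcript_id "t1";'),
    paste0("chrT\ttoy\tCDS\t1\t9\t.\t+\t0\t",
           'gene_id "t1"; transcript_id "t1";'),
    paste0("chrT\ttoy\tCDS\t110\t118\t.\t+\t0\t",
           'gene_id "t1"; transcript_id "t1";'))
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f2)
  m2 <- parse_gene_models(f2, dialect = "gtf")
  expect_equal(m2[[1]]$exon_starts, m1[[1]]$exon_starts)
  expect_equal(m2[[1]]$exon_ends, m1[[1]]$exon_ends)
  expect_equal(m2[[1]]$cds_start, m1[[1]]$cds_start)
  expect_equal(m2[[1]]$cds_end, m1[[1]]$cds_end)
})

test_that("models with CDS length not divisible by 3 are rejected", {
  gp <- c("bad\tchrT\t+\t0\t100\t0\t100\t1\t0,\t100,",
          "ok\tchrT\t+\t0\t99\t0\t99\t1\t0,\t99,")
  f <- withr::local_tempfile()
  writeLines(gp, f)
  expect_warning(m <- parse_gene_models(f, dialect = "genepred"),
                 "divisible by 3")
  expect_length(m, 1)
  expect_equal(m[[1]]$transcript_id, "ok")
  expect_error(suppressWarnings(
    parse_gene_models(f, dialect = "genepred", on_error = "abort")))
})

test_that("protein and junctions extract from a two-exon gene", {
  toy <- toy_two_exon("ATGGCTGCT", "GCTGCTTAA")
  res <- extract_protein_junctions(toy$model, toy$genome)
  expect_equal(res$protein, "MAAAA")
  expect_equal(res$junctions$codon_index, 3L)
  expect_equal(res$junctions$phase, 0L)

  # 10-nt first exon splits a codon: phase 1
  toy2 <- toy_two_exon("ATGGCTGCTG", "CTGCTTAA")
  res2 <- extract_protein_junctions(toy2$model, toy2$genome)
  expect_equal(res2$protein, "MAAAA")
  expect_equal(res2$junctions$codon_index, 3L)
  expect_equal(res2$junctions$phase, 1L)
})

test_that("minus-strand extraction equals the mirrored plus-strand run", {
  toy <- toy_two_exon("ATGGCTGCT", "GCTGCTTAA", utr5 = "CCCC", utr3 = "TT")
  fwd <- extract_protein_junctions(toy$model, toy$genome)
  mir <- mirror_to_minus(toy$genome, toy$model)
  rev <- extract_protein_junctions(mir$model, mir$genome)
  expect_identical(rev, fwd)
})

test_that("UTR-spanning boundaries are excluded from junction records", {
  # intron inside the 5'UTR only: boundary at CDS offset 0 -> no record
  exon1 <- "CCCC"                       # pure UTR exon
  exon2 <- paste0("ATGGCTGCTGCTGCTTAA")
  genome_seq <- paste0(exon1, "GTAAAAAG", exon2)
  model <- list(gene_id = "u", transcript_id = "u", chrom = "chrT",
                strand = "+",
                exon_starts = c(0L, 12L), exon_ends = c(4L, 12L + nchar(exon2)),
                cds_start = 12L, cds_end = 12L + nchar(exon2))
  res <- extract_protein_junctions(model, c(chrT = genome_seq))
  expect_equal(nrow(res$junctions), 0)
  expect_equal(res$protein, "MAAAA")
})

test_that("internal stop codons reject the model", {
  toy <- toy_two_exon("ATGTAAGCT", "GCTGCTTAA")
  expect_error(extract_protein_junctions(toy$model, toy$genome),
               "internal stop")
})

test_that("annotation quality counts exact matches over the id union", {
  a <- c(t1 = "MA", t2 = "MC", t3 = "MD", t4 = "ME")
  b <- c(t1 = "MA", t2 = "MC", t3 = "MD", t4 = "MX")
  expect_equal(compute_annotation_quality(a, b), 0.75)
  expect_equal(compute_annotation_quality(a, a), 1.0)
  expect_equal(compute_annotation_quality(c(x = "M", y = "M"),
                                          c(z = "M", w = "M")), 0.0)
  expect_error(compute_annotation_quality(character(), character()))
})

test_that("database build filters, deduplicates and records quality", {
  ref <- simulate_reference(sim_params(n_genes = 4, seed = 11), "toy")
  # corrupt one provided protein: it must be filtered out and lower quality
  prov <- ref$proteins
  prov[2] <- paste0(prov[2], "Q")
  expect_no_warning(db <- build_reference_db(ref$genome, ref$models, prov,
                                             db_name = "toy"))
  expect_s3_class(db, "junction_db")
  expect_length(db$proteins, 3)
  expect_equal(db$annotation_quality, 0.75)
  # no provided proteins: all models kept, quality 1 by convention
  db2 <- build_reference_db(ref$genome, ref$models, db_name = "toy")
  expect_length(db2$proteins, 4)
  expect_equal(db2$annotation_quality, 1.0)
})

test_that("identical protein sequences collapse to one DB entry", {
  toy <- toy_two_exon("ATGGCTGCT", "GCTGCTTAA")
  m1 <- toy$model
  m2 <- toy$model; m2$gene_id <- m2$transcript_id <- "t2"
  db <- build_reference_db(toy$genome, list(m1, m2), db_name = "dup")
  expect_length(db$proteins, 1)
  expect_equal(names(db$proteins), "t1")
})

test_that("round-trip: 3 x protein length equals CDS length minus stop", {
  ref <- simulate_reference(sim_params(n_genes = 6, seed = 3), "rt")
  db <- build_reference_db(ref$genome, ref$models, ref$proteins, "rt")
  for (id in names(db$proteins)) {
    res <- extract_protein_junctions(
      ref$models[[which(vapply(ref$models, `[[`, "", "transcript_id") == id)]],
      ref$genome)
    expect_equal(3L * nchar(db$proteins[[id]]), res$cds_len - 3L)
  }
})

test_that("strand mirroring a simulated reference leaves the DB unchanged", {
  ref <- simulate_reference(sim_params(n_genes = 5, seed = 21,
                                       minus_strand_prob = 0), "mir")
  db_fwd <- build_reference_db(ref$genome, ref$models, db_name = "mir")
  L <- nchar(ref$genome[["chr1"]])
  rc <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref$genome[["chr1"]]))))
  models_rev <- lapply(ref$models, function(m) {
    m2 <- m
    m2$strand <- "-"
    m2$exon_starts <- rev(L - m$exon_ends)
    m2$exon_ends <- rev(L - m$exon_starts)
    m2$cds_start <- L - m$cds_end
    m2$cds_end <- L - m$cds_start
    m2
  })
  db_rev <- build_reference_db(rc, models_rev, db_name = "mir")
  expect_identical(db_fwd$proteins, db_rev$proteins)
  expect_identical(db_fwd$junctions, db_rev$junctions)
})

test_that("DB serialization round-trips and loader validates", {
  ref <- simulate_reference(sim_params(n_genes = 3, seed = 9), "ser")
  db <- build_reference_db(ref$genome, ref$models, ref$proteins, "ser")
  d <- withr::local_tempdir()
  save_db(db, d)
  db2 <- load_db(d)
  expect_equal(db2$proteins, db$proteins)
  expect_equal(db2$junctions, db$junctions)
  expect_equal(db2$annotation_quality, db$annotation_quality)
  # corrupt: junction referencing unknown protein
  j <- read.delim(file.path(d, "junctions.tsv"))
  j$protein_id[1] <- "nosuch"
  write.table(j, file.path(d, "junctions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_db(d), "unknown protein")
  # missing meta.json
  file.remove(file.path(d, "meta.json"))
  expect_error(load_db(d), "missing")
})
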