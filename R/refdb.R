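#' Reference junction database
#'
#' A `junction_db` holds non-redundant reference proteins together with the
#' positions of the splice junctions of their encoding transcripts,
#' expressed in protein coordinates: the index of the codon immediately
#' downstream of (or split by) each junction, plus the junction's phase
#' (CDS offset mod 3). Phase-0 junctions fall between codons; phase 1/2
#' junctions split a codon and are therefore ambiguous at amino-acid
#' resolution.
#'
#' @param db_name Database name.
#' @param proteins Named character vector of amino-acid sequences.
#' @param junctions Data frame with columns protein_id, codon_index, phase.
#' @param annotation_quality Fraction of transcripts whose provided protein
#'   matched the genome-derived translation.
#' @param build_params List of build parameters (recorded in meta.json).
#' @return An object of class `junction_db`.
#' @export
new_junction_db <- function(db_name, proteins, junctions,
                            annotation_quality = 1.0, build_params = list()) {
  junctions <- data.frame(protein_id = as.character(junctions$protein_id),
                          codon_index = as.integer(junctions$codon_index),
                          phase = as.integer(junctions$phase))
  structure(list(db_name = db_name,
                 proteins = proteins,
                 junctions = junctions,
                 annotation_quality = annotation_quality,
                 build_params = build_params),
            class = "junction_db")
}

#' Validate junction_db invariants; error on violation
#' @param db A `junction_db`.
#' @export
validate_junction_db <- function(db) {
  j <- db$junctions
  if (nrow(j)) {
    unknown <- setdiff(unique(j$protein_id), names(db$proteins))
    if (length(unknown)) {
      sp_stop("junctions reference unknown protein(s): ",
              paste(head(unknown, 3), collapse = ", "))
    }
    if (any(j$phase < 0L | j$phase > 2L)) sp_stop("junction phase outside 0..2")
    plen <- nchar(db$proteins)[j$protein_id]
    if (any(j$codon_index < 0L | j$codon_index >= plen)) {
      sp_stop("junction codon_index outside protein length")
    }
    key <- j$codon_index * 3 + j$phase
    for (sp in split(key, j$protein_id)) {
      if (is.unsorted(sp, strictly = TRUE)) {
        sp_stop("junction list not strictly increasing in (codon_index, phase)")
      }
    }
  }
  if (!is.numeric(db$annotation_quality) ||
      db$annotation_quality < 0 || db$annotation_quality > 1) {
    sp_stop("annotation_quality outside [0, 1]")
  }
  invisible(db)
}

#' @export
print.junction_db <- function(x, ...) {
  cat("junction_db '", x$db_name, "': ", length(x$proteins), " proteins, ",
      nrow(x$junctions), " junctions, annotation quality ",
      format(x$annotation_quality, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert a CDS nucleotide offset to (codon index, phase)
#'
#' @param cds_offset Non-negative integer vector of CDS nucleotide offsets
#'   (0-based; the offset of the first base of the downstream exon).
#' @return Data frame with columns codon_index and phase.
#' @export
cds_offset_to_codon_phase <- function(cds_offset) {
  if (any(cds_offset < 0)) sp_stop("cds_offset must be non-negative")
  data.frame(codon_index = as.integer(cds_offset %/% 3L),
             phase = as.integer(cds_offset %% 3L))
}

# ---- gene model parsing -----------------------------------------------------

new_gene_model <- function(gene_id, transcript_id, chrom, strand,
                           exon_starts, exon_ends, cds_start, cds_end) {
  list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
       strand = strand,
       exon_starts = as.integer(exon_starts), exon_ends = as.integer(exon_ends),
       cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
}

check_gene_model <- function(m) {
  n <- length(m$exon_starts)
  if (n == 0L || length(m$exon_ends) != n) return("no exons")
  if (any(m$exon_ends <= m$exon_starts)) return("empty exon")
  if (is.unsorted(m$exon_starts, strictly = TRUE) ||
      any(m$exon_starts[-1] < m$exon_ends[-n])) {
    return("exons overlapping or unsorted")
  }
  if (m$cds_end <= m$cds_start) return("empty CDS")
  # CDS must fall inside the exon union
  cs <- pmax(m$exon_starts, m$cds_start)
  ce <- pmin(m$exon_ends, m$cds_end)
  cds_len <- sum(pmax(0L, ce - cs))
  covered <- cds_len
  # ends of the CDS interval must be exonic
  in_exon <- function(p) any(m$exon_starts <= p & p < m$exon_ends)
  if (!in_exon(m$cds_start) || !in_exon(m$cds_end - 1L)) {
    return("CDS not contained in exon union")
  }
  if (covered %% 3L != 0L) return("spliced CDS length not divisible by 3")
  NULL
}

parse_genepred_line <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  off <- if (length(f) >= 3 && f[3] %in% c("+", "-")) 0L else
         if (length(f) >= 4 && f[4] %in% c("+", "-")) 1L else
         sp_stop("genePred line ", lineno, ": cannot locate strand column")
  if (length(f) < off + 10L) sp_stop("genePred line ", lineno, ": too few fields")
  g <- f[(off + 1):(off + 10)]
  split_coords <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1]])
  new_gene_model(gene_id = g[1], transcript_id = g[1], chrom = g[2],
                 strand = g[3],
                 exon_starts = split_coords(g[9]), exon_ends = split_coords(g[10]),
                 cds_start = as.integer(g[6]), cds_end = as.integer(g[7]))
}

parse_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (is.null(md$transcript_id)) {
    sp_stop("GTF lacks transcript_id attributes")
  }
  ids <- as.character(md$transcript_id)
  out <- list()
  for (tid in unique(ids)) {
    sel <- ids == tid
    sub <- gr[sel]
    types <- as.character(md$type[sel])
    ex <- sub[types == "exon"]
    cds <- sub[types %in% c("CDS", "stop_codon")]
    if (length(ex) == 0L || length(cds) == 0L) next
    o <- order(GenomicRanges::start(ex))
    ex <- ex[o]
    gene_id <- as.character(md$gene_id[sel][1] %||% tid)
    out[[tid]] <- new_gene_model(
      gene_id = gene_id, transcript_id = tid,
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(GenomicRanges::strand(ex))[1],
      exon_starts = GenomicRanges::start(ex) - 1L,
      exon_ends = GenomicRanges::end(ex),
      cds_start = min(GenomicRanges::start(cds)) - 1L,
      cds_end = max(GenomicRanges::end(cds)))
  }
  unname(out)
}

#' Parse gene models from genePred or GTF annotation
#'
#' Coordinates are normalized to 0-based half-open; minus-strand exon lists
#' are kept in genomic ascending order with the strand flag. Models that
#' violate structural invariants (overlapping exons, CDS outside the exon
#' union, spliced CDS length not divisible by 3) are skipped with a warning,
#' or abort the parse, per `on_error`.
#'
#' @param path Annotation file path.
#' @param dialect `"auto"` (by extension), `"genepred"` or `"gtf"`.
#' @param on_error `"skip"` (default) or `"abort"` for malformed/invalid
#'   records.
#' @return List of gene models.
#' @export
parse_gene_models <- function(path, dialect = c("auto", "genepred", "gtf"),
                              on_error = c("skip", "abort")) {
  dialect <- match.arg(dialect)
  on_error <- match.arg(on_error)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "genepred"
  }
  if (dialect == "gtf") {
    models <- parse_gtf_models(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    models <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      m <- tryCatch(parse_genepred_line(lines[i], i), error = function(e) e)
      if (inherits(m, "error")) {
        if (on_error == "abort") stop(m)
        warning("skipping malformed genePred line ", i, ": ",
                conditionMessage(m), call. = FALSE)
        next
      }
      models[[i]] <- m
    }
    models <- models[!vapply(models, is.null, logical(1))]
  }
  ok <- logical(length(models))
  for (i in seq_along(models)) {
    why <- check_gene_model(models[[i]])
    if (is.null(why)) ok[i] <- TRUE else {
      msg <- paste0("gene model '", models[[i]]$transcript_id, "' rejected: ", why)
      if (on_error == "abort") sp_stop(msg)
      warning(msg, call. = FALSE)
    }
  }
  models[ok]
}

# ---- protein/junction extraction -------------------------------------------

#' Extract the protein and junction records from one gene model
#'
#' Translates the spliced CDS (reverse-complementing minus-strand models)
#' and emits one junction record per internal CDS exon boundary, positioned
#' at the CDS nucleotide offset of the first base of the downstream exon.
#' Boundaries falling in the UTRs (offset 0 or beyond the last CDS codon)
#' are not representable in protein space and are excluded.
#'
#' @param model A gene model from [parse_gene_models()].
#' @param genome Named character vector of chromosome sequences.
#' @return List with elements `protein` (amino-acid string, trailing stop
#'   removed), `junctions` (data frame codon_index, phase), `cds_len`.
#'   Errors if the model contains an internal stop codon.
#' @export
extract_protein_junctions <- function(model, genome) {
  if (!model$chrom %in% names(genome)) {
    sp_stop("chromosome '", model$chrom, "' not in genome")
  }
  why <- check_gene_model(model)
  if (!is.null(why)) sp_stop("invalid gene model '", model$transcript_id, "': ", why)
  chrom <- genome[[model$chrom]]
  cs <- pmax(model$exon_starts, model$cds_start)
  ce <- pmin(model$exon_ends, model$cds_end)
  keep <- ce > cs
  cs <- cs[keep]; ce <- ce[keep]
  pieces <- substring(chrom, cs + 1L, ce)  # 0-based half-open -> substring
  lens <- ce - cs
  cds_nt <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    cds_nt <- revcomp(cds_nt)
    lens <- rev(lens)
  }
  cds_len <- nchar(cds_nt)
  aa <- translate_nt(cds_nt)
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) {
    sp_stop("internal stop codon in '", model$transcript_id, "'")
  }
  offsets <- head(cumsum(lens), -1L)
  offsets <- offsets[offsets > 0L & offsets < cds_len]
  jn <- cds_offset_to_codon_phase(offsets)
  jn <- jn[jn$codon_index < nchar(aa), , drop = FALSE]
  rownames(jn) <- NULL
  list(protein = aa, junctions = jn, cds_len = cds_len)
}

#' Annotation quality: fraction of identical provided/derived proteins
#'
#' Compares the supplied protein set (dataset A) against the proteins
#' re-derived from genome + annotation (dataset B); the quality is the
#' number of ids whose two sequences are exactly identical over the total
#' number of ids in the union of the two sets (ids present on one side only
#' count as non-identical).
#'
#' @param provided_proteins,derived_proteins Named character vectors keyed
#'   by transcript/protein id.
#' @return Fraction in \[0, 1\].
#' @export
compute_annotation_quality <- function(provided_proteins, derived_proteins) {
  ids <- union(names(provided_proteins), names(derived_proteins))
  if (length(ids) == 0L) sp_stop("annotation quality undefined for empty input")
  same <- vapply(ids, function(id) {
    a <- provided_proteins[id]; b <- derived_proteins[id]
    !is.na(a) && !is.na(b) && identical(unname(a), unname(b))
  }, logical(1))
  mean(same)
}

#' Build a reference junction database
#'
#' Derives a protein and its junction records from every valid gene model.
#' When a provided protein set is given, only transcripts whose derived
#' translation is exactly identical to the provided protein are retained
#' (the annotation-consistency filter), and the resulting fraction is
#' recorded as the database's annotation quality. Redundant identical
#' protein sequences are collapsed to a single entry (first id kept).
#'
#' @param genome Named character vector of chromosome sequences, or FASTA
#'   path.
#' @param annotation List of gene models, or annotation file path (genePred
#'   or GTF).
#' @param provided_proteins Optional named character vector (or FASTA path)
#'   of transcript proteins used for the consistency filter.
#' @param db_name Database name.
#' @param on_error `"skip"` or `"abort"` for invalid gene models.
#' @return A `junction_db`.
#' @export
build_reference_db <- function(genome, annotation, provided_proteins = NULL,
                               db_name = "refdb",
                               on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome, alphabet = "dna")
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- parse_gene_models(annotation, on_error = on_error)
  }
  if (is.character(provided_proteins) && length(provided_proteins) == 1L &&
      file.exists(provided_proteins)) {
    provided_proteins <- read_fasta(provided_proteins, alphabet = "protein")
  }
  derived <- list(); junc <- list()
  for (m in annotation) {
    res <- tryCatch(extract_protein_junctions(m, genome), error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") stop(res)
      warning("skipping '", m$transcript_id, "': ", conditionMessage(res),
              call. = FALSE)
      next
    }
    derived[[m$transcript_id]] <- res$protein
    junc[[m$transcript_id]] <- res$junctions
  }
  derived <- unlist(derived) %||% character()
  if (!is.null(provided_proteins)) {
    aq <- compute_annotation_quality(provided_proteins, derived)
    keep <- names(derived)[vapply(names(derived), function(id) {
      !is.na(provided_proteins[id]) &&
        identical(unname(provided_proteins[id]), unname(derived[id]))
    }, logical(1))]
    derived <- derived[keep]
  } else {
    aq <- 1.0
    sp_log("no provided proteins: annotation quality set to 1.0 by convention")
  }
  if (length(derived) == 0L) sp_stop("no transcripts survived database build")
  # collapse identical protein sequences, first id kept (input order)
  keep <- !duplicated(unname(derived))
  dropped <- sum(!keep)
  if (dropped) sp_log(dropped, " redundant identical protein(s) collapsed")
  derived <- derived[keep]
  jdf <- do.call(rbind, lapply(names(derived), function(id) {
    j <- junc[[id]]
    if (nrow(j) == 0L) return(NULL)
    cbind(data.frame(protein_id = id), j)
  }))
  if (is.null(jdf)) {
    jdf <- data.frame(protein_id = character(), codon_index = integer(),
                      phase = integer())
  }
  db <- new_junction_db(db_name = db_name, proteins = derived, junctions = jdf,
                        annotation_quality = aq,
                        build_params = list(n_models = length(annotation)))
  validate_junction_db(db)
  db
}
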