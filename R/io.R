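IUPAC_DNA <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYBJZXU*", "")[[1]]

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and, for nucleotide input, U is normalized to T.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`; controls validation and U->T
#'   normalization.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) sp_stop("cannot read FASTA '", path, "': ",
                                             conditionMessage(e)))
  if (length(ss) == 0L) sp_stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    sp_stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(ss))
  if (alphabet == "dna") {
    seqs <- chartr("U", "T", seqs)
    allowed <- IUPAC_DNA
  } else {
    allowed <- AA_LETTERS
  }
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    sp_stop("non-IUPAC characters in record '", ids[which(bad)[1]], "'")
  }
  setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

DB_FORMAT_VERSION <- 1L

#' Save a reference junction database to a directory
#'
#' The on-disk layout is `proteins.faa` (FASTA), `junctions.tsv`
#' (protein_id, codon_index, phase) and `meta.json` (name, annotation
#' quality, build parameters, format version).
#'
#' @param db A `junction_db` object from [build_reference_db()].
#' @param dir Output directory (created if needed).
#' @export
save_db <- function(db, dir) {
  stopifnot(inherits(db, "junction_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(db$proteins, file.path(dir, "proteins.faa"))
  write.table(db$junctions, file.path(dir, "junctions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(db_name = db$db_name,
               annotation_quality = db$annotation_quality,
               format_version = DB_FORMAT_VERSION,
               build_params = db$build_params %||% list())
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a reference junction database from a directory
#'
#' Re-validates all structural invariants (junction protein ids present,
#' per-protein junction lists strictly increasing, codon indices within
#' protein length).
#'
#' @param dir Directory written by [save_db()].
#' @return A `junction_db` object.
#' @export
load_db <- function(dir) {
  need <- file.path(dir, c("proteins.faa", "junctions.tsv", "meta.json"))
  miss <- need[!file.exists(need)]
  if (length(miss)) sp_stop("database at '", dir, "' is missing: ",
                            paste(basename(miss), collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (!identical(as.integer(meta$format_version %||% -1L), DB_FORMAT_VERSION)) {
    sp_stop("database format version mismatch at '", dir, "'")
  }
  proteins <- read_fasta(file.path(dir, "proteins.faa"), alphabet = "protein")
  junc <- read.delim(file.path(dir, "junctions.tsv"),
                     colClasses = c("character", "integer", "integer"))
  db <- new_junction_db(db_name = meta$db_name,
                        proteins = proteins,
                        junctions = junc,
                        annotation_quality = as.numeric(meta$annotation_quality),
                        build_params = meta$build_params)
  validate_junction_db(db)
  db
}

#' Write junction predictions as TSV or BED
#'
#' Positions are 0-based transcript coordinates of the first base of the
#' downstream exon. BED intervals cover that single base,
#' `[position, position + 1)`. Output is stably sorted by
#' (transcript_id, position).
#'
#' @param predictions Prediction data frame (see [predict_junctions()]).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param one_based If `TRUE`, TSV positions are shifted to 1-based (for
#'   primer-design use); BED output is unaffected (BED is 0-based by
#'   definition).
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "bed"),
                              one_based = FALSE) {
  format <- match.arg(format)
  cols <- c("transcript_id", "position", "resolution", "motif_score",
            "db_name", "subject_id", "e_value")
  extra <- intersect(c("support_count", "supporting_dbs"), names(predictions))
  if (nrow(predictions)) {
    predictions <- predictions[order(predictions$transcript_id,
                                     predictions$position), , drop = FALSE]
  }
  if (format == "tsv") {
    out <- predictions[, c(cols, extra), drop = FALSE]
    if (one_based && nrow(out)) out$position <- out$position + 1L
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(predictions)) {
      ms <- predictions$motif_score
      ms[!is.finite(ms)] <- min(ms[is.finite(ms)], 0)
      rng <- range(ms)
      sc <- if (diff(rng) > 0) round(1000 * (ms - rng[1]) / diff(rng)) else
        rep(500L, length(ms))
      bed <- data.frame(chrom = predictions$transcript_id,
                        start = predictions$position,
                        end = predictions$position + 1L,
                        name = paste0(predictions$db_name, ":",
                                      predictions$subject_id),
                        score = as.integer(sc),
                        strand = "+")
    } else {
      bed <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer(), strand = character())
    }
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read/write junction truth tables (transcript_id, position)
#'
#' The same two-column TSV the database builder and simulator emit for
#' spliced transcripts; positions 0-based.
#' @param path File path.
#' @export
read_truth <- function(path) {
  tr <- read.delim(path, colClasses = NA)
  if (!all(c("transcript_id", "position") %in% names(tr))) {
    sp_stop("truth table must have columns transcript_id, position")
  }
  tr$transcript_id <- as.character(tr$transcript_id)
  tr$position <- as.integer(tr$position)
  tr
}

#' @rdname read_truth
#' @param truth Data frame with columns transcript_id, position (extra
#'   columns are preserved).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
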