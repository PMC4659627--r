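#' @keywords internal
"_PACKAGE"

#' @importFrom stats median setNames
#' @importFrom utils head read.delim write.table
NULL

.sp_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package-level progress/log messages
#'
#' Emitted through [message()] so they can be suppressed; controlled by
#' `options(spliceproj.verbose = FALSE)`.
#' @noRd
sp_log <- function(...) {
  if (isTRUE(getOption("spliceproj.verbose", TRUE))) {
    message("[spliceproj] ", ...)
  }
  invisible(NULL)
}

sp_stop <- function(...) stop(..., call. = FALSE)

#' Reverse-complement a nucleotide string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS nucleotide string to amino acids (standard code)
#'
#' Length must be a multiple of 3 (trailing partial codons are the caller's
#' responsibility). Codons containing ambiguity letters translate to X.
#' Vectorized lookup against Biostrings::GENETIC_CODE.
#' @noRd
translate_nt <- function(x) {
  n <- nchar(x)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(x, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Fetch a scoring matrix shipped with Biostrings by name, cached
#' @noRd
get_submatrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.sp_env[[key]])) return(.sp_env[[key]])
  ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
          "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% ok) sp_stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  .sp_env[[key]] <- e[[name]]
  .sp_env[[key]]
}

#' Integer ranges expressed as length-1 or length-2 vectors
#' @noRd
as_range <- function(x, what) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    sp_stop("invalid range for ", what)
  }
  as.integer(x)
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep.int(rng[1], n) else
    sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

#' Merge a set of 0-based half-open intervals and return total covered width
#' @noRd
union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i]) else {
      tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i]
    }
  }
  tot + (ce - cs)
}
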