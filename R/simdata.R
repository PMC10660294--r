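#' Generate random peptide sequences
#'
#' Residues are drawn i.i.d. uniformly over the 20-letter alphabet using R's
#' integer RNG stream, so output is reproducible for a given seed across
#' platforms.  Uniform composition (rather than proteome-biased) is the
#' simplest model consistent with unbiased simulated peptides; see the
#' methods vignette.
#'
#' @param n Number of sequences (>= 1).
#' @param length Residues per sequence (>= 1).
#' @param rng_seed Integer seed.
#' @return Named character vector of sequences (`peptide_1` ...), with
#'   attribute `rng_seed`.
#' @examples
#' random_peptides(2, 30, rng_seed = 1)
#' @export
random_peptides <- function(n, length, rng_seed = 42L) {
  n <- as.integer(n)
  length <- as.integer(length)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(rng_seed))
  draws <- sample.int(20L, n * length, replace = TRUE)
  letters20 <- aa_alphabet()
  seqs <- vapply(seq_len(n), function(i) {
    paste(letters20[draws[((i - 1L) * length + 1L):(i * length)]], collapse = "")
  }, character(1L))
  names(seqs) <- paste0("peptide_", seq_len(n))
  attr(seqs, "rng_seed") <- as.integer(rng_seed)
  seqs
}

#' Read peptide sequences from FASTA
#'
#' Parsing is delegated to `Biostrings::readAAStringSet` (wrapped lines and
#' gzip-compressed files are transparently supported); residues are
#' uppercased on read and non-alphabet characters are preserved — the
#' hashing functions flag them later via window invalidation.  A light
#' pre-scan reports malformed headers and empty files with line numbers.
#'
#' @param path FASTA file (optionally .gz).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA format error at line 1: file '", path, "' is empty")
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error at line ", first,
         ": expected a '>' header, got '", substr(lines[first], 1L, 30L), "'")
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write peptide sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("peptide_", seq_along(seqs))
  x <- Biostrings::AAStringSet(stats::setNames(as.character(seqs), nm))
  Biostrings::writeXStringSet(x, path, width = as.integer(width),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
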