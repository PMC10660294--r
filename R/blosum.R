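# Standard BLOSUM62 substitution scores (half-bit units), embedded as
# constants in the conventional NCBI residue order.
.blosum62_text <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4
"

.parse_score_text <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("substitution matrix: need a header row and at least one score row")
  }
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[`, character(1L), 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v) || length(v) != length(header)) {
      stop("substitution matrix: malformed score row for '", r[1L], "'")
    }
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(lab, header)
  m
}

#' BLOSUM62 substitution scores
#'
#' The standard 20x20 BLOSUM62 matrix, restricted to the
#' [aa_alphabet()] residues and ordered accordingly.  Positive entries mark
#' biochemically similar residue pairs; the matrix drives the level-2 and
#' level-3 degeneracy partitions (see [derive_partition()]).
#'
#' @return Symmetric integer matrix with residue dimnames.
#' @examples
#' blosum62()["I", "L"]  # 2: isoleucine/leucine are readily exchanged
#' @export
blosum62 <- function() {
  if (is.null(.ph_env$blosum62)) {
    m <- .parse_score_text(strsplit(.blosum62_text, "\n")[[1L]])
    aa <- aa_alphabet()
    m <- m[aa, aa]
    stopifnot(identical(m, t(m)), all(diag(m) > 0L))
    .ph_env$blosum62 <- m
  }
  .ph_env$blosum62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated format used for NCBI scoring matrices
#' (`#` comment lines, a header row of residue codes, then one labelled row
#' per residue).  Columns beyond the 20 standard residues (e.g. `B`, `Z`,
#' `X`, `*`) are dropped.
#'
#' @param path Path to the matrix file.
#' @return Symmetric integer matrix over [aa_alphabet()].
#' @export
read_score_matrix <- function(path) {
  m <- .parse_score_text(readLines(path))
  aa <- aa_alphabet()
  missing <- setdiff(aa, intersect(rownames(m), colnames(m)))
  if (length(missing) > 0L) {
    stop("substitution matrix is missing residues: ", paste(missing, collapse = ", "))
  }
  m <- m[aa, aa]
  if (!identical(m, t(m))) stop("substitution matrix must be symmetric")
  m
}
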