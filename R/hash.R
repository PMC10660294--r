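#' Split-register bit rotation (srol)
#'
#' Treats a 64-bit word as two independent cyclic registers — bits 0–32
#' (33 bits) and bits 33–63 (31 bits) — and rotates each left by `n`.
#' Because 33 and 31 are coprime, the compound rotation has period
#' `lcm(33, 31) = 1023` instead of the 64 of a plain rotation, so k-mer
#' positions remain distinguishable for any practical k.  `srol` is a bit
#' permutation: bijective and linear over XOR.
#'
#' @param x Character vector of 16-digit hex words.
#' @param n Nonnegative rotation count (default 1).
#' @return Character vector of rotated hex words.
#' @examples
#' srol("0000000000000001")          # bit 0 -> bit 1
#' srol("0000000100000000")          # 2^32 wraps to bit 0
#' srol("8000000000000000")          # 2^63 wraps to bit 33
#' @export
srol <- function(x, n = 1L) {
  cpp_srol(x, as.double(n))
}

#' Bitwise XOR of 64-bit hex words
#'
#' @param a,b Character vectors of 16-digit hex words (recycled if scalar).
#' @return Character vector of XORed hex words.
#' @export
xor64 <- function(a, b) cpp_xor64(a, b)

#' Popcount of 64-bit hex words
#'
#' @param x Character vector of 16-digit hex words.
#' @return Integer vector of set-bit counts.
#' @export
popcount64 <- function(x) cpp_popcount(x)

#' Hash single k-mers
#'
#' Base (non-rolling) hash: the XOR over positions `j = 0..k-1` of
#' `srol^(k-1-j)(seed(kmer[j]))`.  Internally the leading chunks go through
#' the precomputed trimer/dimer tables; the result is bit-identical to the
#' naive scan.  Residues outside [aa_alphabet()] raise an error naming the
#' character and its 0-based offset.
#'
#' @param kmers Character vector of k-mers (lengths may differ).
#' @param level Hash level 1, 2 or 3 (ignored when `table` is given).
#' @param table Optional explicit 20-entry seed table.
#' @return Character vector of 16-digit hex hashes.
#' @examples
#' hash_kmer("A") == seed_table(1)[["A"]]
#' hash_kmer("AIM", level = 2) == hash_kmer("ALM", level = 2)  # I ~ L zone
#' @export
hash_kmer <- function(kmers, level = 1L, table = NULL) {
  if (is.null(table)) table <- seed_table(level)
  cpp_hash_kmers(kmers, unname(table))
}

#' One rolling-hash step
#'
#' Advances a window hash by one residue:
#' `srol(prev) XOR srol^k(seed(outgoing)) XOR seed(incoming)`.  Bit-identical
#' to re-hashing the shifted window with [hash_kmer()].
#'
#' @param prev Hex hash of the current window.
#' @param outgoing Residue leaving the window (its first character).
#' @param incoming Residue entering the window (its last character).
#' @param k Window length.
#' @inheritParams hash_kmer
#' @return Hex hash of the shifted window.
#' @export
hash_roll <- function(prev, outgoing, incoming, k, level = 1L, table = NULL) {
  if (is.null(table)) table <- seed_table(level)
  cpp_roll(prev, outgoing, incoming, as.integer(k), unname(table))
}

#' Derive multiple hash values per k-mer
#'
#' Expands one canonical 64-bit hash into `h` values as Bloom filters
#' require.  Index 0 is the canonical hash untouched; index `i > 0`
#' multiplies the base by an odd constant derived from `(i, k)` and applies
#' an xorshift-multiply finalizer.  Each derived map is a bijection of the
#' base, so uniform canonical hashes stay uniform.
#'
#' @param base Character vector of canonical hex hashes.
#' @param h Number of hashes per k-mer (>= 1).
#' @param k The k-mer length the hashes came from (part of the derivation).
#' @return Character matrix, one row per base value, `h` columns; column 1
#'   is the canonical hash.
#' @export
multi_hash <- function(base, h, k) {
  if (length(h) != 1L || is.na(h) || h < 1) stop("number of hashes h must be >= 1")
  cpp_multi_hash(base, as.integer(h), as.integer(k))
}

# pattern spec: "1213..." string or integer vector with entries in 1..3
parse_level_pattern <- function(pattern, k = NULL) {
  if (is.character(pattern) && length(pattern) == 1L) {
    pattern <- suppressWarnings(as.integer(strsplit(pattern, "")[[1L]]))
  }
  pattern <- suppressWarnings(as.integer(pattern))
  if (length(pattern) < 1L || anyNA(pattern) || !all(pattern %in% 1:3)) {
    stop("pattern must consist of levels 1, 2 and 3 only")
  }
  if (!is.null(k) && length(pattern) != k) {
    stop("pattern length (", length(pattern), ") must equal k (", k, ")")
  }
  pattern
}

#' Hash every k-mer window of peptide sequences
#'
#' Streams over each sequence, hashing all length-`k` windows.  In uniform-
#' level mode the first window of a run is evaluated directly and subsequent
#' windows roll in constant time; in pattern mode (per-position hash levels,
#' the spaced-seed analogue) every window is evaluated directly, since mixed
#' seed tables break the rolling cancellation.  Windows containing a
#' non-alphabet character are skipped, and rolling re-initializes at the next
#' fully valid window.
#'
#' @param seqs Character vector of peptide sequences (names become ids).
#' @param k Window length in residues.
#' @param level Hash level 1, 2 or 3 applied at every position.
#' @param pattern Optional multi-level pattern (string like `"1123"` or
#'   integer vector), length `k`; overrides `level`.
#' @param h Hashes per k-mer (see [multi_hash()]).
#' @return Data frame with columns `id`, `pos` (0-based window start) and
#'   `hash1` ... `hash<h>` (hex).  Sequences shorter than `k` contribute no
#'   rows.
#' @examples
#' hash_sequence("ACDEFGHIK", k = 7)
#' @export
hash_sequence <- function(seqs, k = NULL, level = 1L, pattern = NULL, h = 1L) {
  ids <- names(seqs)
  seqs <- as.character(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (!is.null(pattern)) {
    pattern <- parse_level_pattern(pattern, k)
    k <- length(pattern)
    tables <- .all_seed_tables()
  } else {
    if (is.null(k)) stop("k is required")
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    table <- unname(seed_table(level))
  }
  h <- as.integer(h)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    res <- if (is.null(pattern)) {
      cpp_hash_stream(seqs[[i]], k, table, h, TRUE, FALSE)
    } else {
      cpp_pattern_stream(seqs[[i]], pattern, tables, h, TRUE, FALSE)
    }
    n <- length(res$pos)
    if (n == 0L) next
    df <- data.frame(id = rep(ids[[i]], n), pos = res$pos,
                     stringsAsFactors = FALSE)
    hx <- res$hex
    for (j in seq_len(h)) df[[paste0("hash", j)]] <- hx[, j]
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    df <- data.frame(id = character(0L), pos = integer(0L),
                     stringsAsFactors = FALSE)
    for (j in seq_len(h)) df[[paste0("hash", j)]] <- character(0L)
    return(df)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalized canonical hash values of all windows
#'
#' Fast path for the statistical harness: hashes every valid window and
#' returns the canonical values divided by `2^64 - 1`, concatenated across
#' sequences in input order.
#'
#' @inheritParams hash_sequence
#' @return Numeric vector of values in `[0, 1]`.
#' @export
hash_values <- function(seqs, k = NULL, level = 1L, pattern = NULL) {
  seqs <- as.character(seqs)
  if (!is.null(pattern)) {
    pattern <- parse_level_pattern(pattern, k)
    tables <- .all_seed_tables()
    vals <- lapply(seqs, function(s)
      cpp_pattern_stream(s, pattern, tables, 1L, FALSE, TRUE)$norm[, 1L])
  } else {
    if (is.null(k)) stop("k is required")
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    table <- unname(seed_table(level))
    vals <- lapply(seqs, function(s)
      cpp_hash_stream(s, k, table, 1L, FALSE, TRUE)$norm[, 1L])
  }
  unlist(vals, use.names = FALSE)
}
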