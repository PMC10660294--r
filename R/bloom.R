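#' Create a Bloom filter
#'
#' Minimal Bloom filter: an `m`-bit array addressed by `h` hash values per
#' element (`bit = hash mod m`).  Membership queries have no false
#' negatives; the false-positive rate is governed by the occupancy (fraction
#' of set bits) as `occupancy^h`.
#'
#' @param m Number of bits (>= 1).
#' @param h Hash values per element (>= 1).
#' @return An object of class `bloom_filter`.
#' @examples
#' bf <- bloom_filter(m = 1024, h = 3)
#' bf <- bloom_insert(bf, multi_hash(hash_kmer("ACDEF"), h = 3, k = 5))
#' bloom_contains(bf, multi_hash(hash_kmer("ACDEF"), h = 3, k = 5))
#' @export
bloom_filter <- function(m, h = 1L) {
  ptr <- cpp_bloom_new(as.double(m), as.integer(h))
  structure(list(ptr = ptr, m = as.double(m), h = as.integer(h)),
            class = "bloom_filter")
}

.as_hash_matrix <- function(hashes, h) {
  if (is.data.frame(hashes)) {
    cols <- grep("^hash[0-9]+$", names(hashes), value = TRUE)
    hashes <- as.matrix(hashes[cols])
  }
  if (!is.matrix(hashes)) hashes <- matrix(hashes, ncol = h)
  mode(hashes) <- "character"
  hashes
}

#' Insert hashed elements into a Bloom filter
#'
#' @param bf A `bloom_filter`.
#' @param hashes Character matrix of hex hashes, one row per element and
#'   `h` columns (a [hash_sequence()] data frame or a vector when `h = 1`
#'   also works).
#' @return The filter, invisibly (modified in place).
#' @export
bloom_insert <- function(bf, hashes) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_insert(bf$ptr, .as_hash_matrix(hashes, bf$h))
  invisible(bf)
}

#' Query a Bloom filter
#'
#' `TRUE` iff all `h` addressed bits are set; inserted elements always
#' return `TRUE`.
#'
#' @inheritParams bloom_insert
#' @return Logical vector, one entry per row of `hashes`.
#' @export
bloom_contains <- function(bf, hashes) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_contains(bf$ptr, .as_hash_matrix(hashes, bf$h))
}

#' Insert all k-mers of peptide sequences
#'
#' Streaming fast path: rolls over each sequence at the given hash level,
#' expands each canonical hash to the filter's `h` values and inserts them.
#'
#' @inheritParams bloom_insert
#' @param seqs Character vector of peptide sequences.
#' @param k k-mer length.
#' @param level Hash level for the canonical hash.
#' @return Number of k-mers inserted (invisibly returns the count).
#' @export
bloom_insert_peptides <- function(bf, seqs, k, level = 1L) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_insert_seqs(bf$ptr, as.character(seqs), as.integer(k),
                        unname(seed_table(level)))
}

#' Query all k-mers of peptide sequences
#'
#' @inheritParams bloom_insert_peptides
#' @return Named numeric vector `c(n_queries, n_hits)`.
#' @export
bloom_query_peptides <- function(bf, seqs, k, level = 1L) {
  stopifnot(inherits(bf, "bloom_filter"))
  res <- cpp_bloom_query_seqs(bf$ptr, as.character(seqs), as.integer(k),
                              unname(seed_table(level)))
  c(n_queries = res[[1L]], n_hits = res[[2L]])
}

#' Bloom filter occupancy
#'
#' Fraction of bits set; the single-query false-positive probability with
#' `h` hashes is `occupancy^h`.
#'
#' @inheritParams bloom_insert
#' @return Numeric scalar in `[0, 1]`.
#' @export
bloom_occupancy <- function(bf) {
  stopifnot(inherits(bf, "bloom_filter"))
  info <- cpp_bloom_info(bf$ptr)
  info$set_bits / info$m
}

#' Bloom filter metadata
#'
#' @inheritParams bloom_insert
#' @return List with `m`, `h`, `n_inserted`, `set_bits`.
#' @export
bloom_info <- function(bf) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_info(bf$ptr)
}

#' @export
print.bloom_filter <- function(x, ...) {
  info <- cpp_bloom_info(x$ptr)
  cat(sprintf("Bloom filter: m = %.0f bits, h = %d, %.0f insertions, occupancy %.4f\n",
              info$m, info$h, info$n_inserted, info$set_bits / info$m))
  invisible(x)
}

#' Save / load a Bloom filter
#'
#' Binary little-endian layout: magic `"PHBF"`, a 4-byte version, then `m`,
#' `h` and the insertion count as 64-bit words, followed by the packed bit
#' array.
#'
#' @inheritParams bloom_insert
#' @param path File path.
#' @return `bloom_save` returns the path invisibly; `bloom_load` returns a
#'   `bloom_filter`.
#' @export
bloom_save <- function(bf, path) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_save(bf$ptr, path)
  invisible(path)
}

#' @rdname bloom_save
#' @export
bloom_load <- function(path) {
  ptr <- cpp_bloom_load(path)
  info <- cpp_bloom_info(ptr)
  structure(list(ptr = ptr, m = info$m, h = info$h), class = "bloom_filter")
}

#' Theoretical Bloom-filter false-positive rate
#'
#' After `n` insertions into `m` bits with `h` hashes each, the expected
#' occupancy is `q = 1 - (1 - 1/m)^(h n)` and the false-positive rate for an
#' unseen element is `q^h`.
#'
#' @param m Bits in the filter.
#' @param n Elements inserted.
#' @param h Hashes per element.
#' @return Expected false-positive probability.
#' @examples
#' theoretical_fpr(m = 1e6, n = round(1e6 * 0.12556), h = 1)  # ~0.118
#' @export
theoretical_fpr <- function(m, n, h) {
  stopifnot(m >= 1, n >= 0, h >= 1)
  q <- 1 - (1 - 1 / m)^(h * n)
  q^h
}
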