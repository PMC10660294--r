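# Independent bit-vector oracle for the 64-bit operations.
# A word is an integer vector bits[1..64] = bit 0 .. bit 63 (LSB first);
# every operation is done by explicit bit permutation / addition mod 2,
# with no shared code with the package's C++ path.

hex_to_bits <- function(h) {
  nib <- strtoi(strsplit(tolower(h), "")[[1L]], 16L)  # most-significant first
  bits <- integer(64L)
  for (i in 1:16) {
    v <- nib[i]
    pos <- (16L - i) * 4L
    bits[pos + 1:4] <- c(v %% 2L, (v %/% 2L) %% 2L, (v %/% 4L) %% 2L, (v %/% 8L) %% 2L)
  }
  bits
}

bits_to_hex <- function(bits) {
  digits <- strsplit("0123456789abcdef", "")[[1L]]
  out <- character(16L)
  for (i in 1:16) {
    pos <- (16L - i) * 4L
    v <- bits[pos + 1L] + 2L * bits[pos + 2L] + 4L * bits[pos + 3L] + 8L * bits[pos + 4L]
    out[i] <- digits[v + 1L]
  }
  paste(out, collapse = "")
}

# independent rotations of the 33-bit (bits 0-32) and 31-bit (bits 33-63)
# registers, each left by one
srol_bits <- function(bits) {
  low <- bits[1:33]
  high <- bits[34:64]
  c(low[33L], low[1:32], high[31L], high[1:30])
}

srol_n_bits <- function(bits, n) {
  for (i in seq_len(n)) bits <- srol_bits(bits)
  bits
}

xor_bits <- function(a, b) (a + b) %% 2L

# naive scalar base hash: XOR over positions of srol^(k-1-j)(seed(residue))
oracle_hash_base <- function(kmer, table) {
  res <- strsplit(kmer, "")[[1L]]
  k <- length(res)
  acc <- integer(64L)
  for (j in seq_len(k)) {
    acc <- xor_bits(acc, srol_n_bits(hex_to_bits(table[[res[j]]]), k - j))
  }
  bits_to_hex(acc)
}
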