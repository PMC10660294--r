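#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order.
#' This ordering indexes every seed table in the package.  Ambiguity and
#' non-standard codes (B, J, O, U, X, Z, `*`) are deliberately excluded;
#' windows containing them are skipped by the hashing functions.
#'
#' @return Character vector of length 20.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# residue -> 0-based index, NA for non-alphabet characters
aa_index <- function(x) {
  match(toupper(x), aa_alphabet()) - 1L
}
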