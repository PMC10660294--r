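#' Canonical seed-table generator seed
#'
#' The fixed integer (24301, hex 0x5EED) from which the shipped level-1 seed
#' table is generated.  The constant itself is arbitrary; fixing it makes the
#' canonical tables reproducible from source.
#'
#' @return Integer scalar.
#' @export
canonical_seed <- function() 24301L

#' Generate the level-1 (base) seed table
#'
#' Draws 64-bit words from a splitmix64 stream, keeping the first 20 distinct
#' words whose popcount lies in \[30, 34\] — a nearly balanced number of set
#' and clear bits, which keeps XOR combinations of seeds well mixed.
#' Deterministic for a given `rng_seed`.
#'
#' @param rng_seed Integer PRNG seed; the canonical table uses
#'   [canonical_seed()].
#' @return Named character vector of 20 hex words (names are residues),
#'   with attribute `level = 1`.
#' @examples
#' head(generate_base_seeds())
#' @export
generate_base_seeds <- function(rng_seed = canonical_seed()) {
  stopifnot(length(rng_seed) == 1L, is.finite(rng_seed))
  s <- cpp_generate_base_seeds(as.integer(rng_seed))
  names(s) <- aa_alphabet()
  attr(s, "level") <- 1L
  s
}

#' Build a degenerate (level-2/3) seed table
#'
#' Every residue in a degeneracy zone receives the base seed of the zone's
#' lexicographically smallest member, so within-zone substitutions hash
#' identically while different zones keep distinct words.
#'
#' @param base Level-1 seed table from [generate_base_seeds()].
#' @param partition A `degeneracy_partition` (see [derive_partition()]).
#' @return Named character vector of 20 hex words with attribute `level`.
#' @export
build_level_table <- function(base, partition) {
  stopifnot(inherits(partition, "degeneracy_partition"))
  aa <- aa_alphabet()
  if (!identical(names(base), aa)) {
    stop("base must be a complete level-1 seed table over the alphabet")
  }
  tab <- character(20L)
  names(tab) <- aa
  for (g in partition$groups) tab[g] <- base[[min(g)]]
  attr(tab, "level") <- partition$level
  tab
}

#' Canonical seed table for a hash level
#'
#' Level 1 is [generate_base_seeds()] at the canonical seed; levels 2 and 3
#' apply [build_level_table()] with the canonical BLOSUM62 partitions.
#' Tables are cached for the session.
#'
#' @param level 1, 2 or 3.
#' @return Named character vector of 20 hex seed words.
#' @export
seed_table <- function(level = 1L) {
  level <- as.integer(level)
  if (length(level) != 1L || !level %in% 1:3) stop("level must be 1, 2 or 3")
  key <- paste0("seed_table_", level)
  if (is.null(.ph_env[[key]])) {
    .ph_env[[key]] <- if (level == 1L) {
      generate_base_seeds()
    } else {
      build_level_table(seed_table(1L), blosum_partition(level))
    }
  }
  .ph_env[[key]]
}

# all three canonical tables, unclassed, for the C++ pattern interface
.all_seed_tables <- function() {
  lapply(1:3, function(l) unname(seed_table(l)))
}

#' Precomputed dimer and trimer seed tables
#'
#' Expands a seed table to all 400 residue pairs and 8000 triples:
#' `dimer(a, b) = srol(seed(a)) XOR seed(b)` and
#' `trimer(a, b, c) = srol(dimer(a, b)) XOR seed(c)`.  The streaming hasher
#' consumes leading window chunks through these tables when computing the
#' initial (non-rolled) hash; by linearity of `srol` over XOR the result is
#' bit-identical to the residue-by-residue evaluation.
#'
#' @param table A 20-entry seed table.
#' @return List with `dimer` (20x20 character matrix, first residue in rows)
#'   and `trimer` (named character vector of 8000 hex words, names `"ACD"`
#'   etc.).
#' @export
build_nmer_tables <- function(table = seed_table(1L)) {
  aa <- aa_alphabet()
  raw <- cpp_build_nmer_tables(unname(table))
  dimer <- matrix(raw$dimer, nrow = 20L, byrow = TRUE, dimnames = list(aa, aa))
  eg <- expand.grid(c = aa, b = aa, a = aa, stringsAsFactors = FALSE)
  trimer <- raw$trimer
  names(trimer) <- paste0(eg$a, eg$b, eg$c)
  list(dimer = dimer, trimer = trimer)
}

#' Export seed tables as TSV
#'
#' Writes one row per (residue, level) with the hex seed word, for external
#' auditing of the shipped tables.
#'
#' @param path Output file path.
#' @param levels Hash levels to include.
#' @return The path, invisibly.
#' @export
write_seed_tsv <- function(path, levels = 1:3) {
  rows <- do.call(rbind, lapply(levels, function(l) {
    tab <- seed_table(l)
    data.frame(residue = names(tab), level = l, seed = unname(tab),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
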