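test_that("base hash reduces to seed lookups for tiny k", {
  tab <- seed_table(1L)
  expect_identical(hash_kmer("A"), unname(tab[["A"]]))
  expect_identical(hash_kmer("AC"), xor64(srol(tab[["A"]]), tab[["C"]]))
  expect_identical(hash_kmer("ac"), hash_kmer("AC"))  # case-insensitive lookup
})

test_that("base hash is bit-identical to the naive scalar oracle", {
  tab <- seed_table(1L)
  set.seed(5)
  for (k in c(1L, 2L, 3L, 4L, 7L, 12L, 25L)) {
    kmer <- paste(sample(aa_alphabet(), k, replace = TRUE), collapse = "")
    expect_identical(hash_kmer(kmer), oracle_hash_base(kmer, tab),
                     label = paste("k =", k, kmer))
  }
})

test_that("invalid residues raise errors naming character and offset", {
  expect_error(hash_kmer("ACXDE"), "'X' at offset 2")
  expect_error(hash_kmer("*AC"), "offset 0")
  expect_error(hash_kmer(""), "length >= 1")
})

test_that("one rolling step equals re-hashing the shifted window", {
  h_ac <- hash_kmer("AC")
  expect_identical(hash_roll(h_ac, "A", "D", k = 2L), hash_kmer("CD"))
  # homopolymer: identical windows hash identically under rolling
  h_aa <- hash_kmer("AA")
  expect_identical(hash_roll(h_aa, "A", "A", k = 2L), h_aa)
})

test_that("rolled hashes across a sequence equal direct hashes of every window", {
  pep <- random_peptides(1L, 250L, rng_seed = 3L)
  df <- hash_sequence(pep, k = 25L)
  expect_identical(nrow(df), 226L)
  expect_identical(df$pos, 0:225)
  direct <- hash_kmer(substring(pep, 1:226, 25:250))
  expect_identical(df$hash1, direct)
})

test_that("rolling/direct equivalence holds across random sequences, k and levels", {
  set.seed(17)
  for (i in 1:40) {
    len <- sample(10:60, 1L)
    k <- sample(1:min(len, 30L), 1L)
    lev <- sample(1:3, 1L)
    pep <- paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
    df <- hash_sequence(pep, k = k, level = lev)
    direct <- hash_kmer(substring(pep, 1:(len - k + 1L), k:len), level = lev)
    expect_identical(df$hash1, direct, label = paste("len", len, "k", k, "level", lev))
  }
})

test_that("windows containing non-alphabet characters are skipped and rolling restarts", {
  df <- hash_sequence("ACXDE", k = 2L)
  expect_identical(df$pos, c(0L, 3L))
  expect_identical(df$hash1, c(hash_kmer("AC"), hash_kmer("DE")))
  # restart mid-sequence must still agree with direct hashing
  seq2 <- "ACDEFXGHIKLMNP"
  df2 <- hash_sequence(seq2, k = 3L)
  expect_identical(df2$pos, c(0L, 1L, 2L, 6L:11L))
  for (r in seq_len(nrow(df2))) {
    expect_identical(df2$hash1[r], hash_kmer(substr(seq2, df2$pos[r] + 1L, df2$pos[r] + 3L)))
  }
})

test_that("degenerate and edge window counts are honored", {
  expect_identical(nrow(hash_sequence("ACDE", k = 4L)), 1L)      # k == length
  expect_identical(nrow(hash_sequence("ACD", k = 10L)), 0L)      # k > length: empty
  expect_error(hash_sequence("ACD", k = 0L), "k must be >= 1")
})

test_that("level degeneracy: within-zone substitutions leave hashes unchanged", {
  set.seed(23)
  for (lev in 2:3) {
    part <- blosum_partition(lev)
    zones <- Filter(function(g) length(g) > 1L, part$groups)
    base <- paste(sample(aa_alphabet(), 12L, replace = TRUE), collapse = "")
    for (g in zones) {
      pos <- sample(12L, 1L)
      v1 <- paste0(substr(base, 1, pos - 1), g[1L], substr(base, pos + 1, 12L))
      v2 <- paste0(substr(base, 1, pos - 1), g[2L], substr(base, pos + 1, 12L))
      expect_identical(hash_kmer(v1, level = lev), hash_kmer(v2, level = lev))
    }
    # cross-zone substitutions change the hash
    r1 <- zones[[1L]][1L]
    r2 <- setdiff(aa_alphabet(), unlist(zones[1L]))[1L]
    w1 <- paste0(r1, substr(base, 2, 12))
    w2 <- paste0(r2, substr(base, 2, 12))
    expect_false(hash_kmer(w1, level = lev) == hash_kmer(w2, level = lev))
  }
})

test_that("hash streams are deterministic and ids are propagated", {
  peps <- random_peptides(3L, 40L, rng_seed = 8L)
  a <- hash_sequence(peps, k = 10L, h = 3L)
  b <- hash_sequence(peps, k = 10L, h = 3L)
  expect_identical(a, b)
  expect_identical(unique(a$id), names(peps))
  expect_identical(names(a), c("id", "pos", "hash1", "hash2", "hash3"))
})
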