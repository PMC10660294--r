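test_that("insertion sets at most h bits and is idempotent", {
  bf <- bloom_filter(m = 64L, h = 2L)
  hs <- multi_hash(hash_kmer("ACDEF"), h = 2L, k = 5L)
  bloom_insert(bf, hs)
  info1 <- bloom_info(bf)
  expect_lte(info1$set_bits, 2)
  bloom_insert(bf, hs)
  info2 <- bloom_info(bf)
  expect_identical(info2$set_bits, info1$set_bits)
  expect_identical(info2$n_inserted, 2)  # insert ops counted, bits unchanged
})

test_that("bit addressing is hash mod m", {
  bf <- bloom_filter(m = 8L, h = 1L)
  bloom_insert(bf, matrix("000000000000000b", ncol = 1L))  # 11 mod 8 = 3
  expect_identical(pephash:::cpp_bloom_set_positions(bf$ptr), 3L)
})

test_that("queries have no false negatives and an empty filter has no hits", {
  set.seed(2)
  kmers <- unique(vapply(1:50, function(i)
    paste(sample(aa_alphabet(), 6L, replace = TRUE), collapse = ""), character(1L)))
  hs <- multi_hash(hash_kmer(kmers), h = 3L, k = 6L)
  bf <- bloom_filter(m = 512L, h = 3L)
  expect_false(any(bloom_contains(bf, hs)))  # nothing inserted yet
  bloom_insert(bf, hs)
  expect_true(all(bloom_contains(bf, hs)))
})

test_that("a saturated filter answers TRUE for any query", {
  bf <- bloom_filter(m = 4L, h = 1L)
  bloom_insert(bf, matrix(c("0000000000000000", "0000000000000001",
                            "0000000000000002", "0000000000000003"), ncol = 1L))
  expect_identical(bloom_occupancy(bf), 1)
  probe <- multi_hash(pephash:::cpp_random_hex(5L, 3L), h = 1L, k = 9L)
  expect_true(all(bloom_contains(bf, probe)))
})

test_that("hash-count mismatches are rejected", {
  bf <- bloom_filter(m = 64L, h = 3L)
  expect_error(bloom_insert(bf, matrix("00000000000000ff", ncol = 1L)), "expected 3")
  expect_error(bloom_filter(m = 64L, h = 0L), "h must be >= 1")
  expect_error(bloom_filter(m = 0L, h = 1L), "m must be >= 1")
})

test_that("theoretical FPR follows the occupancy formula", {
  expect_identical(theoretical_fpr(m = 1000L, n = 0L, h = 3L), 0)
  # at the load giving 11.8% single-hash occupancy, the h = 1/3/5 chain
  # reproduces 11.8% / 3.1% / 2.2% to one decimal in percent
  n <- 1e6
  m <- 1 / (1 - (1 - 0.118)^(1 / n))
  expect_identical(round(100 * theoretical_fpr(m, n, 1L), 1L), 11.8)
  expect_identical(round(100 * theoretical_fpr(m, n, 3L), 1L), 3.1)
  expect_identical(round(100 * theoretical_fpr(m, n, 5L), 1L), 2.2)
})

test_that("empirical FPR of random unseen k-mers tracks the theoretical rate", {
  ins <- random_peptides(100L, 250L, rng_seed = 51L)
  qry <- random_peptides(100L, 250L, rng_seed = 52L)
  k <- 25L
  n_kmers <- 100 * 226
  m <- round(1 / (1 - (1 - 0.118)^(1 / n_kmers)))
  for (h in c(1L, 3L)) {
    bf <- bloom_filter(m = m, h = h)
    n_ins <- bloom_insert_peptides(bf, ins, k = k)
    expect_identical(n_ins, n_kmers + 0)
    q <- bloom_query_peptides(bf, qry, k = k)
    p_hat <- q[["n_hits"]] / q[["n_queries"]]
    p_theo <- theoretical_fpr(m, n_ins, h)
    se <- sqrt(p_theo * (1 - p_theo) / q[["n_queries"]])
    expect_lt(abs(p_hat - p_theo), 3 * se)
  }
})

test_that("filters round-trip through the binary save format", {
  bf <- bloom_filter(m = 300L, h = 2L)
  hs <- multi_hash(hash_kmer(c("ACDEFG", "GHIKLM", "WYVSTA")), h = 2L, k = 6L)
  bloom_insert(bf, hs)
  path <- withr::local_tempfile(fileext = ".bf")
  bloom_save(bf, path)
  bf2 <- bloom_load(path)
  expect_identical(bloom_info(bf2), bloom_info(bf))
  expect_identical(bloom_contains(bf2, hs), bloom_contains(bf, hs))
  expect_identical(pephash:::cpp_bloom_set_positions(bf2$ptr),
                   pephash:::cpp_bloom_set_positions(bf$ptr))
  # corrupted magic is rejected
  bad <- withr::local_tempfile(fileext = ".bf")
  writeBin(charToRaw("NOTABLOOM"), bad)
  expect_error(bloom_load(bad), "not a Bloom filter")
})
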