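test_that("base seeds are balanced, distinct and deterministic", {
  s <- generate_base_seeds()
  expect_length(s, 20L)
  expect_identical(names(s), aa_alphabet())
  pc <- popcount64(s)
  expect_true(all(pc >= 30L & pc <= 34L))
  expect_identical(anyDuplicated(unname(s)), 0L)
  expect_identical(unname(generate_base_seeds()), unname(s))
  # a different generator seed gives a different (but equally balanced) table
  s2 <- generate_base_seeds(rng_seed = 9999L)
  expect_false(all(unname(s2) == unname(s)))
  expect_true(all(popcount64(s2) >= 30L & popcount64(s2) <= 34L))
})

test_that("level tables share one word per zone and keep zones distinct", {
  for (lev in 2:3) {
    tab <- seed_table(lev)
    part <- blosum_partition(lev)
    base <- seed_table(1L)
    expect_identical(length(unique(unname(tab))), length(part$groups))
    for (g in part$groups) {
      expect_identical(length(unique(tab[g])), 1L)
      # representative = base seed of the lexicographically smallest member
      expect_identical(unname(tab[g[1L]]), unname(base[[min(g)]]))
    }
  }
})

test_that("singleton zones inherit their own base seed", {
  tab2 <- seed_table(2L)
  base <- seed_table(1L)
  singles <- Filter(function(g) length(g) == 1L, blosum_partition(2L)$groups)
  for (g in singles) expect_identical(unname(tab2[g]), unname(base[g]))
})

test_that("dimer and trimer tables satisfy their defining identities", {
  tab <- seed_table(1L)
  nm <- build_nmer_tables(tab)
  aa <- aa_alphabet()

  # exhaustive check of all 400 dimers against the split-rotation identity
  first <- rep(aa, each = 20L)
  second <- rep(aa, times = 20L)
  expected_dimer <- xor64(srol(tab[first]), tab[second])
  expect_identical(unname(nm$dimer[cbind(first, second)]), unname(expected_dimer))

  # all 8000 trimers via srol linearity: trimer = srol(dimer) XOR seed
  eg <- expand.grid(c = aa, b = aa, a = aa, stringsAsFactors = FALSE)
  dimer_ab <- nm$dimer[cbind(eg$a, eg$b)]
  expected_trimer <- xor64(srol(dimer_ab), tab[eg$c])
  expect_identical(unname(nm$trimer), unname(expected_trimer))
  expect_identical(names(nm$trimer), paste0(eg$a, eg$b, eg$c))

  # independent bit-vector oracle on a sample of triples
  set.seed(11)
  for (i in sample(8000L, 25L)) {
    trip <- strsplit(names(nm$trimer)[i], "")[[1L]]
    expect_identical(unname(nm$trimer[[i]]), oracle_hash_base(paste(trip, collapse = ""), tab))
  }
})

test_that("seed TSV export is complete and parseable", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_seed_tsv(path)
  df <- read.delim(path, colClasses = c("character", "integer", "character"))
  expect_identical(nrow(df), 60L)
  expect_identical(sort(unique(df$level)), 1:3)
  expect_true(all(grepl("^[0-9a-f]{16}$", df$seed)))
  expect_identical(df$seed[df$level == 1L], as.character(seed_table(1L)))
})
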