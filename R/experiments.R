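#' Hash-uniformity experiment
#'
#' Generates one random peptide of length `n_hashes + k - 1`, hashes all
#' `n_hashes` k-mer windows at the requested level (or pattern), normalizes
#' by `2^64 - 1` and summarizes the histogram and Kolmogorov–Smirnov test
#' via [uniformity_histogram()].  The defaults (one million 100-mers from a
#' length-1,000,099 sequence, 1000 bins) give a mean bin count of exactly
#' 1000 and, for a uniform hash, a count standard deviation near the
#' multinomial value `sqrt(N p (1 - p)) ~ 31.6`.
#'
#' @param n_hashes Number of k-mer windows to hash.
#' @param k Window length.
#' @param level Hash level.
#' @param pattern Optional multi-level pattern (overrides `level`).
#' @param bins Histogram bins.
#' @param seed RNG seed for the peptide (recorded in the report).
#' @return `uniformity_report` with the run configuration attached.
#' @export
eval_uniformity <- function(n_hashes = 1e6, k = 100L, level = 1L,
                            pattern = NULL, bins = 1000L, seed = 42L) {
  k_eff <- if (is.null(pattern)) as.integer(k) else length(parse_level_pattern(pattern))
  seq_len_total <- as.integer(n_hashes + k_eff - 1L)
  pep <- random_peptides(1L, seq_len_total, rng_seed = seed)
  vals <- hash_values(pep, k = k_eff, level = level, pattern = pattern)
  rep <- uniformity_histogram(vals, bins = bins)
  rep$config <- list(n_hashes = length(vals), k = k_eff, level = level,
                     pattern = pattern, bins = as.integer(bins), seed = seed)
  rep
}

#' Box–Muller normality and independence experiment
#'
#' Hashes a seeded random peptide stream, forms adjacent normalized hash
#' pairs (non-overlapping by default), applies the Box–Muller transform and
#' tests the first `n_keep` transformed values: Shapiro–Wilk normality of Z0
#' and Z1, and the Pearson correlation between them with its
#' `1/sqrt(n - 3)` standard error.  Normality plus independence of (Z0, Z1)
#' is evidence that the underlying hash pairs are uniform and independent,
#' because the transform is a bijection.
#'
#' @param n_keep Transformed values retained for testing (Shapiro–Wilk is
#'   size-sensitive; 1000 sits comfortably inside its 5000 cap).
#' @param n_pairs Pairs to generate before truncation.
#' @param k Window length.
#' @param level Hash level.
#' @param overlapping Pairing mode, see [adjacent_pairs()].
#' @param seed RNG seed for the peptide.
#' @return List with `z0`, `z1` (truncated), `shapiro_z0`, `shapiro_z1`,
#'   `pearson`, `qq_z0`, `qq_z1` and the run `config`.
#' @export
eval_boxmuller <- function(n_keep = 1000L, n_pairs = 2000L, k = 100L,
                           level = 1L, overlapping = FALSE, seed = 42L) {
  n_windows <- if (overlapping) n_pairs + 1L else 2L * n_pairs
  pep <- random_peptides(1L, n_windows + as.integer(k) - 1L, rng_seed = seed)
  vals <- hash_values(pep, k = k, level = level)
  pr <- adjacent_pairs(vals, overlapping = overlapping)
  bm <- box_muller(pr$u0, pr$u1)
  if (length(bm$z0) < n_keep) stop("not enough pairs generated; raise n_pairs")
  z0 <- bm$z0[seq_len(n_keep)]
  z1 <- bm$z1[seq_len(n_keep)]
  list(z0 = z0, z1 = z1,
       shapiro_z0 = normality_check(z0),
       shapiro_z1 = normality_check(z1),
       pearson = independence_check(z0, z1),
       qq_z0 = qq_points(z0), qq_z1 = qq_points(z1),
       config = list(n_keep = n_keep, n_pairs = n_pairs, k = k, level = level,
                     overlapping = overlapping, seed = seed,
                     n_skipped = bm$n_skipped))
}

#' Bloom-filter false-positive-rate experiment
#'
#' For each k-mer length, loads a Bloom filter with the k-mers of one set of
#' random peptides and queries the k-mers of a disjoint set.  Since the
#' filter holds only random k-mers, essentially every hit is a false
#' positive; a uniform hash should therefore match the occupancy-based
#' theoretical rate.  The filter size `m` is solved per condition so that
#' the *single-hash* occupancy equals `occupancy` (the absolute size is a
#' free parameter of the design; only the load matters), and each hash count
#' `h` is run at that same load.  Empirical rates carry binomial standard
#' errors `sqrt(p(1-p)/n_queries)`; per `h`, empirical and theoretical rates
#' are compared across k-mer lengths with a two-sided paired t-test.
#'
#' @param k_values k-mer lengths to test.
#' @param h_values Hash counts per k-mer to test.
#' @param n_seqs Sequences per set (insert set and query set).
#' @param seq_len Residues per sequence.
#' @param occupancy Target single-hash occupancy (default 0.118).
#' @param seed RNG seed; insert and query sets use `seed` and `seed + 1`.
#' @param check_overlap Estimate insert/query k-mer overlap via canonical
#'   hashes and warn above 0.1% (overlap would bias the FPR upward).
#' @return Object of class `fpr_report`: data frame `conditions` with one
#'   row per (k, h) — columns `k`, `h`, `m`, `n_inserted`, `occupancy`,
#'   `n_queries`, `n_hits`, `empirical_fpr`, `se`, `theoretical_fpr` — plus
#'   `ttests` (per-h paired t across k) and `config`.
#' @export
eval_fpr <- function(k_values = c(25L, 50L, 100L), h_values = c(1L, 3L, 5L),
                     n_seqs = 5000L, seq_len = 250L, occupancy = 0.118,
                     seed = 42L, check_overlap = TRUE) {
  stopifnot(occupancy > 0, occupancy < 1)
  insert_set <- random_peptides(n_seqs, seq_len, rng_seed = seed)
  query_set <- random_peptides(n_seqs, seq_len, rng_seed = seed + 1L)
  rows <- list()
  for (k in k_values) {
    n_kmers <- as.double(n_seqs) * (seq_len - k + 1L)
    # m such that 1 - (1 - 1/m)^n_kmers = occupancy at h = 1
    m <- max(1, round(1 / (1 - (1 - occupancy)^(1 / n_kmers))))
    if (check_overlap) {
      ov <- cpp_kmer_overlap(insert_set, query_set, as.integer(k),
                             unname(seed_table(1L)))
      if (ov[[1L]] > 0 && ov[[2L]] / ov[[1L]] > 0.001) {
        warning(sprintf(
          "insert/query k-mer overlap %.3f%% exceeds 0.1%% at k = %d; empirical FPR will be biased upward",
          100 * ov[[2L]] / ov[[1L]], k))
      }
    }
    for (h in h_values) {
      bf <- bloom_filter(m = m, h = h)
      n_ins <- bloom_insert_peptides(bf, insert_set, k = k, level = 1L)
      occ <- bloom_occupancy(bf)
      q <- bloom_query_peptides(bf, query_set, k = k, level = 1L)
      p_hat <- unname(q[["n_hits"]] / q[["n_queries"]])
      rows[[length(rows) + 1L]] <- data.frame(
        k = as.integer(k), h = as.integer(h), m = m, n_inserted = n_ins,
        occupancy = occ, n_queries = unname(q[["n_queries"]]),
        n_hits = unname(q[["n_hits"]]), empirical_fpr = p_hat,
        se = sqrt(p_hat * (1 - p_hat) / q[["n_queries"]]),
        theoretical_fpr = theoretical_fpr(m, n_ins, h))
    }
  }
  conditions <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ttests <- lapply(stats::setNames(h_values, paste0("h", h_values)), function(h) {
    sub <- conditions[conditions$h == h, ]
    if (nrow(sub) >= 2L && stats::sd(sub$empirical_fpr - sub$theoretical_fpr) > 0) {
      paired_ttest(sub$empirical_fpr, sub$theoretical_fpr)
    } else {
      list(t = NA_real_, p_value = NA_real_)
    }
  })
  structure(list(conditions = conditions, ttests = ttests,
                 config = list(k_values = k_values, h_values = h_values,
                               n_seqs = n_seqs, seq_len = seq_len,
                               occupancy = occupancy, seed = seed)),
            class = "fpr_report")
}

#' @export
print.fpr_report <- function(x, ...) {
  cat("Bloom-filter false-positive-rate experiment\n")
  df <- x$conditions
  df$empirical_fpr <- sprintf("%.4f +/- %.4f", df$empirical_fpr, df$se)
  df$theoretical_fpr <- sprintf("%.4f", df$theoretical_fpr)
  print(df[, c("k", "h", "n_inserted", "occupancy", "empirical_fpr",
               "theoretical_fpr")], row.names = FALSE)
  for (nm in names(x$ttests)) {
    tt <- x$ttests[[nm]]
    cat(sprintf("  paired t (%s, empirical vs theoretical across k): t = %.3f, p = %.3f\n",
                nm, tt$t, tt$p_value))
  }
  invisible(x)
}
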