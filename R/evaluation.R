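#' Normalize 64-bit hashes to the unit interval
#'
#' Divides each hash value by `2^64 - 1`, the largest 64-bit integer, so a
#' uniform hash maps to (approximately) Uniform(0, 1).
#'
#' @param hashes Character vector of 16-digit hex words.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_hashes <- function(hashes) {
  cpp_hex_to_norm(hashes)
}

#' Histogram-based uniformity summary
#'
#' Bins normalized hash values into `bins` equal-width bins on `[0, 1]`
#' (the last bin includes its right edge) and summarizes the counts.  For a
#' uniform hash the counts are multinomial with mean exactly `N / bins` and
#' standard deviation close to `sqrt(N p (1 - p))`, `p = 1/bins`.  A
#' one-sample two-sided Kolmogorov–Smirnov test against Uniform(0, 1)
#' accompanies the summary.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param bins Number of bins (>= 1).
#' @return An object of class `uniformity_report`: list with `bin_counts`,
#'   `mean`, `sd`, `ks_stat`, `ks_p`, `n`, `bins`.
#' @export
uniformity_histogram <- function(values, bins = 1000L) {
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  if (length(values) == 0L) stop("values must be nonempty")
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("values must lie in [0, 1]")
  }
  idx <- pmin(bins, floor(values * bins) + 1L)
  counts <- tabulate(idx, nbins = bins)
  ks <- ks_uniform(values)
  structure(
    list(bin_counts = counts,
         mean = length(values) / bins,
         sd = stats::sd(counts),
         ks_stat = ks[["statistic"]],
         ks_p = ks[["p_value"]],
         n = length(values), bins = bins),
    class = "uniformity_report"
  )
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("uniformity: %d values in %d bins; counts %.1f +/- %.1f; K-S D = %.4g, p = %.3g\n",
              x$n, x$bins, x$mean, x$sd, x$ks_stat, x$ks_p))
  invisible(x)
}

#' Kolmogorov–Smirnov test against Uniform(0, 1)
#'
#' One-sample, two-sided, asymptotic (`stats::ks.test`).
#'
#' @param values Nonempty numeric vector in `[0, 1]`.
#' @return List with `statistic` and `p_value`.
#' @export
ks_uniform <- function(values) {
  if (length(values) == 0L) stop("values must be nonempty")
  kt <- suppressWarnings(stats::ks.test(values, "punif", exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Pair up adjacent hash values
#'
#' Groups a stream of normalized hashes into consecutive pairs `(U0, U1)`
#' for the Box–Muller transform.  The default pairing is non-overlapping
#' (positions 0&1, 2&3, ...), keeping the two coordinates from disjoint
#' windows; `overlapping = TRUE` uses the sliding pairing (0&1, 1&2, ...)
#' instead.  A trailing unpaired value is dropped.
#'
#' @param values Numeric vector of normalized hashes.
#' @param overlapping Use sliding pairs instead of disjoint pairs.
#' @return List with numeric vectors `u0` and `u1` of equal length.
#' @export
adjacent_pairs <- function(values, overlapping = FALSE) {
  n <- length(values)
  if (n < 2L) return(list(u0 = numeric(0L), u1 = numeric(0L)))
  if (overlapping) {
    list(u0 = values[-n], u1 = values[-1L])
  } else {
    m <- 2L * (n %/% 2L)
    list(u0 = values[seq(1L, m, by = 2L)], u1 = values[seq(2L, m, by = 2L)])
  }
}

#' Box–Muller transform
#'
#' Maps independent Uniform(0, 1) pairs to independent standard normal
#' pairs: `Z0 = sqrt(-2 ln U0) cos(2 pi U1)`,
#' `Z1 = sqrt(-2 ln U0) sin(2 pi U1)`.  Pairs with `U0 == 0` (hash value 0;
#' probability ~2^-64 per window) are skipped rather than clamped, to avoid
#' an infinite radius without distorting the distribution.
#'
#' @param u0,u1 Numeric vectors of equal length with values in `[0, 1]`.
#' @return List with `z0`, `z1` and `n_skipped` (count of dropped
#'   `U0 == 0` pairs).
#' @export
box_muller <- function(u0, u1) {
  if (length(u0) != length(u1)) stop("u0 and u1 must have equal length")
  keep <- u0 > 0
  r <- sqrt(-2 * log(u0[keep]))
  theta <- 2 * pi * u1[keep]
  list(z0 = r * cos(theta), z1 = r * sin(theta), n_skipped = sum(!keep))
}

#' Shapiro–Wilk normality check
#'
#' Standard Shapiro–Wilk test (`stats::shapiro.test`); the sample size must
#' lie in the test's supported range 3–5000.  Following common practice for
#' this size-sensitive test, callers truncate large streams (the validation
#' drivers use the first 1000 transformed values).
#'
#' @param sample Numeric vector, 3 <= length <= 5000.
#' @return List with `W` and `p_value`.
#' @export
normality_check <- function(sample) {
  n <- length(sample)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires between 3 and 5000 observations, got ", n)
  }
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p_value = unname(sw$p.value))
}

#' Pearson independence check
#'
#' Pearson correlation between the two Box–Muller coordinates, with the
#' large-sample standard error `1 / sqrt(n - 3)` (from the Fisher
#' z-transform).  For independent coordinates `|r|` should be within a few
#' standard errors of zero.
#'
#' @param z0,z1 Numeric vectors of equal length >= 3.
#' @return List with `r`, `se` and `n`.
#' @export
independence_check <- function(z0, z1) {
  if (length(z0) != length(z1)) stop("z0 and z1 must have equal length")
  n <- length(z0)
  if (n < 3L) stop("need at least 3 observations")
  list(r = stats::cor(z0, z1), se = 1 / sqrt(n - 3), n = n)
}

#' Two-sided paired Student's t-test
#'
#' Thin wrapper over `stats::t.test(..., paired = TRUE)` that rejects
#' degenerate input (zero-variance differences) with a clear error instead
#' of an NaN statistic.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `t` and `p_value`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    stop("degenerate input: paired differences have zero variance")
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p_value = unname(tt$p.value))
}

#' Normal Q–Q points
#'
#' Emits (theoretical, sample) quantile pairs for a normal Q–Q plot of a
#' sample, without drawing anything.
#'
#' @param sample Numeric vector.
#' @return Data frame with columns `theoretical` and `sample`.
#' @export
qq_points <- function(sample) {
  data.frame(theoretical = stats::qnorm(stats::ppoints(length(sample))),
             sample = sort(sample))
}
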