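---
title: "Multi-level recursive hashing of peptide k-mers: model and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level recursive hashing of peptide k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pephash)
```

## The problem

Many protein-sequence workflows — k-mer counting, Bloom-filter membership,
minimizer sketching, homology seeding — need to map every k-residue window
of a peptide to a 64-bit integer, millions of times per second.  Generic
string hashes recompute from scratch for each window; a *recursive* (rolling)
hash instead updates the previous window's value in constant time.  Amino
acids also carry structure that nucleotides do not: substitutions between
biochemically similar residues (captured by BLOSUM62) are often conservative,
and a hash that can optionally *ignore* such substitutions enables
similarity-tolerant matching at the hash level.

`pephash` implements such a scheme: seed-table hashing with a split-register
rotation, three degeneracy levels derived from BLOSUM62, per-position
multi-level patterns, multi-hashing for Bloom filters, and the statistical
harness used to check that the resulting hash values are uniform and
independent.

## The hash function

Each residue $a$ has a fixed 64-bit seed word $h(a)$.  A k-mer
$s_0 s_1 \dots s_{k-1}$ hashes to

$$H = \mathrm{srol}^{\,k-1}(h(s_0)) \oplus \mathrm{srol}^{\,k-2}(h(s_1))
      \oplus \dots \oplus h(s_{k-1}),$$

where $\oplus$ is XOR and $\mathrm{srol}$ is a bit permutation described
below.  Sliding the window one residue right is the constant-time update

$$H_{i+1} = \mathrm{srol}(H_i) \oplus \mathrm{srol}^{\,k}(h(s_i))
            \oplus h(s_{i+k}),$$

which follows from linearity of $\mathrm{srol}$ over XOR: rotating the
previous hash advances every seed's rotation count by one, the
$\mathrm{srol}^k$ term cancels the outgoing residue, and the incoming seed
joins with rotation count zero.  The package verifies bit-identity of the
rolled and direct paths exhaustively in its test suite.

### The split rotation

A plain 64-bit rotation has period 64: in windows longer than 64 residues,
positions 64 apart would contribute identically and uniformity degrades.
`srol` therefore treats the word as two independent cyclic registers —
bits 0–32 (33 bits) and bits 33–63 (31 bits) — each rotated left by one.
Since $\gcd(33, 31) = 1$ the compound permutation has period
$\mathrm{lcm}(33, 31) = 1023$, far beyond any practical k.  The split sizes
are forced by that requirement: 33 + 31 is the unique two-register split of
64 whose register widths are coprime with this lcm.  Equivalently, `srol`
is rotate-left-by-one followed by swapping bits 0 and 33.

```{r}
x <- "0000000200000001"        # 1 + 2^33: one active bit per register
length(unique(Reduce(function(a, .) srol(a), 1:1022, accumulate = TRUE,
                     init = x)))  # all 1023 states distinct before returning
srol(x, 1023) == x
```

### Seed tables

The level-1 table assigns each of the 20 residues a distinct 64-bit word.
The words are generated from a splitmix64 stream at the fixed seed
`canonical_seed()` (24301), keeping only words with 30–34 set bits — a
nearly balanced bit composition, so XOR combinations mix well — and the
table ships with the package as code, reproducible from that constant.
Precomputed dimer (400-entry) and trimer (8000-entry) tables expand the
seeds so the initial window hash can be consumed three residues at a time;
linearity guarantees bit-identical results, which the tests check
exhaustively.

### Degeneracy levels

Levels 2 and 3 make the hash *degenerate*: residues in the same zone share
one seed word, so within-zone substitutions leave the hash unchanged.
Zones come from BLOSUM62.  Level 2 groups residues whose pairwise scores
are positive; level 3 relaxes the rule to nonnegative scores.

The construction is the one genuinely open design choice in the package.
The obvious rule — connected components of the graph with an edge per
qualifying pair — is unusable for BLOSUM62: single weak links chain
dissimilar residues together (alanine reaches tryptophan through the
positive path A–S–N–H–Y–W), and under the nonnegative rule 19 of the 20
residues form one component, collapsing level 3 to an almost binary
alphabet whose hashes could not stay uniform.  `pephash` instead uses
greedy mutual-compatibility blocks: residues are scanned alphabetically and
each joins the first zone *all* of whose members it scores positively
against (a clique condition, deterministic, no manual curation).  Level 3
is built by merging whole level-2 zones whenever every cross-zone pair
scores nonnegatively, which guarantees that level 3 coarsens level 2.  Both
rules are implemented (`derive_partition(method = "component")` exists for
comparison); the clique rule is canonical.

```{r}
blosum_partition(2)
blosum_partition(3)
```

The resulting zones (e.g. {I,L,M,V}, {F,W,Y}, {K,Q,R}, {D,E}, {S,T} split
across {A,S} and {T}) closely resemble classical reduced amino-acid
alphabets derived from BLOSUM block-diagonalization, which is the intended
behaviour.  Published zone tables for this family of hash functions live in
supplementary material we treat as non-authoritative; the package documents
its own derived partition and treats it as canonical for all of its tests.

### Multi-level patterns

A pattern assigns a level to each window position
(`hash_sequence(x, pattern = "311...13")`), the graded analogue of a spaced
seed: instead of "don't care" positions, a position can care about identity
(level 1) or only about biochemical class (levels 2–3).  Mixed per-position
tables break the rolling cancellation, so pattern mode recomputes each
window directly in $O(k)$; correctness over speed, noted as an optimization
point.

### Multi-hashing

Bloom filters want $h$ hash values per element.  Index 0 is the canonical
hash untouched; index $i > 0$ multiplies the base by an odd constant
derived from $(i, k)$ and applies a two-round xorshift-multiply finalizer.
Each derived map is a bijection of the base value, so uniformity of the
canonical hash transfers to every index; the test suite checks derived
indices against a Kolmogorov–Smirnov uniformity test at $n = 10^5$.

## Handling real sequences

Input residues are uppercased before lookup (FASTA case is not semantic).
Characters outside the 20-letter alphabet (ambiguity codes B, J, O, U, X,
Z, `*`) invalidate every window containing them: those windows are skipped
and rolling re-initializes at the next clean window, mirroring how
nucleotide rolling hashes treat `N`.  `hash_kmer` on an explicit k-mer is
stricter and raises an error naming the offending character and its
0-based offset.  Window positions are 0-based; a window is the half-open
interval $[\mathrm{pos}, \mathrm{pos} + k)$.

## The synthetic-data model

All experiments run on generated peptides: residues i.i.d. uniform over the
20-letter alphabet, from R's seeded integer RNG (`random_peptides`).  This
emulates unbiased simulated peptide data — sequence length 250 and set
sizes in the million-k-mer range match the validation conditions — but
deliberately does *not* model real proteome composition (residue
frequencies are not uniform in nature, and real proteins contain repeats
and low-complexity regions).  Passing tests therefore demonstrate the
hash's statistical quality on unstructured input; they do not certify
collision behaviour on adversarial or highly repetitive sequences.

## The validation harness

Four experiment families, all seeded (default seed 42, recorded in each
report):

* **Histogram uniformity** (`eval_uniformity`): hash the $10^6$ 100-mers of
  a random length-1,000,099 peptide, normalize by $2^{64} - 1$, bin into
  1000 equal-width bins.  The mean count is exactly $N/\mathrm{bins} = 1000$
  by conservation; for a uniform hash the count standard deviation should
  sit near the multinomial value $\sqrt{N p (1-p)} \approx 31.6$, and a
  one-sample two-sided K-S test against Uniform(0,1) should be
  non-significant at $\alpha = 0.05$.  All three levels are tested.
* **Box–Muller normality/independence** (`eval_boxmuller`): adjacent
  normalized hash pairs $(U_0, U_1)$ — non-overlapping by default, so the
  two coordinates come from disjoint windows; the sliding pairing is
  available via `overlapping = TRUE` — are mapped to
  $Z_0 = \sqrt{-2\ln U_0}\cos(2\pi U_1)$,
  $Z_1 = \sqrt{-2\ln U_0}\sin(2\pi U_1)$.  Because the transform is a
  bijection, normality and independence of $(Z_0, Z_1)$ imply uniformity
  and independence of the hash pairs.  The Shapiro–Wilk test is
  size-sensitive, so the first 1000 transformed values are tested (well
  under the implementation cap of 5000); Pearson correlation between
  $Z_0$ and $Z_1$ is reported with its Fisher-z standard error
  $1/\sqrt{n-3} \approx 0.032$.  Pairs with $U_0 = 0$ (hash value exactly
  zero, probability $\approx 2^{-64}$) are skipped rather than clamped.
* **Bloom-filter false positives** (`eval_fpr`): a filter is loaded with
  the k-mers of one random peptide set and queried with a disjoint set, so
  every hit is a false positive.  The filter size is solved so the
  single-hash occupancy is 0.118 (the absolute size is a free parameter;
  only the load matters), giving analytic rates
  $q_h^h$ with $q_h = 1 - (1 - 1/m)^{hn}$ of 11.8%, 3.1% and 2.2% for
  $h = 1, 3, 5$.  Desk scale is 5000 insert + 5000 query sequences of
  length 250 (about $1.1 \times 10^6$ k-mers each way) across
  $k \in \{25, 50, 100\}$; empirical rates carry binomial standard errors
  and are compared to theory per $h$ with a two-sided paired t-test.  An
  insert/query overlap estimate (via canonical-hash membership) warns above
  0.1% overlap, which would bias the rate upward.
* **Q–Q points** (`qq_points`): (theoretical, sample) quantile pairs are
  emitted for external plotting; no figure aesthetics beyond that.

```{r}
r <- eval_uniformity(n_hashes = 1e5, k = 100, level = 1, seed = 42)
r
```

(The vignette runs a 10× reduced histogram for brevity; the package's
acceptance tests run the full $10^6$-hash configuration, which takes a few
seconds.)

## Numerical choices and edge cases

* 64-bit words cross the R boundary as 16-digit lowercase hex strings
  (exact); normalized values are doubles in $[0,1]$ (53-bit rounding is
  irrelevant at the harness's sample sizes).
* Histogram binning is left-closed with the right edge included in the last
  bin; value 1.0 lands in bin `bins`.
* The K-S test uses the asymptotic two-sided form; ties among $10^6$
  53-bit-rounded values are astronomically unlikely.
* Zone representatives: each zone's shared seed is the level-1 seed of its
  lexicographically smallest member — a deterministic tie-break with no
  statistical consequence.
* The paired t-test refuses zero-variance differences with a clear error
  rather than returning NaN.
* `k` greater than the sequence length yields an empty stream, not an
  error; `k < 1` and invalid patterns are parameter errors.

## Limitations

* The degeneracy zones are this package's own derivation from the stated
  BLOSUM62 rules; other implementations of the same idea may partition
  differently (their exact tables are not public in citable form), so
  hashes are not interchangeable across implementations — nor are they
  meant to be.  Within this package the tables are canonical, versioned,
  and exportable (`write_seed_tsv`) for audit.
* Like every cyclic recursive n-gram hash, the scheme is not formally
  uniform; the validation harness establishes empirical uniformity at the
  tested scales.
* Speed comparisons against generic string hashes are out of scope here;
  the package's contribution is the algorithm's semantics plus its
  statistical validation, with the rolling update giving the expected
  asymptotic advantage (O(1) per window versus O(k)).
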