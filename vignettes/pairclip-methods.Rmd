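---
title: "pairclip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairclip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairclip)
```

## The trimming model

Paired-end read-through contamination has a geometric signature: if the
sequenced fragment (the insert) is `n < N` bases long, then bases `1..n`
of the two mates are mutual reverse complements and bases `n+1..N` of each
mate are the start of the respective ligated adapter. pairclip locates `n`
from the reverse-complement relationship alone, so it needs no adapter
catalogue and is insensitive to adapter variants, as long as four
assumptions hold:

* mates have equal, fixed length `N` (standard for Illumina runs);
* errors are substitutions — no indels, so the junction is at the same
  coordinate in both mates;
* the insert of interest is at least `L` bases (shorter inserts are
  undetectable by construction, see *Limitations*);
* qualities play no role in the decision (only in simulation).

### Stage 1: mismatch-tolerant prefix scanning

The reverse complement of mate 1's `L`-prefix is slid along mate 2; a
window starting at 0-based `p` with at most `floor(L * e1)` mismatches
supports candidate insert length `n = p + L`. The symmetric scan gives the
second candidate set, and only sites supported by both directions survive
the intersection. Each scan compares at most `(N - L + 1) * L <= L * N`
characters (the inner loop aborts once a window exceeds its budget), so a
pair costs at most `2 * L * N` comparisons — linear in `N` for fixed `L`.
`trim_pairs()` reports the actual count per pair in its `comparisons`
column, and the test suite asserts the bound over benchmark-scale runs.

### Stage 2: largest-first validation

With two or more surviving candidates, validation walks them in
descending order, preferring the longest insert (the smallest cut). A
candidate `n` must satisfy two checks: reverse complementarity of the
inferred DNA portions within `floor(n * e2)` mismatches, and equality of
the inferred adapter portions within `floor((N - n) * e3)` mismatches
(vacuously true at `n = N`). The first candidate passing both wins.

A *singleton* intersection is accepted without validation. This is the
deliberate fast path: a site supported independently by both scan
directions is almost always genuine, and validating it would mostly
re-test the same positions. It can in principle admit a false positive —
for libraries where that matters, `trimmer_params(strict_singleton =
TRUE)` forces validation of singletons too (off by default).

### Tolerance semantics

Every tolerance is a **maximum mismatch fraction**: a comparison of
length `len` passes iff its mismatch count is at most `floor(len * e)`.
Setting a tolerance to 1 makes the budget equal to the length, which no
mismatch count can exceed — the check is disabled. This is how
distinct-adapter libraries are handled: with `e3 = 1` the adapter-equality
check is off, and the benchmark shows sensitivity and specificity within
two percentage points of the matched same-adapter run.

The defaults `L = 30`, `e1 = 0.4`, `e2 = 0.6`, `e3 = 0.4` are the
recommended operating point for 101-nt pairs. `L` should be set at or
below the shortest insert worth recovering; raising `e1` admits more
stage-1 candidates (the candidate set grows monotonically in `e1`, a
property the tests check), which stage 2 then prunes.

### Coordinates, edge cases, numerics

* Coordinates are 0-based half-open internally; "insert length `n`" means
  the first `n` bases of each mate are DNA, the rest adapter.
* Candidate `n = N` (zero-length adapter) is representable, validated
  like any other, and reported as *untrimmed* — there is nothing to cut.
  Accepting it still short-circuits smaller candidates, which is what
  saves fully reverse-complementary overlap-only pairs from spurious
  trimming.
* Pairs with unequal mate lengths or mates shorter than `L` violate the
  model's premises; they pass through untrimmed, flagged `skipped`, with
  one summary warning.
* `N` bases never match anything, including another `N`.
* Mismatch budgets are computed as `floor(len * e + 1e-9)`. The epsilon
  matters: in double precision `10 * 0.3` is `2.999...96`, and a bare
  `floor` would shrink the budget by one exactly when `len * e` is
  mathematically integral.
* Ties cannot occur (candidate sets are sets); iteration order is fixed
  ascending for reporting and descending for validation, so results are
  fully deterministic. No parallelism is used — the compiled scan
  processes ~50,000 pairs/s on one core, and serial execution makes
  byte-identical reruns trivial to guarantee.

### The exhaustive oracle

`brute_force_trim()` is a second, independent implementation kept in the
package deliberately: pure R, quadratic, no scanning shortcuts — for every
`n` in `[L, N]` it recomputes the stage-1 criterion directly in both
directions, then applies the same acceptance logic. The test suite asserts
exact agreement with `trim_pairs()` on 10,000 middle-error pairs and 1,000
pairs from each of the eight benchmark presets, plus adversarial cases
(dense candidate sets on short reads, reads containing `N`, all
tolerances disabled).

## The simulator

The generator reproduces a standard benchmark design for paired-end
trimmers:

* fixed 101-nt mates; exactly `round(n_pairs/2)` pairs adapter-appended
  (the count is deterministic rather than Bernoulli so the design ratio
  of 1 is exactly testable; order is shuffled);
* appended adapter length `A ~ Normal(20, 5)`, rounded and clamped into
  `[1, min(read_length - 1, adapter length)]` — an appended adapter is at
  least one base, cannot fill the whole read, and is cropped from the
  adapter sequence. With the built-in adapter pairs the upper clamp is 58,
  so simulated true inserts lie in `[43, 100]`; Gaussian tail mass outside
  the clamp bounds is negligible at (20, 5);
* contaminated pairs: one reference window of length `101 - A` plus the
  first `A` bases of the forward/reverse adapter on the respective mate;
* clean pairs: two independent windows, or — in overlap mode — the two
  ends of a single `2*101 - 50 = 152`-base fragment so the mates share a
  50-base overlap. Overlap mode probes a specific failure mode: trimmers
  that mistake partial mate overlap for read-through. pairclip's scan
  anchors on the 5' prefix of each mate, which for a 50-base overlap lies
  outside the other mate entirely, so such pairs produce no candidates;
* per-base substitution with probability `min(1, 10^(-Q/10) * s)` where
  `Q` is the simulated quality and `s` the error scale — `10^-0.5`, 1,
  `10^+0.5` for the low/middle/high-error conditions, or 0 for
  error-free data (the zero scale is the one extension beyond the strict
  "positive scale" contract; it exists so exact-recovery properties can
  be tested without a special code path). Under a common seed the
  mutation events of a smaller scale are a subset of a larger one's, so
  the low ≤ middle ≤ high ordering of total mutations is exact, not
  merely expected.

Two built-in adapter pairs are provided: the Illumina TruSeq-style pair
(both mates' adapters share a long common prefix) and a deliberately
unrelated "distinct" pair for exercising `e3 = 1`.

### Quality model

Real per-position quality profiles belong to specific instruments and
runs; the default here is a parametric stand-in: mean Phred declining
linearly from 38 at the 5' end to 20 at position 101, Gaussian dispersion
3, discretized and truncated to `[2, 40]`. Truncation pulls the 5' mean
slightly below its nominal 38 (by about 0.1); the 3' mean is unaffected.
This yields per-base error rates from ~2e-4 to 1e-2, a plausible Illumina
profile with the characteristic 3' degradation.
`learn_quality_model()` replaces it with the empirical per-position
distribution of any real constant-length FASTQ when fidelity to a
particular dataset matters.

### Reference

The default reference is a 200,000-base uniform-random string, generated
on the fly so the package builds and tests without downloads. A real
genome FASTA can be supplied instead; its contigs are joined with single
`N` separators and window sampling rejects windows containing `N`, so
windows never span contigs or undetermined regions. A uniform reference
lacks repeats, homopolymer structure and composition bias, which mainly
means simulated *clean* pairs are easier to keep untrimmed than, say,
low-complexity genomic pairs; the specificity numbers on synthetic data
are therefore an upper bound (see *Limitations*).

## Evaluation

* Positive = truth says contaminated; predicted positive = trimmer
  trimmed. Sensitivity, specificity, accuracy and MCC follow. Whether a
  true positive was cut at exactly the true site is a separate number
  (`exact_site_fraction`), because detection and localisation are
  different failure modes.
* MCC is defined as 0 when a denominator factor is zero; otherwise the
  closed form applies even when it yields −1 (all pairs misclassified).
  The tests cross-check MCC against the identity with the Pearson
  correlation of the binary label vectors.
* Contaminated pairs with true insert `< L` cannot be found by any scan
  anchored on an `L`-prefix. When `min_insert` is supplied they are
  excluded from the confusion table and reported as `n_undetectable`, so
  sensitivity reflects the detectable population rather than being
  silently deflated.
* `approximate_true_positives()` is the label-free proxy for use on real
  data: trimmed pairs whose mates are reverse complements within
  `floor(length * tolerance)` mismatches. The default tolerance is 0
  (strict); it is configurable because on error-containing data a strict
  count undercounts genuine trims that carry sequencing errors in the
  insert.

## Problem sizes

The shipped tests run the oracle-equivalence check at 10,000 + 8 × 1,000
pairs, exact-recovery and clean-pair specificity at 10,000 pairs each, the
half-contaminated ratio benchmark at 100,000 pairs, and calibration
recovery at 10,000 contaminated pairs; the whole suite completes in well
under a minute on one core. These sizes put Monte-Carlo noise far below
every asserted tolerance (e.g. the SD of the adapter-length mean at
n = 10,000 is 0.05 against a ±0.2 band).

## Limitations

* Inserts shorter than `L` are invisible; lowering `L` trades this floor
  against stage-1 specificity.
* Substitution-only: an indel between the junctions desynchronizes the
  mates and the pair will typically be left untrimmed (a false negative,
  not a mis-trim).
* Unequal-length mates are passed through rather than trimmed.
* Simulated specificity is optimistic relative to repeat-rich real
  genomes; the aTP diagnostic exists precisely for label-free assessment
  on real data.
* The parametric quality profile is a stand-in, not a fit to any
  particular instrument; learn an empirical model when that matters.
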