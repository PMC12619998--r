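---
title: "Motif similarity P-values: the model behind tomtomlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif similarity P-values: the model behind tomtomlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tomtomlite)
```

## The problem

Transcription-factor binding motifs are not discrete sequences: they are
position matrices. A frequency-based position-weight matrix (PWM) gives, per
position, a probability for each nucleotide; an attribution-based
contribution-weight matrix (CWM) holds per-nucleotide importance scores from
a predictive model and may contain negative, unnormalised values. Deciding
whether two such matrices describe the same binding preference — a motif
discovered de novo against a curated database, or a seqlet extracted from a
model attribution track against known TF motifs — requires a similarity
score *and* a calibrated notion of how often a score that large arises by
chance.

The difficulty is that neither the relative placement nor the widths of the
two matrices are known. Practical comparisons therefore score **every
ungapped alignment** of the query against the target, on both orientations
for DNA, and keep the **maximum**. A null distribution for that maximum must
represent the entire procedure — all offsets, both orientations, and the
column-level score distribution — not just a single alignment. `tomtomlite`
implements the Tomtom statistic: exact, integer-binned null distributions of
the maximum ungapped-alignment score, built by dynamic programming over the
empirical distribution of target-database columns.

## The statistic, step by step

Write $q_1,\dots,q_{w_q}$ for the query columns, $t_1,\dots,t_{n_t}$ for the
columns of one target, and $\gamma(\cdot,\cdot)$ for the column score
(negative Euclidean distance by default; Pearson correlation as the
alternative).

1. **Column scores.** Every query column is scored against every *distinct*
   column in the target database. Duplicated columns are hashed (keys are
   values rounded to $10^{-6}$) so each distinct column is scored once and
   carries an integer multiplicity.

2. **Median centering.** From each query column's scores, the
   multiplicity-weighted median over the whole database is subtracted. An
   uninformative query column scores near its median against everything and
   so contributes little to any alignment — this is what makes the final
   P-values sensitive to information content, not just width. Because the
   median is taken over the whole database (not per target), a null
   distribution computed once is valid for every target of the same length,
   which is what makes caching sound.

3. **Quantization.** Centered scores are mapped to integer bins
   $0,\dots,B-1$ over their observed range ($B = 100$ by default). Integer
   scores make exact convolution of score distributions possible.

4. **Alignment scores.** The score of the alignment at offset $o$ is the sum
   of binned scores of the aligned columns. With the unaligned-position
   adjustment (on by default), target positions not covered by the query are
   scored against a background column, i.e. the query is padded with
   background columns so that every offset's score is a sum of exactly
   $n_t$ terms; scores at different overlaps then live on one scale. When
   the target fits entirely inside the query, the adjustment is the
   identity.

5. **The null of the maximum.** Under the null, target columns are i.i.d.
   draws from the multiplicity-weighted empirical distribution of database
   columns, and each offset (and each orientation) is an independent draw.
   The per-offset score distribution is an exact convolution of per-column
   binned nulls; the maximum over the offset set has survival function
   $$Q(x) \;=\; 1 - \prod_{o} F_o(x^-),$$
   the product running over all $n_t + w_q - 1$ offsets (doubled in
   both-strand mode). P-values are **inclusive**, $P = \Pr(X \ge x)$, so
   quantization ties err conservative. E-values are $P \times$ (number of
   targets); q-values are Benjamini–Hochberg per query.

### The independence construction, and what it implies

Scores at overlapping offsets of one real target share columns; the product
above instead treats each offset as its own draw. This is the construction
that makes the null computable — the distribution of a maximum of dependent
sliding sums has no polynomial-size exact recursion — and it is the
construction the package's enumeration tests pin down: for small grids the
dynamic program agrees with exhaustive enumeration of every offset's score
distribution, entrywise to $10^{-12}$. What the independence product changes
in practice is measured, not assumed: with targets drawn from the null
column distribution, empirical $\Pr(P \le \alpha)$ stays at or below
$\alpha$ at $\alpha \in \{0.01, 0.05, 0.25\}$ (the calibration test and the
acceptance script both recompute this), so the reported P-values are
slightly conservative rather than inflated.

## Accelerations

Three features keep large query-by-database runs cheap without changing
results beyond stated tolerances:

* **Null caching.** The max-score null depends on the query, the target's
  *length*, the strand mode and the scoring configuration — not the target's
  columns. All equal-length targets share one cached distribution; the cache
  key embeds a digest of the configuration so changed settings can never
  serve a stale null. Cached and uncached runs are bitwise identical (tested).

* **Column hashing.** Databases repeat columns (point-mass columns in
  JASPAR-style PFMs especially). Distinct columns are scored once and
  weighted by multiplicity. For bitwise-equal duplicates the hit table is
  bitwise identical with hashing on or off (tested); columns that differ by
  less than the $10^{-6}$ key rounding are merged, which is below the
  precision of curated PFMs.

* **Approximate median.** With very large databases the exact weighted
  median is a sort bottleneck; `median_method = "approximate"` takes the
  midpoint of the histogram bin containing the 50% mass point (histogram of
  $B$ bins over the column's score range). Because every per-column score
  range is contained in the final quantization range, the approximation is
  within one final bin width of the exact median *by construction* — the
  property the contract tests assert. On a 20 x 100 random comparison the
  exact and approximate pipelines agree with $r > 0.999$ on $\log_{10} P$
  (recomputed by `scripts/acceptance.R`).

`threads` partitions work over queries; each query's pipeline is sequential
and free of randomness, so any thread count produces the identical table.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score` | `neg_euclidean` | column score; `pearson` available. Negative Euclidean is maximal (0) only for identical columns and needs no variance, so it is safe for CWMs and near-constant columns. |
| `bins` | 100 | quantization resolution. The null DP costs one convolution per query-column run, linear in `bins` per support point; halving `bins` halves resolution of reported P-values. |
| `strand` | `both` | `both` doubles the offset set and indexes reverse-complement columns; use `given` for CWMs whose sign convention is strand-specific, or for non-DNA alphabets. |
| `adjust` | `TRUE` | unaligned-position adjustment (background padding). Disable to reproduce overlap-only ("incomplete") scores. |
| `median_method` | `exact` | exact weighted median; `approximate` for the histogram median described above. |
| `p_threshold`, `top_k` | off | output filters; the full table is returned by default. |

Defaults for the synthetic generators: Dirichlet concentration 0.5 gives
sharp, TF-like columns (a point-mass-heavy column distribution similar to
curated PFMs); widths 8–12 match typical TF motifs; the planted-scenario
noise model mixes columns with the uniform column at a fixed rate, which is
deliberately simple — it degrades all positions evenly, unlike real
attribution noise which is position-correlated.

## Numerical choices

* Convolutions are computed by direct shifted accumulation of non-negative
  products, not FFT: FFT convolution bounds only the *absolute* error
  (~$10^{-16}$), which destroys the relative accuracy of far-tail masses —
  exactly the P-values one cares about. Direct accumulation keeps relative
  error near machine precision; the survival product is accumulated in log
  space (`log1p`/`expm1`) for the same reason.
* Null pmfs are renormalised once after construction if they drift from unit
  mass by more than $10^{-12}$.
* A degenerate score range (all centered scores equal) collapses to a
  single-bin grid: every comparison then has $P = 1$, which is the honest
  answer for a query that cannot distinguish targets.
* P-values below the null support are 1; above it they are floored at the
  smallest positive double rather than 0.
* Ties for the best alignment are broken by smallest offset, then `+`
  orientation. This is reproducible but not equivariant under reverse
  complementation of the query: when the best score is *exactly* tied across
  orientations (which happens among chance-level, single-column overlaps),
  the reported orientation of the forward and RC runs may coincide instead
  of flipping. P-values are unaffected.
* Pearson correlation against a zero-variance column is defined as 0.

## Problem sizes used by the tests

The test suite and acceptance script generate everything they use:
enumeration checks run on grids up to width 3 x 4 target columns x 8 bins
against exhaustive oracles; calibration uses 20 replicates of 4 x 500
comparisons (40 000 pairs); the transparency checks use a 50-query x
200-target database containing 50 exact duplicate motifs; recovery checks
use 50-motif databases with up to 3 columns of flank shift and random
reverse complementation. These sizes exercise every code path (caching,
hashing, both strands, adjustment) while keeping the whole suite fast enough
to run routinely.

## What passing tests do and do not show

The generators emulate databases of independent random motifs with
TF-like column sharpness, and seqlets that are exact or mildly corrupted
copies of database entries. Real motif databases contain *families* of
highly similar motifs; a seqlet will often match several family members at
indistinguishable P-values, so "recovers the exact source" is a stricter
criterion than real use requires — and conversely, passing it on independent
random motifs does not demonstrate that family members can be told apart.
Real attribution tracks also produce seqlets with correlated, position-
dependent noise and soft edges that the uniform-mixing noise model does not
imitate. The calibration result says P-values are conservative under the
package's own null; it does not certify error rates under database structure
(motif families violate the i.i.d. column assumption).

## Known limitations

* Gapped alignments are out of scope; only ungapped offsets are scored.
* The null's independence-across-offsets construction makes deep-tail
  P-values approximate (empirically conservative); precise ranking *among*
  very strong hits should rely on scores or E-values with that caveat in
  mind.
* Column scores other than negative Euclidean and Pearson (Kullback–Leibler,
  ALLR, Sandelin–Wasserman) are not provided.
* E-values extrapolate only to the binned support; they cannot fall below
  the smallest representable tail mass times the database size.
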