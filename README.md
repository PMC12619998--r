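# tomtomlite

Fast motif similarity search with exact, integer-binned null distributions —
an R implementation of the Tomtom statistic for comparing position matrices.

## Who this is for

Anyone who needs to ask "which known motif does this matrix look like, and
how surprised should I be by the match?":

* comparing de-novo discovered PWMs against a curated database
  (JASPAR-style PFMs, MEME motif files);
* annotating **seqlets** — spans of high-attribution nucleotides extracted
  from a deep-learning model's attribution track, represented as
  contribution-weight matrices (CWMs) — against a TF motif database;
* any pairwise screening of frequency- or attribution-based position
  matrices where calibrated P-values, E-values and FDR q-values matter.

## The statistic

For a query with columns $q_1,\dots,q_{w_q}$ and a target with columns
$t_1,\dots,t_{n_t}$, every ungapped offset $o \in \{-(w_q-1),\dots,n_t-1\}$
(and both orientations for DNA) is scored as the sum of aligned column
scores $\sum_i \gamma(q_i, t_{o+i})$, with $\gamma$ the negative Euclidean
distance by default (Pearson correlation available). The reported match
score is the maximum over all offsets and orientations.

To convert that maximum into a P-value, per-column scores are centered on
their multiplicity-weighted median across the whole target database (this is
what makes the statistic sensitive to information content), quantized into
$B = 100$ integer bins, and convolved exactly: under the null, target
columns are i.i.d. draws from the database's empirical column distribution
and each offset is an independent draw, so the maximum has survival function

$$\Pr(S_{\max} \ge x) \;=\; 1 - \prod_{o}\, F_o(x^-),$$

with each per-offset CDF $F_o$ built by exact convolution of binned
per-column nulls. Unaligned target positions are scored against a background
column (the unaligned-position adjustment), so scores at different overlaps
are comparable. P-values are inclusive ($\Pr(S \ge x)$), hence conservative
under quantization ties; E-value = P × number of targets; q-values are
Benjamini–Hochberg per query.

Three accelerations leave results unchanged (bitwise, and tested as such):
null distributions are **cached** across equal-length targets, duplicated
database columns are **hashed** and scored once with multiplicities, and
queries are partitioned across **threads**. An optional approximate
(histogram) median trades an at-most-one-bin shift for speed on very large
databases.

## Worked example

```r
library(tomtomlite)

db    <- random_pwm_set(25, width = c(6, 10), seed = 42, name_prefix = "db")
query <- db$motifs[[7]]; query$name <- "query"

hits <- tomtom(motif_set(list(query)), db)
head(hits, 5)
#> # A tibble: 5 × 9
#>   query target score offset orientation overlap  p_value  e_value  q_value
#>   <chr> <chr>  <dbl>  <int> <chr>         <int>    <dbl>    <dbl>    <dbl>
#> 1 query db_7    6.22      0 +                 9 1.47e-23 3.67e-22 3.67e-22
#> 2 query db_18   3.17     -3 +                 6 3.64e- 4 9.11e- 3 4.55e- 3
#> 3 query db_8    1.93     -2 -                 6 8.02e- 2 2.01e+ 0 4.89e- 1
#> 4 query db_17   2.14     -1 +                 8 9.04e- 2 2.26e+ 0 4.89e- 1
#> 5 query db_2    1.85     -6 -                 3 1.10e- 1 2.76e+ 0 4.89e- 1
```

The query is a copy of `db_7`, and the table says exactly that: at offset 0,
`+` orientation, all 9 columns aligned, the match is astronomically unlikely
under the null (`p = 1.5e-23`; `e_value = p * 25` targets), while the best
decoy (`db_18`) is a marginal partial match and everything else is
chance-level. `score` is the maximum alignment score reconstructed from bin
midpoints of the median-centered column scores. `glance(hits)` summarises
the table (here: 2 hits at `q < 0.05`).

Seqlet annotation works the same way through a convenience wrapper:

```r
fx  <- planted_database(n_database = 30, n_seqlets = 10, n_decoys = 2,
                        max_shift = 2, rc_prob = 0.5, seed = 11)
ann <- annotate_seqlets(fx$seqlets, fx$database, p_threshold = 0.05)
ann
#> <seqlet annotation> 12 seqlets, 12 assigned to 10 motifs
```

`ann$assignments` maps every seqlet to its best database hit (or
`"unassigned"`); `ann$counts` tallies seqlets per motif —
`autoplot(ann)` draws the tally, `autoplot(hits)` a query-by-target
P-value heatmap, and `plot_motif()` a quick logo.

Motif I/O: `read_meme()` / `write_meme()` (MEME minimal motif format),
`read_jaspar_pfm()` (bracketed or plain count rows), `read_cwm_tsv()` /
`write_cwm_tsv()` for attribution matrices, `write_hits_tsv()` for
Tomtom-style TSV output. A shell entry point wraps it all:

```sh
exec/tomtomlite run --query queries.meme --targets db.meme -o hits.tsv
exec/tomtomlite annotate --seqlets seqlets.meme --database db.meme -o annot.tsv
exec/tomtomlite fixtures --spec spec.json -o fixtures/
```

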