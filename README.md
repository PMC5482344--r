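# ternet

Edge-colored bipartite networks for drug–target interaction data.

Most interaction databases record which drug–target pairs are *active* and
stay silent about everything else. That silence mixes two very different
things — pairs measured and found inactive, and pairs never measured at
all — and conflating them biases every promiscuity statistic computed from
the data. `ternet` keeps the three states apart: every pair of an
*n* drugs × *m* targets network is **active**, **inactive**, or
**unknown** (unknown-by-omission), i.e. the biadjacency matrix is split
into three binary indicator matrices with

    A+ + A− + A* = 1   (elementwise)

From this representation the package computes:

* **Polypharmacology** `π̂_PP(d)` (row sums of `A+`: targets a drug is
  active against) and **polyspecificity** `π̂_PS(t)` (column sums: drugs
  active against a target) — dual notions: polyspecificity in a network
  equals polypharmacology in its transpose.
* **Global completeness** `C_DT = (μ̂+ + μ̂−) / (n·m)`, the fraction of
  pairs with a determined status.
* **Local uncertainty** `ε̂ = |T| − π̂ − k̂−` per entity (equivalently,
  its count of unknown pairs).
* **Degree bounds** `π̂ ≤ π_true ≤ π̂ + ε̂`: if all determinations are
  correct, the true degree lies in this interval, which every new
  determination — including an inactivity — can only tighten.
* Per-entity **profile vectors** (active, inactive, unknown) with
  Euclidean distances and cosine similarities for downstream clustering.

It is tidyverse-native (tibbles in and out, `tidy()`/`glance()`
methods, `autoplot()`), reads/writes long-format edge lists and ternary
status matrices, exports GraphML, and includes seeded generators of
ground-truth and database-style masked networks plus a `ternet`
command-line tool.

## Worked example

The package ships an 8-drug × 4-target network with 19 active, 7 inactive
and 6 unknown pairs:

```r
library(ternet)
net <- load_worked_example()
summary_table(net)
#> # A tibble: 12 × 7
#>    entity side   active inactive unknown lower_bound upper_bound
#>    <chr>  <chr>   <int>    <int>   <int>       <int>       <int>
#>  1 d1     drug        3        0       1           3           4
#>  2 d2     drug        2        1       1           2           3
#>  3 d3     drug        1        1       2           1           3
#>  4 d4     drug        3        1       0           3           3
#>  5 d5     drug        2        1       1           2           3
#>  6 d6     drug        2        2       0           2           2
#>  7 d7     drug        4        0       0           4           4
#>  8 d8     drug        2        1       1           2           3
#>  9 t1     target      5        1       2           5           7
#> 10 t2     target      5        2       1           5           6
#> 11 t3     target      4        1       3           4           7
#> 12 t4     target      5        3       0           5           5
#> # completeness: mu+ = 19, mu- = 7, mu* = 6, c_dt = 0.813
```

Each row is one entity's 3-vector of colored degrees plus its degree-bound
interval: drug `d3` is known active against 1 target, but with 2 pairs
undetermined its true polypharmacology can be anywhere from 1 to 3;
`d7` has no unknown pairs, so its degree 4 is exact. The footer says 26 of
the 32 pairs are determined (`c_dt = 26/32`, printed 0.813 at three
decimals).

The same workflow from the shell:

```sh
ternet=$(Rscript -e 'cat(system.file("exec", "ternet", package = "ternet"))')
edges=$(Rscript -e 'cat(system.file("extdata", "worked_example_edges.tsv", package = "ternet"))')
Rscript "$ternet" completeness --input "$edges"
#> mu_plus	mu_minus	mu_star	c_dt
#> 19	7	6	0.813
```

Subcommands: `summarize`, `completeness`, `bounds`, `profile`,
`decompose`, `convert`, `export-graphml`, `simulate`, `mask`.

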