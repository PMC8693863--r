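# myofuse

Is myotube growth random? During muscle differentiation, mononucleated
myoblasts fuse into multinucleated myotubes. When a time-lapse movie shows
large myotubes accumulating nuclei much faster than small cells, two
explanations compete: a *regulated* process in which nascent "founder"
myotubes actively recruit surrounding myoblasts, or a purely *stochastic*
one in which larger cells simply bump into partners more often. `myofuse`
implements the data-driven **shadow simulation** analysis that separates
the two, for anyone quantifying fusion dynamics from annotated time-lapse
microscopy.

## The method

The input is a **multinucleation census**: per hourly interval *t*, the
counts *C<sub>t</sub>(i)* of cells with *i* nuclei, where annotation bins
every cell with ≥ 4 nuclei into the top class (the *annotation cap*).

1. **Fusion-event estimator.** Each fusion merges two cells, so the number
   of fusion events in interval *t* is estimated from consecutive
   snapshots as

   N<sub>fusion</sub>(t) = Σ<sub>i=2..4</sub> (C<sub>t</sub>(i) −
   C<sub>t−1</sub>(i)) · (i − 1),

   assuming a closed population (fusion only — no division, death, or
   field exit). Because of the cap this is a *lower bound* on the true
   event count whenever cells exceed 4 nuclei.

2. **Shadow simulations.** Starting from *N* mononucleated cells (the
   nuclei total at onset), the estimated schedule is replayed: each event
   picks two distinct cells and merges them. Two null kernels are
   provided — `equal` (every pair equally likely) and `weighted` (cells
   drawn sequentially without replacement with probability proportional
   to their nuclei count, modelling the larger contact area of bigger
   cells). After each interval the simulation records **f4**, the
   fraction of nuclei residing in cells with ≥ 4 nuclei.

3. **Bootstrap test.** 1000 replicate simulations form the null
   distribution of f4 at each interval. The p-value is the exact fraction
   of replicates whose f4 *equals or exceeds* the observed value; the
   null of random fusion is rejected at p ≤ 0.05 (inclusive: 50 of 1000
   replicates is a rejection).

A synthetic-data generator (`equal`, `weighted`, and founder-directed
regimes with ground-truth event logs) makes every stage verifiable, and
supporting metrics cover fusion index, stratified nuclei distributions,
marker-positive nuclear fractions, and nuclei-track migration rates.

## Worked example

A synthetic founder-regime census ships with the package (500 nuclei,
12 hourly intervals, strongly biased recruitment — the kind of directed
growth the test should flag as non-random):

```r
library(myofuse)
census <- read_census_table(system.file("extdata",
  "synthetic_founder_census.csv", package = "myofuse"))
res <- run_both_kernels(census, n_sim = 1000, seed = 7)
attr(res, "schedule")
#> <fusion_schedule: 12 intervals, 104 fusion events total>
res$equal
#> <fusion_test: kernel=equal, n_sim=1000, alpha=0.05, 12/12 intervals rejected>
#>   t observed_f4 exceed_count p_value reject
#>   1     0.02410            0       0   TRUE
#>   2     0.04032            0       0   TRUE
#>   ...
#>  12     0.24714            0       0   TRUE
```

By the final interval 24.7% of the annotated nuclei sit in ≥ 4-nuclei
cells, while *none* of the 1000 random-fusion replicates (under either
kernel) gets that far on the same fusion budget: the estimator credits
only the 104 *visible* events (fusions into already-large cells are hidden
by the cap), and random pairing spreads even those across many small
cells. Both nulls are rejected at every interval — directed growth is not
explained by random fusion, under the equal or the size-weighted kernel.

The same analysis is available from a shell:

```sh
myofuse test --census census.csv --n-sim 1000 --seed 7 --out results/
myofuse synth --regime founder --n 500 --t 12 --rate 15 --seed 1 --out synth/
```

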