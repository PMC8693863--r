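---
title: "Shadow simulations for myoblast fusion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow simulations for myoblast fusion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofuse)
```

## The question and the model

Time-lapse movies of differentiating myoblast cultures show nascent
myotubes (2–3 nuclei) expanding rapidly by fusing with mononucleated
neighbours. `myofuse` asks whether that expansion is consistent with
*random* cell–cell fusion, by comparing the observed multinucleation
dynamics against stochastic simulations that are matched to the data — a
"shadow" of the experiment that replays the same number of fusion events
under a null pairing rule.

The data model is deliberately minimal. A field of cells is described
only by the multiset of per-cell nuclei counts. The population is closed:
fusion merges two cells into one with the summed nuclei count, and no
division, death, or migration in or out of the field occurs over the
assay window (nuclei are conserved; the cell count falls by one per
event). Space, motility, and contact geometry are abstracted away — the
size-weighted kernel is the only nod to geometry, under the simplistic
assumption that an *n*-nucleated cell presents *n* times the contact area
of a mononucleated one.

Annotation imposes a *cap*: a human annotator (or a segmentation
pipeline) reliably distinguishes 1-, 2- and 3-nuclei cells, but records
every cell with 4 or more nuclei as a "4-nuclei cell". The census at
interval $t$ is therefore $C_t(i)$ for $i \in \{1, \dots, \mathrm{cap}\}$
with the top class open-ended. All defaults use cap = 4; the cap is
configurable throughout.

## Estimating the fusion schedule

Under fusion-only dynamics, the number of events in interval $t$ is

$$\widehat{N}_\text{fusion}(t) \;=\; \sum_{i=2}^{\mathrm{cap}}
\bigl(C_t(i) - C_{t-1}(i)\bigr)\,(i-1),$$

with weight $\mathrm{cap}-1$ for the top class. The weight $(i-1)$ is the
number of fusions needed to assemble an $i$-cell from singletons, and the
telescoping difference credits each interval with the events that
happened inside it. Two properties matter for interpretation:

* **Exactness below the cap.** If no cell's true size ever exceeds the
  cap, the estimate equals the realized event count exactly — the test
  suite checks this against the synthetic generator's event logs.
* **Lower bound above the cap.** A fusion *into* an already-capped cell
  leaves every census class unchanged except $C_t(1)$ (weight 0), so it
  is invisible; a fusion *between* two capped cells even decrements the
  top class. Per event the contribution to the estimate is at most 1,
  so cumulatively the estimate never exceeds the truth.

Negative raw differences cannot be replayed by a simulator and would
imply a broken closed-population assumption (cell death, field exit,
annotation noise); they are clamped to zero with a warning, and the raw
values are kept in the schedule for diagnostics. No smoothing is applied
to the census.

## The shadow simulation and its statistic

A replicate starts from $N$ mononucleated cells, where $N$ is the
annotated nuclei total at onset (exact when the movie starts before any
fusion). For each interval it executes
$\widehat{N}_\text{fusion}(t)$ pair-selection/merge steps and then
records

$$f_4(t) \;=\; \frac{\#\{\text{nuclei in cells with} \ge 4
\text{ nuclei}\}}{\#\{\text{all nuclei}\}},$$

i.e. the probability that a randomly chosen nucleus sits in a large
multinucleated cell. The end-of-interval timing matches the hourly
annotation. Two pairing kernels define the null:

* **equal** — all $\binom{m}{2}$ unordered pairs equally likely;
* **weighted** — two sequential size-proportional draws without
  replacement (first cell with probability $\propto$ size, second
  $\propto$ size among the rest). A pair-level alternative (pair
  probability $\propto$ product of sizes) exists in the literature of
  coagulation kernels but is not the direct reading of per-cell
  size-proportional selection, and is not implemented as a kernel.

The observed statistic comes from capped counts (numerator
$\mathrm{cap}\cdot C_t(\mathrm{cap})$), so it is itself a lower bound on
the true fraction; the simulated statistic uses true simulated sizes by
default. The two distortions act in opposite directions (an
underestimated schedule *and* an underestimated observation) and only
bite late in an experiment, once cells exceed the cap. For sensitivity
analysis, `cap_statistic = TRUE` applies the annotation cap to the
simulated states as well. Note that the capped statistic is not
guaranteed monotone in time (merging two capped cells shrinks both
numerator and denominator); the default uncapped statistic is
non-decreasing within every replicate, which the suite property-tests.

## The bootstrap test

For each interval, the ensemble (default `n_sim = 1000` replicates)
provides the null distribution of $f_4(t)$. The p-value is the exact
exceedance fraction

$$p(t) \;=\; \frac{\#\{r : f_4^{(r)}(t) \ge f_4^{obs}(t)\}}{n_{sim}},$$

with ties counted as exceedances (conservative) and no continuity
correction, so p-values live on the grid $\{0, 1/n_{sim}, \dots, 1\}$.
Rejection uses the inclusive threshold $p \le \alpha$ with
$\alpha = 0.05$: exactly 50 exceedances in 1000 replicates is a
rejection. p-values are reported per interval without multiple-testing
correction — each interval is a separate claim about the trajectory — and
an optional Bonferroni column is available for summary use. The onset
snapshot is not tested (no schedule exists for it). Because the statistic
is one-sided and discrete, the test is conservative under its own null:
at the calibration conditions used in the test suite (equal-regime data,
$N = 500$, $T = 10$, $\lambda = 15$) the empirical type-I error is about
0.03 at $\alpha = 0.05$.

## The synthetic-data generator

`generate_experiment()` produces ground-truth trajectories with full
event logs, so the estimator (against the log), the simulator (against
enumeration), and the test (calibration and power) are all verifiable
without any external data. Three regimes span the hypothesis space:
`equal` and `weighted` mirror the two null kernels; `founder` models
directed growth — the acceptor is drawn with weight $\beta$ if
multinucleated and 1 if mononucleated, and the donor uniformly among
mononucleated cells (falling back to uniform pairing when none remain).
$\beta$ is a free synthetic parameter, not an estimate of any biological
quantity; at $\beta = 0$ the regime degenerates to equal pairing among
mononucleated cells.

Event counts per interval are Poisson with mean $\lambda_t$ — the
minimal counting model for independently occurring events; a
deterministic-count mode supports exact estimator checks. Events that
would exhaust the population are dropped with a warning. Defaults
($N = 1000$ nuclei, $T = 15$ hourly intervals, $\lambda = 15$,
$\beta = 50$, cap 4) emulate a well-populated field followed over the
8–23 h window in which secondary fusion unfolds; nuclei totals reported
for such assays aggregate many fields, so the per-field scale is an
order-of-magnitude choice, not a fitted value. What the generator does
*not* emulate: division and death before fusion onset, cells leaving the
field, annotation mistakes (mis-segmented nuclei), and spatial
correlation between successive fusion events. Passing tests therefore
validate the computational chain, not the closed-population assumption
itself in any particular movie — inspect the `raw` column of the
estimated schedule for systematic negatives before trusting the test on
real data.

```{r example}
exp <- generate_experiment(regime_config("founder", N = 500, T = 12,
                                         rate = 15, founder_bias = 50,
                                         seed = 2026))
res <- run_both_kernels(exp$observed, n_sim = 1000, seed = 7)
res$equal
```

## Numerical and design choices

* **Statistic denominator.** $f_4$ uses *all* nuclei in the field as the
  denominator — it is a per-nucleus probability. The alternative
  (denominator restricted to nuclei of multinucleated cells) is exposed
  as `multinucleated_only = TRUE`, off by default. Whether a given
  annotation pipeline counts every nucleus in the field or only nuclei
  of tracked cells is a provenance question for the input table, not a
  package setting.
* **Reproducibility.** Every stochastic entry point takes an integer
  seed. Ensembles derive one substream per replicate from the master
  seed (order-independent), and `run_both_kernels()` derives one
  substream per kernel from the run seed by stage name, so results for
  one kernel are bit-identical whether or not the other runs. Reruns
  with the same manifest are bit-identical; changing the master seed
  moves only the simulated ensembles, never the estimator output.
* **Exceedance comparison.** Observed and simulated statistics are exact
  binary rationals of small integers; ties at 0 and 1 are exact, and the
  inclusive `>=` comparison is applied directly to the doubles.
* **Degenerate inputs.** Empty populations, all-zero snapshots,
  single-snapshot series, infeasible schedules (more fusions than
  cells), and sub-2-cell draws all raise errors before any computation;
  negative estimates and dropped synthetic events warn and are recorded.
* **Kernel ordering.** Size-weighted pairing concentrates nuclei faster
  than equal pairing: its mean $f_4$ dominates at every interval for
  moderate-to-heavy fusion loads. The dominance closes — and can invert
  slightly at the final intervals — when cumulative fusions approach the
  number of cells, because almost every nucleus then sits in a
  $\ge 4$-cell under either kernel. The suite tests dominance at 240
  fusions among 500 cells, where it is well resolved.
* **Problem sizes.** The test suite and acceptance script run the full
  analysis at the conditions above ($N = 500$, $T = 10$–$12$,
  $n_{sim} = 1000$; 100–200 replicate experiments for calibration and
  power), and validate kernels by exhaustive enumeration over all states
  with at most 6 cells and 10 nuclei, using $10^5$ draws per state with
  a familywise-adjusted acceptance band.

## Limitations

The test is purely simulation-based; no parametric approximation to the
null is offered. The estimator trusts the closed-population assumption
and understates fusion activity once cells pass the annotation cap, so a
non-rejection late in a heavily fused experiment is weaker evidence than
an early one. The founder regime is a caricature of directed recruitment
(acceptor-biased, donor-uniform); it is designed to probe the test's
power, not to be fitted to data.
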