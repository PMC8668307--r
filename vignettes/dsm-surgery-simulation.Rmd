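---
title: "Simulating surgical procedure duration with a design structure matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating surgical procedure duration with a design structure matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmsim)
```

## The model

A surgical procedure is decomposed into an ordered list of activities
(surgemes).  The process structure is a design structure matrix: a square
matrix over the activities in which an off-diagonal mark records that one
activity's output is another's input.  `dsmsim` stores this unambiguously
as a provider → consumer edge list; the matrix file format carries an
orientation flag (default: reading down column *j* gives the inputs of
activity *j*) because the DSM literature uses both conventions and silent
transposition is the classic failure mode.

Three parameters drive the duration model:

* **Rework probability** `P_ir = P_i × P_r` per dependency — the chance
  that a deviation in the provider (`P_i`, *volatility*, estimated as the
  deviant fraction `N_oc / N_o` of observed executions) propagates into a
  forced repeat of the consumer (`P_r`, *sensitivity*, `N_ir / N_ic`).
  When deviation classes with different sensitivities are tallied
  separately, per-class probabilities combine as
  `1 − Π(1 − P_class)` — the probability that at least one class triggers.
* **Rework impact** `RI ∈ [0, 1]` per activity — the fraction of the
  activity redone when rework occurs.  Elicited from senior raters over a
  range of situations and averaged.
* **Improvement curve** `IC ∈ (0, 1]` per activity and rework iteration —
  the learning multiplier on successive repeats.  For fully trained
  surgeons it is constant at 1; a shorter list than the realised number of
  iterations is extended by repeating its last value.

Durations are triangular three-point estimates (BCV ≤ MLV ≤ WCV, minutes),
chosen because annotated video samples are small and highly variable;
degenerate estimates (all three equal) are allowed and give deterministic
activities.  Inputs are taken at 0.1-minute precision and summaries are
printed to 0.1 min, matching what can realistically be read off video.

## Partitioning

Rework loops are exactly the strongly connected components of size ≥ 2 of
the dependency graph (computed via igraph, and cross-checked in the test
suite against a brute-force Warshall-reachability oracle).  The execution
sequence is the declared protocol order: partitioning reports loops, it
does not reorder the procedure.  The sequenced order is produced by a
Kahn topological sort of the loop-condensed graph with ties broken by
declared order, which reproduces the declared order whenever it is
topologically consistent (always true for the modelled protocols).
Active sets are computed by scanning that order and cutting immediately
before any activity that depends on a not-yet-executed upstream activity.

## The Monte Carlo engine

Each run:

1. draws one first-trial duration `D_0` per activity by inverse-CDF
   transform of a uniform variate (or fixes `D_0 = MLV` in `mlv_only`
   mode);
2. for every rework loop, walks the cyclic dependencies in loop order and
   draws each edge's iteration count `nr`; the consumer's rework cost is
   `D_0 × RI × Σ_{i=1..nr} IC_i`.  Rework reuses the run's drawn `D_0`
   (rework is a fraction of the original work, not a fresh draw);
3. applies the same single-edge machinery to every non-loop dependency;
4. totals `D_total = Σ D_0 + Σ loop rework + Σ single-edge rework` — an
   exact accounting identity asserted per run in the tests, not an
   approximation.

**Trigger convention.**  A rework iteration occurs while the uniform draw
is *below* `P_ir` (`rework_trigger = "standard"`), making the uncapped
count geometric with `P(nr = k) = p^k (1 − p)` and preserving the meaning
of `P_ir` as a small probability of rework.  The inverted reading — rework
while the draw *exceeds* the threshold, under which 0.1 would rework 90% of
passes — is available as `rework_trigger = "literal"` for comparison
experiments, but is not the default precisely because it contradicts the
interpretation of 0.1 as a rare event.

**Caps.**  `P_ir = 1` would loop forever under per-iteration Bernoulli
semantics.  The default cap is therefore 1 iteration for probabilities
≥ 0.999 — a certainty observed in the data means "this rework happens,
once per pass" — and 25 otherwise, where the truncation error of the
geometric tail is below `p^25` and numerically negligible for any
realistic `p`.  An explicit `max_reworks_per_edge` overrides both.

**Propagation depth.**  Rework of a loop member does not re-trigger rework
of downstream activities outside the loop: the engine is first-order, and
higher-order compounding is the risk module's job (below).  Dependencies
inside a loop that are not cyclically consecutive (chords) are treated as
sequencing-only; loops whose members do not form a full cycle of edges
raise a structural error rather than silently simulating half a loop.

**Random stream.**  A single seeded generator is consumed in a fixed
activity-then-edge order, and every edge always consumes exactly `cap`
uniforms regardless of how many trigger.  This makes runs bit-reproducible
and gives exact stochastic monotonicity: raising any single rework
probability, with everything else and the seed fixed, can only leave each
run's total unchanged or increase it — a property the suite asserts
run-by-run.

**Deterministic analogue.**  `expected_duration()` replaces sampling by
MLVs and the random count by its expectation.  It computes the exact
expectation of the improvement-curve sum,
`Σ_{k=1..cap} IC_k q^k`, rather than `E[nr]` times a mean multiplier; the
two coincide for constant curves (all validated cases) but only the former
matches the `mlv_only` Monte Carlo mean for genuinely decreasing curves,
which is the self-consistency the tests check at 20 000 runs within three
standard errors.

## Risk propagation

Each dependency's risk factor is `R = P_ir × RI`.  Over *n* propagation
steps risk compounds as `R^n`, so the maximum cumulative risk is the
geometric series `CR = Σ_{n≥1} R^n = R / (1 − R)` for `R < 1`.  Pairs with
`R ≥ 1` (e.g. a certain full-impact loop) have a divergent series: they are
reported as unbounded and excluded from totals with an explicit count,
because folding an infinity into a sum would misstate every margin.

The matrices are oriented receivers-in-rows / providers-in-columns, so the
column sum `f_j` is the total maximum risk activity *j* transfers to others
and the row sum `e_i` is the total it receives; `Σf = Σe =` the grand
total by the double-sum identity.  Because the scalar double sum and the
per-activity reading are both defensible summaries, the report exposes
both: `tr_total` and `tr_activity = f + e`.

## Parameter estimation

`estimate_volatility()`, `estimate_sensitivity()` and
`estimate_rework_probabilities()` turn annotation tallies into edge
probabilities.  `fit_triangular()` anchors BCV and WCV at the sample
extremes and estimates MLV by the sample median for n ≤ 5, switching to a
half-sample mode estimator for larger samples — the median is the only
stable choice at the sample sizes video annotation yields, while the
half-sample mode tracks the dense region instead of the tail once there is
enough data; both are clamped to `[min, max]` so the triangular invariants
hold by construction.  `N_ic` and `N_oc` are accepted as independent
tallies and a mismatch is flagged, not resolved: the annotation pipeline,
not the estimator, owns that reconciliation.

## The packaged fixtures

The two shipped fixtures emulate the *structure* of a standard and a
pediatric laparoscopic cholecystectomy protocol: nine activities with one
certain two-activity rework loop (artery clipping ↔ cutting, rework
probability 1 both ways, RI 1) plus cleaning dependencies A4–A7 → A8 and a
0.1 default elsewhere; and eleven activities, strictly feed-forward, all
probabilities and impacts 0.1.  Their per-activity duration profiles are
**synthetic**: fixed weight vectors (longer dissection/separation steps,
shorter cutting steps) rescaled so the MLVs total `duration_scale`
(defaults 10 and 5.7 minutes, the two protocols' model-predicted totals),
with `BCV = 0.8 × MLV` and `WCV = 1.5 × MLV`.  No number derived from
these duration profiles is a protocol measurement, and passing tests on
these fixtures demonstrates engine correctness on the described
structures — not calibration to any real surgery.  `make_random_dsm()`
generates reproducible random structures for property testing and does not
emulate any protocol at all.

Real annotated data also exhibit features the generator deliberately
omits: inter-rater disagreement, duration correlation between adjacent
activities, heavy-tailed complication durations, and surgeon-level
heterogeneity.  Conclusions about real procedures require estimating the
inputs from real annotations via the estimation module.

## Numerical choices and degenerate inputs

* Triangular sampling is exact inverse-CDF; degenerate spans return the
  point mass, and one-sided triangles (BCV = MLV or MLV = WCV) use the
  surviving branch.  Samples are clamped into `[BCV, WCV]` against
  floating-point spill.
* Probabilities are validated into `[0, 1]` at construction; `p = 0` edges
  are legal declared dependencies that never rework.
* Text serialisation uses 17 significant digits so that a
  write-read cycle reproduces doubles bit-exactly and seeded summaries
  survive file round trips unchanged.
* Condensation topological ties break by declared order; loop members are
  listed in declared order; equal-width half-sample windows take the first.
* Test problem sizes: loop-detection oracle comparisons on random DSMs up
  to 8×8; distribution-level checks at 20 000 runs (50 000 draws for the
  sampling-mean check), asserted within three standard errors or at
  α = 0.001 for the two-sample test; series-vs-closed-form agreement at
  1e−9 up to `r = 0.9`.

## Limitations

* Durations are purely additive: no overlapped or resource-constrained
  activities, no schedule compression, no costs.
* Rework is first-order outside loops; long-range cascades appear only
  through the risk module's geometric bound, which is a per-pair maximum,
  not a matrix-power path analysis.
* Loops are simulated along their cyclic dependency sequence; exotic
  strongly connected structures without a full cycle are rejected rather
  than approximated.
* The validation statistic `relative_error()` uses the *prediction* as
  denominator — the convention consistent with both published comparison
  figures it reproduces — so it is not symmetric in its arguments.
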