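---
title: "phenoDE: methods, fixture calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoDE: methods, fixture calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoDE)
```

# The modelling problem

phenoDE explores the parameter space of growth–division (cell cycle)
models that are constrained by *discrete* phenotypes rather than by
time-series data. A parameter vector is *feasible* when the model it
defines reproduces the required viability phenotype of every strain in
a training set; the collection of feasible vectors — typically a large,
irregular region — is then interrogated for what it predicts about
strains whose phenotypes are unknown. The package implements four
layers: simulation and phenotype classification, feasible-ensemble
generation (Latin hypercube sampling and a modified differential
evolution), ensemble statistics (prediction range, robustness,
relative-abundance variability), and a random-forest classifier that
maps abundance statistics to network modules.

# Simulation and phenotype rules

Integration is fixed-step explicit Euler, `dt = 0.05` min over a
2000-min horizon — deliberately not adaptive, so that feasibility is a
property of one reproducible numerical procedure. Division events fire
at the first grid point where the model's trigger predicate holds; the
division map (size times the daughter fraction `f`) is applied at that
grid point, before the next Euler step, and the simulation follows the
daughter cell that retains fraction `f < 0.5` (the smaller cell of the
asymmetric division).

A trajectory's phenotype code is decided in this order:

1. **Inviable (2)** — cell size exceeds the cap (default 25 arbitrary
   units) at *any* grid point, or the integration blew up. The cap
   takes precedence over every other rule: a multiply periodic cell
   that transiently crosses the cap is inviable, because the
   inviability rule is quantified over all times.
2. **Viable (1)** — at least three divisions, and the size at the last
   division is within 5% of the sizes at *both* previous divisions.
   The denominator of the 5% band is the last division size (the rule's
   source does not name a denominator; the last size is the reference
   the comparison is anchored to).
3. **Multiply periodic (0)** — at least three divisions, band violated.
4. **Inviable (2, reason `"arrest"`)** — fewer than three divisions.
   The published rules cover only the cap and the ≥3-division cases; a
   cell that stops dividing is not viable, so arrest maps to code 2,
   with the reason string preserving the distinction.

Feasibility is always judged on the 32-bit float truncation of the
parameter vector (`truncate32()`), which discards vectors that are
feasible only by virtue of double-precision digits.

# The toy fixture: what it emulates and how it was calibrated

The reference yeast model behind this methodology is not
redistributable, so the package ships a synthetic stand-in that mirrors
its *interface*: a size variable, three network modules, a strain panel
built by zeroing rates, and a feasible region with non-trivial
structure. The fixture makes no claim of biological realism.

## Dynamics

Species: size `V` (exponential growth, rate `mu = 0.007`/min, mass
doubling time ≈ 99 min), START activator `A` (two redundant synthesis
routes `ks_a = 0.108`, `ks_a2 = 0.012`, both driven by `V`), S/G2/M
activity `B` (Hill activation by `A`, `h = 4`), EXIT effector `E`
(Hill activation by `B`), EXIT clearance factor `Z` (integrates `E`),
and one pure reporter per module. `E` and `Z` jointly clear `A`
(`ki_ae = 0.25`, `ki_az = 1.5`), closing a delayed negative-feedback
loop: as `V` grows, `A` rises, `B` and `E` pulse, `Z` shuts `A` down,
`E` collapses. Division triggers on the *downward* crossing of `E`
through `theta_lo = 0.08` after it has exceeded `theta_hi = 0.3`
(hysteresis), and `V` is reset by `f = 0.45`.

## Why these numbers

Two structurally simpler designs fail, and knowing why documents the
parameter choices:

* Without positive feedback, a fast cascade with a slow integrating
  clearance variable settles into homeostasis — `A` is pinned at the
  Hill threshold and `E` creeps monotonically, so no division ever
  fires. The loop must operate as a *delay* oscillator: `A`'s
  relaxation time (1/`kd_a` = 10 min) is comparable to the follower
  and clearance timescales (5–10 min).
* A delay oscillator emits a pulse of `E` every ≈ 30 min while `V`
  grows ≈ 20% between pulses. If the division threshold sits high in
  the pulse-amplitude range, division "selects" a pulse, and division
  size is quantized in ±10% steps — violating the 5% viability band
  for the wild type.

The shipped fixture therefore operates the delay oscillator in a
*phase-locked* regime: a scan over the daughter fraction, arming
threshold and clearance decay (`f` ∈ 0.35–0.5, `theta_hi` ∈ 0.3–0.6,
`kd_z` ∈ 0.08–0.2) shows interleaved bands where division locks to the
pulse train (division-size spread < 0.5%, code 1) and bands of
quasiperiodic division (spread 5–20%, code 0). The reference point
(`f = 0.45`, `theta_hi = 0.3`, `kd_z = 0.1`) sits inside a locked band:
the wild type divides 17 times in 2000 min with terminal division sizes
1.887, 1.889, 1.892. The band structure is a feature, not an accident:
phenotypes flip across the jittered feasible neighborhood, which is
precisely the "strains whose viability differs across the feasible
region" property the fixture must exhibit. One consequence worth
stating: changing *only* `f` to 0.5 leaves the locked band and yields a
multiply periodic (code 0) wild type — size-map convergence arguments
do not apply to a pulse-quantized trigger.

Under the reference vector the nine eliminable rates span all three
codes: reporter knockouts are viable; `ks_a` and `ks_a2` knockouts are
viable (redundant routes) but near a code boundary; `ki_ae` deletion
gives a multiply periodic cell; `ki_az`, `ks_e` and `ks_z` deletions
are inviable (no clearance or no trigger pulse, so `V` grows past the
cap). The default training constraint is three strains — wild type
viable, one reporter knockout viable, growth-rate knockout inviable —
small enough that feasibility checks cost four simulations.

## The jittered reference ensemble

`make_reference_ensemble()` stands in for an externally supplied
ensemble of optimally performing vectors: multiplicative log-normal
jitter (default σ = 0.02) around the reference on all kinetic
parameters except the structural constants `f`, `h` and the trigger
thresholds (mirroring the practice of holding a few constants fixed),
with initial conditions left at their reference values; candidates are
kept if their float32 truncation passes FC1. At σ = 0.02 roughly 60%
of candidates are feasible; the feasible fraction falls monotonically
with σ (a tested property). Across a feasible ensemble the 10-strain
default panel typically yields 3–6 distinct prediction vectors with a
strongly skewed distribution (one row carrying ~70% of the vectors) —
qualitatively the same skew reported for the real system.

# Differential evolution with feasibility criteria

Mutation and crossover follow the classic scheme (`F = 0.1`,
`C = 0.5`, partner indices drawn without replacement excluding the
focal parent); the population default in desk-scale runs is smaller
than the reference study's 19 purely for budget. Selection accepts a
trial only if all active criteria pass:

* **FC1** — phenotype capture, always enforced. Every FC1-passing
  trial is recorded whether or not it is accepted; the prediction
  matrix is computed over all recorded vectors.
* **FC2** — the estimated volume of the parent population with the
  trial swapped in must strictly exceed the current volume. The
  estimator is the axis-aligned log bounding-box product
  (`estimated_log_volume()`): the region's published description
  compares volumes across ~80 orders of magnitude, implying a
  product-of-ranges-style estimate; the exact published algorithm is
  unavailable, so the estimator sits behind an interface and can be
  swapped. Comparisons happen on the log scale; the estimator is
  monotone (adding a vector never shrinks it). The volume axes default
  to the kinetic parameters that actually vary in the initial
  population — a fixed constant has zero range, and including it pins
  the log-volume at −∞, which would silently disable FC2.
* **FC3** — the trial's prediction vector must be new with respect to
  *all* prediction vectors seen this run (initial parents and accepted
  trials), a running-set interpretation of "up through the current
  generation". Prediction vectors computed during FC3 are cached on
  the run's record so the range S can be read off without
  re-simulation.

The dynamic-volume trace is recomputed once per generation over the
current parents (the published trace's exact windowing is unavailable);
with FC2 active it is non-decreasing, since parents change only
through volume-expanding acceptances.

Initial-population selection implements three modes. `Vmax` is greedy:
seed with the vectors attaining each per-axis extreme, fill greedily by
log-volume, then apply improving single swaps to a fixed point.
`SmaxVmax` buckets the ensemble by prediction vector, takes one
volume-greedy representative per bucket (largest buckets first) up to
N, then fills any shortfall volume-greedily. Both are stand-ins for
unavailable published procedures, chosen to satisfy their stated goals
("maximize the estimated volume", "each member generates a different
prediction vector").

## Scheme comparison at desk scale

The acceptance suite checks that scheme-8-style runs (Smax & Vmax
seeding, FC1+FC3) find strictly more unique prediction vectors than
FC1-only runs with random seeding, in at least 90% of ten seeds, at
matched sampling budgets. At full scale the published advantage is
driven by long-run DE contraction crippling the FC1-only arm; at three
generations of eight parents contraction has not set in, so the toy
expresses the advantage through the initial population — consistent
with the finding that initial-population selection dominates the
outcome (random seeding reportedly costs scheme 8 about 81% of its
efficiency). The comparison uses a jitter-0.04 seeding ensemble so the
region holds enough prediction-vector buckets for diverse seeding to
matter; measured before the test was frozen: 9 strict wins and 1 tie
in 10 seeds.

# Robustness scoring

The perturbation grid multiplies one critical parameter at a time by
1 ± 0.2, 1 ± 0.4, 1 ± 0.6, 1 ± 0.8 and additionally sets it to zero —
nine levels, all factor levels positive, so perturbed parameters never
go negative. "Maintained" is judged against the same vector's
pre-perturbation phenotype for that strain, simulated once and cached;
blow-ups count as lost. R̂ sums the indicator over parameters × strains
× levels (≤ 900 on a 10 × 10 grid), R̃ sums the nine levels of one
(vector, parameter, strain) cell, R̄ and Ř take ensemble maxima, and
relative robustness reports the sign of the R̄ difference per pair,
with ties reported as 0 (the published comparison shows only ±1 and is
silent on ties).

# Abundance statistics and ranking

Time-averaged species concentrations over the full horizon are the
abundance predictions; every ordered pair of distinct species forms a
relative abundance, computed per strain (wild type included by
default) and per ensemble vector with WT-seeded initial conditions.
CV = sample standard deviation (n−1) / mean across vectors — the n−1
convention is a package choice, stated because the source does not name
one — and non-finite CVs are dropped. A protein's variability score
sums the CVs of all ratios with that protein in the numerator (or
denominator; the correlation between the two rankings is itself an
exposed statistic). Percentile = 100·(n − rank)/(n − 1), anchoring
rank 1 at 100 and the last rank at 0; the "high" category is the top
half; ties break by species name for determinism. Process aggregation
averages member-protein scores, with singleton processes reported as
±0.00. The exact inclusion rules behind the published 47,850-record
count do not factor cleanly, so wild-type inclusion, the species set
and the orientation are all arguments.

# The module classifier

Features per record: mean, standard deviation, CV of the relative
abundance, and the numeric mutant id (passed through as a raw numeric
feature, imitating the cited toolbox's behaviour — a caveat, since ids
carry no metric meaning). Labels come from the module of the reference
species; unannotated species (the size variable) are dropped. The
forest is implemented in compiled code because no random-forest package
ships with the target environment and the evaluation protocol is part
of the method: 100 trees, bootstrap samples of size n with replacement
(so ≈ 63.2% of rows are in-bag per tree; a tested property), Gini
splits over `floor(sqrt(p))` candidate features, unlimited depth. Every
row is scored by vote fractions over the trees for which it was
out-of-bag; one-vs-rest ROC AUC uses the midrank (Mann–Whitney)
convention for ties; thresholds sweep OOB vote fractions (the
alternative — full-forest posteriors — is noted as an open choice in
the build contract; OOB fractions are the unbiased option). The Z-test
compares the mean per-run AUC to 0.5 with SE = sd/√(n_runs), one-sided;
under the label-permutation null the statistic is approximately
standard normal, so a null p-value above 0.05 is expected with ~95%
probability per module — the acceptance test asserts it at a fixed
seed.

The synthetic feature generator shifts (mean, std, CV) by
module-specific directions scaled by `effect_size` (default 1.5 noise
standard deviations, which lands the true-label OOB AUC near 0.84 —
chosen a priori as "strong but overlapping" structure; `effect_size =
0` makes labels exchangeable). What a green classifier test
establishes is that the pipeline detects module-structured statistics
when they exist and reports chance under the null; it does not
establish anything about real cell-cycle networks.

# Numerical choices and degenerate inputs

* Euler is never adaptive; non-finite state or |state| > 1e12 aborts
  integration and the trajectory is classified inviable.
* `truncate32` errors on values that overflow single precision rather
  than silently mapping them to ∞.
* A wild type with no divisions cannot seed mutant initial conditions:
  such vectors fail FC1 whenever the constraint contains a mutant, and
  prediction entries fall back to code 2 with the failure logged by
  reason.
* Horizon 0 yields a single-point trajectory with no events.
* Volume comparisons use strict `>` (FC2's "expansion"); degenerate
  axes yield −∞ and are excluded from default axis sets rather than
  papered over.
* LHS stratification is exact: each axis places exactly one sample per
  stratum, which the tests assert combinatorially rather than by a
  distributional approximation.

# Known limitations

* The toy fixture's phase-locked viability is sensitive to the trigger
  constants by design; users who re-parameterize it should re-run
  `make_toy_model(validate = TRUE)` to confirm the fixture contract.
* The bounding-box volume estimator ignores correlations between
  parameters; it orders ensembles consistently but its absolute values
  are not meaningful.
* Desk-scale DE runs (N ≤ 8, tens of generations) cannot reproduce
  published full-scale quantities (ensemble sizes in the thousands,
  S in the hundreds); the suite tests mechanisms and orderings, not
  those magnitudes.
* The generic (non-compiled) model path integrates in R and is two to
  three orders of magnitude slower than the native toy path; it exists
  for extensibility and as an independent cross-check of the compiled
  integrator, not for production ensemble generation.
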