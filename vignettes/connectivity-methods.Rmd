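---
title: "Estimating effective and functional brain connectivity from regional time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective and functional brain connectivity from regional time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcconnect)
```

## The problem

Regional fMRI analyses summarize each region of interest (ROI) as a single
BOLD time series — typically a couple of hundred volumes at a repetition
time of a few seconds — and ask two complementary questions about a set of
such series. *Functional connectivity* (FC) asks which pairs of regions
fluctuate together after the shared influence of all other regions is
removed; it is symmetric and is naturally expressed as partial Pearson
correlation. *Effective connectivity* (EC) asks which regions drive which:
it is directional, and `gcconnect` estimates it as nonlinear conditional
Granger causality — region A is said to influence region B when A's past
improves the prediction of B's present beyond what B's own past and the
past of every other region already achieve. Both analyses produce graphs
over the same nodes (directed for EC, undirected for FC), which are then
summarized by ten global graph metrics and related to participant-level
covariates in adjusted linear models.

Because raw cohort fMRI is rarely shareable, the package is built around a
synthetic-cohort generator with known planted structure. Every statistical
property the pipeline claims — calibration of edge detection, recovery of
planted couplings, suppression of indirect paths, nominal coverage of
association estimates — is demonstrated on data where the truth is known.

## The nonlinear predictor

The Granger comparison needs a regression of a target series on the lagged
values of a set of input series. We use a *deep stacking network* (DSN)
composed of one small *adaptive-kernel convolution* module per input
series. For input series $s$ and time $t$, the module:

1. convolves six $1 \times 2$ filters (weights $w_{k}$, bias $b_k$) with
   the input's immediate past, giving a six-dimensional hidden vector
   $h_k(t) = w_{k1} s(t-1) + w_{k2} s(t-2) + b_k$;
2. passes each component through a PReLU with a learnable slope per
   filter, $a_k(t) = \max(h_k, 0) + \alpha_k \min(h_k, 0)$ — this is the
   *adaptive kernel*, a length-6 filter whose coefficients depend on the
   data at each timestep;
3. applies that kernel causally to the input's past six samples:
   $\hat y_m(t) = \sum_{k=1}^{6} a_k(t)\, s(t-k)$.

Module outputs are combined by a learned element-wise weighted sum
$\hat y(t) = c_0 + \sum_m c_m \hat y_m(t)$. Each module has
$6 \times 2$ filter weights, 6 biases and 6 PReLU slopes; with one module
per region the whole model stays below two hundred parameters.

Two presentation choices deserve a note. First, the PReLU slopes are
shared across timesteps: a literal per-timestep parameterization would
carry more parameters than data points and reconstruct any target
perfectly, which destroys the prediction-error contrast the Granger index
is built on. Second, the adaptive kernel is applied to lags $1..6$ — all
strictly in the past — so the Granger semantics (past predicts present)
hold by construction; concurrent samples are never used.

Training uses minibatch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning
rate $10^{-3}$) on mean squared error, with a 20% validation split, early
stopping (patience 8) and restoration of the best weights. The defaults —
60 epochs, batch size 64 — were chosen once for the desk-scale problems
the package targets (couplings of strength $\ge 0.5$ among up to a few
dozen regions, a few thousand pooled training samples): the models are
tiny and converge well within this budget, and the full cross-validated
edge sweep over a cohort stays in the seconds-to-minutes range on one CPU.
All randomness (initialization, splits, shuffling) derives from one
integer seed, so every estimate is reproducible bit for bit.

## The Granger causality index and edge tests

For an ordered pair (source, target) conditioned on the remaining regions,
two models are trained: a *reduced* model whose inputs are the target's
own past plus all conditioning regions, and a *full* model that adds the
source. The index is

$$\mathrm{GC}_{\text{source} \to \text{target} \,|\, \text{rest}}
  = \ln \frac{\mathrm{MSE}_{\text{reduced}}}{\mathrm{MSE}_{\text{full}}},$$

evaluated on held-out data. The log-ratio form is the classic Granger
log-variance ratio: zero means no improvement, positive values mean the
source carries unique predictive information, and the one-tailed test
"mean > 0" is well-posed. (The raw difference
$\mathrm{MSE}_{\text{reduced}} - \mathrm{MSE}_{\text{full}}$ is available
via `dsn_config(gc_type = "difference")`.)

At the **group level**, participant scans are partitioned into $K = 5$
folds; for each fold the models are trained on the other folds' scans and
the index is evaluated on the held-out fold. An edge is drawn when a
one-tailed Student t test over the $K$ fold indices rejects mean $\le 0$
at $\alpha = 0.05$ ($K - 1$ degrees of freedom). At the **individual
level**, one scan is set aside, the remaining scans are partitioned into
$K$ disjoint sets, one model is trained per set, and all $K$ indices are
evaluated on the omitted scan alone before the same t test. The fold unit
is always the scan, never the timepoint, so no participant contributes to
both sides of a train/evaluate split.

Implementation note: the full model for every edge into a given target is
the same model (all regions as inputs), so it is trained once per
(target, fold) and reused across candidate sources; per-edge seeds are
derived from (master seed, target, input set, fold), which makes a
standalone `gc_index()` call reproduce the values inside the graph sweep
exactly. Edges are tested individually at $\alpha$ with no multiplicity
correction by default, matching common practice for these graphs; an
optional Benjamini–Hochberg flag exists.

Held-out evaluation gives the null a mildly *conservative* slant: under
independence the larger full model overfits slightly more than the
reduced one, so the index is biased a little below zero and observed
false-positive rates sit below $\alpha$. We regard that as the right side
to err on for edge detection.

## Functional connectivity

`partial_correlation_matrix()` computes all conditional correlations at
once from the precision matrix, $r_{ij} = -P_{ij} / \sqrt{P_{ii} P_{jj}}$,
which agrees with the two-residual regression definition to numerical
precision (this equivalence is enforced in the test suite at $10^{-10}$).
Significance uses the t transform with partial degrees of freedom
$df = T - 2 - (R - 2)$; the subtraction of the conditioned regressors is a
convention choice, made explicit because with $T = 200$ and $R = 24$ it
shifts df by about 10%. Retained edges keep their sign; graph metrics that
need non-negative weights consume absolute values. The group consensus
graph is the plain element-wise mean of individual weight matrices,
without re-thresholding.

## Graph metrics

Ten global metrics are computed per graph, each with a directed and an
undirected variant: degree (total edge count), strength (mean nodal sum of
absolute weights; in/out averaged when directed), clustering coefficient
and transitivity (directed versions count all triangle orientations with a
reciprocal-edge correction in the denominator), modularity (Newman Q,
in/out-degree null model when directed, maximized by greedy label moving
plus a merge pass over 20 seeded restarts), global efficiency and
characteristic path length (binary shortest paths; unreachable pairs are
excluded from path length and contribute zero to efficiency), in–out
assortativity (correlation of source in-degree with target out-degree over
edges), small-worldness $\sigma = (C/C_{\mathrm{null}})/(L/L_{\mathrm{null}})$
against 100 degree-preserving rewired null graphs (10 swaps per edge,
seeded), and the flow coefficient (fraction of realizable length-2 paths
through each node among ordered neighbour pairs not directly connected —
the unconnected-pairs denominator convention, which differs across toolbox
versions and is therefore stated here explicitly).

Degenerate cases are handled by explicit conventions rather than errors
where a cohort-level table needs complete rows: nodes with fewer than two
neighbours contribute 0 to mean clustering and flow; assortativity of a
regular graph is undefined and reported as `NA`; `metric_vector()` records
undefined entries as missing rather than zero. All deterministic metrics
are verified against brute-force enumeration twins on random graphs, and
the modularity heuristic against exhaustive partition search for up to
eight nodes (observed gap bounded at 0.02).

## Associations

`fit_association()` is ordinary least squares of one outcome on an
intercept, fixed nuisance covariates (gender, race, age by default) and a
single predictor, on complete cases per model, with two-tailed p values;
`run_association_screen()` sweeps all metric × predictor pairs at
$\alpha = 0.05$ without cross-test correction (an FDR flag is available).
Predictors are left on their raw scales by default; z-scoring flags exist.

## The synthetic generator, and what it does not emulate

`simulate_system()` draws
$x_j(t) = d\, x_j(t-1) + \sum_{i \to j} f(\beta\, x_i(t - \ell)) + \varepsilon$
with self-decay $d = 0.3$, unit innovation noise, a 100-sample burn-in and
per-column z-scoring. Coupling forms are linear $u$, mean-removed
quadratic $u^2 - 1$, sigmoid $\tanh u$, and a dead-zone threshold
$u\,\mathbf{1}(|u| > 0.5)$; the two smooth nonlinearities are the
defaults for planted systems since the estimator's purpose is nonlinear
coupling. Construction of a `causal_system` runs a probe simulation and
rejects parameterizations whose variance drifts (bounded-variance check
between the second and last quarters). Cohorts share the topology;
coupling strengths get per-participant Gaussian jitter truncated to
preserve signs, and per-participant seeds derive from the master seed.
The default study scale mirrors a midlife community cohort protocol:
around one hundred participants, 200 volumes of 24 task regions or 160
volumes of 33 resting regions at a 3 s sampling interval; validation runs
use 6 regions and 20 participants to keep the cross-validated edge sweep
fast.

The generator is a stand-in, not a BOLD model: there is no hemodynamic
convolution (the analysis pipeline it emulates does not deconvolve an HRF
either), no measurement drift, motion or physiological noise, and
between-participant variation touches only coupling strengths, never
topology. Passing tests therefore demonstrate statistical correctness of
the estimators under the stated generative assumptions — calibration,
recovery, conditioning — not performance on real BOLD, whose
autocorrelation structure and artifacts are outside this model.

Covariate tables plant effects in the direction covariate =
$\beta\,z(\text{metric})$ + nuisance loadings + noise. With metrics fixed
by the graphs, this is the only direction in which a known coefficient can
be planted exactly; the recovery and coverage checks therefore regress the
planted covariate on the z-scored metric (adjusting for the same nuisance
terms), where the generating $\beta$ is the true coefficient. The
screening interface keeps metrics as outcomes, matching the analysis
design it reproduces; under the global null its flag rate is checked
against $\alpha$.

## Numerical choices and limitations

* GC indices require $\mathrm{MSE}_{\text{full}} > 0$; a perfect fit
  signals degenerate input and raises an error, as do constant target
  series and diverging training losses.
* `partial_correlation_matrix()` requires $T > R + 2$ and raises an error
  on singular covariance (collinear regions) rather than regularizing;
  shrinkage estimators are out of scope.
* The K-fold indices entering a group-level t test share training data
  across folds, so the t test's independence assumption is approximate —
  a known property of cross-validated inference; the calibration tests
  show the resulting edge decisions err conservative.
* Small-worldness values near 1 are sensitive to the null-model
  parameters; the defaults (100 nulls, 10 swaps per edge) are stated
  rather than tuned, and the self-null check (a random graph against its
  own ensemble gives $\sigma \approx 1$) guards the implementation.
* Validation problem sizes (20 replicate cohorts of 20 participants and 6
  regions; 100 random graphs for the oracle suite; 200 association
  replicates) are the package's chosen desk-scale defaults, large enough
  for the rates being checked to be stable at the stated thresholds.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(example_system(6), n_participants = 20,
                          n_timepoints = 200, between_subject_sd = 0.1,
                          seed = 42)
ec <- group_ec_graph(cohort, dsn_config(k = 5, seed = 5), alpha = 0.05)
fc <- individual_fc_graph(cohort$series[[1]], alpha = 0.05)
metric_vector(ec, n_null = 50, seed = 1)
```

The full pipeline — simulation, EC, FC, metrics, covariates, associations,
with all artifacts as CSV/JSON — is `run_pipeline(run_config(seed = 7),
"out/")`, and `scripts/acceptance.R` in the source repository recomputes
the package's validation quantities end to end.
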