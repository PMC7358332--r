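---
title: "Granger-Geweke connectivity at slow sampling rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-Geweke connectivity at slow sampling rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowgc)
```

## The measures

For two scalar series $x$ and $y$ conditioned on the remaining regions $z$,
the package decomposes their conditional linear dependence as

$$F_{x,y|z} \;=\; F_{x \to y|z} + F_{y \to x|z} + F_{x \circ y|z}.$$

All terms are log ratios of innovation variances from vector autoregressive
(VAR) models fitted by ordinary least squares:

* **Directed (lag-based) GC.** $F_{x \to y|z} = \log
  \sigma^2_y(\text{past of } y, z) / \sigma^2_y(\text{past of } x, y, z)$:
  the reduced model omits the source's past. This is the *two-stage*
  estimator (one full and one reduced regression per source region).
* **Instantaneous GC.** $F_{x \circ y|z} = \log \left(\Sigma_{xx}
  \Sigma_{yy} / \det \Sigma_{[xy]}\right)$ on the full model's residual
  covariance $\Sigma$: same-sample dependence of the innovations.
* **Full measure.** The sum above; for uncoupled series it is exactly
  zero, which `population_gc()` verifies analytically.
* **Partial correlation (PC).** $-P_{ij}/\sqrt{P_{ii}P_{jj}}$ from the
  precision matrix $P$ of the zero-lag covariance. PC mixes instantaneous
  and lagged dependence once lag coefficients are nonzero; setting them to
  zero restores the identity with normalized residual correlation (a
  property-style test exercises this numerically).

The *one-stage* variant (`one_stage_gc()`) avoids the reduced regression:
the full model's implied autocovariance sequence is computed recursively
from the Yule-Walker relations (companion-form discrete Lyapunov equation
for lag zero), and each leave-one-region-out subprocess's innovation
variance is solved from its block-Toeplitz linear prediction problem, with
the predictor depth doubled until the innovation log-determinant changes by
less than $10^{-10}$ (cap 64). `population_gc()` applies the same
machinery to known parameters, giving the exact oracle against which both
sample estimators are tested.

Sample GC values are *not* clamped at zero: the small-sample positive bias
(order $p/T$) is left visible and handled by surrogate nulls downstream.

## Segments: the unit of temporal contiguity

Every scan carries a list of contiguous segments. Fitting pools lagged
(predictor, response) pairs within segments and never across them, so

* motion scrubbing (`scrub()`; FD threshold 0.5 mm, one neighbor frame per
  side per model order),
* sub-task block concatenation (`concat_blocks()`), and
* interleaved subsampling (`decimate_concat()`, which multiplies the
  sampling interval while conserving the total sample count)

cannot contaminate lag-based estimates with artificial transitions.
Columns are demeaned per segment (each segment may come from a different
portion of the recording); covariances are normalized by the effective
regression sample count so magnitudes stay comparable across
segmentations.

Model adequacy is screened by four diagnostics (`stationarity_tests()`):
log spectral radius of the companion matrix (negative = stable), the
consistency between model-implied and observed lag-0/lag-1 covariance
structure (pass at 80%), Durbin-Watson statistics of the residuals (pass
when in (1, 3) for more than 90% of series), and an augmented
Dickey-Fuller unit-root regression per series with the 5%
response-surface critical value (pass for more than 90% of series). The
ADF regression is implemented in-package (constant term, Schwert-rule lag
order) because no installed package provides it.

## The simulator: why slow timescales make dGC recoverable

Latent dynamics follow the vector Ornstein-Uhlenbeck model
$\tau \dot r = -r + W r + \varepsilon$, $\varepsilon \sim N(0, \Sigma)$,
with drift $A = (W - I)/\tau$. Sampling at interval $\Delta$ is **exact**:
the sampled process is a VAR(1) with coefficient $e^{\Delta A}$ and
innovation covariance $\Gamma(0) - e^{\Delta A}\Gamma(0)e^{\Delta A'}$,
where $\Gamma(0)$ solves the continuous Lyapunov equation
$A\Gamma(0) + \Gamma(0)A' + \Sigma = 0$. No Euler integration is used, so
neural series can be generated at a 5 ms step without discretization
error. We deliberately use the *unscaled* innovation covariance (rather
than its $1/\Delta$-scaled rate form, which is exposed as the
`sigma_rate` attribute): this keeps the stationary covariance equal to
$\Gamma(0)$ at every sampling step, so statistics are self-consistent
across sampling rates. Lyapunov equations are solved by an
eigendecomposition transform ($O(N^3)$, needed for neuron-level systems)
with a Kronecker-product fallback for small or defective systems.

Observables are produced by causal convolution with a double-gamma
hemodynamic kernel (peak delay 6 s, undershoot delay 16 s, unit
dispersions, peak:undershoot ratio 6, 32 s support, unit-sum
normalization), an onset-latency shift per node, decimation to the scan
interval (default 750 ms), and **additive Gaussian measurement noise**
with SD equal to `noise_frac` times each channel's SD.

`noise_frac` deserves emphasis. A noiselessly convolved and slowly sampled
series is almost perfectly predictable from its own past (the hemodynamic
kernel passes almost no power above 0.1 Hz), so the innovation covariance
of the fitted VAR approaches singularity and GC log ratios degenerate.
Real scans contain substantial thermal noise. The experiment wrappers use
`noise_frac = 0.2` (20% of signal SD, a mid-range functional SNR for
regional averages); this is a fixed generator condition, not a tuning
parameter.

**Emergent timescales.** Each eigenvalue $\lambda$ of $A$ contributes a
mode with timescale $-1/\mathrm{Re}(\lambda)$. A purely feedforward
(nilpotent) weight matrix leaves every timescale equal to $\tau$ — a
property tested exactly. Sparse random net-excitatory clusters
(`build_cluster_network()`: 100 neurons, connection probability 0.1,
weights +0.08/-0.06, 80/20 E/I split) are rescaled so the leading
within-cluster eigenvalue is 0.98, i.e. a slowest emergent mode of
$50\tau$ (2.5 s for $\tau = 50$ ms) — recurrent excitation, not slow
units, creates the slow dynamics. Only 5% of each cluster's neurons act as
"ports" for internode connections. For balanced bidirectional couplings
(the E-I feedback configuration) the `clone_clusters` flag reuses one
within-cluster block across nodes: with independently sampled clusters the
node-level zero-lag cancellation that defines "balance" is broken by
construction noise, whereas cloned blocks make it exact at the population
level.

**Experiment protocols.** `two_node_experiment()` simulates the two-node
feedforward network (weight 0.9) at 5 ms, convolves, samples at the
requested intervals, and estimates iGC/dGC/PC on 200 timepoints, 25
repetitions. Significance is assessed at the *group level*: estimates are
averaged across repetitions and compared against equally rep-averaged
phase-scrambling surrogate nulls (Benjamini-Hochberg across measures).
Per-repetition significance fractions are reported alongside but are not
the primary outcome — a single 200-sample estimate is too variable to
clear its surrogate null reliably, while the rep-averaged statistic
separates cleanly. `cluster_pair_experiment()` applies the same protocol
to two-cluster neuron-level networks after node averaging; the
symmetric excitatory-feedback pattern uses a within-cluster radius of
0.95 rather than 0.98, because mutual excitation adds to the leading
eigenvalue and would otherwise leave no stability headroom.

**Cohorts.** `generate_cohort()` emulates a multi-subject panel: per
subject, a Gaussian weight perturbation (SD `between_subject_sd`) shared
across conditions, restricted by default to the union of nonzero
connections (`perturb = "edges"` — individual variability in existing
anatomical connections; dense perturbation of all entries buries the
loading directions below what connectivity features can linearly resolve),
resampled until every condition network is stable; subject-specific HRF
onset latencies drawn as a common truncated-normal shift (preserving
relative latencies between nodes within subject); one or more runs per
condition; and behavioral scores equal to a loadings matrix times the
vectorized weight perturbation plus Gaussian noise. Everything is
reproducible from the spec seed.

The six-node `dual_timescale_networks()` pair (fast 50 ms subnetwork on
nodes 1-3, slow 1 s subnetwork on nodes 4-6, different directed chains per
condition) is the standard two-condition testbed: classification,
decorrelation and feature-selection experiments run on cohorts generated
from it.

## Decorrelation

`zca_whiten()` applies $C^{-1/2}$ (the whitening transform closest to the
data in least squares, with region-anchored axes that correspond across
subjects); `gev_decorrelate()` jointly diagonalizes a task and a rest
covariance by whitening with the first and eigendecomposing the whitened
second. The eigenvector-product formula $E_T D_T^{-1/2} E_R$ is available
behind `method = "literal"` for comparison, but it does not jointly
diagonalize in general, so the whitening construction is the default.
Partial correlations computed after either projection are zero up to
double-precision round-off; values below $10^{-10}$ are treated as exactly
zero, and the classifier's standardizer never rescales feature columns
with SD below $10^{-8}$ — otherwise machine-precision residue would be
amplified into apparent signal.

## Classification, feature selection, behavior

Classification uses a linear SVM (cost 1) by default, with logistic
regression and lasso/ridge penalties available on a log grid for the
optional five-fold tuning protocol (tune on each fold in turn, evaluate on
the remainder). Features are z-scored with training-fold statistics only.
Accuracy is reported with exact Clopper-Pearson intervals; permutation
tests permute condition labels within subject and use the add-one-smoothed
p value $(b+1)/(n+1)$ on 10-fold accuracy. N-way decoding trains
one-versus-all learners and takes the largest decision value (ties to the
lowest class index). Subject-averaged decoding trains on half the
subjects and classifies means of held-out folds of size $m$, with halves
exchanged.

Two-level RFE: 10 outer folds measure per-level generalization accuracy;
within the training folds, absolute discriminative weights are averaged
over 5 inner folds, with the fold split redrawn three times per level for
a stable ranking; the lowest-weight 10% of features (retention rounded up,
at least one dropped) is eliminated per level until none remain. Reported
retained sets come from the elimination run on all observations, which
makes them nested by construction, while accuracies come from the outer
cross-validation. The N-way variant drops the union of each
one-versus-all learner's bottom 1%. The elbow is the breakpoint of a
constrained two-line least-squares fit over level index — plateau line
(excluding the very first level) required to have strictly greater slope
than the decline line; if no breakpoint satisfies the constraint (a flat
or strictly linear curve) the last level is returned with a warning. In
the dual-timescale testbed, dGC elbow sets recover the planted
slow-subnetwork edges; for iGC the elbow is very aggressive (slow lagged
couplings also carry instantaneous signal at a 750 ms interval), so fast
pair recovery is assessed at the minimal retained sets of six or fewer
features and by weight rank.

Task-generic features use the binomial tail rule: presence of a feature in
each of $n$ selected sets is Bernoulli with $p$ = mean set size divided by
the feature count; features present in at least $k^*$ sets, the smallest
count with $P(X \ge k) < \alpha$, are flagged. Set overlap significance
permutes feature identities preserving set sizes. Digraph extraction
antisymmetrizes dGC, selects candidate connections by RFE on one fold of
subjects (plus symmetric counterparts), then tests those candidates per
remaining subject against that subject's phase-scrambling null with
Bonferroni correction, keeping only the dominant direction of each pair.

Phase scrambling preserves the Fourier amplitude spectrum exactly,
randomizes phases with conjugate symmetry (DC and any Nyquist bin
untouched, so mean and variance are preserved), and is applied
independently per region — the null must destroy cross-region dependence.

Behavioral prediction is leave-one-out ridge regression (penalty 1 on
training-fold-standardized features, unpenalized intercept; an
epsilon-insensitive variant was considered and rejected as needlessly
nonsmooth at these sizes), scored with the percentage-bend robust
correlation (bend 0.2) and Benjamini-Yekutieli control across scores.
Composite identification z-scores all scores, predicts each out-of-sample,
correlates each subject's predicted composite with every observed composite,
and compares diagonal to off-diagonal correlations with a one-sided
two-sample Kolmogorov-Smirnov test.

## Problem sizes and what the tests show

The test and acceptance workloads are desk-scale by design: two-node
experiments use 200 timepoints and 25 repetitions with 100 surrogates;
cluster pairs 10 repetitions; cohorts 40 subjects (400 timepoints and two
runs per condition for the behavior analyses); permutation tests 100-200
permutations. At these sizes every qualitative claim — timescale-dependent
recoverability of directed GC, the decorrelation dissociation between GC
and PC, planted-feature recovery, behavioral parameter recovery — is
reproduced with comfortable margins, but absolute accuracies are not
comparable to kilosubject panels.

The generator emulates linear latent dynamics, a canonical hemodynamic
response with latency variability, stationary Gaussian noise, and linear
score loadings. It does not emulate nonstationary task structure,
physiological confounds, spatially correlated measurement noise,
nonlinearity of neural dynamics or of the hemodynamic transduction, or
real anatomical connectivity — passing tests therefore validate the
estimation and decoding machinery, not claims about any particular real
dataset.

## Known limitations

* Conditional GC is pairwise-conditional on all remaining regions;
  fully multivariate blockwise measures and spectral (frequency-domain)
  GC are out of scope.
* The one-stage reduced-model route assumes the fitted full model is
  stable; it refuses unstable fits.
* The ADF critical value is the 5% constant-only response-surface value;
  other significance levels are not exposed.
* `read_scan()` auto-detects delimiter and header heuristically; files
  with exotic encodings should be read manually into `regional_scan()`.
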