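---
title: "Granger-causal hub analysis of the default-mode network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-causal hub analysis of the default-mode network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmngc)
```

# The scientific question

The default-mode network (DMN) is the set of brain regions whose activity
is higher at rest than during directed tasks.  Its eight core nodes here
are the posterior cingulate cortex (PCC), medial prefrontal cortex (MPFC),
bilateral inferior parietal cortex (lIPC, rIPC), bilateral inferior
temporal cortex (lITC, rITC) and bilateral hippocampal formation (lHC,
rHC).  PCC, MPFC and the IPC nodes act as *hubs*: they interact most
widely with the rest of the network, and their connectivity degrades in
Alzheimer-type dementia.

`dmngc` quantifies *directed* (effective) connectivity between every
ordered pair of nodes with Granger causality, summarises each subject's
network as a directed graph, reduces the graph to a single
hub-communication index, and asks whether that index separates a patient
cohort from controls.

# The analysis chain

## Temporal preprocessing

Four steps, in fixed order, mirror a standard resting-state fMRI protocol
(`preprocess_pipeline()`):

1. `discard_initial()` — drop the first 5 volumes (signal equilibration),
   e.g. 300 acquired time points become 295 analysed ones at TR = 2 s.
2. `detrend_linear()` — remove each region's least-squares line.
3. `bandpass()` — ideal rectangular frequency-domain filter keeping the
   closed band 0.01–0.1 Hz.  Because the filter zeroes FFT bins, it is a
   projection: applying it twice equals applying it once, and the DC bin
   is removed whenever `f_lo > 0`.  Bins satisfying `f_lo <= f <= f_hi`
   are kept; the closed-interval convention is deliberate and tested.
4. `remove_global_signal()` — regress each region on an intercept plus the
   global signal.  The global-signal *estimator* is underdetermined at
   this stage of a ROI pipeline (no whole-brain mask is available), so the
   default is the mean across the supplied regions; any external series
   can be passed instead.

## Bivariate VAR and Geweke's measures

For a pair of series $x_t, y_t$, the *full* model regresses each series on
an intercept and lags $1..p$ of both series; the *restricted* model of
each series uses only its own lags.  With residual variances
$\sigma^2_{full}, \sigma^2_{restr}$ (divisor $n_{eff} = T - p$),

$$F_{x \to y} = \ln\frac{\sigma^2_{restr}(y)}{\sigma^2_{full}(y)}, \qquad
  F_{y \to x} = \ln\frac{\sigma^2_{restr}(x)}{\sigma^2_{full}(x)}, \qquad
  F_{x \cdot y} = \ln\frac{\sigma^2_{full}(x)\,\sigma^2_{full}(y)}
                          {\det\Sigma},$$

where $\Sigma$ is the full-model innovation covariance.  $F_{x \to y}$
measures how much the past of $x$ improves prediction of $y$ beyond $y$'s
own past; the instantaneous term $F_{x\cdot y}$ captures same-time
dependence and is reported but never used for graph edges.  All measures
are non-negative and invariant under per-series affine rescaling.

The default order is $p = 5$: at TR = 2 s this spans lags up to 10 s,
covering inter-regional haemodynamic delays of roughly 8 s.

Two fitters are provided.  `fit_var_ols()` is plain least squares.
`fit_var_fos()` is Fast Orthogonal Search: a greedy selection over the
candidate set {intercept, lags 1..p of both series} that repeatedly admits
the candidate with the largest residual-sum-of-squares reduction (computed
by Gram–Schmidt orthogonalization against admitted terms) and stops when
the best *relative* reduction falls below a threshold.  The stopping
threshold is not specified in the source methodology; this package fixes
it at $10^{-3}$ and exposes it as a parameter.  Two numerical choices are
worth noting:

* the intercept is always admitted first (series are detrended but not
  guaranteed exactly mean-free per window);
* at threshold 0 FOS admits every independent candidate and *is* OLS —
  this single code path is cross-checked against `stats::lm` in the test
  suite, and OLS serves as the oracle for FOS;
* with a positive threshold the full and restricted FOS fits are not
  exactly nested, so an F value could be marginally negative; F is floored
  at 0.  The surrogate test is rank-based, so the floor does not affect
  its validity.

Residual variances use the divisor $n_{eff}$ rather than $n_{eff} - k$;
the choice cancels in the variance ratio asymptotically and is documented
for exactness.

## IAAFT surrogate significance

BOLD series are autocorrelated (the band-pass filter alone guarantees
that), so analytic F-distributions do not apply.  Significance is judged
against Iterated Amplitude Adjusted Fourier Transform surrogates
(`iaaft()`): starting from a random permutation of the series, alternate
(a) imposing the original Fourier amplitude spectrum while keeping current
phases and (b) rank-remapping values onto the original sorted values,
until the rank ordering stabilises (cap 100 iterations, the standard
iterated-surrogate practice).  The last step is always (b), so the
surrogate's value multiset equals the original's *exactly* while its
spectrum matches approximately (within a few percent in the tests).

`test_direction()` replaces only the *source* series with surrogates; the
target is untouched.  Rationale: the restricted model of the target is
then literally identical across replicates, and the null distribution
isolates exactly the cross-prediction gain.  (Surrogating both series is
available via `surrogate_target = TRUE`.)  The p-value uses the add-one
estimator $p = (1 + \#\{F_{surr} \ge F_{obs}\})/(1 + N)$, which is never
exactly zero, and "significant at $p = 0.05$" is the one-sided comparison
$p < \alpha$.  With $N = 1000$ surrogates the achievable minimum is
$1/1001$; the rejection rule at $\alpha = 0.05$ admits up to 49
exceedances.

No correction is applied across the 56 simultaneous directed tests per
subject — this mirrors the source methodology; `test_all_pairs()` says so
in a (suppressible) message.

**Curtailed sampling.**  `surrogate_config(early_stop = TRUE)` stops a
pair's replicate loop as soon as the exceedance count makes significance
unattainable.  Because the count only grows, the accept/reject decision is
provably identical to the full run (asserted in the tests); only the
p-value of non-significant pairs becomes a conservative estimate from the
replicates actually drawn.  Cohort-scale tests and the acceptance script
use this; the default is off.

**Seeding.**  Every stochastic component is a pure function of a master
seed: per-subject and per-pair seeds are derived with `derive_seed()`
(counter-based mixing), so any single pair can be recomputed in isolation
and whole runs are bit-reproducible.  Within one pair the replicates draw
sequentially from the pair's stream.

## Graphs, hub index, group summaries

`build_graph()` places the edge $(s, t)$ iff the test $s \to t$ was
significant.  `hub_index()` computes per-node out/in-degrees, the total
edge count $D_{all}$, the count $D_{outer}$ of edges linking a hub with a
non-hub (either direction), and the hub-communication index
$D_{outer}/D_{all}$.  For 8 nodes with 4 hubs, $D_{all} \le 56$ and
$D_{outer} \le 32$.  An edgeless graph yields an *undefined* (flagged)
ratio, not zero: 0/0 is no evidence about hub communication, and such
subjects are excluded from group statistics with a warning.

`group_edge_proportions()` gives, per ordered pair, the fraction of
subjects carrying the edge; `categorize_proportion()` bands it as in the
group connectivity figures.  The captions' ranges are ambiguous at the
boundaries; the documented convention is $[0.5, 0.6) \to$ `50_to_60`,
$[0.6, 0.8] \to$ `60_to_80`, $(0.8, 1] \to$ `above_80` ("more than 80%"
read strictly).

## Group statistics and ROC

The two cohorts are compared with a one-tailed Welch test on the
hub index (the named "two sample independent test" is not further
specified; Welch is the robust default) and a classical one-way ANOVA.
`roc_curve()` sweeps candidate thresholds — midpoints between adjacent
pooled unique scores plus $\pm\infty$ — calling a subject positive
(patient) when its score is *below* the threshold, since the patient
group scores lower.  `optimal_cutoff()` maximises Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ ("best cutoff" is not
otherwise defined; the reported sensitivity/specificity pair is
consistent with a Youden-type choice); ties resolve to higher
specificity, then lower threshold.

## ROI utilities

`sphere_mask()` builds spherical ROIs from centre-to-centre Euclidean
distance in world millimetres (closed ball), supporting anisotropic
voxels; `intersect_with_threshold()` keeps mask voxels *strictly* above a
statistic threshold; `template_fit_score()` is the component-selection
score — mean intensity inside the union of template spheres minus mean
intensity outside all of them — which is shift-invariant and scales
linearly with the map; `select_best_component()` takes the maximiser,
ties to the lowest index.  The ICA decomposition itself is out of scope;
this module consumes component maps as plain arrays.  No NIfTI reader is
available in the supported dependency set, so volumes and masks travel as
R arrays and JSON voxel lists.

# The synthetic world

`make_default_coupling()` / `simulate_cohort()` define the cohorts every
cohort-level test runs on: stable VAR(5) processes over the 8 DMN nodes,
16 control and 15 patient subjects, 295 time points at TR = 2 s
(a 300-volume run minus 5 discarded), innovation SD 1, own-lag AR
coefficient 0.3, cross-coupling coefficient 0.4, multiplicative
between-subject jitter with 10% relative SD truncated at zero (sign-
preserving).  Burn-in of 200 steps removes initial transients.  The
"patient" variant multiplies every coupling incident to MPFC/lIPC/rIPC by
an attenuation factor (default 0.4), *except* edges touching PCC — in the
degraded network PCC keeps its afferents, as observed clinically.  The
attenuation factor is a free simulation parameter, not an estimate: no
effect size is reported for it.

The control topology is hub-centric under the constraints that every
hub–hub and hub–non-hub pair carries a directed coupling, non-hub pairs
carry none, and PCC only receives:

* MPFC is a pure source: it drives lIPC and all four non-hubs at lag 1 and
  rIPC at lag 2;
* lIPC drives rIPC (lag 1);
* each non-hub sends to lIPC at lag 1 and to rIPC at lag 2;
* every node feeds PCC at lag 5.

Three properties of this choice matter, and they were chosen because
*bivariate* Granger analysis detects indirect influence as readily as
direct influence:

1. the cross-edge graph is a DAG, so the companion spectral radius equals
   the own-lag AR radius (0.3) and stationarity holds for any coupling
   strength or jitter draw;
2. every two-step causal path ends in a node the origin also drives
   directly, so indirect influence only ever reinforces a true edge;
3. the two aggregator hubs (lIPC, rIPC) listen to the same sources at
   *different* lags, and PCC listens at the longest lag, so no node's past
   carries another target's drivers at the age that target needs them — a
   first design draft without these offsets produced spurious PCC-outgoing
   edges in 100% of subjects, which is a property of bivariate causality,
   not a detector bug.

What a green cohort test establishes, therefore, is that the pipeline
recovers ground truth *on a network where pairwise analysis can be
faithful*, at realistic length, autocorrelation and cohort size.  It does
not establish faithfulness on networks with strong unshadowed indirect
paths, nor does the generator emulate haemodynamic convolution (an
optional double-gamma HRF flag exists but is off by default, because the
causal ground truth is defined at the VAR level), measurement noise
spectra, motion artefacts, or spatial structure.  In synthetic mode the
pipeline accordingly skips preprocessing by default: the generator's
output is already stationary, trend-free and band-unlimited, and
band-passing it would only blur the VAR ground truth; in load mode the
preprocessing defaults mirror the acquisition protocol.

With these defaults the control cohort's hub index concentrates near
$16/22 \approx 0.73$ (22 true edges of which 16 are hub–non-hub) and the
attenuated cohort falls toward $4/7 \approx 0.57$ (at full attenuation
only the 7 PCC afferents remain, 4 of them hub–non-hub), so the two
cohorts straddle the reported cutoff region — which is what makes the
qualitative cohort-separation reproduction meaningful.

# Numerical and engineering choices

* The IAAFT/refit loop is compiled (RcppArmadillo).  One cohort analysis
  performs on the order of $10^5$–$10^6$ VAR fits and FFTs; the package
  carries a small mixed-radix FFT with reusable plans because the
  available FFT routes are impractically slow at awkward lengths such as
  $295 = 5 \times 59$ (a large-prime stage is batched through BLAS).  The
  transform is verified against R's `fft()` and exercised by the
  IAAFT spectrum tests.
* VAR fitting runs on the Gram matrix (normal equations) inside the
  orthogonal search; designs here are tiny (11 candidates) and
  well-conditioned after detrending, and FOS(threshold 0) is tested to
  match `stats::lm` to $10^{-8}$.
* Collinear candidates (residual norm below $10^{-12}$ of the diagonal
  scale) are skipped; a perfectly predictable series (zero residual
  variance) raises an explicit error.
* Degenerate inputs are first-class: constant series are rejected by the
  fitters, returned unchanged by `iaaft()`, and an all-zero graph yields a
  flagged undefined hub index.

# Known limitations

* Bivariate (not conditional) causality only; indirect influences on
  unshadowed paths will be detected as edges.  Frequency-domain
  decompositions are out of scope.
* The surrogate test controls the per-pair error rate; nothing corrects
  across the 56 pairs, by design fidelity.
* The ROC cutoff is fitted and evaluated on the same cohorts; no
  cross-validation (explicitly out of scope).
* The component-selection score operates on supplied maps; ICA itself is
  not implemented.
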