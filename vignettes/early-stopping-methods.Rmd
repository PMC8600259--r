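---
title: "Sequential early stopping for block-design task fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential early stopping for block-design task fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsprt)
```

## The problem

A task fMRI run presents stimulus blocks on a fixed schedule and keeps
scanning until a predetermined number of volumes has been collected, whether
or not the data already answer the question. For long runs this wastes
scanner time and, worse, accumulates head motion: subjects move more in the
second half of a session, so the extra volumes can actively degrade the
analysis. `rtsprt` implements the alternative: analyse each volume the
moment it arrives, track for every brain voxel whether it can already be
classified as task-active or not, and terminate a stimulus condition as soon
as a sufficient fraction of voxels has been classified.

Three statistical components make this work: an incrementally updated
voxelwise GLM with a robust variance estimator, a truncated two-stage
sequential probability ratio test (SPRT) per voxel, and a global
percent-classified stopping rule per condition.

## Voxelwise GLM with sandwich variance

At scan $t$ each voxel's signal history $Y_t$ ($t \times 1$) is modelled as
$Y_t = X_t \beta + E_t$, where $X_t$ is the first $t$ rows of a design
matrix known before the session starts. The design contains an intercept,
one regressor per stimulus condition — the block indicator convolved with a
double-gamma haemodynamic response function (HRF) — and five slow cosine
drift regressors with periods $2T, T, T/1.5, T/2, T/2.5$ for $T$ the full
run duration, which absorb scanner drift, physiology and other slow
fluctuations. Interest is in a linear contrast $c\beta$ (here: one
condition versus rest), estimated by ordinary least squares,
$c\hat\beta_t = c (X_t'X_t)^{-1} X_t' Y_t$.

The package never models the error covariance explicitly. Autoregressive
covariance estimation is too slow to run per voxel per scan in real time,
so the variance of $c\hat\beta_t$ is estimated by the model-free sandwich
form
$$\widehat{\mathrm{var}}[c\hat\beta_t] =
  c (X'X)^{-1} \Big[\textstyle\sum_i r_i^2\, x_i x_i'\Big] (X'X)^{-1} c',$$
which is consistent under heteroscedasticity and, with Bartlett-weighted
cross-lag terms added (`lag > 0` in `sandwich_variance()`, the Newey–West
form), under serial correlation. The default is the lag-0 (HC0) form with
no small-sample correction: inference only starts after at least 78 scans,
where the finite-sample bias factor $(t-p)/t \ge 0.9$ is immaterial relative
to the Monte-Carlo noise of the variance itself. The Newey–West window is
exposed for data with strong serial structure.

Implementation-wise, `glm_stream_init()`/`glm_update()` accumulate $X'X$
and $X'Y$ in constant work per voxel per scan; `glm_fit()` refreshes
$\hat\beta$ for all voxels in one Cholesky solve shared across the brain
(identical, by construction and by test, to per-voxel solves). Voxels
delivering non-finite values are flagged `degenerate` and carried along
without ever raising an error — a real-time loop must not halt mid-run.

## The two-stage truncated SPRT

For each voxel we test $H_0: c\beta = \theta_0 = 0$ against
$H_a: c\beta = \theta_1 > 0$ with Wald's sequential likelihood-ratio
statistic evaluated at the current estimate, conditioning on the current
variance estimate:
$$\Lambda_t = \frac{(c\hat\beta_t - \theta_0)^2 -
  (c\hat\beta_t - \theta_1)^2}{2\,\widehat{\mathrm{var}}[c\hat\beta_t]}.$$
Sampling continues while $B < \Lambda_t < A$; the voxel is classified
`nonactive` when $\Lambda_t \le B$ and `active` when $\Lambda_t \ge A$,
with the boundaries $A = \log\frac{1-\beta_E}{\alpha_E}$,
$B = \log\frac{\beta_E}{1-\alpha_E}$ controlling both error levels
(defaults $\alpha_E = 0.001$, $\beta_E = 0.1$, giving $A = 6.80$,
$B = -2.30$). Decisions are absorbing. $\Lambda_t$ is *recomputed* from the
current estimate and variance each scan rather than accumulated over
per-scan increments, because both the estimate and its variance are
re-estimated as data accrue.

Two practical modifications shape the procedure:

* **Truncation.** The run never exceeds `max_scans` (238 for the packaged
  protocol). Voxels still undecided at truncation stay labelled
  `undecided` by default — an indifference zone is the price of early
  stopping for voxels whose effect sits between the hypotheses. An optional
  post-hoc labelling by the sign of $\Lambda$ (`truncation_label = TRUE`)
  is provided for users who need a two-way map.
* **Two-stage calibration.** $\theta_1$ cannot be fixed in advance in
  meaningful units because voxel noise levels vary enormously. So no
  decisions are made during a first stage (presets: 78 scans = 2 blocks per
  condition, or 154 = 4 blocks); at its end each voxel's alternative is set
  to $\theta_1 = z_t \sqrt{\widehat{\mathrm{var}}[c\hat\beta]}$ with
  $z_t = 3.10$ (the conventional activation threshold; the upper 0.001
  normal quantile is 3.09, printed as 3.10 at the usual precision).
  $\theta_1$ is then held fixed: the targeted activation *magnitude* stays
  constant while its z-equivalent grows as the variance shrinks. The
  4-block first stage is the default — with only 2 blocks the variance
  estimates are still volatile and the implied $\theta_1$ values
  correspondingly inflated.

Because $\widehat{\mathrm{var}}[c\hat\beta_t]$ shrinks roughly like the
design factor $c(X'X)^{-1}c'$, a threshold $z$ at an early stopping point
corresponds to a larger z at full duration; `rescale_z_equivalent()`
computes this equivalence through the truncated design matrices. For the
packaged protocol and the easy-versus-rest contrast, $z = 3.1$ at 154 scans
corresponds to about 3.87 at 238 scans; at 78 scans the design factor is
dominated by the near-collinearity of the short data window with the slow
drift terms and the equivalence is much larger (about 6.4), and it is very
sensitive to the exact timing geometry — which regressor's block completes
at the stage boundary, the lead-in, and the sampling convention can move it
by a factor of 1.3.

Testing one voxel is done at level $\alpha_E$; testing ~10^5 voxels
simultaneously inflates the family-wise rate. An optional Bonferroni mode
divides $\alpha_E$ by the voxel count before forming the boundaries; it is
off by default because very small $\alpha_E$ makes boundary crossings, and
hence early stopping, rare. One-sided testing (activation = positive
contrast) is the default; the two-sided mode replaces the point alternative
with the symmetric mixture $\pm\theta_1$, which makes classification exactly
invariant to a sign flip of the data.

## The global stopping rule

A condition stops when the fraction of in-mask voxels classified either way
reaches a threshold (70/80/90% are the conventional choices; 80% is the
default as a compromise between scan-time savings and correspondence with
full-duration maps). Degenerate voxels are excluded from numerator and
denominator: they can never be classified, so counting them would make the
threshold unreachable for reasons unrelated to evidence. The rule is
guarded during the first stage, evaluated every scan afterwards (an
`eval_interval` option evaluates it on a coarser grid), and each condition
is routed independently — the easy blocks can stop while the hard blocks
continue. Stop decisions are monotone by construction since voxel decisions
are absorbing; on any fixed dataset the 70% rule therefore never stops
later than the 80% rule, nor 80% later than 90%.

## Design-matrix conventions

Several small conventions were genuinely open; the package fixes them as
follows and exposes each as a parameter.

* **HRF**: canonical double-gamma (peak delay 6 s, undershoot delay 16 s,
  unit dispersions, undershoot ratio 1/6), peak-normalised, convolved with
  the block indicator on a 0.1 s grid and sampled at scan acquisition times
  $(i-1)\,\mathrm{TR}$. Alternative gamma-family shapes change block
  regressors negligibly at 36 s block length.
* **Condition regressors** are normalised to unit peak over the *full* run,
  so coefficients read as peak signal change and truncating the design
  never rescales earlier rows (the streaming build is always a prefix of
  the full build — a property tested over randomised protocols).
* **Drift basis**: DCT-II-style columns $\cos(\pi j (i - 1/2)/N)$ on scan
  index $i$ of $N$ = `max_scans`, whose periods are exactly $2T/j$. A
  zero-phase variant is available.
* **Block completion scans** are reported with the trailing rest included
  (a 36 s block plus 21 s rest starting at 6 s completes at scan 21 with
  TR 3 s); with `rest = 0` the convention reduces to the scan containing
  the last task second. The packaged protocol infers a 6 s lead-in from
  this arithmetic.
* **Scan indexing** is 1-based in all reports; temporal derivatives and
  motion regressors are omitted by default but `design_spec()` accepts
  arbitrary extra columns.

## What the simulator emulates — and what it does not

`simulate_run()` generates each voxel as
$X\beta_{true} + \mathrm{drift} + \mathrm{AR(1)\ noise}$:

* **Task signal** uses the same HRF-convolved block regressors as the
  analysis (this part is deliberately well-specified). Effects are given as
  a target z at full duration and converted through
  $\sigma^2\, c(X'X)^{-1}c'$, so nominal effect sizes transfer across
  protocols; the default z = 6 represents a clearly active voxel.
* **Noise** is AR(1) Gaussian (default innovation SD 1, lag-1 correlation
  0.3 — a mid-range value for a 3 s TR). AR(1) is the minimal serially
  correlated model that actually exercises the sandwich estimator; it is
  *not* the analysis model, which assumes nothing about the correlation
  structure.
* **Drift** is a per-voxel random combination of three slow cosines with
  periods drawn from 150–1200 s and random phases — deliberately *not* the
  analysis drift basis, so drift removal is tested as an approximation
  rather than a tautology.
* **Ground truth** is an independent random active set per condition
  (default 25% of voxels).

Real data differ in ways the simulator does not attempt: spatially
structured signal and noise (an optional smoothed-noise mode exists but is
off by default), motion and spin-history artefacts, physiological cycles,
non-Gaussian spikes, and voxelwise variance heterogeneity beyond what AR(1)
plus drift induces. Passing the packaged tests therefore demonstrates the
statistical engine is correct and calibrated under its stated model, not
that any particular subject will stop at any particular scan.

## Numerical choices and degenerate inputs

Normal equations are solved by Cholesky factorisation refreshed each scan
from the accumulators; a failed or near-singular factorisation (relative
pivot below $\sqrt{\epsilon}$) marks estimates undefined rather than
returning garbage. Rank-deficient batch fits name the offending columns.
The Newey–West variance is clamped at zero against roundoff. Variances
$\le 0$ or non-finite propagate a `degenerate` status through calibration
and classification instead of raising. Smoothing uses a separable Gaussian
truncated at $4\sigma$ with edge-renormalised rows, so constant images are
preserved exactly. Thresholds compare inclusively ($\ge$), and ties at the
boundaries classify (crossing means $\Lambda \ge A$ or $\le B$).

## Worked example

```{r example, eval = FALSE}
protocol <- make_paper_protocol()
sim <- simulate_run(simulation_config(seed = 1), protocol)
cfg <- run_config(sim$series, protocol = protocol,
                  sprt = sprt_config(first_stage_scans = 154, max_scans = 238),
                  threshold = 0.8)
report <- run_realtime(cfg)
report
```

Test problem sizes were chosen to probe each claim at the smallest scale
where the Monte-Carlo error is decisively below the tolerance: 200 random
problems for incremental-versus-batch equivalence (an algebraic identity),
20,000 replicates for the SPRT operating characteristics (3 binomial
standard errors below Wald's bounds), 10,000 voxels for the null z
calibration (Kolmogorov distance 0.03), and a 20×20×10 grid for the
end-to-end sensitivity/specificity run.

## Known limitations

* The package consumes already-registered volumes; motion correction and
  scanner transfer are integration points, not package features.
* The plug-in SPRT's error control is exact only with known variance; with
  the estimated sandwich variance the operating characteristics hold
  asymptotically, which is why decisions are withheld until at least 78
  scans.
* Undecided voxels at truncation are a designed outcome, not a failure —
  interpret classified fractions accordingly.
* The global rule treats all in-mask voxels equally; anatomically weighted
  or ROI-specific rules would need a custom mask per condition.
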