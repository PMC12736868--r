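---
title: "Modelling anatomy effects in bioimpedance bladder monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anatomy effects in bioimpedance bladder monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bioimpedance-based bladder monitoring injects a small alternating current
through surface electrodes on the lower abdomen and tracks how measured
voltages change as the bladder fills with conductive urine. Two signals are
standard: the raw voltage change against a near-empty baseline,
$\Delta V = V - V_0$, and the voltage change ratio,
$\mathrm{VCR} = |V - V_0| / V_0 \cdot 100$. Both correlate with bladder
volume, but both are attenuated by body habitus: a larger waist moves the
electrodes away from the bladder, and a thicker subcutaneous fat layer
shunts and attenuates the measurement current. `bladdersim` quantifies these
effects in silico and tests whether simple anatomical normalizations let a
single *generalized* volume estimator replace burdensome patient-specific
calibration.

The package is organized as a pipeline (driven by the numbered scripts in
`analysis/`): virtual anatomies → forward conduction solves → measurement
frames and signals → envelope/correlation characterization → elastic-net
volume estimators with feature-stability diagnostics → anatomical frame
scaling.

## Virtual anatomies

Each virtual patient is a cylindrical abdomen, 30 cm tall, with

* a waist circumference $w$ (six values, 0.775–1.275 m, step 0.10 m,
  spanning roughly the 10th–90th percentile of adults),
* a subcutaneous fat shell of thickness $f$ (0.02–0.08 m, step 0.02 m),
* a fixed 0.15 cm skin shell,
* a muscle interior (abdominal organs are predominantly muscle-like
  dielectrically), and
* a spherical bladder centred at mid-height with a fixed anterior offset of
  $r/3$ (with $r = w/2\pi$), whose radius follows the simulated volume
  (10, 20, 100, 220, 340, 460 mL; 10 mL is the baseline).

Six gel electrodes of 1.5 cm radius sit on the anterior semicircle at
$\{-90, -54, -18, +18, +54, +90\}$ degrees from the anterior midline — an
equiangular arrangement whose end electrodes are diametrically opposite.
An equiangular belt whose ends are diametrically opposite does not pin
down the absolute angles; this semicircular layout covers the bladder
region symmetrically and is fixed as the package's convention.

Configurations in which the growing bladder would intersect the fat shell
cannot occur in vivo and are removed: a `(w, f)` pair is retained as a
virtual patient only if it is feasible at the maximum volume (feasibility is
monotone, so it is then feasible at every volume). With the default grid
this keeps **15 of 24** combinations:

```{r}
library(bladdersim)
sw <- enumerate_sweep(sweep_grid())
nrow(sw$patients)  # 15
```

The frequency grid holds nine values in 10–250 kHz: five per decade plus
the standard 50 kHz working frequency (a pure five-per-decade grid holds
only eight points in that band; 50 kHz is the convention for single-
frequency analyses throughout).

## Tissue dielectrics

Each domain's complex relative permittivity follows a 4-term Cole-Cole
model,

$$\hat\varepsilon(\omega) = \varepsilon_\infty + \sum_{n=1}^{4}
\frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} +
\frac{\sigma_s}{j\omega\varepsilon_0},$$

from which the solver takes $\sigma = -\omega\varepsilon_0\,
\mathrm{Im}\,\hat\varepsilon$ and $\varepsilon_r = \mathrm{Re}\,
\hat\varepsilon$. Parameters ship as an editable table
(`inst/extdata/tissue_dielectrics.tsv`): Gabriel-type literature sets for
muscle, average infiltrated fat and dry skin; a saline-like single-
dispersion set for urine ($\sigma_s$ = 1.75 S/m); and a constant-property
gel ($\sigma$ = 0.3 S/m, $\varepsilon_r$ = 100) standing in for a digitized
interpolation curve whose points are not available. The urine and gel
entries are **literature defaults, not study ground truth** — published
urine conductivities span roughly 1.5–3 S/m, and the exact choice shifts
the urine–muscle contrast and with it the absolute signal levels and the
weak frequency trend of $|\Delta V|$ (see *Limitations*). Users can supply
their own table via `tissue_table(name, file = ...)`.

Over 10–250 kHz every shipped tissue is in its beta-dispersion regime, so
effective conductivity is non-decreasing in frequency — asserted by the
test suite on the full grid.

## Forward solver

The quasi-static complex conduction problem
$\nabla\cdot(\sigma^*\nabla\varphi) = 0$, with
$\sigma^* = \sigma + j\omega\varepsilon_0\varepsilon_r$, is discretized by a
structured finite-volume mesh in cylindrical coordinates:

* radial grid lines pinned to the muscle|fat and fat|skin interfaces (the
  thin skin is one cell thick — two-point fluxes with harmonic averaging
  handle the jump);
* angular and axial grid lines **snapped to the electrode patch
  boundaries**, uniform across each patch and each inter-electrode gap,
  coarser posteriorly and towards the cylinder ends. Aligning the mesh with
  the patches is essential: with patch-agnostic grids the covered-face set
  changes discontinuously under refinement and frame voltages do not
  converge;
* the spherical bladder enters through per-cell urine volume fractions
  (midpoint subsampling with the cylindrical Jacobian) with linear mixing
  of the complex conductivities; the discretized bladder volume is within
  a fraction of a percent of the requested volume at every level.

Electrodes follow the **complete electrode model**: each patch is an
equipotential coupled to the surface cells through an effective contact
impedance $z_c = t_{gel}/\sigma^*_{gel}$ (the 0.5 cm gel body is not
meshed), with prescribed net currents (+1 mA / −1 mA on the driven pair,
zero elsewhere) and a zero-mean potential reference over the six
electrodes.

The resulting complex symmetric system is solved by conjugate gradients
with unconjugated inner products (COCG), preconditioned by a sparse
Cholesky factorization of the real part (relative residual $10^{-12}$).
The factorization is computed once per (anatomy, volume, frequency) and
reused across all 15 current-pair right-hand sides. A direct factorization
of the complexified system was rejected after profiling: the sparse LU of
the doubled real form fills in badly on this 3-D stencil, while the real
part is an excellent preconditioner (the displacement-current term is a
modest perturbation at these frequencies), so COCG converges in a few tens
of iterations.

Mesh resolution is a single integer `level` scaling cell counts in every
direction (level 1 ≈ 8k cells, level 4 ≈ 73k). Sweeps run at level 1;
levels 3→4 change frame-voltage magnitudes by at most ~1% on sampled
configurations (the suite asserts < 2%), while level-1 voltages carry a
few percent discretization error — acceptable because every downstream
comparison is relative. Reciprocity ($Z_{cc\to pu} = Z_{pu\to cc}$),
linearity in current, inverse scaling in conductivity and exact sagittal
mirror symmetry hold to solver precision and are asserted in the tests.

## Frames and signals

With six electrodes there are $\binom{6}{2} = 15$ current-carrying pairs
and, per pair, $\binom{4}{2} = 6$ pick-up pairs: **90 measurement frames**,
enumerated lexicographically with stable identifiers (`cc12_pu34`, ...).
The *neighboring set* N — the conventional EIT addressing scheme — keeps
frames whose CC and PU pairs are both adjacent along the arc; because the
belt spans a semicircle (electrodes 1 and 6 are opposite, not adjacent)
adjacency does not wrap, giving $|N| = 12$. A wrap-around mode is available
by flag.

Signals are computed against the 10 mL baseline row of the same patient
and frequency; feature tables hold $|\Delta V|$ and VCR over the five
non-baseline volumes (15 patients × 5 volumes = 75 rows × 90 frame
columns at one frequency). Missing baselines are hard errors. Magnitudes
of the complex frame voltages are analyzed; phase is retained upstream but
unused.

## Characterization

`signal_envelope()` summarizes a signal at maximal bladder volume per
waist, fat or frequency group (mean, sample n−1 standard deviation,
quartiles, pooled over frames and remaining conditions).
`aggregated_pcc()` pools every (row, frame) observation at maximal volume
into one Pearson correlation against the parameter — the plain reading of
an "aggregated" coefficient; a per-frame averaging mode exists by flag.
Frequency correlates on $\log_{10} f$ by default. On the forward sweep the
envelopes shrink monotonically with waist and with fat, and the
correlations are strongly negative for waist, intermediate for fat and
weak for frequency, for both signals (recomputed by
`scripts/acceptance.R`; the test suite asserts the pattern).
`afe_required_step()` converts the weakest mean full-bladder signal into
the voltage step an analog front end must resolve for a target volume
resolution — with a 0.44 mV mean at 460 mL, a 10 mL target needs steps of
about 9.6 µV.

## Volume estimators

Four baseline models, all elastic nets (via glmnet; penalty weight
$\lambda$ is the elastic-net penalty weight, L1 ratio = glmnet's `alpha`),
fitted on one frequency slice (50 kHz by default, pooling available by
flag):

| model | features | scope | cross-validation |
|---|---|---|---|
| 1 | 90 frames, $|\Delta V|$ | patient-specific | LOO over 5 measurements |
| 2 | 92 (+waist, fat), $|\Delta V|$ | generalized | leave-one-patient-out (15 folds) |
| 3 | 90 frames, VCR | patient-specific | LOO over 5 measurements |
| 4 | 92 (+waist, fat), VCR | generalized | leave-one-patient-out (15 folds) |

Hyperparameters are grid-searched (defaults: $\lambda$ log-spaced
$10^{-7}$–$10^{-1}$, 25 points; L1 ratio 0.1–1.0 step 0.1) by minimizing
the scoring metric (MAE in mL or MAPE in %) pooled over all held-out
predictions; ties break to the smallest penalty, then the smallest L1
ratio. Within-fold standardization is glmnet's, fitted on the training
partition only. The solver path is warm-started from the data-driven
maximal penalty — the grid values lie far below it, and coordinate descent
started cold there is both slow and fragile. Reports hold, per model:
error mean ± sample SD across patients
(patient-specific) or folds (generalized), selected-feature counts
($|\beta| > 10^{-10}$), the fraction $F_N$ of the neighbor set used
(denominator $|N|$, averaged over folds), mean pairwise Jaccard, and the
stability score.

One consequence of within-fold standardization deserves a flag: inside a
single patient (and frequency), every VCR feature column is a constant
rescaling of the corresponding $|\Delta V|$ column
($\mathrm{VCR}_f = |\Delta V|_f \cdot 100 / V_{0,f}$ with $V_{0,f}$ fixed
per frame), and column scaling is absorbed by standardization — so the
*patient-specific* VCR and $|\Delta V|$ models produce identical
cross-validated predictions and selection patterns. Unstandardized
fitting would break this equivalence (at the price of severe sensitivity
to feature scale); the generalized models are not affected because
baselines differ across patients.

## Feature-selection stability

Across the cross-validation folds (all 75 within-patient folds pooled for
patient-specific models, the 15 patient folds for generalized ones):

* mean pairwise Jaccard
  $\bar J = \binom{N}{2}^{-1}\sum_{i<j}|S_i \cap S_j| / |S_i \cup S_j|$
  (empty ∪ empty counts as identical);
* selection probability $\hat\Pi_k$ = fraction of folds with a nonzero
  coefficient for feature $k$;
* stable set $\hat S_{stable} = \{k : \hat\Pi_k \ge \pi_{thr}\}$ with
  $\pi_{thr} = 0.8$, boundary included;
* stability score $S$ = fraction of selected features (union over folds —
  the documented reading of "selected"; a per-fold averaging mode is a
  flag) that are stable, defined as 1 when nothing was ever selected.

All three agree with brute-force set-arithmetic oracles on a thousand
randomized instances in the test suite.

## Anatomical frame scaling

One multiplicative factor per measurement row, uniform across frames:

* linear: $V_s = V / (\alpha_{lin} w \cdot \beta_{lin} f)$ — only the
  product $\alpha_{lin}\beta_{lin}$ is identifiable, so the fit reports the
  product and fixes $\beta_{lin} = 1$;
* exponential: $V_s = V\,(\eta\, e^{-\delta_1 w - \delta_2 f} +
  \alpha_{off})$ — physics-informed (fields decay exponentially with
  distance from the source).

The choice of curve-fitting objective is genuinely open; the package
adopts a *reference-collapse* least squares: parameters minimize
the squared distance between scaled training rows and the training-pool
mean signal per volume, restricted to the elastic-net-selected features.
This matches the stated purpose (adjust overall magnitude, preserve
relative spatial structure) and keeps scaling separable from the
regressor. Consequences worth knowing: the fitted multiplier is determined
only up to the normalization of the reference curve (planted-law recovery
tests compare decay rates exactly and gain/offset after removing that
scale), and the linear law has a closed-form solution while the
exponential law is Levenberg–Marquardt-refined from a log-linear
initialization.

`evaluate_scaled()` is fully nested: within each of the 15
leave-one-patient-out folds the scaling is fitted on training patients
only, both partitions are scaled, the elastic net is re-selected by
patient-level cross-validation inside the training partition (5 groups by
default — a full inner LOO triples the cost without changing outcomes),
refitted, and the held-out patient predicted. On sweeps whose
inter-patient variation follows the exponential law exactly, exponential
scaling collapses the anatomy effect (held-out MAE of a few mL where the
unscaled and linearly scaled models err by tens of mL) — and the same
ordering holds on the forward-solver sweeps.

## The synthetic generator

`synthetic_voltage_table()` is a fast parametric stand-in for the forward
sweep used by the estimator and scaling tests: per-frame baseline levels
(log-uniform 0.2–5 mV) and fractional volume sensitivities (5–60% at full
volume), both attenuated exponentially in $(w, f)$. Default decay rates are
set to reproduce the envelope compression of the simulated sweeps (signal component:
$\delta \approx (3.1, 10)$ per m; baseline component slightly increasing
with fat so that VCR attenuates faster than $|\Delta V|$), with an optional
log-frequency tilt (−2%/decade) and multiplicative Gaussian noise. It
emulates the envelope compression, the patient-specific scaling structure
and the volume linearity of the simulated data; it does **not** emulate
frame-to-frame spatial correlation, solver discretization error, or any
nonlinearity of the volume response, so estimator results on it
demonstrate machinery, not physics.

## Numerical choices and problem sizes

* $\varepsilon_0 = 8.8541878128\times10^{-12}$ F/m; SI units internally,
  volumes exposed in mL.
* COCG relative residual $10^{-12}$, max 400 iterations; glmnet threshold
  $10^{-10}$, max iterations $10^5$.
* Coefficient nonzero tolerance $10^{-10}$, shared by the estimation and
  stability modules.
* Sweeps and the acceptance script run at mesh level 1 (~8k cells, about
  2–3 s per configuration including the 15 injections); the convergence
  check compares levels 3 and 4 on a sampled configuration. The analysis
  scripts state their grid sizes in their headers.
* Test fixtures use reduced hyperparameter grids (e.g. 6 × 2) — grid
  density affects the chosen penalty, not the qualitative contrasts the
  tests assert.

## Limitations

* The cylinder is an idealized torso: no lateral curvature, hip structure
  or tissue heterogeneity; single-row belt only.
* Urine and gel dielectric parameters are literature defaults (see above).
  The absolute signal levels, and weak secondary trends such as the
  $|\Delta V|$-versus-frequency correlation, shift with the urine
  conductivity chosen; the qualitative anatomy effects do not.
* Exact voltage agreement with other solvers is out of scope; acceptance
  is property-based (reciprocity, symmetry, convergence, monotonicity,
  sign patterns) plus the exactly recomputable combinatorial and geometric
  results.
* Electrode angular positions and the inner model-selection scheme of the
  nested scaled evaluation are documented package conventions where the
  study conditions are silent.
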