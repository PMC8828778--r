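---
title: "Models and methods behind the cici package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cici package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cici)
```

## The experimental system

Chemically induced chromosomal interaction (CICI) experiments tether two
genomic loci in living yeast on demand. Each locus carries a repeat array
(LacO or TetO) bound by a repressor fusion; the two fusions carry FKBP12 and
FRB domains that dimerize only in the presence of rapamycin. Separate
LacI-GFP and TetR-mCherry fusions make the two loci visible as a green and a
red "chromosome dot". Adding rapamycin therefore switches on an attractive
interaction between the loci, and the readout is the distance between the
two dots in projected fluorescence images: dots within **0.4 µm** are
scored as co-localized.

Two kinds of data come out of such experiments, and this package quantifies
both:

* **population time courses** — at each time after rapamycin addition, the
  fraction of cells with co-localized dots;
* **single-cell distance traces** — time-lapse distance measurements on a
  10-min frame grid, from which contact *formation* and *disruption* events
  are called, together with a budneck (Myo1) marker that timestamps cell
  division.

Companion assays reuse the same machinery: correlation of contact metrics
with published Hi-C contact frequencies, qPCR-based replication-timing
curves, and gel-band quantification of donor usage in mating-type
switching.

## The population kinetics model

The observed co-localization probability after inducer addition reflects two
consecutive, independent exponential waiting times: rapamycin entering the
nucleus (rate $k_2$) and the two loci encountering each other (rate $k_1$).
The convolution of the two processes gives

$$P(t) = a_1 + \frac{a_2}{k_2 - k_1}
  \left[\frac{1}{k_1}\left(1 - e^{-k_1 t}\right)
      - \frac{1}{k_2}\left(1 - e^{-k_2 t}\right)\right],$$

implemented in `coloc_model()`. Its anchor points are $P(0) = a_1$ (the
pre-induction baseline set by chance proximity) and
$P(\infty) = a_1 + a_2/(k_1 k_2)$ (the steady-state plateau). When
$|k_1 - k_2| < 10^{-9}$ the implementation switches to the analytic limit
$a_1 + a_2[(1-e^{-kt})/k^2 - t\,e^{-kt}/k]$ rather than dividing by a
vanishing difference.

Derived quantities:

* **half-time** $t_{1/2} = \ln 2 / k_1$ (`half_time()`), the characteristic
  encounter time of the loci pair;
* **efficiency** $(P_\mathrm{final} - P_\mathrm{initial}) /
  (1 - P_\mathrm{initial})$ (`cici_efficiency()`), the net co-localization
  gain normalized by the available head-room.

`fit_timecourse()` fits $a_1$, $a_2$, $k_1$ by weighted least squares on the
observed fractions with $k_2$ **fixed at 0.2 min⁻¹** (nuclear entry of the
drug is a property of the strain background, not of the loci pair, so it is
shared across fits). Choices that matter:

* weights are $1/\mathrm{SE}^2$ with the per-timepoint binomial standard
  error floored at $1/(2n)$, so timepoints with observed fractions of
  exactly 0 or 1 cannot acquire infinite weight;
* bounds $a_1 \in [0,1]$, $a_2 \ge 0$, $k_1 \in (10^{-4}, 10)$ min⁻¹, with
  16 deterministic L-BFGS-B starts on a log-spaced $k_1$ grid; ties are
  broken by objective value, then by smaller $k_1$;
* a time course with zero variance pins $a_2 = 0$ and reduces to a weighted
  mean for $a_1$;
* the parameter covariance is the Gauss–Newton $(J^\top W J)^{-1}$.

The fit is exactly invariant to time-unit rescaling provided $k_2$ and the
$k_1$ bounds are rescaled accordingly (tested).

## Single-cell event rules

Formation and disruption are called by a small state machine
(`call_events()`) that encodes the scoring rules verbatim:

* **QC**: a trace is analyzable only if the dots are clearly detected in at
  least 80% of frames (`qc_trace()`).
* **Formation**: the first run of at least 3 consecutive frames with
  distance ≤ 0.4 µm. Frames with undetected dots break a run. The event is
  timestamped at the *first* frame of the run — the contact exists from its
  first observed frame (the alternative, the last frame of the run, would
  date the contact by the rule rather than by the observation).
* **Disruption** (scanning after a formation): the first frame whose
  distance exceeds 0.6 µm, or the second frame above 0.4 µm within any 4
  consecutive frames, timestamped at that second loss. After a disruption
  the machine scans for a fresh formation, so traces can alternate.
* Frames with missing distance count as neither co-localized nor lost:
  missing data must not fabricate either kind of event.

Two readings of "lost at least twice within four frames" are implemented
(`window_mode = "sliding"` or `"anchored"`); with two required losses they
are provably equivalent — a 4-frame window holds two losses exactly when two
successive losses are ≤ 3 frames apart — and the test suite checks the
equivalence exhaustively. The sliding reading is the default and the
distinction would only matter if `losses_required` were raised above 2.

The event caller is verified against an independently written brute-force
oracle on *every* binary co-localization sequence up to length 12 and every
ternary (co-localized / lost / above-hard-threshold) sequence up to length
8, including sequences with missing frames.

**Division alignment.** The budneck marker disappears during some frame
interval; division time is taken as the midpoint of that interval, and
disruption times are reported relative to the nearest subsequent division
(negative = before division; `disruption_relative_to_division()`). On a
10-min grid any convention within the interval shifts times by at most
5 min. `persistence_through_division()` scores a contact as disrupted at
division when a disruption call lands within one frame before to four
frames after the division frame — four frames because the disruption rules
themselves need up to a 4-frame window to fire after the physical
separation.

## Formation-time mixtures

Single-cell formation times are fitted with one- and two-component
exponential mixtures (`fit_exponential_mixture()`). The package fits the
**raw, unbinned times by maximum likelihood** rather than least squares on
a histogram: MLE is bin-free and strictly more informative, and the
distribution display (10-min bins) remains purely a visualization. A
histogram least-squares mode (`method = "histogram"`) is retained for
fidelity checks against histogram-based fits; the two agree on simulated
data within their respective errors. The amplitude $A_1$ is interpreted as
the mixture weight (probability mass) of the fast component.

Model selection uses AIC with 1 free parameter for the single model and 3
for the double (`compare_models_aic()`); AIC rather than a small-sample
correction, matching the stated test, and the nesting inequality (double
log-likelihood ≥ single) is asserted as an invariant. Right-censored cells
(no formation within the movie) are excluded, mirroring the histograms being
fit; a censored-likelihood term would be the natural extension but would
change the estimand.

`joint_mixture_fit()` maximizes the summed log-likelihood over **shared**
time constants $(t_1, t_2)$ with one $A_1$ per group (e.g. G1 versus budded
cells), the model used to ask whether cell-cycle stage changes the *mix* of
fast and slow encounters rather than their rates. Both mixture fits run EM
from a deterministic grid of starts; standard errors come from the observed
information on $(\log t_1, \log t_2, \mathrm{logit} A_1)$ with a delta-method
back-transform.

## Spot detection

Detection follows the projected-image convention: `max_project()` takes the
per-pixel maximum across z inside cell masks (pixels outside all cells are
zeroed), and all distances are 2-D distances in the projection — axial
separation is deliberately invisible, exactly as in the imaging analysis
this reproduces. Dots are connected components of supra-threshold pixels,
split by cell label. The threshold is user-supplied, either absolute or as
mean + n·SD of the in-mask intensities (default n = 5); no canonical value
exists, so it is a config parameter.

The sub-pixel centroid is an **aperture centroid**: background-subtracted
intensity weights over a fixed square window (half-width 3 px ≈ 2 PSF sigma)
centered on the component peak and restricted to the component's cell. An
aperture centroid is used instead of a centroid over supra-threshold pixels
because the latter's accuracy degrades sharply as the threshold rises (fewer
and noisier pixels); the aperture makes localization accuracy essentially
threshold-independent. Background is the median in-mask intensity, robust
because dots occupy a small area fraction. If the aperture carries no
weight (flat image), the plain intensity-weighted component centroid is the
fallback.

Coordinates put the top-left corner of pixel (1,1) at (0,0) µm, so a pixel
center sits at $(\mathrm{col} - 0.5) \cdot \mathrm{pixel\_size}$. The
co-localization boundary is inclusive (≤ 0.4 µm); ties at the boundary have
measure zero in real data.

Cell segmentation is an input (label matrix); `otsu_threshold()` exists
only so synthetic fixtures can be processed without an external mask.

## Hi-C correlation

Hi-C values are consumed as a small curated table of per-pair 10-kb
bin-pair contact frequencies (`load_pair_table()`), replica columns
averaged; no contact-matrix processing is in scope. The bundled
`synthetic_hic_pairs.csv` is a *synthetic* stand-in whose values only mimic
the qualitative structure (intra-arm > inter-domain > inter-chromosomal).
`regress_r2()` is ordinary least squares of a contact metric on the Hi-C
signal, untransformed by default (a `log_x` option exists since contact
frequencies span orders of magnitude); $R^2$ equals the squared Pearson
correlation, asserted to $10^{-12}$.

## Replication timing

qPCR Ct tables become relative copy-number curves in three steps
(`qpcr_curves()`): dose relative to a late-replicating control region as
$2^{\Delta Ct}$ (perfect doubling per cycle is assumed — Ct differences are
used without an efficiency model), primer-bias correction by normalizing to
the t = 0 sample so $r(0) = 1$ by construction, then averaging biological
replicates. The pipeline is invariant to a per-replicate constant Ct offset
(machine calibration), which the tests assert.

The 30–40 min window mean (`window_mean()`, inclusive endpoints — on a
10-min grid the window holds exactly the 30- and 40-min points) summarizes
how early an origin fires. Systematic drift (e.g. uneven G1 release) is
corrected by matching the *difference* between two unperturbed anchor
origins to the background strain (`drift_correct()`). The correction is
multiplicative per timepoint — an additive shift applied after the
difference could never change the anchor difference, so the multiplicative
reading is the only self-consistent one; a whole-curve variant
(`per_timepoint = FALSE`) applies the ratio of time-averaged differences
instead. Where both anchor differences vanish (notably t = 0) the 0/0 ratio
borrows the nearest defined scale; the scale is clipped to [0.5, 2] with a
warning since larger corrections would signal a failed experiment rather
than drift. Strain comparisons are Welch t-tests on replicate window means
by default; `pooled = TRUE` reproduces the classical equal-variance
Student's test.

## The synthetic-data generator

Every pipeline stage is testable against generated data with known ground
truth. The generator states a world once; its defaults are not tuned to
test outcomes.

* **Distance traces** (`simulate_distance_trace()`): the inter-locus
  separation vector follows a 2-D Ornstein–Uhlenbeck process — the simplest
  stationary confined-motion model — with RMS separation 0.7 µm and
  relaxation time 20 min, which puts unbound co-localization baselines in
  the observed 10–40% range. Dynamics are 2-D because the measured distance
  is 2-D; z exists only in image rendering. After drug addition, frames
  with true separation ≤ 0.4 µm bind with a per-frame probability; bound
  frames hold the separation at zero. Divisions recur every 150 min with a
  uniform phase, and a bound pair is disrupted at division with probability
  11/58 (the observed disrupted:intact odds across divisions). A
  division-disrupted pair is displaced to 1.2 µm (order of a spindle
  half-length) rather than relaxing from zero — otherwise it would
  instantly re-bind and the disruption would be invisible to any
  distance-based caller. All randomness is pre-drawn with state-independent
  consumption, so changing one switch (e.g. disabling binding) never
  perturbs the rest of the path, and each cell derives a deterministic
  sub-seed from one global seed.
* **Ground truth** records the molecular bound state, but
  `true_formation_frame` is defined as the 3-frame co-localization rule
  applied to the *noiseless* distance: under a 0.7-µm confinement the
  unbound pair dips below 0.4 µm regularly, so no distance-based caller
  could recover binding onset itself, and the honest contract is "the
  caller reproduces the rule on noiseless data exactly" (tested, along with
  ≥ 95% ±1-frame agreement at 0.05 µm localization noise).
* **Z-stacks** (`render_zstack()`): dots are 3-D Gaussians (lateral sigma
  in pixels, axially widened 2.5×) whose integral is the photon count,
  on a flat background, with Poisson shot noise.
* **Population time courses**: binomial draws around the convolution
  model, rejected if the requested parameters push $P(t)$ outside [0, 1].
* **qPCR tables** (`simulate_qpcr()`): per-locus copy number
  $c(t) = 1 + (1 + e^{-s(t - m)})^{-1}$ rising sigmoidally from 1 to 2
  around midpoint $m$; $Ct = Ct_0 - \log_2 c(t) +$ Gaussian noise. The
  control region must carry the latest midpoint. An optional drift
  function emulates uneven G1 release for testing the anchor correction.

What the generator does **not** emulate: polymer (Rouse) physics, nuclear
landmarks (nucleolus, spindle pole body), photobleaching trends,
chromatic aberration, segmentation errors, or qPCR efficiency differences
between primers. A green test therefore establishes that the *analysis*
is correct under the stated model, not that the model captures every
feature of real microscopy data. No motion parameters were reported for
the real strains, so the OU defaults are calibration choices of this
package, stated here once.

## Numerical choices and degenerate inputs

* Mixture EM stops on log-likelihood change < 1e-10 or 500 iterations;
  a dying component (all responsibility on one side) halts the update
  rather than producing NaNs; all-identical times force the
  single-component model with a warning.
* `fit_timecourse` uses parameter scaling in L-BFGS-B (`parscale`) so the
  numerically small $a_2$ converges to the same relative precision as the
  other parameters.
* Components are ordered $t_1 \le t_2$ after fitting; the fast amplitude is
  reported for the fast component by construction.
* Empty dot sets yield an `NA` distance flagged for QC, never an error;
  an all-below-threshold image is a valid empty detection.
* `regress_r2` errors on constant x (undefined) and returns 0 with a
  warning on constant y.

## Known limitations

* No TIFF input/output: stacks are in-memory arrays (no TIFF codec among
  the package's dependencies); the command-line interface covers the
  CSV/JSON-based workflows and image detection is API-only.
* No dot tracking across frames: per-frame minimum distances, as in the
  underlying scoring, which can switch identity when multiple dots are
  present.
* The mixture standard errors are Wald-type from the observed information;
  profile or bootstrap intervals would be preferable near the $A_1$
  boundary.
* Drift correction assumes the anchors themselves are unperturbed; if a
  forced interaction altered an anchor's timing, the correction would
  propagate that bias.
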