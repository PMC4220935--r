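---
title: "Coarse-to-fine detection of calcified plaque with acoustic shadowing in IVUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine detection of calcified plaque with acoustic shadowing in IVUS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivuscalc)
```

## The problem

Intravascular ultrasound (IVUS) images a coronary vessel from inside the
lumen, producing a cross-sectional view centred on the catheter. Calcified
plaque is the most echogenic structure in these frames: it reflects almost
all of the ultrasound energy, so it appears as a bright arc lying along the
vessel wall, and the tissue radially behind it receives almost no signal —
the *acoustic shadow*. Because the beam travels radially, the shadow is
rectangle-like in polar coordinates: a dark block occupying the same angular
range as the plaque and extending from just behind it to the edge of the
imaging area. This pairing — bright arc plus dark radial block — is what the
detector looks for; bright structures *without* a shadow (collagen bundles,
guide-wire artifacts, the adventitia itself) must be rejected.

`ivuscalc` implements the full coarse-to-fine pipeline as a tested library
with a thin command-line front end:

1. **Pixel classification** by a shifted-Rayleigh mixture model (RMM) with
   neighbourhood-aware priors, fitted by a generalized EM algorithm;
2. **Angular localisation** by sum-product belief propagation (BP) on a
   one-dimensional Markov random field over the polar image's angle
   columns;
3. **Refinement** of candidate arcs by five anatomical constraints;
4. **Border tracing** of the accepted plaques by free-endpoint minimal-cost
   path search on gradient cost grids.

A seeded synthetic phantom generator and the evaluation stack (plaque
measurements, sensitivity/specificity, linear regression, Bland–Altman
agreement) make every stage testable without any image download.

## Geometry and the maximum intensity curve

All detection happens on the polar grid: rows index radius (row 1 at the
catheter centre), columns index angle (column $c$ at $(c-1)\,\Delta\theta$
degrees, counterclockwise). `to_polar()` chooses the radial step so the last
row reaches the nearest Cartesian edge; `to_cartesian()` inverts it.
"Below" a curve always means larger radius.

The *maximum intensity curve* (MIC), `compute_mic()`, is the per-column row
of the brightest pixel. Where a calcified plaque is present the MIC passes
through it, because calcium out-reflects every other tissue; elsewhere it
follows the brightest wall or adventitia speckle. The first `ringdown_rows`
rows (default 8) are excluded so the catheter ring-down artifact cannot
win.

## The Rayleigh mixture model

Speckle intensity in B-mode ultrasound is well described by Rayleigh
statistics, so gray levels are modelled as a $K$-component mixture of
shifted Rayleigh densities

$$p(x \mid s_j, t_j) = \frac{x - t_j}{s_j^2}
  \exp\!\left(-\frac{(x - t_j)^2}{2 s_j^2}\right), \qquad x > t_j,$$

with mode $s_j$ and translation $t_j$. $K = 5$ by default: the goal is not
to name five tissues but to guarantee that the hypoechoic family — blood
speckle and acoustic shadow — occupies the two lowest-mean classes, which
is exactly what the angular-localisation stage consumes.

**Initialisation.** One-dimensional k-means on intensity (deterministic,
quantile-seeded centres, so a fit is reproducible without a seed) gives
cluster means $\mu_j$; $t_j$ starts at the cluster minimum and the mode
follows from the shifted-Rayleigh mean identity
$\mu = t + s\sqrt{\pi/2}$. Pixel priors start uniform.

**Priors with spatial structure.** Instead of global mixing proportions,
every pixel carries its own prior vector built from the current
responsibilities in three steps: a per-pixel weight
$w_{ij} = \gamma_{ij}\exp(-a\,\delta_i^2/b)$ that discounts pixels deviating
from their $3\times3$ neighbourhood mean ($\delta_i$ is the local contrast
on the $[0, G_{\max}]$ scale); aggregation of those weights over the
neighbourhood, raised to $\beta$ (default 2) to sharpen; and normalisation
over components. The effect is the classic one for speckle: an isolated
outlier pixel inside a homogeneous region keeps its region's label.

**Fitting.** The M-step is a backtracked steepest ascent on the surrogate's
parameter term with analytic gradients, as small images do not justify a
closed-form solve for the shifted family. Three numerical choices matter,
all made after observing failure modes of the plain recipe on synthetic
data and all config-exposed:

* *Support margin* (`support_eps`, 0.5 gray): pixels within half a
  quantization step of a component's translation are excluded from its
  likelihood term; the $-1/(x - t_j)$ gradient term is singular exactly at
  the initialisation point ($t_j$ = cluster minimum), and intensities carry
  no information below the quantization scale anyway.
* *Support extension*: the masked objective can never pull a translation
  below the smallest pixel the component currently covers (those pixels
  have zero density, hence zero responsibility, hence no gradient), so the
  fit would stay locked at the k-means slice boundaries. After each M-step,
  each translation may move *down* by a fraction of its mode whenever that
  raises the observed-data log-likelihood.
* *Monotonicity guards*: the prior update is blended toward the
  responsibilities just enough that the surrogate's prior term never
  decreases, and an M-step that would lower the observed likelihood (a
  rare support-boundary artifact) is skipped. Every block is then monotone
  in the observed likelihood and the reported objective trace is
  non-decreasing by construction.

Convergence is declared when no mode or translation moves by more than
`em_tol` (default $10^{-3}$ gray) in an iteration. MAP labelling
(`map_classify()`) assigns each pixel to its largest responsibility.

## Angular localisation

The two labelled classes with the smallest mean gray values form the dark
mask. Its per-column upper border $u(c)$ is the first *run* of at least
`dark_run` (default 4) consecutive dark rows below the MIC: because the
shifted-Rayleigh supports force low-intensity speckle outliers inside
bright tissue into the dark classes, a single dark pixel is not credible
evidence of a region border, while the shadow and the lumen are solidly
dark and unaffected by the run requirement.

Three per-column factors summarise the shadow evidence: $f_1 = N_r - u(c)$
(how far the dark region extends toward the imaging edge), $f_2 = u(c) -
m(c)$ (how tightly it hugs the MIC) and $f_3$ (the mean gray level between
the MIC and the border — bright tissue there argues against a shadow). The
column prior is a logistic squashing of the normalised linear score

$$s(c) = \lambda_1 \frac{f_1}{N_r} - \lambda_2 \frac{f_2}{N_r}
        - \lambda_3 \frac{f_3}{G_{\max}},$$

centred at the midpoint of the per-image score range. Two deliberate
choices here: the weights default to $(1, 1, 0.5)$ because their stated
purpose is to bring the three factors to the same order of magnitude and
the bright-tissue range of $f_3/G_{\max}$ spans roughly twice that of the
two geometric factors; and the centring uses the range midpoint rather
than the median, because a median split forces half of the columns of any
homogeneous (plaque-free) frame above 0.5 by construction — with midpoint
centring a homogeneous frame sits near 0.5 everywhere and the decision is
deferred to the refinement stage, while a frame containing shadow-backed
columns separates cleanly.

The columns then form a binary MRF — states $+1$ (plaque) and $-1$
(background), pairwise compatibility $\psi = \begin{pmatrix} q & 1-q \\
1-q & q\end{pmatrix}$ with $q = 0.7$ — solved by synchronous sum-product
message passing with damping 0.5 until the largest belief change falls
below $10^{-3}$. The chain is closed into a ring by default because the
angular axis is periodic and plaques crossing $\theta = 0$ must not be
split; a `chain` mode exists, on which the fixed point equals exact
enumeration (this is tested to $10^{-6}$). Beliefs at or above 0.5 mark
plaque columns; maximal runs become candidate angular segments, with a run
across column 1 forming a single wrapping segment.

## The five refinement constraints

Candidates are screened in order, short-circuiting on the first failure
(the accepted set is provably order-independent; only the diagnostic flags
differ):

1. **Brightness**: at least `rate_min` (0.5) of the MIC pixels in the
   segment exceed `t_gray` (0.55 $G_{\max}$) — calcium is bright.
2. **Slope**: the MIC rises or falls by at most `slope_max` (1 row/column)
   between the segment endpoints — plaque grows along the wall, not
   radially.
3. **Angular length**: between `ang_len_min` (4 columns) and `ang_len_max`
   ($2N_c/3$). The upper bound rejects full-circle bright rings such as
   the adventitia; the lower bound rejects speckle-scale candidates for
   which the slope test is undefined and the region statistics are
   unstable.
4. **Shadow contrast**: the mean gray level up to `flank_depth`
   (0.3 $N_r$) below the MIC inside the segment must undercut both flank
   regions (same depth, `flank_width` columns each side) by
   `shadow_margin` (0.08 $G_{\max}$) — there must actually be a shadow.
5. **Shadow shape**: anchored at $r^\ast$, the larger endpoint MIC row,
   the closeness rectangle (height 0.25 $N_r$) and the extent rectangle
   (down to the last row) must be filled with dark-mask pixels to at
   least `rho_close` (0.5) and `rho_rect` (0.5) — the shadow starts right
   behind the plaque and is rectangle-like. The closeness height scales
   with the radial sampling because the rectangle's top rows necessarily
   contain the bright band between $r^\ast$ and the shadow onset: a
   fixed-height band shorter than the plaque thickness would fail every
   true plaque regardless of the data.

## Border tracing

For each accepted candidate the leading (upper) border is traced in the
window between the ring-down band and the MIC, the trailing (lower) border
between the MIC and $r^\ast + h_{\text{sub}}$ (default 15 rows; deeper
shadow rows carry no edge information, only noise). After radial Gaussian
smoothing ($\sigma = 1$ row) the cost is the central radial difference,
negated for the upper border (minima on dark$\to$bright transitions) and
kept for the lower (bright$\to$dark), shifted non-negative per grid. A
dynamic program finds the column-monotone path with $|\Delta\text{row}|
\le 1$ minimising the cost sum; both endpoints are free, so the path
attains the global minimum (verified against exhaustive enumeration), and
ties resolve toward the smaller row. Wrapping segments are unrolled before
tracing. The two paths plus the segment borders close into a polygon in
polar coordinates and map exactly to Cartesian points.

## Measurements and evaluation

`measure_plaque()` reports angular length AL $= \text{len}\cdot
\Delta\theta$ (degrees), angular centre AC (circular midpoint), plaque
area PA $= \sum_c \tfrac12 (r_{\text{low}}^2 - r_{\text{up}}^2)
\Delta\theta$ (mm², a polar integral, resolution-independent), mean
thickness PT and mean leading-edge distance to the catheter DC (mm).
Frame- and pixel-level sensitivity/specificity use the standard
definitions TP/(TP+FN) and TN/(TN+FP); regression goes through
`stats::lm`; Bland–Altman agreement uses $\bar d \pm 2\,\mathrm{sd}(d)$
limits with the two ratio indices and the percentage of points outside
the limits.

## The synthetic phantom

`generate_phantom()` draws every tissue region independently from its
shifted-Rayleigh law directly on the polar grid (the domain the pipeline
operates in; physically accurate RF-domain simulation is out of scope).
The default geometry is a 128 × 180 grid: blood-filled lumen to row 55,
vessel wall rows 56–73, adventitia below, and optionally a uniformly
bright plaque band on the wall with the shadow replacing everything
radially behind it. Default levels $(t, s)$ on a 0–255 scale — lumen
$(10, 15)$, shadow $(0, 5)$, adventitia $(25, 25)$, wall $(40, 35)$,
plaque $(120, 40)$ — are chosen for physical plausibility: blood speckle
is weak but nonzero echo, shadow is near-black dropout, calcium is the
brightest structure, and the five populations are distinct enough that
the $K=5$ mixture's two darkest classes model the hypoechoic family, as
the method assumes. Distractors reproduce the classic false positives:
a collagen-like bright arc embedded in the adventitia (no shadow), a
narrow guide-wire streak inside the lumen, and a full-circle bright ring
with darkness behind it.

`phantom_suite()` randomises plaque position, arc length (20–100°) and
thickness (8–12 rows) under a master seed, alternating plaque and control
frames and cycling the distractor types through the controls.

What the phantom does *not* emulate — and hence what passing tests do not
show about clinical data: depth-dependent attenuation and focusing,
intra-plaque brightness decay, elliptical or eccentric vessels, motion
and side-branch anatomy, and speckle correlation (pixels are drawn
independently). The phantom validates the pipeline's logic, not its
clinical operating point.

## Problem sizes and runtime choices

The shipped study sizes are a 50-frame suite on the 128 × 180 grid for
end-to-end checks, 200 random instances for each exactness oracle
(belief propagation vs enumeration at up to 12 columns; path search vs
enumeration at up to 8 × 8), 20 replicates of $n = 20{,}000$ samples for
mixture recovery, and 50 random instances for the gradient/finite-
difference comparison. These sizes give stable pass/fail behaviour on a
single CPU in a few minutes.

## Known limitations

* The trailing edge is intrinsically less reliable than the leading edge:
  it sits at the transition into a signal-free region, so its localisation
  tolerance is deliberately looser.
* The five constraint thresholds are calibrated on the phantom suite;
  clinical use would require re-calibration against annotated frames,
  for which every threshold is exposed in `constraint_config()`.
* Mixture fitting underestimates the top component's mode by 10–20% when
  tissue populations overlap heavily (mass near the class boundary is
  absorbed by the lower neighbour); class *ordering*, which is all the
  downstream stages use, is unaffected.
* `read_frame()` supports PNG and TIFF; frames stored in clinical DICOM
  containers must be exported to one of these first.
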