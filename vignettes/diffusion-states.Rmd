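---
title: "Classifying membrane diffusion states with the normalized variance statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying membrane diffusion states with the normalized variance statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptvar)
```

## The problem

A receptor protein diffusing in a living plasma membrane does not see a
homogeneous fluid. Cortical actin filaments partition the membrane into
corrals whose boundaries act as soft potential barriers, and lipid-protein
interactions can order the lipids around a receptor into a nanoscopic
domain that moves with it as a "dressed" unit. Single-particle tracking at
video rate (frame period $\tau$ = 25 ms here, trajectories up to 100 s,
localization accuracy ~40 nm) samples this motion coarsely: each recorded
step temporally averages much faster microscopic motion, and the
statistics of the coarse-grained steps carry the signature of the local
environment.

`sptvar` implements a pipeline that reads (or simulates) such
trajectories and classifies the environments they explore.

## The statistics

### Bidirectional single-frame MSD

For a position series $\vec r(t)$ sampled every $\tau$, the single-frame
MSD at an interior time point is the two-sided average

$$\overline{R_\tau^2}(t) = \tfrac12\left[\,|\vec r(t+\tau)-\vec r(t)|^2 +
|\vec r(t)-\vec r(t-\tau)|^2\,\right],$$

computed by `msd_series()`. Frames adjacent to a tracking gap are
skipped. For free diffusion $E[R_\tau^2] = 4D\tau$, which gives the
conversion `diffusion_coefficient()`: $D = \overline{R_\tau^2}/4\tau$.

### The normalized variance V

The dispersion of $R_\tau^2$ over a window distinguishes environments.
We use the dimensionless form

$$V = 4\,\frac{\mathrm{Var}(R_\tau^2)}{\langle R_\tau^2\rangle^2}.$$

The constant 4 is forced analytically by the free-diffusion limit: for
2D Brownian motion the two-term averaged $R_\tau^2$ of independent
Gaussian steps has $\mathrm{Var}/\mathrm{mean}^2 = 1/2$ exactly, so free
diffusion gives $V = 2$ at any diffusion coefficient. A ratio of a
variance (units $\mu m^4$) to a first moment would carry units and could
not have a universal value of 2; the dimensionless normalization is the
only form with that property, which is why the package adopts it.

The interpretation chain is:

* **free diffusion**: $V = 2$ — purely stochastic, single step scale;
* **actin corral** ($V > 2$): the soft barrier stalls the molecule
  intermittently, mixing stalled (small) and free (large) steps and
  over-dispersing $R_\tau^2$;
* **lipid domain / dressed protein** ($V < 2$): motion bounded inside a
  small domain clips the large-step tail and under-disperses
  $R_\tau^2$.

### Finite-window calibration

$V$ is estimated per sliding window (default 40 frames, i.e. 38
$R_\tau^2$ values; step 20 frames; both config-exposed since real
windowing conventions vary). The plug-in estimator
$4\,s^2/\bar x^2$ is biased low by $O(1/n)$ — a combination of ratio
bias and the lag-1 autocorrelation that the shared middle displacement
induces between consecutive $R_\tau^2$ values. The bias is not
negligible at practical window lengths (expectation ~1.90 instead of 2
at $n = 38$, ~1.66 at $n = 10$). Because the null distribution of the
raw estimator is scale-free, the correction depends only on $n$:
`normalized_variance()` multiplies by a factor $\kappa(n) = 2 /
E_\mathrm{null}[\hat V_\mathrm{raw}]$, tabulated once by high-precision
Monte Carlo under the free-diffusion null (the generator script ships in
`data-raw/`), interpolated linearly in $1/n$, and asymptotically
$1 + 2/n$. The calibrated estimator has expectation exactly 2 under
free diffusion for every window length and every $D$; for other regimes
the factor is a fixed convention that preserves all orderings.

### Histogram, populations, contour map

`segment_stats()` summarizes each window by $(\overline{R_\tau^2}, V,
D)$. `msd_histogram()` bins $\log_{10}\overline{R_\tau^2}$ (default 10
bins per decade, edges aligned to the decade grid so peak locations are
reproducible) and splits two populations either at the deepest valley
between the two highest modes or by a 1D two-component Gaussian mixture
on the log scale (`mclust`), flagging unimodal data as degenerate.
`contour_map()` builds a kernel density of $(\log_{10}
\overline{R_\tau^2}, \log_{10} V)$ with per-axis Scott bandwidths
($\sigma\,n^{-1/6}$), and `find_peaks()` scores local maxima by
topographic prominence (watershed union-find over grid cells sorted by
height) with sub-bin quadratic refinement. Repeated visits to one
environment concentrate density, so distinct diffusion states appear as
distinct peaks.

### Confinement events

`confinement_index()` implements the probability-of-staying index of the
Simson–Sheetz–Jacobson family: for each window of $W$ frames the maximal
excursion $R$ from the window start is converted to the probability
$\psi$ that free diffusion at a reference $D$ would stay within $R$,
via the standard log-linear approximation $\log_{10}\psi = 0.2048 -
2.5117\,D t/R^2$, and $L = \max(0, -\log_{10}\psi - 1)$. Each frame is
assigned the mean $L$ over the windows covering it;
`extract_confined_events()` turns threshold crossings into events
(defaults: window 30 frames, $L_c = 3.16$, minimum duration 10 frames,
gaps under 2 frames merged — conventional operating values, all
config-exposed). On a 50/50 mixture of free and strongly corralled
synthetic tracks at these defaults, both sensitivity and specificity
exceed 0.8 (asserted as a regression test). The reference $D$ defaults
to the fast-population mode converted through $D = R^2/4\tau$.

### Pair correlation

Co-moving receptor pairs are detected with the phasor statistic: writing
each centred position series as $\vec r_k(t) = A_k(t)e^{i\theta_k(t)}$,

$$C(\mathrm{lag}) = \mathrm{Re}\!\left[\frac{\sum_t \vec r_1^{\,*}(t)\cdot
\vec r_2(t+\mathrm{lag})}{\sqrt{\sum|\vec r_1|^2}\sqrt{\sum|\vec
r_2|^2}}\right]
= \frac{\sum_t A_1 A_2 \cos(\theta_2 - \theta_1)}{\sqrt{\sum
A_1^2}\sqrt{\sum A_2^2}},$$

so $|C| \le 1$, with $C = 1$ for identical motion, 0 for a 90°-rotated
copy, $-1$ for anti-phase motion. Windows with $C > 0.8$ count as
correlated (`extract_correlated_segments()`), and their
sub-trajectories can be routed back through `segment_stats()`.

Two conventions are deliberate design choices. First, positions are
centred on the **segment centroid** before correlating: on raw
laboratory coordinates the statistic is dominated by the static offset
from the arbitrary origin and approaches 1 for any two distant, immobile
molecules, which cannot be the intended meaning; centring makes $C$
measure co-movement. A `first_point` policy is retained for sensitivity
analysis. Second, the default lag is 0; the lag dependence is computable
but the 0.8 selection is applied at a single lag. For independent
40-frame free segments the null probability $P(C > 0.8)$ is below 1%
(Monte-Carlo property test), so the selection is stringent.

## The simulator

The generator produces trajectories with the statistical structure the
analysis assumes, in four regimes (all parameters in
`membrane_params()`, defaults documented there; length unit µm, energy
unit kT).

**Free**: exact Gaussian increments, variance $2D\tau$ per axis per
frame.

**Corral**: overdamped Langevin motion in a radial Gaussian ridge
$U(r) = H\exp(-(r-R_c)^2/2w^2)$ centred on the corral boundary. A smooth
ridge reproduces stall-and-hop phenomenology: the molecule pauses at the
wall, occasionally hops. Integration uses a stochastic Heun
(predictor–corrector) drift update; with the default 50 substeps per
frame, halving the integration step leaves ensemble step moments
statistically unchanged (explicit Euler at the same step fails this
check for kT-scale ridges, which is why Heun is used). Two physical
points deserve emphasis: (i) the Kramers escape time of a smooth ridge,
roughly $(R_c\,w/D)\,e^{H_\mathrm{eff}}$, is finite — for $H \approx 10$
kT at membrane scales it is of order $10^2$–$10^3$ s, so genuine escapes
within a 100 s observation are expected physics, and full containment
over 100 s is only asserted at substantially higher barriers; (ii) when
$w$ is not small against $R_c$ the ridge leaks into the corral interior
($U(0) = H e^{-R_c^2/2w^2}$), lowering the effective barrier.

**Domain (dressed protein)**: free diffusion inside a flat-bottomed disc
of radius $a$ around a domain centre that itself diffuses slowly;
outside the disc the excess radial excursion relaxes back elastically at
rate $\mathrm{cholesterol}/t_\mathrm{relax}$ (exact exponential update,
unconditionally stable). The flat bottom is essential: a purely elastic
(Ornstein–Uhlenbeck) tether is a Gaussian process, all of whose
displacements are Gaussian, so its squared steps are exponential-family
and give $V \ge 2$ — an elastic dressing alone *cannot* reproduce the
under-dispersed $V < 2$ signature (Monte Carlo: calibrated $V \approx
2.5$ for a stiff tether). Bounded, non-Gaussian confinement can: in the
frame-decorrelated limit the positions are uniform in the disc and the
population value is exactly $V = 4\cdot 3/8 = 3/2$ (closed form from the
moments of uniform-disc differences). Ensemble values around 1.6–1.7 at
the defaults reflect partial frame-to-frame correlation and the drifting
centre. Setting cholesterol to 0 (or $t_\mathrm{relax} \to \infty$)
switches the boundary off and recovers free diffusion continuously.

**Pair**: two molecules at $D$, coupled by a harmonic attraction of
stiffness $k_\mathrm{pair}\cdot\mathrm{cholesterol} + k_\mathrm{direct}$
acting on their separation, with the pair centroid dressed in a lipid
domain as above (stability also scaled by cholesterol). Higher
cholesterol tightens both the coupling and the shared domain, so the
fraction of windows with $C > 0.8$ is non-decreasing in cholesterol —
the qualitative behaviour expected if membrane cholesterol mediates the
receptor–receptor attraction. The extra `pair_direct_k` field models
direct dimerization that survives cholesterol depletion; combined with a
corral barrier it produces the over-dispersed ($V > 2$) signature of a
deterministic interaction in a cholesterol-poor membrane. Linear
relaxations use exact exponential updates.

**Localization noise** is added separately (`add_localization_noise()`)
as independent Gaussian error with per-axis SD $\sigma_\mathrm{loc}/
\sqrt 2$, so `sigma_loc` is the *radial* RMS error; a stated "40 nm
accuracy" is `sigma_loc = 0.04`. The axis convention matters (plausible
alternatives differ by $\times 2$ in the implied MSD floor) and is
therefore fixed explicitly: a stationary emitter then shows a mean
observed single-frame squared displacement of $2\sigma_\mathrm{loc}^2 =
0.0032\ \mu m^2$, consistent with an MSD determination accuracy of a few
$10^{-3}\ \mu m^2$.

**Cholesterol presets.** The drug treatments used in live-cell work are
mapped to the dimensionless stability scale as interpretive presets, not
fits: native = 1, nystatin (redistributed cholesterol) = 0.5,
methyl-β-cyclodextrin (depleted) = 0.1.

### Default parameters

No corral sizes, barrier heights or domain radii are published for the
cell systems this emulates; the defaults are order-of-magnitude choices
a membrane biophysicist would call representative, and all are exposed:
$D$ = 0.5 µm²/s, corral radius 0.25 µm with an 8 kT, 0.08 µm ridge,
domain radius 0.1 µm with a 1 ms boundary relaxation, domain-centre $D$
= 0.005 µm²/s, pair stiffness 1000 kT/µm². The `slow_domain` preset uses
a 0.2 µm confinement zone: at that size the boundary barely affects the
one-frame step, so the apparent single-frame MSD matches $4D\tau$ for
the apparent $D$ of the slow receptor group (0.12 µm²/s), which is how
that group is defined; smaller domains would push the one-frame MSD
below the defining value.

### What the generator does and does not emulate

It reproduces: coarse-grained sampling at a fixed frame period,
localization error, the four qualitative environments, and optional
rendering into 16-bit TIFF stacks (Gaussian PSF + Poisson noise) for
exercising the detection/linking front end. It does **not** emulate
quantum-dot blinking, intensity fluctuations, stage drift, heterogeneous
per-cell diffusivities, corral lattices (each track sees a single
corral), membrane topography, or ligand-binding kinetics. Passing tests
on synthetic data therefore validate the *statistical machinery* — the
estimators, their calibration and their discrimination power under the
stated models — not the biological conclusions one might draw from any
particular cell type.

## Tracking front end

`detect_spots()` finds 8-neighbourhood local maxima above a robust
background threshold (median + $k\times$MAD) and refines them by
intensity-weighted centroid; `link_nearest()` connects nearest positions
in consecutive frames by greedy mutual-nearest-neighbour assignment with
a hard distance gate and optional gap bridging. Distance ties resolve to
the lower track id, so linking is deterministic. This is deliberately
the simple described rule, not a full multiple-target tracing algorithm:
no intensity statistics, no merge/split handling, no blinking-robust gap
closing.

## Numerical and testing choices

* Problem sizes: statistical tests and the acceptance script use 500
  tracks x 400 frames per regime (9 500 windows), which puts Monte-Carlo
  standard errors on ensemble $V$ near 0.01 — small enough to resolve
  every regime contrast the package asserts.
* Determinism: every stochastic routine takes an explicit seed and is
  bit-reproducible; the pipeline writes byte-identical CSVs for
  identical config + seed.
* Degenerate inputs: constant $R_\tau^2$ gives $V = 0$; an all-identical
  segment cloud falls back to a minimum kernel bandwidth; zero-norm
  phasor segments and zero-mean $R_\tau^2$ raise informative errors
  rather than NaNs.
* The stage order (population split before or after confinement
  filtering) is not fixed by convention; the pipeline computes the
  split first and feeds the fast-population mode to the confinement
  stage as its reference $D$, but both stages are independently callable
  in either order.

## Known limitations

* The $\kappa(n)$ calibration is exact only under the free null; for
  strongly non-free windows the finite-window bias differs slightly, so
  regime $V$ values carry a small $O(1/n)$ convention dependence (the
  orderings are unaffected).
* Windowed $V$ values from overlapping windows of one track are
  correlated; tests therefore aggregate per track before computing
  confidence intervals.
* The confinement index uses the log-linear $\psi$ approximation, which
  saturates ($L = 0$) for free-like excursions by construction and is
  inaccurate for $Dt/R^2 \lesssim 0.1$; thresholded event extraction is
  insensitive to this region.
* Linking is greedy and gate-limited; it will fragment tracks in dense
  fields where a global assignment would not.
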