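---
title: "Mixture timing kernels in TOF-PET: simulation, reconstruction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture timing kernels in TOF-PET: simulation, reconstruction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tofmix)
```

## The problem

Time-of-flight (TOF) PET reconstruction conventionally assumes one
coincidence timing resolution for the whole scanner. BGO detectors that
exploit prompt Cherenkov photons break that assumption: the number of
detected Cherenkov photons fluctuates event by event, so the coincidence
time-difference distribution is not one Gaussian but a *family* of
double-Gaussian mixtures — a narrow "fast" component for Cherenkov-rich
events and a wide "slow" component for scintillation-only events, mixed
with an abundance weight $\alpha$. Events can be sorted into timing
categories (here: 25, from pairing 5 rise-time classes per detector), each
with its own mixture kernel.

`tofmix` provides, at desk scale, the full statistical pipeline for
studying such detectors:

1. a **kernel model**: evaluate, sample, and fit zero-mean two-component
   Gaussian mixtures, plus the packaged bank of 25 measured BGO-Cherenkov
   timing categories;
2. a **coincidence simulator**: back-to-back photon transport to a
   cylindrical ring scanner with the timing spread applied *per coincidence
   pair* (category drawn uniformly, component drawn by its abundance), and
   the applied kernel/component stored per event;
3. a **list-mode TOF-MLEM reconstruction** that can apply the mixture
   kernel, the exact decomposed component, a single Gaussian, or no TOF
   weighting;
4. the **NEMA-style metric suite** (CRC, background variability, CNR,
   half-diameter bias) used to compare the models.

## The kernel model

A timing kernel is
$$f(t) = \alpha\,\mathcal N(t; 0, \sigma_F^2) +
         (1-\alpha)\,\mathcal N(t; 0, \sigma_S^2),$$
with widths quoted as FWHM ($\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$).
Both components are **centered**: real rise-time sorting shifts the mean of
the measured distributions, but the package sets the simulated kernels to
zero mean and leaves time-walk correction out of scope, so reconstruction
and simulation share one convention.

The bank's "abundance ratio" column is interpreted as the **mixing weight
of the fast component** (the probability that a pair's spread is drawn from
the narrow Gaussian). The values near 0.5 and the way $\alpha$ multiplies
the fast-component CDF in the TOF weight make this the only consistent
reading of a quantity loosely described as a fast/slow ratio.

Fitting is by expectation-maximization with both means fixed at zero; free
parameters are $(\sigma_F, \sigma_S, \alpha)$. Initialization is a
method-of-moments split ($0.5\times$ and $2\times$ the sample SD, weight
0.5), convergence is declared when the log-likelihood improves by less than
$10^{-8}$ per sample (cap: 500 iterations), and the smaller-sigma component
is reported as "fast". The log-likelihood trace is nondecreasing (standard
EM guarantee) and is exposed for inspection. At $10^6$ samples per kernel
the refit sigmas land within about $\pm 0.8$ ps of the inputs, comfortably
inside the $\pm 2$ ps fidelity band the package's acceptance checks assert.

```{r fit-example}
bank <- default_kernel_bank()
set.seed(1)
x <- sample_delta_t(bank$kernels[[13]], 1e5)$delta_t_ps
fit_two_gaussian_mixture(x)$kernel
```

## The simulator

**Geometry.** Crystals are uniformly spaced in azimuth on a cylinder (no
blocks or gaps); detection is front-face: a photon is assigned the crystal
whose angular/axial bin contains its intersection with the detector
cylinder, with no depth-of-interaction modeling — the measured kernels
already embody the detector physics. The full-size model (666 crystals
$\times$ 48 rings of $4\times4\times20$ mm$^3$ at 424 mm radius) is
available as `full_ring_scanner()`; the default is the desk-scale 2D
system: one ring of 360 crystals at the same radius.

**2D mode.** Single-ring scanners are treated as 2D systems: emission
directions are drawn in-plane rather than isotropically. With a 4 mm axial
slab at 424 mm radius an isotropic simulation discards ~99.5% of decays;
the in-plane convention preserves the transaxial statistics of every
accepted event while keeping full studies in the minutes range. Multi-ring
scanners emit isotropically.

**Coincidence sorting.** A pair is kept when both photons land on crystals
and their circular crystal-index distance reaches the minimum sector
difference, which scales the full-size scanner's 83-sector rule as
$\mathrm{round}(83/666 \cdot n)$ (45 for the 360-crystal ring). Only true
coincidences are produced: no positron range, acollinearity, scatter,
randoms, energy blurring, dead time, or multiple coincidences. This is a
deliberate reading of the reconstruction-side study the package supports,
which uses true events only.

**Timing.** The geometric time difference is $(d_a - d_b)/c$ (positive when
detector $a$ is farther; $c = 0.2998$ mm/ps), and the measured difference
adds one zero-mean Gaussian draw of the selected kernel component — applied
at the *pair* level, equivalent in distribution to spreading both singles.
The applied category and component are stored per event, which is what
makes the decomposed reconstruction possible.

**Emission sampling.** Decay counts are Poisson with mean (total activity
$\times$ duration); 1 kBq/cc equals one decay per second per mm$^3$, so a
voxel's rate is its concentration times its volume. Positions are uniform
within the voxel.

**Attenuation** is off by default (the bundled studies compare
reconstructions of true events without an attenuation step, which is
self-consistent). When enabled, events survive with probability
$\exp(-\int \mu\, dl)$ along the full LOR — correct for collinear true
pairs — and the same factors enter the reconstruction's sensitivity and
forward model.

## The reconstruction

List-mode MLEM with the multiplicative update
$$\lambda_j \leftarrow \frac{\lambda_j}{s_j}
  \sum_i \frac{p_{ij} K_{ij}}{\sum_k p_{ik} K_{ik} \lambda_k},$$
where $p_{ij}$ is the Siddon intersection length of event $i$'s LOR with
voxel $j$ and $K_{ij}$ the TOF weight: the kernel mass falling in the 1-ps
TOF bin $[k_t, k_{t+1})$ that contains the event's measured time
difference, evaluated at the voxel center's signed TOF projection $v'$ on
the LOR,
$$K = \alpha\left[\mathrm{cdf}_F(k_{t+1}-v') - \mathrm{cdf}_F(k_t-v')\right]
 + (1-\alpha)\left[\mathrm{cdf}_S(k_{t+1}-v') - \mathrm{cdf}_S(k_t-v')\right].$$
The four TOF models differ only in which CDFs they use: the event's mixture
kernel, the single decomposed component actually applied during simulation,
one Gaussian, or (non-TOF) the constant 1. Summed over bins the weights
telescope to 1 for every voxel, which is why the sensitivity image
$s_j = \sum_{\text{pairs}} a_{ij} p_{ij}$ is TOF-independent and can be
shared across all models on one geometry.

Numerical choices:

* **TOF bin width** defaults to 1 ps; with 1-ps bins each (event, voxel)
  pair costs one CDF difference.
* **Row truncation**: voxels with $|v' - \Delta t| > 5\sigma_{\max}$ are
  dropped from TOF rows; the discarded kernel mass is below $3\cdot10^{-7}$.
* **Initial image**: 1 inside the sensitivity support, 0 outside; no
  post-filtering; plain MLEM (no subsets), so the Poisson list-mode
  log-likelihood is provably nondecreasing.
* Per-event system rows are constant across iterations, so they are
  precomputed once (single-precision values; the update itself runs in
  double precision — EM monotonicity holds for whatever nonnegative system
  matrix is used, so mixed precision does not break the guarantees).
* Events whose forward projection is zero are skipped and counted; after
  every update $\sum_j \lambda_j s_j$ equals the number of events used
  (relative error $<10^{-6}$ is asserted in the tests).

Calibration scales the image so the mean over a background mask equals the
known background concentration, following the convention of calibrating on
the final iteration and applying that one scale to the whole series.

## Phantoms and metrics

`nema_iq_phantom()` builds the standard image-quality layout: six spheres
(inner diameters 10/13/17/22/28/37 mm) on the 114.4 mm pitch circle in the
central plane, the four smallest hot at 4:1 against an 11.38 kBq/cc
background, the two largest water-filled and cold, every sphere wrapped in
a 1 mm cold wall, water attenuation everywhere. The body is a 110 mm
cylinder — a desk-scale choice so the phantom fits the default
$128 \times 128 \times 1$ grid of 2 mm voxels; concentrations and sphere
layout are standard. The lung insert is omitted.

ROIs are placed analytically from the phantom specification (never
estimated from the image), with voxel membership by center-in-circle,
matching the rasterizer's center-point convention. Per sphere: one ROI of
the sphere's diameter on the central slice, one half-diameter ROI for the
bias analysis, and 60 background ROIs. The background layout is a
deterministic polar lattice filtered to keep 15 mm clearance from the body
edge and no overlap with any sphere or wall, then thinned evenly to 60; a
fixed 12-angle-by-5-ring pattern does not fit the desk-scale body for the
largest ROI size, and with a single-slice grid there are no axial
replicates to use.

Figures of merit follow the standard definitions: hot
$\mathrm{CRC} = 100\,(\mu_H/\mu_B - 1)/(\text{ratio} - 1)$, cold
$\mathrm{CRC} = 100\,(1 - \mu_C/\mu_B)$,
$\mathrm{BV} = 100\,\mathrm{SD}(\text{bg ROI means})/\mathrm{mean}$
($N-1$ SDs), and
$\mathrm{CNR} = (\mu_H - \mu_B)/\sqrt{\sigma_H^2 + \sigma_B^2}$ with
$\sigma_B$ the average background-ROI SD. CNR is reported as `NA` on
noise-free images where both SDs vanish. Bias uses the half-diameter ROIs
across noise realizations, as percent deviation from the expected
concentration with the SE over realizations.

## The bundled studies

`run_kernel_fidelity_study()` simulates a point source at the isocenter
(geometric time difference identically zero), histograms the measured time
differences for one category, and refits every kernel of the bank from
`n_per_kernel` samples to tabulate sigma errors.

`run_nema_study()` executes the model matrix per noise realization:

| label | simulated timing | reconstruction kernel |
|---|---|---|
| `mch` | 25-kernel mixture bank | per-event mixture kernel |
| `ch-mix` | single mixture (bank row 1) | mixture kernel |
| `ch-dcmp` | *same dataset* as `ch-mix` | exact decomposed component |
| `gauss` | single Gaussian 213 ps | 213 ps Gaussian |
| `notof` | mixture-bank dataset | none |
| `mch-low` | `mch` thinned to the `gauss` count | per-event mixture kernel |

The identical-geometry simulator cannot reproduce the sensitivity advantage
of a denser crystal, so the study **emulates it as a count ratio**: the
single-Gaussian dataset is thinned to $1/1.52$ of the mixture dataset's
trues (the trues ratio of the two full-scale scanner models), and `mch-low`
is the count-matched control. This is an emulation of a physics effect, not
a physics result.

Desk-scale defaults: 2D ring, $128^2 \times 2$ mm grid, 0.25 s acquisitions
($\approx 2\times10^5$ trues per realization), 3 realizations, 40
iterations with metrics at the marker iterations 1-5, 10, 20, 40. A full
study runs in a few minutes on one core. The acceptance checks use 0.1-0.115 s
acquisitions ($0.9$-$1.05\times10^5$ trues) so the whole suite stays within
a test run's budget; these sizes are stated here as the package's own
desk-scale choices.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure of the study: Poisson
decays, geometric LOR formation with a sector cut, per-pair mixture timing
spreads with stored provenance, and count ratios between scanner models. It
does **not** model scatter, randoms, energy windows, positron range,
acollinearity, detector penetration, dead time, or 3D axial sampling.
Passing tests therefore demonstrate correctness of the kernels,
projector, TOF weighting, EM updates and metrics — and the *qualitative*
orderings between timing models (single-Gaussian kernels converge faster at
matched counts; more counts win on CNR) — but not the absolute full-scale
figures (printed CNR gains of 22.79-26.4%, $10^7$-scale coincidence counts,
absolute CRC/BV values at 150 iterations), which depend on full 3D
geometry and crystal physics.

## Known limitations

* Mixture fits assume exactly two zero-mean components; kernels with
  comparable component widths are weakly identifiable and the fitted
  $\alpha$ is then poorly determined (the overall FWHM remains correct).
* The 2D desk scale leaves axial effects (axial compression, oblique ray
  sampling) unexercised; the full 3D geometry is configurable but slow.
* The half-diameter bias ROIs still contain partial-volume effects for the
  10 mm sphere on the 2 mm default grid (5 voxels across).
* Calibration by the background mean ties absolute concentrations to the
  convergence of the background; early-iteration images inherit that scale
  by construction.
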