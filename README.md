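# tofmix

Desk-scale simulation and reconstruction toolkit for time-of-flight (TOF)
PET with **multiple mixture timing kernels**, written for researchers
studying BGO detectors that exploit prompt Cherenkov photons.

Conventional TOF reconstruction assumes one Gaussian timing resolution for
every event. Cherenkov-capable BGO detectors instead produce a *family* of
coincidence time-difference distributions: each event pair belongs to one
of several timing categories, and each category is a zero-mean
double-Gaussian mixture

    f(t) = alpha * N(t; 0, sigma_F^2) + (1 - alpha) * N(t; 0, sigma_S^2),

with a narrow "fast" (Cherenkov-rich) and a wide "slow"
(scintillation-only) component mixed with abundance `alpha`, widths quoted
as FWHM (= 2.3548 sigma). The package ships a bank of 25 such measured
timing categories (fast FWHM 179.8-263.8 ps, slow 660.3-897.3 ps).

What the package does:

* **kernels** — evaluate/sample mixture kernels; fit them back from data by
  zero-mean two-component EM; validate a whole bank (simulate-and-refit
  fidelity, ±2 ps at 10^6 events/kernel).
* **simulate** — list-mode true-coincidence generation on a cylindrical
  ring scanner from shape-based digital phantoms (NEMA-IQ layout included),
  with the timing spread applied per coincidence pair and the applied
  kernel/component stored per event.
* **recon** — list-mode TOF MLEM where the per-voxel TOF weight is the
  kernel mass in the 1-ps bin containing the measured time difference,

      K = alpha * (cdfF(k+1 - v') - cdfF(k - v'))
        + (1 - alpha) * (cdfS(k+1 - v') - cdfS(k - v')),

  with four kernel models: per-event mixture, exact decomposed component,
  single Gaussian, or non-TOF.
* **metrics** — NEMA-style contrast recovery (CRC), background variability
  (BV), CNR = (muH - muB)/sqrt(sdH^2 + sdB^2), and half-diameter bias
  across noise realizations.
* **experiments** — scripted kernel-fidelity and NEMA model-comparison
  studies (mixture vs decomposed vs single-Gaussian vs non-TOF, with
  count-matched controls).

## Worked example

Simulate a 2D NEMA acquisition with the 25-kernel mixture timing model,
reconstruct 20 MLEM iterations with the matching mixture kernels, calibrate
to kBq/cc, and tabulate the NEMA figures of merit:

```r
library(tofmix)

scanner <- ring_scanner()                      # 360 crystals, 424 mm, 2D
grid    <- voxel_grid(128, 128, 1, c(2, 2, 2))
phantom <- nema_iq_phantom()                   # 11.38 kBq/cc, 4:1 hot ratio

cfg <- acquisition_config(phantom, scanner, grid, duration_s = 0.12,
                          timing_model = "mixture_bank", seed = 7)
lm  <- simulate_acquisition(cfg)               # ~1.0e5 true coincidences

sens <- sensitivity_image(scanner, grid)
res  <- lm_mlem(lm, recon_config(grid, 20, recon_model("mixture")),
                sensitivity = sens)

img  <- calibrate(res$image, nema_background_mask(phantom, grid), 11.38)
rois <- place_rois(phantom, grid)
sphere_metrics(img, rois)[, c("sphere", "diameter_mm", "hot", "mu_roi",
                              "crc_pct", "bv_pct", "cnr")]
```

```
  sphere diameter_mm   hot    mu_roi  crc_pct    bv_pct       cnr
1      1          10  TRUE 30.221770 57.10973 17.025617  1.062411
2      2          13  TRUE 36.857092 74.07032 14.576354  1.442642
3      3          17  TRUE 39.768054 81.47200  9.060699  1.615122
4      4          22  TRUE 39.559280 82.63492  6.770119  1.440157
5      5          28 FALSE  1.606235 85.89032  5.107642 -1.348118
6      6          37 FALSE  1.968121 82.82650  3.851290 -1.303345
```

Reading the table: after 20 iterations the hot spheres (true concentration
45.52 kBq/cc) recover 57-83% of their contrast — recovery rises with sphere
size, while the background variability (noise surrogate) falls; the two
cold spheres read near zero against the 11.38 kBq/cc background. The CNR
column is the per-sphere contrast-to-noise ratio (negative for cold
spheres).

Per-event provenance makes the *decomposed* reconstruction possible — using
for each event the exact Gaussian component the simulator applied:

```r
lm_ch <- simulate_acquisition(acquisition_config(
  phantom, scanner, grid, duration_s = 0.12,
  timing_model = "single_mixture", seed = 8))
res_mix  <- lm_mlem(lm_ch, recon_config(grid, 20, recon_model("mixture")),
                    sensitivity = sens)
res_dcmp <- lm_mlem(lm_ch, recon_config(grid, 20, recon_model("decomposed")),
                    sensitivity = sens)
```

`run_nema_study()` wires the full model matrix (mixture, decomposed,
single-Gaussian with count matching, non-TOF) across noise realizations and
returns CRC/BV/CNR tables with standard errors; `run_kernel_fidelity_study()`
reproduces the simulate-and-refit fidelity check for all 25 kernels. A thin
command-line wrapper for shell pipelines is installed at
`system.file("cli", "tofmix", package = "tofmix")` (subcommands `simulate`,
`reconstruct`, `fidelity`, `analyze`; list-mode files are versioned
delimited text, images are NIfTI).

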