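# dtcmr

Simulation-driven analysis pipeline for **diffusion tensor cardiovascular
magnetic resonance (DT-CMR)** of the left ventricle, written for
methods-development work comparing stimulated-echo (STEAM) and
second-order motion-compensated spin-echo (M2-SE) acquisitions across
cardiac phases. Every stage of a DT-CMR analysis — from raw
diffusion-weighted frames to group statistics — is implemented against a
synthetic short-axis phantom with known microstructural ground truth, so
the whole chain is verifiable without scanner data.

## What it does

* **Phantom generation** — a short-axis LV ring with a linear transmural
  helix-angle (HA) variation (default +60° endocardium → −60°
  epicardium), a prescribed per-phase sheetlet angle (E2A), prescribed
  eigenvalues, a hyperintense blood pool, Rician noise and beat-to-beat
  RR-interval jitter; acquisitions follow the two study protocols
  (STEAM: TR = 2 RR, b = 150/450 s·mm⁻² in 6 directions, 8 averages;
  M2-SE: TR = 1 RR, 16 averages, TE = 76 ms). Forward model per frame:
  `S = S0 · exp(−b gᵀDg)`.
* **Preprocessing and tensor fit** — intensity-based blood-pixel nulling
  with exact restoration, rigid-translation registration (normalized
  cross-correlation, subpixel refinement), correlation-based frame
  rejection, beat-to-beat b-value correction for STEAM
  (`b′ = b (RR − δ/3)/(RR₀ − δ/3)`), and a pixelwise log-linear
  least-squares tensor inversion using every frame separately.
* **Cardiac-coordinate maps** — MD, FA, tensor mode, eigenvalues, helix
  angle, transverse angle and the absolute second-eigenvector (sheetlet)
  angle E2A, all defined against per-pixel radial/circumferential/
  longitudinal directions.
* **Quality statistics** — transmural HA profiles and the
  wall-thickness-normalised helix-angle gradient (HAG, °/%), HA R² and
  RMSE, transverse-angle SD, an automated HA-map scoring rubric
  (3: >95 % normal spokes, 2: >75 %, 1: ≥50 %, 0: failure), and
  repeated-measurement SNR per image.
* **Sequence theory** — the closed-form spin-echo/stimulated-echo SNR
  ratio

  `SNR_SE / SNR_STEAM = [(1 − e^(−Trecov_SE/T1)) e^(−TE_SE/T2) e^(−b_SE·D)] /
  [½ (1 − e^(−Trecov_STEAM/T1)) e^(−TE_STEAM/T2) e^(−b_STEAM·D) e^(−TM/T1)]`,

  root-mean-square diffusion distances `√(2DΔ)`, and breath-hold
  scheduling arithmetic.
* **Gradient design** — exact piecewise moments `Mₙ = ∫G(t)tⁿdt` and
  b-values `b = γ²∫q(t)²dt` of piecewise-linear waveforms with
  refocusing-pulse polarity handling, plus design of velocity- and
  acceleration-compensated (M₀ = M₁ = M₂ = 0) paired-lobe waveforms under
  amplitude/slew limits.
* **Strain and statistics** — Green–Lagrange strain curves from
  displacement-field series, an analytic contracting-ring displacement
  generator, paired Wilcoxon / Friedman-with-Bonferroni / Pearson and
  Spearman group statistics, and an end-to-end cohort driver.

## Worked example

```r
library(dtcmr)

spec   <- lv_phantom_spec(sigma = 2)               # noisy phantom
field  <- build_tensor_field(spec, "systole")      # ground-truth tensors
series <- simulate_dwis(field, steam_protocol(), seed = 7,
                        spec = spec, phase = "systole")
res    <- process_series(series, max_shift = 4)    # full pipeline
round(as.data.frame(res$summary)[, c("md","fa","e2a","hag","ha_r2",
                                     "ta_std","score")], 4)
#>      md     fa     e2a    hag  ha_r2 ta_std score
#>  0.0011 0.4239 58.7522 1.2036 0.9981 4.7046     3
```

MD is recovered near the prescribed mean eigenvalue (1.07 × 10⁻³
mm²·s⁻¹), E2A near the prescribed systolic 60°, the transmural HA
gradient at 1.2 °/% (±60° across the wall), and the HA map scores 3
(>95 % of spokes with a clean linear transmural profile). Other stages:

```r
w <- design_m2_waveform(450, gmax = 43, slew = 180)
attr(w, "design")[c("d1", "d2", "total_ms", "b")]
#> lobes 10.5 / 21.6 ms, total 72.1 ms, b = 450.0 s/mm^2

sc <- strain_from_displacements(simulate_displacements(spec, 0.50, -0.177))
c(sc$peak_radial, sc$peak_circ)
#> 0.498 -0.177

theoretical_snr_ratio(t1 = 1090, t2 = 51, d = 1.2e-3,
                      trecov_se = 1000, trecov_steam = 1000, tm = 1000,
                      te_se = 76, te_steam = 25, b_se = 30, b_steam = 34)
#> 1.850
```

The cohort driver reproduces the whole study design (subjects × 2
sequences × 3 phases) and its statistics:

```r
res <- run_study(experiment_config(n_subjects = 15, seed = 1))
# or from a shell:
#   Rscript inst/scripts/run_study.R --subjects 15 --seed 1 --out study_out
```

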