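# pcdmd — material decomposition for three-bin photon-counting CT

Photon-counting CT detectors record, in one scan, separate images for
several photon-energy bins (here 30–50, 50–65 and 65–140 keV). Because
materials attenuate X-rays with different energy dependence — iodine's
K-edge at 33.2 keV makes its bin-1 attenuation jump — the three bin images
determine, per pixel, a mixture of basis materials. `pcdmd` is a
self-contained R workbench for this decomposition into water, calcium and
iodine. It is aimed at researchers who want to study the *method* —
simulation-to-real calibration, deep-learning decomposition, transfer
learning, and classical baselines — on fully synthetic, reproducible data,
without access to scanner hardware.

The package contains:

* a physics-based scan simulator: Kramers spectrum hardened to a target
  half-value layer, NIST-style attenuation tables with the iodine K-edge,
  analytic disk projections, Poisson noise, filtered back-projection
  (parallel and fan geometry);
* digital multi-energy phantoms with exact material label maps, including
  the concentration sets of a Gammex-style calibration phantom
  (real: Ca 100/300, I 2/5/10/15 mg/mL; simulated augmentation to 8 Ca and
  9 I levels);
* an empirical sim-to-real LAC calibration,
  `LAC_real = a·exp(−b·LAC_sim) + c`, fitted per energy bin by nonlinear
  least squares on insert-ROI pairs;
* **MD-Unet**: a 3D encoder–decoder over the bin-stacked volume (spatial
  pooling only, so the 3-bin axis survives to a bin-collapsing softmax
  head; weighted skip connections on the first two scales; 29 hidden
  layers, 1024 channels at the deepest scale), trained with a customized
  loss `FL + λ·MGE` — background-weighted focal loss (γ = 2) plus a
  Sobel-based mean gradient error (λ = 0.01) — under a two-phase transfer
  protocol (pre-train on calibrated simulations; fine-tune on real-domain
  scans with encoder scale 1 frozen). Network, backprop and Adam are
  implemented in base R on BLAS matrix products;
* classical baselines: per-pixel least squares (`md_ls`) and
  TV-regularized (`md_tv`) image-domain decomposition on the fluence-
  weighted per-bin basis matrix;
* the evaluation suite: CNR = |ROI − background| / SD(background), mean
  IoU, mean Dice and the pooled R² score, with JSON/CSV reports.

## Worked example

```r
library(pcdmd)

spectrum <- build_spectrum(kvp = 140, hvl_target = 5)   # HVL-matched beam
basis    <- basis_matrix(spectrum)                      # bins x materials
round(basis, 5)
#>        water calcium  iodine
#> bin1 0.28902 0.00222 0.01871
#> bin2 0.21331 0.00078 0.00914
#> bin3 0.18107 0.00035 0.00334
```

The water column is the effective water LAC per bin (1/cm); solute columns
are per mg/mL. Iodine's bin-1 entry is 5.6× its bin-3 entry — the K-edge
signature the decomposition exploits.

```r
# scan the Gammex-layout phantom (2 Ca + 4 I inserts) and decompose it
phantom <- calibration_phantom(n_pixels = 64, insert_radius = 22)
scan    <- simulate_scan(phantom, spectrum,
                         geometry = ct_geometry("parallel", n_views = 60,
                                                detector_bins = 64),
                         flux = 1e6, rng_seed = 1)
maps    <- md_ls(scan$image, basis)
miou(to_categorical(maps), scan$labels)
#> [1] 0.3854815
```

Least squares collapses on the reconstructed images — beam hardening plus
the near-collinear Ca/I columns push calcium into the iodine channel. The
learned pipeline closes that gap; `transfer_benchmark()` runs the whole
protocol (simulate, calibrate, pre-train, fine-tune with scale 1 frozen,
score a held-out scan) for one seed:

```r
transfer_benchmark(seed = 1)
#>   seed miou_transfer miou_scratch   miou_ls frozen_identical
#> 1    1     0.9230461           NA 0.2500766             TRUE
```

Held-out mean IoU ~0.92 for the transferred network versus ~0.25 for
MD-LS. `run_experiment(experiment_config("desk", seed = 1))` drives the
same pipeline and additionally evaluates MD-TV and a plain-Unet arm
(cross-entropy only, no transfer), returning a full metrics report.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the desk-scale end-to-end experiment from scratch against the
installed package — phantom simulation, per-bin calibration fitting,
two-phase training, decomposition by all methods, metric report (printed to
stdout) — and writes the acceptance JSON to `--out`.

## Layout

```
R/                  spectral model, phantoms, CT simulator, calibration,
                    network + losses, trainer, baselines, metrics, driver
inst/extdata/       mass attenuation tables (CSV)
inst/cli/           thin command-line wrapper over the same functions
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
scripts/            acceptance.R
```
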