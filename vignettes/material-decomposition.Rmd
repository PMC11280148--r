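---
title: "Methods: three-bin photon-counting CT material decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-bin photon-counting CT material decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A photon-counting CT detector sorts every detected photon into a
threshold-defined energy bin, so one axial scan yields several co-registered
reconstructions — here three, for 30–50, 50–65 and 65–140 keV. Because
linear attenuation coefficients (LACs) of different materials vary
differently with energy (iodine in particular jumps at its 33.2 keV K-edge,
inside bin 1), the three bin images over-determine a per-pixel mixture of
basis materials. `pcdmd` implements, end to end and on synthetic data it
generates itself, a deep-learning material decomposition of water, calcium
and iodine from such three-bin images, together with the classical
least-squares (`md_ls()`) and total-variation-regularized (`md_tv()`)
image-domain decompositions it is compared against, and the evaluation
metrics (CNR, mean IoU, mean Dice, pooled R²).

# The simulator: the package's stated world

**Spectrum.** `build_spectrum()` uses Kramers bremsstrahlung — photon
fluence ∝ (kVp − E)/E on a 1-keV grid — filtered by an aluminum slab whose
thickness is solved by bisection so that the beam's half-value layer (HVL)
equals a requested value, to 1e-6 relative; the default is 5.0 mm Al at
140 kV. The HVL is the one beam-quality number a bench physicist would
measure on the system, which is why the spectrum model is parameterized by
it; the true tube filtration of any particular scanner is unknown, so the
default is a documented, configurable guess. (An intensity-weighted Kramers
form E·(kVp−E) was rejected: its unfiltered HVL at 140 kV already exceeds
8 mm Al, which would make a measured 5 mm HVL unreachable by added
filtration.)

**Attenuation.** Mass attenuation tables for water, calcium, iodine and
aluminum ship as CSV under `inst/extdata` (approximate transcriptions of
standard reference values; the iodine K-edge is carried as a genuine
discontinuity at 33.2 keV). Interpolation is log–log and never bridges the
edge. Solutes follow a dilute additive rule,
μ(E) = μ_water(E) + (μ/ρ)_solute(E)·c/1000 with c in mg/mL — water
displacement is neglected, the usual phantom-insert convention.

**Scan.** `forward_project()` computes line integrals analytically from
disk chord lengths (phantoms are disks, so projections are exact to
rounding — this gives the suite a 1e-9 chord-law oracle free of
rasterization error), attenuates the in-bin spectrum ray by ray, applies
Poisson counting noise at a configurable per-ray flux, clamps starved rays
at one count, and log-transforms. `fbp_reconstruct()` is standard filtered
back-projection (spatial-domain Ram-Lak kernel, optional Hann apodization,
linear-interpolation backprojection) in parallel-beam geometry by default;
the prototype-style fan geometry (source–isocenter 227.5 mm, 1440 views,
48 × 80 = 3840 detector pixels) is available via
`full_protocol_geometry()` and a flat-detector weighted FBP. Parallel beam
is the desk default because every quantitative oracle has a clean analytic
form there; both reconstructions recover a monochromatic water disk to
better than 0.1 %.

**Desk flux.** The desk preset uses 10⁶ photons per ray (summed over bins).
At 64-pixel desk scale a detector element is ~3.9 mm wide — hundreds of
times the area of a real photon-counting pixel — so a proportionally larger
per-ray count is the physically consistent choice, and it keeps Poisson
noise from dominating the much coarser desk voxels.

**The real-domain emulator.** No prototype-scanner data are publicly
available, so `emulate_real_domain()` manufactures a controlled
simulation-to-real gap: a pointwise saturating nonlinearity of the same
exponential family the calibration fits (defaults a = −0.9, b = 1.1,
c = 0.9: monotone increasing, zero at zero LAC, mild compression at high
LAC), additive Gaussian noise (default 0.01 cm⁻¹), and an optional ring
gain. The emulator's role is to make calibration and transfer learning
*testable*: the calibration round-trip recovers the emulator's true
parameters, and a network pre-trained on raw simulation measurably degrades
on emulated-real images unless the calibration and fine-tuning stages are
used. What a green benchmark does **not** establish is performance on real
scanner data — detector spectral distortions, scatter, pulse pileup and
charge sharing are all outside the emulator.

# Calibration

`fit_lac_curve()` fits LAC_real = a·e^(−b·LAC_sim) + c to insert-ROI pairs
by iterative nonlinear least squares (multi-start over the decay rate with
the linear parameters profiled out, then quasi-Newton polishing with
analytic gradients to gradient norm < 1e-10 or 500 iterations). A
4-parameter logistic variant is provided as well — both families describe a
saturating monotone correspondence and fit bench data comparably; the
exponential is the default and the choice is recorded in the fit metadata. The logistic family has an exact sign symmetry
(a, b, c, d) ~ (−a, −b, c, a+d); fits are canonicalized to b ≥ 0.
Calibration is fitted per energy bin (LAC scales differ by bin) on ROI
pairs and then applied pixelwise to every simulated training image before
pre-training.

# The network

`build_network()` constructs a 3D encoder–decoder over the bin-stacked
volume: five scales by default, two 3×3×3 convolutions per block (each
followed by 3D batch normalization and ReLU), 64 channels at the first
scale doubling to 1024 at the deepest. Pooling is **spatial-only** (1×2×2):
the three-bin depth axis is the carrier of all spectral information and is
never collapsed until the output head, which spans the full bin depth with
a 1×1 spatial kernel, projects to the four classes (background, water,
calcium, iodine) and applies a per-pixel softmax. Skip connections exist at
every scale; on scales 1–2 they pass through learnable scalar gates
initialized at 1.0 — the minimal realization of a "weighted" skip, and
toggleable. Under the documented layer-counting convention (convolutions +
poolings + up-convolutions + gates + output projection; batch norms bound
to their convolutions) the default network audits to 29 hidden layers.

The loss is FL + λ·MGE: a focal loss
−w_i·(1−p)^γ·t·log p (γ = 2; w_i = w_b for background, 1 otherwise;
probabilities clamped at 1e-7) plus λ = 0.01 times a mean gradient error
that compares Sobel gradient-magnitude-squared fields of prediction and
truth per class (reflect boundary). w_b is not specified by the source
method; the default 0.25 simply down-weights the dominant background class
and is logged in every result. With γ = 0, w_b = 1, λ = 0 the loss is
exactly mean cross-entropy, which is also how the plain-Unet comparison arm
is trained. There is no canonical value for w_b; it is exposed in the
configuration and recorded in every result log.

Everything — forward, backward, Adam — is implemented in base R on BLAS
matrix multiplies (im2col convolutions), because no deep-learning framework
is available to the package; the full backward pass verifies against
finite differences to ~1e-8 relative.

# Transfer learning

Training is two-phase with batch size 1 and Adam: pre-train every parameter
on calibrated simulated phantoms (diverse random inserts; augmented with
flips, 0–360° rotations, and elastic deformation from a smoothed 8×8
displacement grid capped at 8 px), then fine-tune on real-emulated scans of
the fixed multi-energy phantom with **encoder scale 1 frozen** —
convolutions, batch-norm parameters and running statistics alike — and
elastic deformation disabled (real data carry artifacts; only flips and
rotations are applied). Fine-tuning and validation use repeated scans of
the same phantom layout deliberately: that mirrors how a physical
multi-energy phantom is actually used, and it guarantees every material
class is present in the held-out scan, so the mean-IoU score degrades
smoothly with boundary errors instead of cliff-dropping when a stray pixel
invents an absent class.

The full protocol (50/100 epochs, 87/16 images, learning rate 1e-5,
256-pixel grids, 5-scale/64-channel network) is preserved as the documented
`full` preset of `experiment_config()`. The `desk` preset scales every knob
to minutes on one CPU: 64-pixel grids, 60 views, a 3-scale/8-channel
network, 30/8 images, 10/20 epochs — and learning rate 1e-3, because a
~100-step budget at 1e-5 cannot move any network measurably; the learning
rate is scaled with the budget, once, as part of the desk world.
At this scale the seeded benchmark (`transfer_benchmark()`, seeds 1–3)
reaches a median held-out mean-IoU of ~0.94 versus ~0.25 for per-pixel
least squares — the qualitative ordering the method claims — while training
from scratch only falls behind transfer when real data and fine-tuning
budget are scarce, which is exactly the regime transfer learning is for
(with a generous fine-tuning budget on the fixed phantom, a from-scratch
network can match or beat the transferred one by overfitting the layout).

# Baselines and categorical maps

`md_ls()` solves the per-pixel normal equations for the bins × materials
basis matrix of fluence-weighted effective LACs (`basis_matrix()`), and
clamps negative concentrations with a recorded mask. `md_tv()` adds an
isotropic total-variation penalty per material map and minimizes by
monotone accelerated proximal gradient iterations (fixed step 1/L from the
basis spectral norm, Chambolle projection for the TV proximal operator,
momentum restarts on any objective increase, warm start at the unclamped
least-squares solution so the β = 0 limit is the exact fixed point).
Internally the basis columns are rescaled to unit norm, with the TV weights
adjusted so the stated objective is unchanged — the water and solute
columns differ by two orders of magnitude.

`to_categorical()` turns concentration maps into class labels: background
where everything is below threshold; otherwise solutes *detected* against
concentration thresholds (defaults Ca 50, I 1 mg/mL) compete by
reference-normalized score, and water is the in-object fallback. Water is
not an argmax competitor because its volume fraction is ≈1 everywhere
inside an aqueous object. A practical warning from the package's own
experiments: through FBP, beam hardening plus the near-collinear calcium
and iodine basis columns (≈12° apart after normalization) systematically
push least-squares calcium into the iodine channel — image-domain MD-LS
scores a mean IoU of ~0.25 on the noisy phantom benchmark no matter the
thresholds. That failure is real, expected, and the reason learned
decomposition helps; the exactness of the chain itself is established on
`effective_bin_image()` data, where the linear model holds by construction
and the chain returns the ground-truth labels.

# Metrics

`cnr()` is |ROI mean − background mean| / background SD with the
population (denominator-n) SD. `miou()`/`mdsc()` average per-class IoU and
Dice over the four classes, counting a class absent from both maps as 1
(convention logged in every report) — so a water-only phantom is not
penalized for containing no iodine; per class DSC = 2·IoU/(1+IoU) exactly.
`r2_score()` pools squared errors over all material channels and pixels; it
is computed on one-hot maps when no continuous ground truth exists, and the
report flags an undefined CNR (zero background spread, as on exact one-hot
maps) as NA rather than failing.

# Numerical and design notes

* All randomness flows through R's RNG from explicit seeds; training runs,
  scans and sampled phantoms are bit-reproducible per seed.
* Pixel membership in phantoms is by center point: labels are unambiguous
  one-hot maps, and partial volume enters only through the physics
  (projection + FBP), never the ground truth.
* Image grids are row-major with the physical origin at isocenter and y
  increasing downward; the same convention drives rasterization,
  projection, backprojection and ROI masks, so all stages are co-registered
  by construction.
* The photon-starvation clamp (1 count) is standard practice and logged as
  a warning with the affected ray count.
* Images persist as plain-text CSV slices with a JSON metadata sidecar —
  no binary imaging format is assumed to exist in the environment.
* Known limitations: no detector energy-response model (pileup, charge
  sharing), no scatter, no helical acquisition, no anthropomorphic
  phantoms; thin or protruding structures are outside the generator's
  vocabulary, so nothing here validates performance on such shapes.
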