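---
title: "Models and methods: ex vivo hippocampal diffusion MRI with hdmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ex vivo hippocampal diffusion MRI with hdmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmri)
```

`hdmri` implements an analysis pipeline for ultra-high-field ex vivo
diffusion MRI of the human hippocampus: acquisition calibration, T2
relaxometry and inter-shell compensation, local reconstruction (DTI and
analytical Q-ball), a four-compartment NODDI variant adapted to fixed
tissue, streamline tractography, and subfield connectomics — together with
a synthetic digital phantom that exercises every stage. This vignette is
the package's account of the underlying models, the numerical choices, and
what the test suite does and does not establish.

## Acquisition calibration

A pulsed-gradient spin-echo (PGSE) measurement attenuates signal by two
factors, the transverse-relaxation decay $e^{-\mathrm{TE}/T_2}$ and the
diffusion decay $e^{-bD}$. Under the rectangular-pulse approximation the
diffusion sensitization is

$$ b = (\gamma G \delta)^2 (\Delta - \delta/3) = q^2 \tau, $$

with $\gamma$ the water-proton gyromagnetic ratio (default
$2.6752218744\times 10^8\,\mathrm{rad\,s^{-1}T^{-1}}$), $G$ the gradient
amplitude, $\delta$ the pulse width, and $\Delta$ the pulse separation.
`compute_b()` evaluates this; `invert_b()` solves it for $G$.

Protocol design caps the total attenuation at a floor (default 0.05) split
equally between the two decays: each factor must stay at or above
$\sqrt{0.05}$, giving

$$ \mathrm{TE}_{\max} = -T_2 \ln\sqrt{0.05}, \qquad
   b_{\max} = -\ln\sqrt{0.05}/D. $$

For fixed grey matter at room temperature ($T_2 \approx 46$ ms,
$D \approx 0.16\times10^{-3}\,\mathrm{mm^2/s}$) this yields
$\mathrm{TE}_{\max} \approx 69$ ms and $b_{\max} \approx 9361$ s/mm².
Reporting conventions (`report_te_max()`, `report_b_max()`): TE rounded to
the nearest ms, b floored to an integer. Only the rectangular-pulse form
is implemented; no trapezoid/ramp correction is attempted, so gradient
amplitudes of sequence-specific (effective-gradient) protocols are not
reproduced.

```{r calibration}
report_te_max(46)
report_b_max(0.16e-3)
```

## T2 relaxometry and inter-shell compensation

Fixed tissue has short T2, and a multi-shell ex vivo protocol run at each
shell's minimum echo time carries a shell-dependent T2 weighting.
`fit_t2_map()` fits $S_0 e^{-\mathrm{TE}/T_2}$ per voxel: a log-linear
least-squares pass (nonpositive samples excluded, not clamped — the log is
undefined and exclusion is unbiased at high SNR) initialises a damped
Gauss–Newton (Levenberg–Marquardt) refinement, vectorised across voxels.
A voxel is flagged invalid — never silently zeroed — when fewer than two
usable echoes remain or when the fitted decay over the echo range is below
1% (a constant series has unbounded T2).

`histogram_modes()` locates the main modes of a T2 (or any scalar) map via
a Gaussian-kernel density estimate with Silverman's rule-of-thumb
bandwidth on a 512-point grid; modes are strict local maxima, returned in
ascending order. In fixed brain tissue two modes are expected — a
white-matter mode near 36 ms and a grey-matter mode near 46 ms — and the
phantom uses exactly those values as its ground truth.

`compensate_t2()` multiplies a shell's volumes voxelwise by
$e^{\Delta\mathrm{TE}/T_2(v)}$, referencing every shell to the lowest-TE
shell. On the noiseless phantom this inverts the simulated TE weighting to
better than $10^{-3}$ relative; on noisy data it rescales noise by the same
factor, so per-shell SNR (relative to the shell's own b0) is unchanged.

## Local models

**DTI.** `fit_dti()` uses weighted linear least squares on the log signal
with one reweighting pass (weights = squared predicted signal). Negative
eigenvalues are clamped to zero and counted. `tensor_metrics()` derives
MD = trace/3, the standard invariant FA, and the colour-encoded direction
map (|principal eigenvector| × FA, x→red, y→green, z→blue).

**Analytical Q-ball.** `fit_aqbi()` expands the b0-normalised single-shell
signal in a real, even-degree, symmetric spherical-harmonics basis
(degrees 0–8 by default, 45 coefficients; coefficients ordered by
ascending degree $l$, then order $m=-l..l$), solves the
Laplace–Beltrami-regularised least squares
$(B^\top B + \lambda L^2)^{-1}B^\top s$ with $L = \mathrm{diag}(l(l+1))$
and $\lambda = 0.006$, and applies the Funk–Radon transform analytically
per degree: ODF coefficients $c'_{lm} = 2\pi P_l(0)\, c_{lm}$. The ODF is
scaled so its degree-0 term corresponds to unit integral over the sphere.
The original (non-solid-angle) analytical Q-ball is implemented; min-max
normalisation is not applied to analysis outputs.

**Peaks.** `extract_peaks()` evaluates the ODF on an icosahedral
tessellation (subdivision 4; 1281 antipodal vertex pairs, ~3.6° spacing),
takes strict local maxima over the neighbour graph, merges antipodes,
drops peaks below half the voxel maximum, and greedily enforces a 25°
minimum separation (≤ 3 peaks). A constant ODF has no strict local
maximum and returns zero peaks by decision.

**Angular resolution.** The crossing tests deserve a note on regimes. With
the tissue diffusivity of fixed grey matter ($0.16\times10^{-3}$ mm²/s),
$b = 4500$ s/mm² gives $bD \approx 0.7$ — the angular contrast of an
in vivo scan at $b \approx 1000$. Order-8 Funk–Radon ODFs resolve
orthogonal crossings in that regime but merge 60° crossings into a single
lobe; that is physics of the transform, not an implementation limit. The
synthetic crossing oracle therefore uses the field's canonical stick
diffusivity $1.7\times10^{-3}$ mm²/s ($bD \approx 7.7$), where both 90°
and 60° crossings must (and do) resolve within 10°, and additionally
checks the 90° case at the ex vivo diffusivity.

## Four-compartment ex vivo NODDI

The diffusion attenuation of a voxel is a mixture of four non-exchanging
compartments,

$$ A = f_{ic}A_{ic} + f_{ec}A_{ec} + f_{iso}A_{iso} + f_{stat}A_{stat}, $$

with the nested parametrisation
$f_{stat} = (1-f_{iso})f'_{stat}$,
$f_{ic} = (1-f_{iso})(1-f'_{stat})f^{*}_{ic}$,
$f_{ec} = (1-f_{iso})(1-f'_{stat})(1-f^{*}_{ic})$, so closure
$f_{ic}+f_{ec}+f_{stat}+f_{iso}=1$ holds identically (to $10^{-12}$ in
floating point).

* $A_{ic}$: Watson-dispersed sticks (zero-radius cylinders),
  $A_{ic} = \langle e^{-b d_\parallel (g^\top u)^2}\rangle_{u\sim
  \mathrm{Watson}(\mu,\kappa)}$. Dispersion is reported as
  ODI $= (2/\pi)\arctan(1/\kappa)$.
* $A_{ec}$: Gaussian anisotropic tensor, the Watson orientation average of
  an axially symmetric tensor with $d_\parallel$ and tortuosity
  $d_\perp = d_\parallel(1-f^{*}_{ic})$; with
  $\tau_1 = \langle(\mu^\top u)^2\rangle$ this gives the closed form
  $g^\top\langle D\rangle g = d_\perp + (d_\parallel-d_\perp)
  [\tfrac{1-\tau_1}{2} + \tfrac{3\tau_1-1}{2}(g^\top\mu)^2]$.
* $A_{iso}$: free water, $e^{-b d_{iso}}$.
* $A_{stat}$: water trapped in fixed glial cells, modelled as zero-radius
  spheres — unattenuated at every b, $A_{stat}=1$. This "stationary"
  compartment is the ex vivo extension of the standard three-compartment
  model.

Diffusivities are fixed, not fitted: $d_\parallel = d_{iso,\,tissue} =
0.16\times10^{-3}$ mm²/s (the grey-matter mean diffusivity of fixed tissue
at 20 °C) and $d_{iso} = 2.0\times10^{-3}$ mm²/s (free water at 20 °C).
The kernels are evaluated as functions of b only — diffusion-time
independence is assumed even though the three shells vary $\Delta$.

**Watson integrals.** The stick average is computed exactly up to
quadrature: the spherical integral of $e^{u^\top Q u}$ with
$Q = \kappa\mu\mu^\top - b d_\parallel g g^\top$ reduces, in the
eigenframe of $Q$, to a single polar integral with a modified-Bessel
azimuthal factor,
$I = 2\pi\int_{-1}^{1} e^{\lambda_3 t^2 + (1-t^2)(\lambda_1+\lambda_2)/2}
I_0\!\big((1-t^2)(\lambda_1-\lambda_2)/2\big)\,dt$,
evaluated with 64-point Gauss–Legendre quadrature after shifting the
eigenvalues so the largest is zero (no overflow at any $\kappa$; $\kappa$
capped at $10^8$, numerically a pure stick). $I_0$ uses the
Abramowitz–Stegun polynomial approximations of the exponentially scaled
Bessel function (|error| < 2×10⁻⁷; base R's `besselI` underflows above
~2×10⁵ and is far slower). The quadrature was validated against
Monte-Carlo Watson sampling (10⁶ draws) in the test suite.

**Fitting.** `fit_noddi()` per voxel: $S_0$ = mean over b0 volumes;
attenuations by division; orientation initialised from the DTI principal
eigenvector of the lowest shell; a coarse grid over
$(f_{iso}, f'_{stat}, f^{*}_{ic}) \in \{0,0.1,\dots,1\}^3$ and five ODI
values selects the best least-squares start; refinement is Nelder–Mead
over only four parameters $(f^{*}_{ic}, \mathrm{ODI}, \theta, \phi)$
because, given those, the model is linear in $f_{iso}$ and in the combined
Watson-compartment mass $m = (1-f_{iso})(1-f'_{stat})$ — an exact
2-variable constrained least squares (variable projection) solved inside
the objective. Fractions pass through a logistic transform; convergence
diagnostics (residual norm, iterations, flag) are stored per voxel. No
spatial regularisation is applied. The estimator is ordinary least squares
on magnitudes — the conventional "Gaussian-approximation" choice for these
SNRs; see the limitations section for what that implies at the highest
shell.

## The digital phantom

`build_phantom()` emulates the *structure* of the hippocampal sample, not
its anatomy: a 24×24×48-voxel slab at 0.3 mm isotropic whose long axis is
anterior–posterior, split into head/body/tail thirds and laminar
y-layers reusing the canonical 22-region legend (7 head, 8 body, 7 tail),
wrapped in a one-voxel free-water rim ($f_{iso}=1$). Layer contrasts
follow the laminar pattern the pipeline is meant to resolve: a coherent
high-density white-matter sheet ($f^{*}_{ic}=0.6$; alveus along x, fimbria
along the long axis), a soma-dominated pyramidal-like layer
($f^{*}_{ic}=0.12$, high stationary fraction), and a dispersed
molecular-like layer ($f^{*}_{ic}=0.32$, ODI 0.55). A block of the body's
molecular-like layer carries two equal-weight populations crossing at 90°.
A gradient slope (default 0.01 per mm) raises anterior grey-matter
$f^{*}_{ic}$ and, with opposite sign, posterior white-matter
$f^{*}_{ic}$ — the rostro-caudal pattern the region statistics must
recover. Ground-truth T2 is 36.3 ms in the white-matter sheets and 46.4 ms
in grey layers (the two histogram modes), 90 ms in the rim.

These layer values are scenario choices: the study this package builds on
reports regional intra-cellular-fraction means but no per-layer ground
truth, so the defaults were fixed once, before any acceptance measurement,
and are not tuned. Real tissue differs in ways the phantom does not
attempt: curved laminae, partial-volume mixing, B1/coil inhomogeneity,
and spatially varying diffusivities. A green recovery test therefore
establishes correctness of the estimators under the stated model, not
anatomical realism.

`simulate_dwi()` evaluates the four-compartment forward model per voxel
(two-population voxels mix attenuations linearly by weight, each
population with its own Watson orientation), applies the optional
$e^{-\mathrm{TE}/T_2}$ weighting, and adds Rician noise per shell with
$\sigma$ = (shell's own TE-attenuated mean b0)/SNR; default shell SNRs
9.9/7.6/4.2 in increasing-b order. The canonical three-shell scheme
(`hydi_scheme()`) uses b = 4500/7500/10000 s/mm², 60 directions per shell
(deterministic spherical-Fibonacci points), per-shell TE
24.2/39.8/54.8 ms, Δ = 14.4/30/45 ms, δ = 4.3 ms, and 6 b0 volumes per
shell (the b0-per-shell count is a scenario choice; the source protocol
does not state it).

## Tractography

Streamline regularized deterministic (SRD) and probabilistic (SRP)
tracking run on either field type: ODF fields (per-voxel amplitudes
pre-evaluated on a 321-pair tessellation — evaluating trilinearly
interpolated SH coefficients and trilinearly interpolating amplitudes are
the same linear operation) or tensor fields (trilinear tensor
interpolation, principal axis by power iteration, FA amplitude). Defaults
are the dense ex vivo parameters: 70 µm step, 30° cone half-angle around
the incoming direction, 8 seeds per voxel placed uniformly inside masked
voxels, 0.5/100 mm length gate, relative amplitude cutoff 0.1.

At each step the admissible candidates lie within the cone and above the
amplitude cutoff; SRD takes the largest amplitude, SRP samples
proportionally to amplitude (Gumbel-max trick, so a whole batch of live
streamlines samples in one vectorised pass). The step direction is the
low-pass $\hat v = \mathrm{normalize}(w\,v_{in} + (1-w)\,v_{chosen})$ with
inertia $w = 0.3$ — the "regularized" element; the cited algorithm's exact
regulariser is not public, so this is a design choice. Tracking is
bidirectional; the backward half starts against the forward half's actual
first step, which keeps the per-step curvature bound valid across the seed
junction. Termination: mask exit, no admissible candidate, or the length
cap.

One deliberate deviation: candidate amplitudes are shifted by the
per-voxel ODF minimum before thresholding and sampling. Raw Funk–Radon
ODFs sit on a large isotropic pedestal (the degree-0 term), which makes
amplitude-proportional sampling near-uniform inside the cone — a random
walk that loses ~96% of streamlines on a straight-fiber slab. The min-max
shift is the established practice for Q-ball-based tracking and restores
coherent probabilistic propagation; SRD's argmax is unaffected by the
shift. Scalar analyses and peak extraction still use raw amplitudes.

Reproducibility: one `set.seed(rng_seed)` governs seed placement, initial
directions, and SRP sampling for the whole batched run; the same seed
reproduces the tractogram exactly.

## Connectomics

`build_matrix()` counts each streamline once, by its endpoint label pair
(strict containing-voxel lookup, no search radius): different nonzero
labels increment the symmetric pair, same-label or unlabelled endpoints
contribute nothing, so the matrix is symmetric with a zero diagonal by
construction. A streamline traversing more than two regions contributes
only its endpoint pair — the conservative reading of "connections linking"
two regions. Log-mean-length normalisation is implemented but off by
default, matching the source protocol's explicit decision that a
high-SNR, short-fiber dataset needs none. `filter_bundle()` keeps
streamlines joining the start and end sets (order-insensitive), traversing
every waypoint set, and avoiding exclusion voxels; it is idempotent.

## Known limitations

* **Stationary fraction vs the Rician floor.** At the stated shell SNRs
  (9.9/7.6/4.2 at b0), diffusion-weighted signals on the b = 10,000 shell
  sit at single-measurement SNR ~1–2, where magnitude noise adds a
  sizeable positive floor. An unattenuated compartment is statistically
  confounded with that floor: per-voxel fits can trade $f_{stat}$ against
  $f_{ic}$ with *lower* residual than the truth. Pilot experiments with
  floor-subtraction, quasi-likelihood on squared signals, and full Rician
  maximum likelihood did not remove the effect — it is an identifiability
  property of the model at this noise level, not an optimizer artifact.
  Noiseless recovery is exact to ~10⁻⁴; under the stated shell SNRs the
  fixed-seed recovery test measures a median per-voxel intra-cellular
  fraction error of ~0.15, so noisy per-voxel fractions should be read as
  medians over regions, not voxelwise truth.
* The phantom's laminar geometry is rectilinear; no partial-volume
  mixing across layer boundaries is simulated except what trilinear
  interpolation introduces during tracking.
* Time-dependence of extra-cellular diffusion is ignored (kernels depend
  on b only), consistent with the source model's stated assumption.
* The NIfTI-1 and TCK readers/writers cover the subset of those formats
  this pipeline emits (single-file NIfTI, sform affine, common datatypes;
  Float32LE TCK).
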