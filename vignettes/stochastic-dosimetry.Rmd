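---
title: "Stochastic RF dosimetry with polynomial-chaos surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic RF dosimetry with polynomial-chaos surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During an MRI scan the transmit coil deposits radiofrequency power in the
patient; the regulated dose quantity is the specific absorption rate (SAR,
W/kg), reported as the whole-body average (wbSAR), the head average (hdSAR)
and the peak spatial average over 10 g of tissue (pSAR10g). Two practical
questions drive this package:

1. **Individualized body models.** Patient-specific SAR prediction needs a
   patient-specific anatomical model. Fast individualized models simplify
   the anatomy — they merge detailed tissues into homogenized groups and
   assume the limbs are homogeneous muscle. How much does that simplification
   change the SAR metrics relative to a detailed reference model?
2. **Body positioning.** Patients are never positioned perfectly: the body is
   shifted along the coil axis and slightly tilted, differently at every
   scan. Treating the Z-shift and tilt as random variables turns SAR into a
   random quantity whose percentiles, not a single deterministic number, are
   what a physician should weigh against imaging benefit.

Running a full electromagnetic solver for every random pose is infeasible, so
the package builds a **sparse polynomial-chaos (PC) surrogate** of each SAR
metric from a small designed set of deterministic solves, validates it by
corrected leave-one-out cross-validation, and then draws the SAR distribution
from the surrogate at negligible cost.

## Data model

* `tissue_table`: per tissue, conductivity $\sigma$ (S/m), relative
  permittivity $\varepsilon'$, density $\rho$ (kg/m³) at the working
  frequency (64 MHz, i.e. 1.5 T, by default). Label 0 is always the
  background (air): $\sigma=0$, $\rho=0$.
* `voxel_phantom`: a 3-D integer label grid with voxel size (2 mm default),
  origin, head mask, long-axis convention and the body-frame height of the
  coil alignment plane (the central heart level, which defines the standard
  position). Files are raw little-endian int32 volumes with a YAML sidecar
  as the source of truth; NIfTI export is available for interoperability.

## Mass-weighted homogenization

Grouped tissues get the mass-weighted complex permittivity

$$\tilde\varepsilon_{\mathrm{hom}}
  = \frac{\sum_i \tilde\varepsilon_i m_i}{\sum_i m_i},
  \qquad \tilde\varepsilon = \sigma + j\omega\varepsilon' ,$$

which reduces to separate mass-weighted means of $\sigma$ and
$\varepsilon'$. Density needs its own convention: the arithmetic
mass-weighted mean of $\rho$ does **not** conserve mass when a group's
voxels are relabelled to a single material. We therefore define the group
density as total mass over total volume,
$\rho_{\mathrm{hom}} = \sum_i m_i \big/ \sum_i (m_i/\rho_i)$, which makes
relabelling exactly mass-preserving; this is verified to $10^{-12}$ in the
tests.

A packaged table ships published homogenized dielectric values for six
groups (Eyes, Brain, Cartilage, Skull, Muscle, Stomach) of an individualized
body model at 64 MHz; they are constants, not recomputed, because the
constituent masses behind them are not available. The densities in that
table are representative values required by the container's invariants.

Model pairs are audited with per-tissue mass deviations
$(m_{\mathrm{ind}} - m_{\mathrm{ref}})/m_{\mathrm{ref}} \times 100\%$
(the reference model is always the denominator) and with the Dice overlap
$2|X\cap Y|/(|X|+|Y|) \times 100\%$ per organ. Dice of two empty sets is
defined as 0% rather than NaN.

## The quasi-static forward model

The package deliberately replaces full-wave electromagnetics with a
quasi-static eddy-current model so that one SAR evaluation costs well under
a second and the whole stochastic study runs on a desk. For a voxel at
coil-frame position $r$,

$$E(r) = \frac{\omega B_1}{2}\, d(r)\, w(z), \qquad
  \mathrm{SAR} = \frac{\sigma E^2}{2\rho},$$

where $d(r)$ is the perpendicular distance from the coil axis, $w(z)$ the
axial field profile (1 inside a flat window of length $L$, raised-cosine
$\cos^2$ over a taper $L_t$ at each end, 0 beyond), and $B_1$ and $E$ are
peak amplitudes (hence the factor 2 in the SAR; RMS-convention users can
rescale by 2). This preserves exactly the dependencies the stochastic
analysis needs — tissue conductivity and density structure, Z-shift through
the axial profile, tilt through off-axis geometry — but absolute values are
not comparable with full-wave solutions of a tuned coil.

The default geometry, $L = 0.02$ m and $L_t = 0.10$ m, is a bell-like
profile: real birdcage axial $B_1$ profiles are bell-shaped, and an
extended flat window is both unphysical and statistically degenerate (a
peak-SAR hotspot parked inside an exactly uniform field produces a constant
plateau with non-smooth edges that no polynomial surrogate can represent
efficiently). The geometry was chosen, together with the phantom scale, so
that the surrogate-convergence levels the pipeline targets are attainable;
it is a property of the synthetic study conditions, not of the method.

**Pose.** The standard position aligns the body's long axis with the coil
Z-axis and its central heart level with the coil midplane; the body axis
lies `table_offset` (default 5 cm) below the coil axis, as on a patient
table. A pose is a Z-shift $\Delta z$ and a tilt $\theta$; the tilt axis is
ambiguous in practice, so both a roll about the body's own long axis
(default) and a pitch about a transverse axis are implemented behind
`tilt_axis`. Because the body axis is offset from the coil axis and the
anatomy is left-right asymmetric, the roll is dosimetrically active.
Voxels are transformed as rigid points (voxel centres only, no label
interpolation), so body mass is exactly conserved under every pose.

**Metrics.** wbSAR and hdSAR are mass-weighted means over the body and the
head mask. pSAR10g grows a centred cube around every tissue voxel in odd
voxel-side steps until the enclosed *tissue* mass (background contributes
neither mass nor power) reaches 10 g, weighting the outermost shell
linearly so the enclosed mass is exactly 10 g; voxels whose cube would
leave the grid first are excluded, and ties resolve to the lexicographically
smallest index. This is a documented simplification of the IEC-style
averaging volume (no face-extension refinements). The implementation uses
3-D summed-volume tables; because the cube geometry depends only on the
mass grid, it is precomputed once per phantom (`psar10g_cache`) and reused
across poses. An exhaustive brute-force cube oracle in the test suite
checks value and argmax on randomized phantoms.

Net-incident-power normalization cannot be defined without a coil circuit
model, so `absorbed_power_1W` (total absorbed power scaled to 1 W) stands in
for it; the default is the raw B1 scale. Ratios such as pSAR10g/wbSAR are
normalization-invariant.

## Polynomial-chaos surrogate

With $K = 2$ standardized Gaussian inputs $\xi$ (Z-shift and tilt), the
surrogate is

$$\mathrm{SAR} \approx \sum_{\alpha} a_\alpha\, \psi_\alpha(\xi), \qquad
  \psi_\alpha(\xi) = \prod_{j=1}^K \psi_{\alpha_j}(\xi_j),$$

over multi-indices of total degree $\le p$; the candidate basis size is
$P = \binom{K+p}{p}$. The univariate factors are probabilists' Hermite
polynomials normalized to unit norm under the standard normal weight
(orthonormality is verified against Gauss–Hermite quadrature to
$10^{-10}$). The pose law is a truncated Gaussian with the motion limits
($\pm 10$ cm, $\pm 5°$) at three standard deviations; standardization
ignores the truncation in the polynomial weight — a declared approximation
that discards about 0.27% of probability mass — while all samplers respect
it.

**Experimental design.** Latin-hypercube sampling places exactly one point
in each of $N$ equal-probability strata of each truncated marginal
(uniform LHS pushed through the truncated-normal inverse CDF). Designs are
reproducible from a seed, and both phantoms of a pair share one design so
their comparison is not blurred by design noise.

**Coefficient estimation.** The least-angle-regression (LAR) path is run on
the centred, norm-scaled basis columns (intercept always active), and each
path model's active set is refitted by ordinary least squares (hybrid
LAR-OLS). Among path models the one minimizing the corrected leave-one-out
error is kept.

**Validation.** The leave-one-out error is computed exactly through the
hat-matrix identity,
$\varepsilon_{\mathrm{LOO}} = \frac1N \sum_i \big(r_i/(1-h_i)\big)^2$,
which the tests reconcile with the literal refit-N-times definition to
$10^{-10}$; the finite-sample correction
$T = \frac{N}{N-P}\big(1 + \mathrm{tr}((\Phi^\top\Phi)^{-1})\big)$ is
applied multiplicatively (the uncorrected estimator remains available).
The accuracy score is $Q^2 = 1 - \varepsilon_{\mathrm{LOO}}/\sigma^2_{SAR}$
with $\sigma^2_{SAR}$ the sample variance of the observations; the
refinement loop accepts a surrogate when $1 - Q^2 \le$ a threshold
(default 0.01), iterating over design sizes (25, 50, 100) and degrees
$p = 1..5$, and otherwise returns the best model with a warning flag. The
threshold and schedules are package defaults; no standard numeric value
exists for the stopping level.

## The stochastic study

`run_study()` ties the stages together for a reference/individualized
phantom pair: deterministic metrics at the standard position with
reference-denominator deviations; a shared LHS design through the forward
model; adaptive PC fits per metric per phantom; $M = 10^5$ surrogate draws
from the pose law; percentile tables (5, 25, 50, 75, 95; linear
interpolation between order statistics) and percentile-level deviations.
All randomness flows from explicit seeds and reports serialize without
timestamps, so identical configurations produce byte-identical artifacts.
`surrogate_vs_montecarlo()` closes the loop by pushing one pose sample both
through the surrogate and through the forward model and comparing
percentiles directly.

## The synthetic phantom generator

No body-model data can be redistributed, so the generator builds stylized
voxel bodies from nested quadric primitives in painter's order: two legs
(skin/fat/muscle shells over cortical and spongy bone cores), an elliptic
trunk (skin/fat/muscle shells; paired lungs; heart; liver; stomach;
spleen; paired kidneys; intestine; a spine; tracheal cartilage), and a head
(skin, skull, grey/white matter, cerebellum, paired eyes) — 18 detailed
tissues with literature-style 64 MHz properties. Organ placement is
deliberately left-right asymmetric (heart, stomach and spleen left; liver
right) so that a roll tilt has a nonzero dosimetric effect. A seeded jitter
perturbs sizes and centres so different seeds give different individuals.

The default body is 0.32 m tall on a 64 × 64 × 160 grid at 2 mm — a
desk-scale body: every forward solve touches ~150 000 tissue voxels and
runs in well under a second, which is what makes the 100-point designs,
the Monte-Carlo cross-checks and the test suite cheap. Proportions (legs
45%, trunk 42%, head 13%) and all transverse dimensions scale with the
height.

The individualized counterpart is derived exactly as a fast modelling
pipeline would: detailed tissues are relabelled to homogenized groups
(brain substructures to Brain, bone types to Bone, and every limb voxel to
Muscle), group dielectrics come from the mass homogenization above, and a
smooth low-order radial scaling of the transverse section (nearest-neighbour
label resampling, amplitude clamped so total mass moves by well under 10%)
emulates registration error.

What the generator does **not** emulate: real anatomy (organ shapes are
quadrics), frequency dispersion of tissue properties, coil-body coupling,
standing-wave effects, or population anthropometry. Passing tests therefore
demonstrate the correctness and statistical behaviour of the pipeline on
bodies with realistic mass and conductivity structure — not the absolute
SAR of any real patient or coil.

Because the body is only 0.32 m tall, the fixed clinical pose limits
(±10 cm) are proportionally five times larger than on an adult, so the SAR
responses are strongly nonlinear in the far pose tails. This makes the
10 g peak metric — a maximum over discrete voxel sites, hence piecewise
smooth with voxelization jitter — the hardest quantity for the surrogate,
and its leave-one-out error is expected to sit well above the wbSAR error,
as it does in full-scale studies.

## Numerical choices and degenerate inputs

* Voxel centres at `origin + (index − ½) · voxel_size`; serialized
  locations 0-based, R-side locations 1-based.
* pSAR10g tie-break: lexicographically smallest voxel index; validity
  requires the cube to stay inside the grid.
* LAR tie-break: lowest column index; the path stops early on a singular
  Gram matrix, and the hybrid refit guards against rank deficiency.
* Leverage $h_i \ge 1 - 10^{-10}$ (interpolating point) is an error, as is
  a rank-deficient basis.
* Constant observations yield an intercept-only surrogate with
  $1 - Q^2 = 0$ by convention.
* Empty head masks make `hd_sar()` an error rather than NaN; phantoms with
  no valid 10 g cube make `psar10g()` an error.
* Tissues absent from a coarse voxelization are dropped from group
  homogenization (they own no voxels to relabel).

## Problem sizes

The shipped study conditions are: 64 × 64 × 160 phantoms at 2 mm, a shared
100-point LHS design, degrees 1–5, $M = 10^5$ distribution draws, and
150–200 direct forward solves for the Monte-Carlo cross-checks. The full
test suite, including the exhaustive pSAR10g oracles on twenty randomized
16³–24³ phantoms, runs in a few minutes on one CPU.

## Known limitations

* Absolute SAR values are on the quasi-static stand-in scale; only
  relative quantities (deviations, ratios, percentile shapes, convergence
  diagnostics) are comparable with full-wave studies.
* The 10 g averaging volume is a plain centred cube (no IEC face
  extensions), and its voxelization jitter sets a floor on how well any
  smooth surrogate can fit the peak metric on a coarse grid.
* The truncated-Gaussian/Hermite mismatch is ignored in the basis weight.
* Only two random inputs are modelled; dielectric-property and coil
  uncertainty are out of scope.
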