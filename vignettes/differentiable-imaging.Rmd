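---
title: "Differentiable forward models for X-ray imaging inverse problems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable forward models for X-ray imaging inverse problems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adxray)
```

## The common problem statement

Every modality in this package is an instance of one minimization,

$$ L(x) = \lVert A x - y \rVert_2^2 + \lVert x \rVert_1, $$

where $y$ is measured data, $x$ a latent quantity (transform coefficients, a
high-resolution image, a complex transmission function), and $A$ the forward
model of the instrument. For anything beyond a dense matrix $A$, deriving
$\nabla_x L$ by hand is error-prone and has to be redone for every model
change — especially once geometry parameters (scan positions, projection
shifts, a propagation distance) are themselves refined. The package
therefore evaluates each forward model on a reverse-mode automatic
differentiation tape: each taped primitive records its inputs and one
vector-Jacobian product per input, and a backward sweep in reverse creation
order accumulates exact gradients for every optimizable array at a cost
comparable to one extra forward evaluation.

The tape is deliberately small: arithmetic and reductions; structural
primitives (blocks, embeddings, row/element extraction); linear operators
with hand-written adjoints (orthonormal DCT, periodized biorthogonal-4.4
DWT, masking, same-size correlation, mean binning, Riemann projection,
centered orthonormal Fourier and angular-spectrum propagators); and a
bilinear warp differentiable both in the image and in the sampling
coordinates. Complex fields travel as real/imaginary duplets, so derivatives
with respect to complex quantities are ordinary real derivatives of the pair
(the Wirtinger view). Everything is double precision.

Two independent oracles guard the tape: central finite differences
(`fd_gradient()`, used by `verify_gradients()` on every model's closure),
and the hand-derived gradients of the dense generic loss
(`analytic_grad_x()`, `analytic_grad_A()`). The test suite requires
agreement at $10^{-4}$ relative on every modality and $10^{-6}$ against the
analytic forms.

## Operator conventions

* **Coordinates.** Sampling at pixel centers; the affine origin is the image
  center, so rotation about the volume midpoint is the zero-parameter case.
  Warps use bilinear interpolation with zero fill outside the support —
  differentiable, and the standard choice for affine resampling. A warp
  whose sampling grid is a pure translation takes a block-copy fast path;
  rotations at fixed (non-refined) angles are cached as sparse
  interpolation operators.
* **Transforms.** The DCT is orthonormal type-II (Parseval holds exactly,
  and the adjoint is the inverse); the Fourier propagator is the centered
  orthonormal transform (unitary, so far-field propagation conserves
  intensity to machine precision). The wavelet is biorthogonal 4.4 with
  *periodized* boundary handling implemented through cached per-length
  analysis matrices whose synthesis is the exact matrix inverse: perfect
  reconstruction and exact adjoints by construction. The price is the
  constraint that every decomposed dimension be even — image sizes here are
  powers of two times small integers, so this never binds. (A symmetric
  extension would avoid wrap-around artifacts near edges at the cost of an
  approximate, redundant boundary treatment; for reconstruction in a
  regularized latent space the periodized form is cleaner to invert and to
  differentiate.)
* **Angular spectrum.** Transfer-function propagation
  $\mathcal{F}^{-1}\{e^{i k_z z}\,\mathcal{F}\{\cdot\}\}$ with
  $k_z = 2\pi\sqrt{\lambda^{-2} - f_x^2 - f_y^2}$ and evanescent components
  suppressed. The $z$-independent $k_z$ grid is precomputed and cached per
  (shape, wavelength, pixel size), so one call costs two transforms and one
  elementwise product; when the distance is refined, only the phase factors
  are rebuilt each iteration.
* **Binning.** The downscale operator is factor-squared *mean* binning
  (detector pixel integration), not decimation.
* **Sub-pixel crops.** Scan windows are extracted by the same bilinear warp
  at real-valued top-left positions, so they equal integer slicing at
  integer positions but stay differentiable in the position — integer
  slicing is not, and that difference is exactly what makes scan-position
  refinement possible.

## Losses and their conventions

All reductions are sums, not means. The Huber fidelity is the standard
symmetric form — quadratic in $|r| < \delta$, linear beyond, with
$\delta = 1$ by default. The isotropic total variation is
$\sum \sqrt{\varepsilon + \Delta_r^2 + \Delta_c^2}$ with forward differences
and $\varepsilon = 10^{-8}$, keeping the gradient finite on flat regions; a
squared anisotropic variant is available behind `squared = TRUE`. The 1D
total variation penalizes successive differences of the column-major
serialization (the scan raster order). L1 uses the subgradient convention
$\operatorname{sign}(0) = 0$; the complex modulus uses subgradient 0 at the
origin. The ptychographic magnitude penalty sums moduli over exactly the
elements with $|x| > 1$ — compliant elements contribute neither value nor
gradient, encoding that a transmission function cannot amplify. (An
alternative penalizing only the *excess* $|x| - 1$ would be gentler; the
implemented form penalizes the full modulus of offending elements.)

## Optimizer harness

`minimize()` offers two methods. The limited-memory quasi-Newton path
(L-BFGS-B via `stats::optim`, driven by tape gradients) handles the smooth,
medium-sized problems; the relative-loss-change tolerance maps onto its
`factr` control. The first-order adaptive path (Adam, implemented in the
package) serves the large complex duplet problem of ptychography and the
geometric alignment parameters, and implements the stopping rule directly:
relative loss change below `tol` for five consecutive iterations. Runs are
deterministic given inputs and seed. A non-finite loss mid-run aborts with a
classed condition carrying the best-so-far partial state, which the
`reconstruct_*` drivers surface as a warning plus partial result.

One known terminal-accuracy limit: on nonsmooth composites (any loss with an
L1 term) a line-search quasi-Newton method stalls within about $10^{-4}$
relative of the optimum, with the exact stall point depending on the start.
The orthant-wise variant that fixes this is out of scope, and the effect is
irrelevant at the accuracy the reconstructions need.

## Optimization schedules

Three of the four modalities are jointly nonconvex, and a cold joint start
lets the "easy" parameter block absorb the other's residual. The drivers
therefore stage their solves; each stage is plain gradient minimization of
the same composite loss, only over a subset of parameters:

* **Super-resolution** first sharpens the image under the initial kernel
  (a unit-sum Gaussian of width factor/2), then refines image and kernel
  jointly. Cold joint starts leave the image at its interpolation
  initialization while the 169-parameter kernel soaks up the whole
  residual.
* **Ptychography** settles the object at the nominal geometry before any of
  probe, positions or distance are opened; the propagation distance is
  refined as a dimensionless multiple of the nominal value (a raw
  coordinate in meters is six orders of magnitude out of scale with the
  object duplet). With position refinement the field of view is padded by
  4 px so estimates can wander past the nominal scan extent.
* **Tomography with alignment** alternates an early-stopped volume fit at
  the current alignment with a fully converged alignment-only solve, over
  three rounds with growing volume budgets, then polishes everything
  jointly in several restarted quasi-Newton blocks (a fresh limited-memory
  state escapes the stalls one long run hits near L1 kinks; the joint
  stage is what finally resolves the detector tilt, which the biased
  warm-up rounds systematically underestimate). Early stopping in the
  warm-up is the point: a converged limited-angle volume explains the
  misaligned data almost perfectly and zeroes the alignment gradient.
  During alignment-only stages the model projections are constant, so they
  are precomputed once per round and each iteration costs only the
  per-projection data warps; the adaptive method with ~0.2 px steps is
  used there because the shift landscape defeats a quasi-Newton line
  search. Angular sampling matters as much as the solver: with the study's
  61 projections over 120° the volume cannot absorb the inconsistencies a
  coarser tilt series lets it swallow.

## What the synthetic studies emulate — and what they do not

The generators in `R/synth.R` define the package's study conditions; every
stochastic draw takes an explicit seed and repeated calls are bitwise
identical.

* `make_phantom("sparse-dct")` is exactly $K$-sparse in the DCT basis with
  low frequencies favoured — the compressible-signal model under which
  sparse recovery from a 30% *random* mask succeeds. A *regular* stride
  mask (the scan-friendly pattern) violates the incoherence the theory
  needs; the package runs it without error and the reconstruction degrades,
  as expected.
* `simulate_cs_scan` modulates the image by a bounded smooth random walk
  along the scan raster (amplitude 0.2, i.e. a gain in $[0.8, 1.2]$) before
  masking — the slow beam-intensity drift that stripes real scans. Under
  the data-side residual $\Phi\Psi x - y\cdot\Phi w$ the co-estimated
  background $w$ converges to the *reciprocal* gain (so $\Psi x$ comes out
  de-striped); the scale split between image and background is fixed for
  reporting by normalizing $\mathrm{median}(w) = 1$. Recovery is scored as
  correlation with the reciprocal gain.
* `simulate_lr` blurs with a 13×13 kernel and bins 4× — the stated
  degradation. The blind-recovery study uses a Gaussian kernel of width 2,
  which equals the initialization width (factor/2): the kernel check
  validates that joint optimization *keeps* the kernel near an
  already-plausible estimate while the image sharpens, not blind kernel
  discovery from nothing.
* `simulate_sinogram` projects the truth, then warps each projection by
  drawn shifts and a common detector tilt. It returns both the injected
  warps and the *correcting* parameters (their exact inverse, with the
  shift rotated accordingly), which is what recovery is scored against.
  `make_volume_phantom` provides the standard alignment-study volume:
  slices blended smoothly along the vertical axis (real specimens are
  z-continuous — with independent random slices the slice-axis shifts are
  unidentifiable), apodized in-plane, with empty slices at both stack ends
  (±3 px shifts must not push content off the detector frame) and ten
  high-contrast bead-like point features, mirroring the fiducial markers
  added to real tomography samples.
* `simulate_ptycho` scans a raster grid with uniform position jitter,
  storing nominal positions in the dataset and actual ones in the truth
  record. Far-field studies use a feathered-disk probe of radius 12 px in a
  48 px box at 12 px steps (75% overlap — the diversity phase retrieval
  needs).

None of the generators models partial coherence, detector point-spread,
scattering beyond the projection/thin-sample approximations, or realistic
counting statistics (Poisson noise is available as a robustness option but
the headline studies are noiseless, matching the plain least-squares
fidelities). Passing the recovery studies therefore demonstrates the
correctness and the self-consistency machinery of the framework, not
end-to-end performance on beamline data.

## Problem sizes used by the bundled studies

The acceptance studies run at desk scale, chosen to finish in minutes on one
CPU: compressive sensing at 64×64 with $K = 40$ and a 30% mask (plus a
48×48 background-corrected variant); super-resolution at 104×104 (26×26
measured); tomography at a single 64×64 slice with 60 angles over 120°, and
the alignment study on a 12-slice 48×48 volume with 61 angles over 120°,
±3 px shifts and a 2° tilt; ptychography on a 96×96 object with a 5×5 scan
of 48×48 patterns (far field), ±1 px jitter for position refinement, and a
48×48 near-field instance for distance refinement started 20% off.

## Known limitations

* The wavelet transform requires even dimensions at every level
  (periodization); use sizes divisible by $2^{\text{levels}}$.
* Regular sparse masks sit outside the sparse-recovery guarantees; the
  solver runs but quality depends on the image.
* The detector tilt is only weakly coupled to the data at small detector
  sizes: its first-order effect is absorbed by the per-projection shifts,
  so reliable tilt recovery needs the bead-like features and the staged
  schedule described above, and degrades below ~64 px detectors.
* L-BFGS terminal accuracy on L1 composites is about $10^{-4}$ relative
  (see above).
* The angular-spectrum loss is oscillatory in the propagation distance;
  finite-difference checks of the $z$ gradient need steps small against
  $1/k_z$, and distance refinement assumes a start within the central basin
  (about ±20% here).
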