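---
title: "A finite-element model of scleral air-puff deformation imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A finite-element model of scleral air-puff deformation imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scleraAPDI simulates air-puff deformation imaging (APDI) of the rabbit
sclera: a millisecond air pulse indents the equatorial sclera of a
pressurised eye globe, and the depth and shape of the indentation carry
information about the tissue's stiffness. The package implements the forward
finite-element model, the deformation statistics read off the sagittal
surface profile, two in-silico parametric studies, and a one-dimensional
inverse analysis that estimates the scleral material coefficient from
measured apex-displacement-versus-IOP data. This vignette records the model,
its assumptions, the numerical choices, and the design decisions that were
genuinely open.

## The mechanical model

**Geometry.** The globe outline is an ellipse with axial (horizontal)
diameter `AL` and equatorial (vertical) diameter `EL`; the interior is a
second ellipse with semi-axes `(AL/2 - 0.6, EL/2 - THK)`, so the wall is
exactly `THK` thick at the equator and 0.6 mm thick at the posterior pole —
the two constraints the construction must honour. The cornea is a spherical
cap whose edge sits at parametric angle 120 degrees from the posterior pole
and whose apex protrudes 1 mm beyond the ellipse, giving a total axial
extent of `AL + 1`. The sphere is fixed by passing through the limbus ring
and the protruded apex; exact tangency at the limbus is then not available
(the three conditions would overdetermine a sphere), so tangency is
approximate and the interior surface blends linearly into the inner corneal
sphere over a +-6 degree parametric band at the limbus. The model covers one
side of the sagittal plane and one side of the axial plane (a quarter
globe), with symmetry restraints on both planes and the most posterior node
fixed. The air puff is centred on the uppermost equatorial point, which lies
in the sagittal plane; mirroring across the axial plane is an approximation
inherited from the reference model it reproduces (the puff is not symmetric
about that plane, but it decays to nothing well before reaching it).

**Material.** One-term Ogden, incompressible, with strain energy
`W = (mu/alpha) (lambda1^alpha + lambda2^alpha + lambda3^alpha - 3)` on the
isochoric stretches plus a volumetric penalty `kappa/2 (J-1)^2`,
`kappa = 1000 mu alpha`. Under incompressible uniaxial tension this reduces
exactly to `sigma = mu (lambda^alpha - lambda^(-alpha/2))`. The exponent is
fixed at `alpha = 40` (the tissue's strain-stiffening shape); `mu` (MPa)
scales the stress response and is the quantity of clinical interest. The
scleral coefficient decreases linearly from `mu` at the equator to `mu_post`
at the posterior pole, `mu(x) = mu - (mu - mu_post) x / x_f`, where `x` is
the element centroid's axial distance behind the equator and `x_f = AL/2`;
anterior of the equator the coefficient is held at `mu` (no anterior
variation is modelled). The cornea uses the same law with its own
coefficient (default 0.083 MPa); it sits 60 degrees away from the air-puff
site and couples only weakly to the outputs. The stress and consistent
tangent are evaluated in closed form through matrix powers of the
right Cauchy-Green tensor (`tr(Cbar^(alpha/2))` with `alpha/2` an integer),
which avoids spectral decomposition entirely; the 3D material therefore
requires `alpha` to be a positive even integer. Verified properties: the
analytic tangent matches finite differences to ~1e-9 relative, stress is
frame-indifferent, the small-strain shear modulus is `mu alpha / 2`, and the
lateral-stress-free uniaxial state reproduces the closed form to <0.5%
(volumetric-penalty leakage).

**Elements and solver.** 20-node serendipity hexahedra with uniform-reduced
2x2x2 integration — the same family and integration rule as the quadratic
solid elements of the reference model — meshed as a structured
shell-of-revolution grid with collapsed (degenerate) hexahedra at the two
poles. Meridian elements are banded 20% posterior cap / 30% + 30% equatorial
(split exactly at the puff centre) / 20% cornea, and azimuthal elements
cluster toward the sagittal plane, so the output stations at +-2 mm stay
resolved even on coarse meshes. Two elements span the wall by default. The
solver is total-Lagrangian with full Newton iteration; both the intraocular
pressure and the puff are follower loads (they act along the deformed
surface normal, and their load stiffness enters the tangent). The tangent is
symmetrised and factorised fresh each iteration with sparse simplicial
LDL' (whose pivots expose indefiniteness without a failure path); an
indefinite tangent — routine near the deepest indentation — is re-factorised
with a growing diagonal shift (damped Newton). Load increments
sub-step adaptively: the fraction halves when Newton fails, carries over to
the next increment, and re-grows after repeated easy convergence. With
`alpha = 40` the Newton residual legitimately overshoots by ~1e3 for one
iteration before entering the quadratic basin, so the line search triggers
only on element inversion or >1e4 residual growth. Assembly order is fixed;
identical inputs reproduce bit-identical solutions.

**IOP and the stress-free geometry.** The design geometry is what is
observed *under* pressure, so the unloaded geometry is recovered by the
fixed-point iteration `X1 = X0 - u0`, `X(i+1) = Xi - (xi - X0)`, run for
exactly 3 iterations by default (an optional tolerance stop exists). On the
baseline globe the maximum nodal mismatch contracts by roughly an order of
magnitude per iteration (about 5e-2 to 2e-5 mm over three iterations). IOP
is modelled as a prescribed uniform follower pressure on the cavity surface
(1 mmHg = 133.322 Pa exactly); parametric studies treat IOP as an
independent input, re-running the stress-free iteration at each IOP. The
inverse analysis instead computes the stress-free geometry once at the
10-mmHg reference and reuses it for 15/20/25 mmHg (`fixed_at_reference`
mode), as the measurement protocol it emulates does. An optional
volume-coupled cavity mode (pressure rising in proportion to the relative
cavity volume displaced, solved monolithically through a rank-one
Sherman-Morrison update of the tangent) is provided but off by default,
with an ocular-rigidity-like default stiffness of 4 kPa per 1% volume.

**Air puff.** A unit-peak spatial kernel centred on the uppermost equatorial
point, ramped linearly over 6 quasi-static load steps to a 15.4 kPa peak;
the nominal 20 ms duration is bookkeeping only (no inertia, and the
unloading phase is not modelled). Kernel distances use the chordal distance
in the pre-puff configuration (a geodesic approximation good to <0.5% within
the kernel support), the footprint is fixed in that configuration, and the
load follows the deforming normals.

**The calibrated kernel width.** The width of the instrument's spatial
pressure distribution is the one load parameter with no published value: the
only hard anchors are the 2.4-mm nozzle bore and the statement that, at the
baseline inputs (`mu` = 0.083 MPa, `THK` = 0.35 mm, IOP = 18 mmHg,
`mu_post = mu`, `AL` = 18, `EL` = 19), the apex displacement is 1 mm. These
two anchors are mutually inconsistent in this model: a Gaussian at the
nozzle bore (FWHM 2.4 mm) yields a mesh-converged baseline AD of 0.356 mm —
an impinging jet spreads well beyond its nozzle. The package resolves this
the way the original study fixed its own free constant (it chose `mu` so
that baseline AD = 1 mm): the Gaussian FWHM is set once by solving
`AD(FWHM) = 1 mm` at the baseline on a 900-element mesh, giving
`FWHM = 3.35 mm`, frozen as the package default before any downstream
quantity was computed. The nozzle-bore width remains available
(`airpuff_profile(fwhm_mm = 2.4)`) and the width is itself a legitimate
study parameter. Consequences of this choice are discussed under
*Limitations*.

## Output parameters

The sagittal outer-surface profile is extracted at the pre-puff (initial,
heights `Y`) and peak-load (final, heights `y`) states, in a scan frame with
`x = 0` at the scleral apex (the highest pre-puff point, which is the puff
centre) and `+x` toward the posterior pole. Heights are sampled at the fixed
lab-frame stations `x = -2, 0, +2` mm by monotone (shape-preserving) cubic
interpolation — Eulerian sampling, as an OCT B-scan segmentation measures
height at fixed lateral position. The three outputs are

* `AD  = Y0 - y0` (mm), the apex displacement;
* `CPR = (Y0 - y0) / (Y2 - y2)`, the central-peripheral ratio;
* `AR  = (Y2 - y2) / (Y-2 - y-2)`, the asymmetry ratio.

The `+x`-posterior orientation is the one under which the model reproduces
the reported directions of all the posterior-stiffness effects (AR falls and
CPR rises as `mu_post` rises); a fore-aft symmetric configuration (sphere,
uniform coefficient, symmetric restraints) gives AR = 1 to machine
precision. Displacements below 1e-6 mm in a ratio's denominator make that
ratio undefined; it is reported as `NA` with a warning rather than
propagating numerical noise.

## Parametric studies

`sensitivity_study()` sweeps each of the six inputs over its range (defaults:
`mu` 0.06-0.10 MPa, `THK` 0.34-0.40 mm, IOP 10-25 mmHg, `mu_post/mu`
0.25-1, `AL` 17-19 mm, `EL` 18.4-19.6 mm; initial values 0.083 / 0.35 / 18 /
1 / 18 / 19 — the tabulated initial IOP of 18 mmHg is used where the source
text elsewhere mentions 15) while the other five sit at their initial
values, re-running the stress-free preload for every evaluation. Percent
changes are reported from the low end to the high end of the range — the
reading consistent with the published AD span of 0.5-2.5 mm over the `mu`
range — with the alternative initial-to-high convention reported alongside.
`random_sampling_study()` draws every input independently and uniformly
(the posterior coefficient as a ratio in 0.25-1 times the drawn `mu`),
solves each draw, and reports the squared Pearson correlation (with
p-values) between every input and every output; failed draws are excluded
and counted. The draw matrix is generated up front from the seed, so the
sequence is reproducible regardless of solver failures.

## Inverse analysis

`estimate_mu()` minimises `f_apex(mu)` — the squared mismatch between the
simulated and measured apex displacement at the 10-mmHg reference — over
`mu` in [0.05, 0.15] MPa with bounded golden-section/parabolic-interpolation
search (`stats::optimize`, the same algorithm family as the minimiser named
by the measurement protocol), absolute tolerance 1e-4 MPa. AD is strictly
decreasing in `mu` over the bounds, so the problem has a unique solution for
attainable targets; solver failures inside the search return a large finite
penalty so the bracket completes, and an optimum within `2 tol` of a bound
raises a boundary warning. The fitted model then predicts AD at 15/20/25
mmHg reusing the 10-mmHg stress-free geometry, and is scored by RMSE against
the held-out measurements.

## Synthetic data

`generate_synthetic_experiment()` emulates the ex vivo protocol: several
eyes times four scleral locations (S, I, EN, ET), AD measured at IOP 10, 15,
20, 25 mmHg, with a true coefficient drawn uniformly per eye-location
(default range 0.06-0.14 MPa) and additive independent Gaussian measurement
noise. The default noise (0.13 mm) sits mid-way in the 0.08-0.18 mm spread
of reported experimental standard deviations. The generator shares the
forward code path with the inverse fit (fixed-at-reference stress-free mode)
and is seeded, so fixtures are reproducible byte for byte. What it does not
emulate: real segmentation error structure (correlated along the surface),
location-to-location geometry differences (all locations share the common
globe), and any viscoelastic or dynamic response — so passing round-trip
tests demonstrates the identifiability of `mu` under the model's own
assumptions, not robustness to model error in real eyes.

## Numerical choices and problem sizes

* Default mesh: ~5000 quadratic hexahedra, matching the reference model's
  element count. Baseline AD changes by 0.3% between 900 and 2000 elements
  and by ~2% between 400 and 2000; the mesh-refinement property test checks
  this convergence directly.
* Working resolutions, chosen once on that convergence evidence and used
  throughout the shipped analyses: 300 elements for single-configuration
  results (the acceptance script; baseline AD 0.966 there vs 1.002 at 900
  elements), 120-250 for property and behaviour tests, and 80-100 for the
  many-solve studies (the 200-draw sampling study and the inverse
  round-trips), where only rankings and relative recoveries are asserted.
* Newton tolerance 1e-6 relative; displacement increments capped at 0.5 mm;
  at most 40 iterations per attempt with early stall detection after 12.
* Volumetric penalty ratio 1000 (kappa ~ 3.3 GPa-scale for the baseline
  tissue): cavity-volume errors from compressibility are ~1e-5 relative.
* Ties and degenerate inputs: zero-width sweep ranges give exactly 0% change;
  zero-variance inputs make R^2 undefined (reported `NA` with a warning);
  ratio denominators below 1e-6 mm make CPR/AR undefined (`NA`).

## Limitations

* The spatial puff profile is a calibrated Gaussian, not the instrument's
  measured distribution. The calibration reproduces the baseline AD exactly,
  and the directions of all sensitivity effects are insensitive to it, but
  magnitudes that hinge on how the load samples the globe's curvature
  inherit it. The axial-length effect is the clearest casualty: this model
  gives AD rising ~87% across AL 17-19 mm versus the reported ~138%, and the
  (tiny, ~1%) reported AR-AL effect is below this model's discretisation
  noise, with no sign stable under refinement. Both are left as honest
  disagreements rather than fitted away.
* No anisotropy, no viscoelasticity, no unloading phase, no fluid-jet CFD,
  no optic-nerve head or retinal layers; the limbus blend is a modelling
  convenience, not physiology.
* The axial-plane mirror symmetry is inherited from the reference model and
  is an approximation for a top-centred puff.
* Cavity pressure is prescribed (constant during the puff) by default; the
  volume-coupled mode exists but published study conditions treat IOP as an
  independent input.

## Reproducing the shipped numbers

`scripts/acceptance.R` recomputes the baseline AD, the six-parameter
sensitivity percent-changes, and the two absolute AD differences from
scratch at the 300-element working resolution. The README shows a worked
example whose printed numbers come from running the package as installed.
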