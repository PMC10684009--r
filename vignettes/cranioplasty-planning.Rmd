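---
title: "Simulating and predicting spring-assisted cranioplasty outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and predicting spring-assisted cranioplasty outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sagittal craniosynostosis — premature fusion of the sagittal suture — leaves
an infant skull long and narrow. The standard aesthetic measure is the
cephalic index (CI), skull width over skull length, around 0.70 or below in
affected children. In spring-assisted cranioplasty the surgeon removes a
parasagittal strip of bone between the coronal and lambdoid sutures and
implants two or three compressed metal springs across the cut; as they
expand they widen the skull and raise the CI.

Choosing the surgical parameters (osteotomy width and length, spring count,
position and wire gauge) is largely experience-driven. `craniospring`
implements a planning architecture in which a parametric finite-element (FE)
model of the calvarium generates simulated outcomes over the surgical and
material parameter space, and fast regression surrogates trained on those
simulations predict the immediate post-operative CI for new configurations,
so candidate plans can be screened without further FE runs.

This vignette records the model, its numerical choices, the calibrated
configuration, and what the package's tests do and do not demonstrate.

## The parametric calvarium

The calvarium is modelled as a curved shell of uniform thickness: a
superellipsoid-like dome truncated at a base plane. The coordinate
convention is x anteroposterior (+x anterior), y mediolateral, z vertical,
origin at the centroid on the base plane.

* The plan-view outline is a superellipse with semi-axes `l_skull/2` and
  `w_skull/2` and separate anterior/posterior exponents
  (`curvature_anterior`, `curvature_posterior`; 2 = elliptical, larger =
  fuller). Defaults 2.0 / 2.2 give a slightly fuller occiput, as in
  scaphocephaly.
* The meridian profile is circular up to a truncation colatitude
  `base_angle_deg` (default 110°). Values above 90° place the widest
  section above the clamped base — a parietal-eminence-like bulge — so the
  caliper width can respond to lateral expansion.
* The surface is meshed on a structured grid built with the concentric
  square-to-disc map (square rings to circular rings), which is free of the
  corner degeneracies of the smooth elliptical map. One element spans the
  thickness; node clouds are rescaled per axis after meshing so the
  bounding box equals (`l_skull`, `w_skull`, `h_skull`) exactly at every
  resolution.
* Coronal and lambdoid sutures are transverse bands (3 mm wide by default)
  centred at ±0.30 `l_skull`, so the inter-suture distance is
  0.6 `l_skull` — about 96 mm on a 160 mm skull, matching the reported
  suture-to-suture cut length. The anterior fontanelle is a diamond patch
  (30 × 25 mm) at the coronal/midline junction. All positions and widths
  are configuration values.
* The base boundary condition clamps the rim face (every node column on the
  truncation boundary), a resolution-independent set on the base plane.

Two element types are provided. The default is the 20-node serendipity
hexahedron with 3×3×3 Gauss quadrature. The 8-node trilinear brick
(2×2×2 quadrature) is enhanced with the classical Wilson/Taylor
incompatible bending modes (nine internal DOFs, centroid-Jacobian
corrected, statically condensed per element): a one-element-thick plain
trilinear shell locks in shear and under-predicts bending displacement by
roughly a third, which is why commercial "linear brick" elements ship the
same cure. The plain element remains available (`enhance = FALSE`) for
verification tests such as the single-element patch test.

### Sub-element material features

At practical resolutions (4–12 mm) the 3 mm suture bands are thinner than
one element. Rather than letting the compliant band width equal the element
size (which makes the model impossible to mesh-converge), each element
stores its overlap fraction with the suture bands and the assembly blends
bone and suture properties with a series rule of mixtures,
`1/E_eff = f/E_suture + (1-f)/E_bone`. This conserves both the membrane
compliance and the hinge-rotation compliance of the band independently of
resolution. The fontanelle patch uses an area-coverage fraction
(7×7 subsampling) in the same way.

## Osteotomy and spring feet

The osteotomy removes every element whose far face lies closer to a cut
plane than its near face (equivalently, element centroid inside the strip),
between `x = ±(0.3 l_skull − l_ost)` and `|y| ≤ w_ost/2`. Because the
structured grid cannot conform to the cut, removal alone leaves a staircase
boundary whose effective width and length jitter by half an element per
refinement level. Two measures make the cut geometry exact at any
resolution:

* nodes on faces between a removed element and its kept neighbour are
  projected onto the exact cut planes (lateral faces to `±w_ost/2`, end
  caps to the axial cut ends), guarded so no node moves more than 0.9
  elements; quadratic mid-edge nodes are re-midpointed afterwards;
* each spring foot is represented not by one snapped node but by the edge
  node columns within a finite footprint (6 mm default) of its target
  position, with tent weights — the consistent-load treatment of a load at
  an arbitrary position on a discretised edge. The reported anchor position
  `x_actual` still lies within one element of the target.

Residual staircase-transition nodes (where the cut line crosses from one
grid ring to the next) cannot be projected without inverting elements; they
are the dominant source of the few-percent discretisation wobble discussed
under mesh sensitivity.

## Elasticity and the spring coupling

Small-strain isotropic linear elasticity with geometric linearity: the
simulated openings (millimetres on a 160 mm skull) stay within the
small-displacement regime, and no constitutive information beyond (E, ν)
per region is available. The sparse symmetric stiffness is assembled in
compiled code and factorised once per simulation (supernodal Cholesky);
the relative equilibrium residual is checked against 1e-8.

Springs follow a monotone non-increasing force–opening law, by default
linear: force `F0` at zero opening, zero at `opening_max`. The spring force
depends on how far the cut has opened and vice versa; a damped fixed-point
iteration (under-relaxation 0.5, adaptively halved whenever the update
stops contracting, tolerance 1e-4 on the relative force change) resolves
the coupling, reusing the factorisation so each iteration costs one
back-substitution. For a linear structure and linear law the converged
state has the closed form `F* = F0 / (1 + c F0 / opening_max)` per spring
(`c` the structural compliance at the anchors), which the test suite uses
as an independent oracle.

### Calibrated spring catalog

The published description of the implants gives wire diameters (1.0, 1.2,
1.4 mm) but no force magnitudes. The catalog therefore carries calibrated
configuration, not ground truth:

* `F0` scales as the torsional wire stiffness, `d_wire^4`;
* `F0(1.2 mm) = 6.711 N` and `opening_max = 10 mm` were fixed once so that
  the reference validation scenario (below) lands at post-operative
  CI 0.7230 (+1.05 percentage points), the value the architecture is
  expected to reproduce, while keeping the campaign response as large as
  the validation pin allows.

With this catalog the validation simulation's maximal displacement is
about 6.6 mm. Different assumed spring strengths rescale all displacement
outputs roughly proportionally.

## The simulation campaign and surrogates

`sample_parameters()` draws the ten simulation parameters uniformly within
their default ranges — bone modulus 100–3000 MPa (the range the reference
simulations actually swept; the infant-bone literature range 1000–4500 MPa
is available by argument), Poisson's ratio 0.2–0.3, thickness 2–4 mm,
osteotomy width 10–20 mm, suture offset 0–40 mm, spring distance 10–40 mm,
two or three springs, three wire gauges — with two couplings: skull size is
varied through a single scale factor on the 165/116/87 mm base shape
(length then spans 153–170 mm and width 107.5–119.5 mm, with fixed
pre-operative proportions), and infeasible `(l_ost, x_spring)` pairs
(spring outside the cut) are rejected and redrawn. Campaign runs use the
9 mm enhanced-brick preset on one fixed grid topology sized for the base
skull, so the discretisation is identical across runs and the response
stays smooth in the size parameters; 212 simulations take about a minute
on one CPU. Records are cached per id when a cache directory is set, so an
interrupted campaign resumes.

Six regressors predict the post-operative CI (percent scale) from the ten
parameters plus the pre-operative CI: linear regression, RBF support
vector regression, a decision tree, a random forest, gradient-boosted
trees, and regularised gradient boosting (XGBoost). Features are
standardised for the linear and kernel models only. Hyperparameters are
tuned by an in-package tree-of-Parzen-estimators optimiser: random
warm-up, then per-dimension Parzen models of the good (best-γ quantile)
and bad trials, candidates drawn from the good density and ranked by the
good/bad density ratio. Tuning minimises 5-fold cross-validated RMSE;
the best configuration is refitted on the full 170-row training set and
evaluated on the held-out 42 rows.

### What the surrogates can and cannot reach here

On this reimplementation the held-out R² tops out near 0.8 (SVR and
XGBoost) rather than the 0.97 reported for the reference pipeline. The
analysis in the package's development notes attributes this to two
structural differences, not to the learners:

* the reference geometry was remeshed per run from a conforming CAD model,
  so its response is smooth everywhere; a structured-grid mesher leaves
  small response jumps where a cut or suture boundary crosses an element
  face as parameters vary (locally the response is smooth to ~0.001 pp),
  and at 170 training points those jump surfaces are unlearnable detail;
* pinning the validation case to CI 0.723 forces weak springs on this
  geometry family, so the campaign's CI variance is an order of magnitude
  smaller than the reference study's, which shrinks R² for a given
  absolute error (held-out RMSE here is 0.03–0.06 CI percentage points,
  well under the reported 0.12–0.20).

## The validation scenario

The held-out test case mirrors the reference study's cohort-average
5-month-old sagittal-craniosynostosis skull: 160 × 114 × 99 mm (pre-op CI
0.7125, reported as 0.71), 2 mm thick, bone E = 41 MPa and ν = 0.22,
sutures 16 MPa / 0.49, a 20 mm wide suture-to-suture osteotomy (96 mm
long), and two 1.2 mm springs 34 mm from the sutures. The cohort shape
model itself is not redistributable; the package substitutes its own
parametric calvarium with the published overall dimensions and labels it a
synthetic stand-in in every report.

Two properties of this case deserve emphasis:

* its bone modulus (41 MPa) lies far below the campaign range, so every
  surrogate prediction for it is an extrapolation; `run_validation()`
  prints the out-of-range warning prominently rather than hiding it;
* the default simulation preset is the 20-node element at 6 mm, inside the
  mesh-converged band; with the calibrated catalog it yields post-op
  CI 0.7230 (+1.05 pp) and ~6.6 mm maximal displacement.

```{r}
library(craniospring)

study <- sample_parameters(n = 212, seed = 20231128) |>
  run_campaign(campaign_config())
split <- split_dataset(study, seed = 7)
comparison <- compare_models(split$train, split$test, budget = 30, seed = 11)
report <- run_validation(comparison$models)
report
autoplot(comparison)
```

## Mesh sensitivity

`mesh_sensitivity()` re-runs one spring-assisted simulation over a
resolution ladder (default 12/9/6/4.5 mm) for both element orders and
reports the coarsest level whose maximal displacement lies within 2% of
the finest. On the validation configuration the quadratic element
converges at 9 mm (≈ 930 elements) against 6 mm (≈ 2 000) for the enhanced
linear brick, and the two orders agree within a few percent at matched
resolution. The default materials are the validation-case values; the
reference sensitivity configuration (421 MPa bone) can be passed
explicitly. An irreducible inter-level wobble of roughly 1% (linear) to
2.5% (quadratic) remains from the staircase-transition nodes along the cut
edge; levels outside the asymptotic range (coarser than ~12 mm) are
visibly pre-convergent, as expected.

## Known limitations

* Immediate post-operative mechanics only: no skull growth, viscoelastic
  relaxation, contact, or large-deformation kinematics; outcomes weeks to
  months after surgery are outside the model.
* The parametric stand-in shares one geometry family between campaign and
  validation skulls. The reference study validated against an
  independently-shaped statistical model that is evidently stiffer
  relative to its campaign geometry; with one family, pinning the
  validation CI compresses the campaign variance (see above).
* One reported qualitative trend — larger displacements with springs
  closer to the sutures — does not reproduce here: in this geometry feet
  near mid-cut consistently produce the largest edge bulge under every
  spring law and suture treatment tried. The package reports the trend it
  computes.
* Surrogate predictions for bone moduli below ~100 MPa are extrapolations
  and flagged as such.
* Suture geometry (band positions and widths, fontanelle size) is a
  configurable idealisation, not patient anatomy; no imaging is ingested.
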