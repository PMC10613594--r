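---
title: "Shielded dose calculation and attraction-repulsion inverse planning for tongue HDR-ISBT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shielded dose calculation and attraction-repulsion inverse planning for tongue HDR-ISBT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyshield)
```

## The problem

High-dose-rate interstitial brachytherapy of tongue cancer places the
planning target volume (PTV) within millimeters of the mandible, a
late-reacting tissue at risk of osteoradionecrosis. A resin spacer with an
embedded 3-mm lead slab is inserted between tongue and jaw: the spacer adds
distance, the lead absorbs part of the Ir-192 photon fluence. Standard
brachytherapy dose engines follow the TG-43 formalism, which assumes an
infinite water medium, so the shielding effect is invisible both to dose
*evaluation* and to inverse *optimization*. `brachyshield` implements both
with the lead block as a first-class participant.

## Dose model

### TG-43 single-dwell dose rate

The dose rate at polar coordinates $(r, \theta)$ around a dwell is

$$\dot D(r, \theta) = S_K \, \Lambda \,
  \frac{G_L(r, \theta)}{G_L(r_0, \theta_0)} \, g(r) \, F(r, \theta),$$

with air-kerma strength $S_K$ (U), dose-rate constant $\Lambda$
(cGy h$^{-1}$ U$^{-1}$), the line-source geometry function
$G_L = \beta / (L r \sin\theta)$ ($\beta$ the angle subtended by the active
length $L$ at the field point; $1/(r^2 - L^2/4)$ on axis, $1/r^2$ for
$L = 0$), radial dose function $g$, anisotropy function $F$, and reference
point $r_0 = 10$ mm, $\theta_0 = 90^\circ$. All distances are mm, doses Gy.
Tables for $g$ and $F$ are linearly interpolated and clamped at their
boundaries (with a warning); the bundled tables are smooth *synthetic* toys
normalized at the reference point so that the package builds and tests
without external data — measured consensus tables for a real source are
supplied via `read_source_tables()`.

### Superposition and the two kernel strategies

`compute_dose()` forms the total-course dose
$D(v) = n_\mathrm{fx} \sum_i t_i\, \dot d_i(v)\, A_i(v)$, linear in every
dwell time $t_i$ (seconds per fraction) and in $S_K$. Two strategies are
shipped:

- **direct**: the TG-43 formula is evaluated per (dwell, voxel) pair, with
  the source long axis taken along the local catheter direction (central
  difference of neighboring dwell positions; the z axis for single-dwell
  catheters);
- **kernel**: a single-dwell kernel is precomputed on a grid at the dose
  grid's spacing with a fixed axis along z, then resampled by trilinear
  interpolation at each voxel-minus-dwell offset. This mirrors the
  export-a-kernel workflow of a treatment planning system.

The direct mode is the oracle for the kernel mode: the test suite and the
acceptance script measure the fraction of voxels receiving 2–10 Gy where the
two agree within 1%. How a curved catheter should orient the *kernel* is
genuinely under-determined; we document that the kernel mode fixes one
orientation and offer the direct mode when per-dwell orientation matters.

Voxels within 1 mm of a dwell — and near-axis points inside the
active-length envelope, where $G_L$ is undefined — are held at the nearest
valid radius and flagged `near_source`; flagged voxels are excluded from DVH
computation by default.

### Lead-block attenuation

The block is a named structure (z-sorted planar contours). It is rasterized
once per dose computation onto a dedicated fine grid (`raster_spacing`,
default 0.5 mm) and the lead path length $\ell_i(v)$ of the segment from
dwell $i$ to voxel $v$ is measured by Siddon-type voxel-boundary traversal
(exact chord lengths through mask voxels, invariant under swapping the
endpoints). The per-dwell transmission is

$$A_i(v) = 2^{-\ell_i(v)/\mathrm{HVL}},$$

half-value layer algebra being $\mu = \ln 2 / \mathrm{HVL}$ and
$\mathrm{HVL} = t \ln 2 / (-\ln T)$ for a slab of thickness $t$ transmitting
$T$. The default HVL of 2.76 mm is the configurable Monte Carlo-derived
calibration for a 3-mm lead slab in an Ir-192 beam (broad-beam transmission
0.470); note that $3\ln 2/(-\ln 0.470) = 2.754$ mm — the printed calibration
pair is internally consistent only to its printed precision, and the package
treats the HVL as the primary parameter.

Only primary attenuation is modeled: no buildup, no backscatter enhancement
on the source side of the block, no energy deposition difference inside the
lead itself. Voxels inside the block are flagged `in_shield` (their
attenuation-only dose is unreliable) and excluded from DVHs by default;
their stored value carries the partial-path attenuation the ray tracer
yields.

## The ARM optimizer

Every voxel of every constrained structure is an optimization point (a voxel
under two constraints contributes one point per constraint). Per iteration:

1. dose accumulation $D_v = \sum_j \mathrm{rate}_{vj} t_j$ and contribution
   factors $c_{vj} = d_{vj} / \sum_k d_{vk}$ (shield attenuation included;
   rows sum to 1);
2. violation scores $s_v = (L_v - D_v)/L_v > 0$ below a lower limit
   (attraction), $s_v = (U_v - D_v)/U_v < 0$ above an upper limit
   (repulsion), 0 inside the limits; net per-dwell force
   $f_j = \sum_v w_v c_{vj} s_v$;
3. multiplicative feedback $t_j \leftarrow \max(t_\mathrm{min},
   t_j (1 + \eta f_j))$.

The loop stops when the maximum relative dwell-time change falls below
`convergence_tol` or at `max_iterations`. The functional form of the force
is this package's own definition: the underlying idea is an electrostatic
attraction/repulsion analogy whose published description gives the sign
semantics and the contribution weighting but not a closed formula; the
relative-violation linear sum preserves both, makes a feasible plan an exact
fixed point, and gives the single-voxel problem a closed-form solution
($D = U$) used in the tests. The multiplicative update (rather than
additive) keeps dwell times non-negative by construction.

Numerical safeguards: if the violation objective
$V = \sum_v w_v (\text{relative excess} + \text{relative deficit})^2$ rises
for 10 consecutive iterations, $\eta$ is halved; after 3 halvings the run
aborts with a diagnostic. A step that would drive every dwell time to zero
also aborts (an all-zero plan is an absorbing state of a multiplicative
update). A violated constraint with a zero limit is a domain error, since
the relative violation is undefined. Defaults — $\eta = 0.05$,
`convergence_tol` $10^{-4}$, 500 iterations, $t_\mathrm{min} = 0$ — are
stable on all fixture phantoms and live in `arm_config()` /
`default_config()`.

Constraint choice matters with voxel-wise limits: voxels adjacent to a dwell
legitimately receive hundreds of Gy, so a voxel-wise *upper* limit on the
PTV produces enormous repulsion and collapses the plan. The shipped examples
therefore give the PTV a lower limit only (the prescription) and put the
upper limit on the organ at risk; the mandible aim used by the acceptance
script, 40% of the prescription, is a planning aim of this package, chosen
so that it actively binds on the synthetic cohort while staying below the
EQD2-derived hard limit.

## DVH and EQD2

DVHs are kept as sorted per-voxel dose vectors ("dose-sorted"), with
$D_{x\,\mathrm{cc}}$ / $D_{x\%}$ read off by linear interpolation between
voxel ranks — no histogram binning, so bin width never enters as a hidden
parameter. Voxel membership is binary (no partial-volume voxels), consistent
with the even-odd rasterizer. `rescale_to_d95()` multiplies dose and dwell
times by prescription/$D_{95\%}$, which linearity makes mutually consistent.
EQD2 uses the linear-quadratic conversion
$\mathrm{EQD2} = D (d + \alpha/\beta)/(2 + \alpha/\beta)$, $d = D/n$, and
`physical_dose_for_eqd2()` inverts it through the positive quadratic root.
With 9 fractions and $\alpha/\beta = 3$ Gy, an EQD2 limit of 61 Gy maps to a
physical dose of 40.6 Gy — the mandible planning limit quoted in the README.

## The synthetic phantom

`generate_phantom()` draws, from one seed, an ellipsoidal PTV (volume
uniform on 2.7–28.6 cm³, semi-axes in ratio 1 : 1.25 : 1.5), 3–14 parallel
catheters on a jittered transverse grid with 2.5-mm dwell steps, a
curved-prism mandible (arc cross-section, 8 mm thick, ±40°) lateral to the
PTV, a resin spacer slab filling the PTV–mandible gap (thickness uniform on
3–14.9 mm; the sampled lower bound is raised from 2.8 mm to the 3-mm lead
thickness so the block always fits), and the 3-mm lead slab centered in the
spacer. The prescription is 54 Gy in 9 fractions; initial dwell times are
uniform, normalized so the unshielded PTV D95 equals the prescription. The
dose grid is 1 × 1 mm transverse with the longitudinal spacing equal to the
2-mm slice thickness, covering all structures with a 5-mm margin. All
randomness flows through one seed with the caller's RNG state restored.

What the phantom does *not* emulate: real mandible anatomy (an arc prism has
closed-form path lengths, which is the point), CT-number heterogeneity,
catheter curvature, applicator reconstruction uncertainty, or the backscatter
physics deliberately excluded from the dose model. Passing tests on phantoms
therefore demonstrate the correctness of the algorithms under the stated
geometry, not clinical accuracy on patient anatomy; on these phantoms the
lead slab shields essentially the whole mandible arc, so the computed dose
reductions are larger than what partially-shielded clinical geometry yields.

`perturb_phantom()` translates the lead slab by a seeded random vector in
the plane perpendicular to the PTV–mandible axis, supporting sensitivity
experiments on block placement (a displaced block stops covering the
mandible and the shielded mandible dose rises — a property the test suite
checks with the dose engine).

## Numerical choices and problem sizes

- Coordinates are patient-space mm with a voxel-center convention; masks and
  dose grids share one `grid_spec`, eliminating off-by-half ambiguity.
- Rasterization uses the polygon of the nearest-z contour slice (even-odd
  rule, no inter-slice interpolation), each slice representing half a slice
  thickness either side; the choice is stated so it can be revisited.
- Ray tracing accuracy is controlled by a single parameter, the block raster
  spacing (0.5 mm default); slab phantoms give closed-form path-length
  checks (3 mm perpendicular, $3\sqrt 2$ mm at 45°).
- Tests and the acceptance script use deliberately modest problem sizes —
  phantom grids of roughly $10^5$ voxels, a 10-phantom acceptance cohort,
  100-ray dense-sampling oracles with $10^4$ samples per ray — chosen so the
  whole suite runs in minutes on one core while still exercising every code
  path at clinically shaped geometry.
- Native file formats are documented JSON dialects (`R/io.R`); a dose grid
  is one JSON object with a flattened value array, trading file size for
  exact text round-trips. DICOM import/export is out of scope for this
  package.

## Limitations

- Water-equivalent tissue everywhere except the lead block; no
  heterogeneity from CT numbers.
- Attenuation-only shielding: no backscatter dose enhancement upstream of
  the block, unreliable dose inside it (flagged).
- The ARM force law is this package's stated formulation of the
  attraction-repulsion idea; other formulations converge to different
  trade-off points on infeasible problems.
- The bundled source tables are synthetic; quantitative work on a real
  source requires its consensus data via `read_source_tables()`.
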