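---
title: "Quantifying particle orientation at the air-water interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying particle orientation at the air-water interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awiorient)
```

## The problem

When a protein solution is blotted into a thin unsupported film and
plunge-frozen for cryo-electron microscopy, the film is bounded by two
free surfaces — the upper and lower menisci of the air-water interface.
Large complexes adsorb to these surfaces within milliseconds, and the
air-exposed side of an adsorbed particle can unfold. In tomograms of such
films one sees two populations of surface-bound particles, typically with
very unequal occupancy between the two menisci, and subtomogram averages of
the surface-bound population show a characteristic one-sided loss of
density.

`awiorient` answers a geometric question about this situation: *does the
damaged side of each particle face the air?* The analysis has five steps:

1. Model each interface as a smooth height field fitted through the
   centers of the particles adsorbed to it.
2. Evaluate the unit normal of that surface at every particle position,
   signed so it points into the air.
3. Derive a reference-frame *denaturation direction*: the unit vector from
   the particle center to the center of mass of the *missing density* —
   the clamped voxelwise difference between an intact reference map and
   the average of damaged particles.
4. Rotate that reference direction into each particle's tomogram-frame
   orientation (from subtomogram averaging).
5. Measure the displacement angle $\delta$ between the per-particle
   denaturation direction and the local air-side normal, and bin it in
   7.5° steps over $[0°, 180°]$.

$\delta = 0°$ means the damaged side points exactly at the air;
$\delta$ uniformly spread as $\sin\delta$ means no preferred geometry.

## The interface model

The interface is a thin-plate spline — the minimum-bending-energy
interpolant through $N$ particle centers $(x_i, y_i, z_i)$:

$$f(x, y) = a_0 + a_x x + a_y y + \sum_{i=1}^{N} w_i\, U(\lVert (x,y) -
(x_i,y_i) \rVert), \qquad U(r) = r^2 \log r,$$

subject to $\sum w_i = \sum w_i x_i = \sum w_i y_i = 0$. A smoothing
parameter $\lambda \ge 0$ is added to the kernel diagonal; the default
$\lambda = 0$ interpolates every center exactly, which matches treating
the particle centers as noiseless samples of the surface. The bordered
system is solved by the null-space (QR) method, so the side conditions
hold to machine precision; an independent dense solve of the full
$(N{+}3)$ system serves as the test oracle. Coordinates are centered on
their centroid before assembly, making the fit exactly invariant under
in-plane translation of the data.

Normals are analytic: $\nabla U = (x - x_i)(2\log r + 1)$ etc., and the
air-side unit normal is $(-f_x, -f_y, 1)/\lVert\cdot\rVert$, negated for
the lower meniscus. The air side is explicit metadata (`side`), never
inferred from the data: a silent sign flip would mirror the entire
$\delta$ distribution, so we refuse to guess it.

One surface is fitted per tomogram *and per meniscus*. Mixing both
menisci in one height field would be geometrically meaningless — they are
two different surfaces separated by the film thickness. How particles are
assigned to menisci is up to the caller (the synthetic scenes label them
at generation; for real data a z-threshold at the film midplane is the
obvious rule and the labels are an input column).

## The denaturation direction

The reference direction is computed from two co-gridded maps: an intact
reference and the average of damaged particles. The difference is clamped
at zero — a signed "missing density" has no meaningful center of mass —
and the direction runs from the box center (particles are centered by
construction of subtomogram averaging; the density-weighted center is
available as an option) to the center of mass of the clamp. Directions
shorter than 0.25 voxel are rejected as numerically meaningless. Maps are
assumed co-aligned: a grid mismatch is an error, never a silent resample.

Per particle, the reference direction is rotated by the particle's
orientation. The package uses intrinsic ZYZ Euler angles $(\mathrm{rot},
\mathrm{tilt}, \mathrm{psi})$ in degrees, acting on column vectors,
carrying reference-frame vectors into the tomogram frame:
$R = R_z(\mathrm{rot})\,R_y(\mathrm{tilt})\,R_z(\mathrm{psi})$. This
convention is enforced by tests (e.g. $(0,180,0)$ maps $+z$ to $-z$)
because orientation conventions are the most common silent failure mode
when moving particle metadata between packages.

$\delta$ is reported on the full $[0°, 180°]$ range rather than folded at
90°: *toward* versus *away from* the air is precisely the scientific
question. Bulk particles (not on either meniscus) are excluded from
$\delta$ with a reported count rather than assigned to the nearest
surface. The histogram is emitted both as raw counts and as
sine-corrected densities (counts divided by $\sin$ of the bin center, the
solid-angle weight); whether a published angular histogram is
sine-corrected is often unstated, so both are always written.

## The subtomogram-averaging layer

The $\delta$ analysis consumes orientations; the package includes the
minimal averaging machinery needed to produce them from subtomograms and
to validate maps:

* **Alignment** is an exhaustive search over a near-uniform ZYZ grid
  (default 15°, with azimuth count scaled by $\sin(\mathrm{tilt})$),
  with the best circular integer shift within a small radius found by
  zero-mean normalized cross-correlation. Exhaustive search is
  transparent and exactly testable at toy box sizes ($\le 64^3$); score
  ties break to the lexicographically lowest angles so results are fully
  deterministic. An optional missing-wedge mask can be applied to the
  rotated reference during scoring (constrained correlation); it is off
  by default.
* **Gold-standard averaging** splits the stack randomly into two halves
  refined fully independently; each half starts from the plain average of
  20 randomly chosen particles (the default `n_seed = 20`) and iterates
  align-all/average. No symmetry is applied. The half-map FSC (shell
  width one Fourier pixel, shells by rounded radius) is then an unbiased
  resolution estimate, read off at 0.143 by linear interpolation in
  frequency.
* **Mask-bias control**: masked FSC is validated by high-resolution noise
  substitution — phases beyond 60 Å (default) are replaced using the
  phases of a seeded white-noise volume, which preserves both the
  amplitude spectrum and Friedel symmetry exactly. If the masked FSC of
  the phase-randomized half-maps stays high above the randomization
  frequency, the verdict is "biased".
* **Multi-reference classification** aligns every particle against every
  class map (references low-passed to 50 Å by default to avoid reference
  bias), assigns by best score, and re-averages until assignments
  stabilize. When alignments from a prior consensus refinement exist they
  can be passed in, restricting the rotation search to local
  perturbations — the standard and much cheaper practice for
  classification after alignment.

Band-pass filtering uses raised-cosine edges (2 shells wide) rather than
hard cutoffs to avoid ringing; the edge shape is our choice, as display
filters rarely state one. A finite low-resolution limit always removes
the DC term outright, since a band-pass has zero mean by definition.

## The synthetic scene generator

No particle-level ground truth is publicly available for real
interface-adsorption data, so validation runs on synthetic scenes with
analytic ground truth. A scene is a slab of solution bounded by two
spherical-cap menisci over a square field. Defaults (all configurable):

| parameter | default | why |
|---|---|---|
| `slab_thickness` | 1500 Å | typical unsupported-film thickness scale |
| `field_size` | 4000 Å | a workable patch of one grid hole |
| `lower_curv_radius` | 30 000 Å | gently curved, densely occupied surface |
| `upper_curv_radius` | 10 000 Å | the sparser surface is more strongly curved |
| `n_lower : n_upper` | 200 : 20 | the observed ~10:1 occupancy asymmetry |
| `damaged_fraction` | 0.9 | the scale of damage reported for adsorbed particles |
| `kappa` | 50 | vMF concentration of the damage axis about the normal |
| `snr` | 0.3 | realistic subtomogram signal-to-noise power ratio |
| `wedge_halfangle` | 30° | a ±60° tilt range |

Meniscus curvatures are order-of-magnitude choices — for real films the
curvature is unknown and probably stochastic; spherical caps were chosen
over free surfaces because they keep analytic normals available as an
oracle. Surface particles sit exactly on their cap (placed uniformly in
the plane; the area element of these shallow caps deviates from planar
uniformity by under 2%, which we ignore). Each adsorbed particle draws
its damage axis from a von Mises-Fisher distribution about the local
air-side normal — the canonical rotationally symmetric distribution on
the sphere, with the concentration $\kappa$ as the single noise knob —
and its Euler angles are constructed so the phantom's damage axis ($+z$)
maps onto that draw, with uniform in-plane spin. $\kappa$ is capped at
$10^8$, where the sampler's worst-case deviation from the mean direction
is ~0.03°. Bulk particles get uniform positions strictly between the
menisci and uniform orientations.

The particle phantom is a soft-edged barrel — an equatorial wheel plus
two polar domes — and its damaged variant has the $+z$ dome removed and
the adjacent upper third of the wheel attenuated by half, leaving 61.5%
of the intact density (within the one-third-to-one-half loss regime that
motivates the geometry). Subtomograms are rendered by trilinear rotation,
optional Fourier-space wedge zeroing (tilt axis $y$), and white Gaussian
noise scaled to the requested power SNR. No CTF, dose weighting or
tilt-series projection is simulated: the analysis under test is
geometric, and imaging fidelity beyond wedge + noise would add cost
without touching the quantities being validated. Passing tests on these
scenes therefore demonstrates correctness of the geometry and the
recovery machinery, not robustness to CTF effects, alignment errors from
structured noise, or crowded fields.

## Numerical choices and degenerate inputs

* Coordinates are 0-based voxel indices; physical position =
  `origin + index * voxel_size`, in Å. MRC2014 mode-2 (float32) I/O.
* TPS: duplicate $(x, y)$ within $10^{-6}$ Å are merged by z-averaging;
  collinear footprints are an error; the condition number of the reduced
  system is checked. Queries more than 20% of the footprint diameter
  outside the control hull warn about extrapolation.
* FSC shells: width one Fourier pixel, assignment by rounded radius,
  DC excluded; `resolution_at` interpolates the first downward crossing
  and flags curves that never cross ("limit").
* Alignment determinism: one documented seed drives the half split and
  seed-particle choice; equal scores break lexicographically; rerunning
  any stage with the same config and seed is byte-identical, and the
  pipeline fans one global seed out as seed, seed+1 (noise), seed+2
  (averaging) so stages can be rerun independently.
* Empty classes in classification keep their previous map and are
  flagged, not dropped.

### A note on exactness in the averaging tests

The averaging recovery tests draw orientations from the 90°-multiple
rotations (the proper octahedral group), which the 30° search grid
contains. These rotations permute voxels exactly, and because they form a
group, the consensus frame the two half-sets converge to is itself a
group element — so orientation recovery is exact and the half-map
correlates with the phantom at 1.0. For orientations drawn from the full
Euler grid (which is not closed under composition) the consensus frame
generically falls between grid points, and trilinear interpolation then
caps the achievable correlation near 0.99 regardless of implementation;
the noisy-alignment test covers that regime with a one-grid-step error
budget instead.

## Problem sizes

The shipped tests run the full pipeline at deliberately small scale,
chosen as the smallest sizes at which each property is statistically
decidable: $32^3$ boxes at 8 Å/voxel, 40-particle averaging stacks, 60-
to 200-particle classification sets, 300-particle surface fits, and a
2000-particle orientation null (the sine-corrected flatness bound itself
is only decidable near $10^5$ draws, where it is tested at the vector
level). `scripts/acceptance.R` re-runs the same experiments from scratch
at comparable sizes and writes the headline numbers as JSON.

## Known limitations

* Trilinear interpolation limits map fidelity at toy box sizes (see
  above); production STA packages use sinc-family interpolation.
* The exhaustive rotation search scales as (grid size × box volume) and
  is meant for validation-scale problems, not datasets of thousands of
  $128^3$ particles.
* The missing wedge is modelled as a hard binary mask and, during
  alignment, applied only to the reference (no per-particle wedge
  bookkeeping through averages).
* Meniscus physics (Young-Laplace shapes, pinning at the carbon edge) is
  not modelled; caps are a geometric stand-in.
* The difference-map direction assumes the intact and damaged averages
  are already on one grid and aligned; registration is out of scope.
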