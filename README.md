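# awiorient

Orientation analysis of partly denatured protein particles relative to the
air-water interface in cryo-electron tomograms.

## The problem

Proteins in the thin unsupported films used for cryo-EM adsorb to the two
free surfaces of the film — the upper and lower menisci of the air-water
interface — and the air-exposed side of an adsorbed complex can unfold.
Subtomogram averages of such particles show one-sided density loss. The
question this package answers quantitatively is: **does the damaged side of
each particle face the air?**

For tomographers and methods developers it provides the full chain needed
to ask that question of particle metadata plus reference maps, and a
synthetic ground-truth generator to validate every stage.

## The method

The interface through the adsorbed particle centers is modelled as a
thin-plate spline height field

```
f(x,y) = a0 + ax·x + ay·y + Σ wᵢ U(‖(x,y) − (xᵢ,yᵢ)‖),   U(r) = r² log r,
```

with the standard side conditions `Σw = Σwx = Σwy = 0` and analytic
normals. A reference denaturation direction `P_denat` is the unit vector
from the particle center to the center of mass of the *missing density*
`R_missing = max(R_intact − R_denat, 0)`, where `R_intact` is an intact
reference map and `R_denat` the average of damaged particles. Rotating
`P_denat` into each particle's orientation (intrinsic ZYZ Euler angles,
`R = Rz(rot)·Ry(tilt)·Rz(psi)`) and comparing with the local air-side
surface normal `P_normal` gives the displacement angle

```
δ = arccos(P_denat · P_normal)  ∈ [0°, 180°],
```

binned in 7.5° steps; δ = 0° means the damaged side points exactly at the
air. Raw counts and sine-corrected (solid-angle-weighted) densities are
both reported.

Around this sits the minimal subtomogram-averaging machinery the analysis
rests on: MRC2014 I/O, band-pass/Gaussian filters, Fourier shell
correlation with gold-standard half-sets, mask-bias control by
phase randomization beyond 60 Å, exhaustive-rotation alignment, and
multi-reference classification of intact versus damaged particles.

## Worked example

Simulate a vitreous slab with two menisci (150 particles on the dense
lower surface, 15 on the sparse upper one, 10 in the bulk), damage axes
concentrated about the local air-side normal (von Mises-Fisher, κ = 50),
then run the five analysis steps:

```r
library(awiorient)

cfg <- scene_config(n_lower = 150, n_upper = 15, n_bulk = 10,
                    kappa = 50, snr = Inf, seed = 42)
scene <- simulate_scene(cfg)
scene
#> <scene> 175 particles (150 lower, 15 upper, 10 bulk), 150 damaged
#>   slab 1500 A thick, field 4000 A, kappa = 50

intact  <- make_phantom("intact")
damaged <- make_phantom("damaged")
p_ref <- reference_denaturation_vector(intact, damaged)
round(p_ref, 3)
#> [1] 0 0 1

surfaces <- fit_scene_surfaces(scene$particles)
surfaces[["tomo1/lower"]]
#> <tps_surface> 150 control points, lambda = 0, side = lower
#>   control-point residual RMS: 1.501e-12 A
#>   footprint (A): x [0.9556, 3956], y [70.19, 3986]

vectors <- particle_denaturation_vectors(scene$particles, p_ref)
deltas  <- displacement_angles(scene$particles, vectors, surfaces)
#> excluding 10 bulk particle(s) from the displacement-angle analysis
angle_histogram(deltas)
#> <angle_distribution> 165 angles in 24 bins of 7.5 deg
#>   fraction of angles below 30 deg: 1.000
#>   median bin: [7.5, 15) deg
```

The damage axes were generated pointing at the air, and the recovered δ
distribution says exactly that: every particle's denatured side is within
30° of the local interface normal, with the median in the 7.5–15° bin —
the width expected for κ = 50 axis noise. A scene generated with `kappa =
0` (no preferred geometry) instead reproduces the sin δ null, which is the
package's negative control.

The whole chain, including TSV/BILD/JSON outputs, is one call:

```r
report <- run_recovery_experiment(cfg, out_dir = "run1")
report
#> <run_report> 165 particles analyzed (10 bulk excluded)
#>   median displacement angle: 9.60 deg
#>   fraction below 30 deg: 1.000
```

`run1/` then contains `particles.tsv`, `ground_truth.tsv`, per-meniscus
surface models, `deltas.tsv`, `histogram.tsv` (counts and sine-corrected),
`vectors.bild` (ChimeraX-compatible arrows from each particle center along
its denaturation direction), and `report.json`. A function-level CLI
(`awi_cli()`, wrapped by `inst/scripts/awiorient-cli.R`) exposes
`simulate`, `fit-surface`, `analyze`, `fsc`, `sta` and `run-all`
subcommands over the same functions.

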