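# retractx

Model-based correction of surgical **brain retraction** for image-guided
neurosurgery. When retractor blades open a corridor through brain tissue they
create a *topological discontinuity* that ordinary image-to-image or
FEM-based brain-shift correction cannot represent. `retractx` implements the
full correction chain on top of an **extended finite element** (XFEM) tissue
model:

1. **Retractor tracking** — probe-digitised blade corners define a dense
   pre-retraction template cloud; a sparse, noisy, partially occluded laser
   range scan of the deformed blades is completed by trimmed
   iterative-closest-point augmentation and registered per blade face with
   nonrigid **coherent point drift** (CPD).
2. **Boundary conditions** — tracked face displacements, offset by the blade
   thickness along the face normal, become Dirichlet data on the
   crack-adjacent mesh nodes of the matching side; the phantom base (brain
   stem) is fixed at zero.
3. **XFEM solve** — on a uniform hexahedral mesh, the displacement field

   `u(x) = Σ_i N_i(x) u_i + Σ_j N_j(x) H(x) a_j + Σ_m N_m(x) Σ_l F_l(x) c_m^l`

   enriches standard trilinear shape functions with a Heaviside step
   `H = sign((x − x*)·e_n)` across the crack plane (node set `J`) and the four
   asymptotic crack-tip functions `F_l = √r {sin θ/2, cos θ/2, sin θ/2 sin θ,
   cos θ/2 sin θ}` around the crack front (node set `M`), so the retraction
   gap opens without any remeshing. Linear isotropic elasticity
   (default `E = 3 kPa`, `ν = 0.45`) closes the system `K a = P`, solved by
   sparse Cholesky after exact constraint elimination.
4. **Model-updated images** — a crack-aware back-interpolation inverts the
   deformation per side of the crack: voxels with a material source pull the
   pre-retraction intensity, voxels between the two deformed crack faces are
   filled with background (the visible gap), and voxels outside the mesh are
   copied unchanged.
5. **Evaluation** — embedded fiducial beads give the forecast error
   `‖C_model − C_post‖` and the correction (motion-recapture) accuracy
   `(1 − ‖C_model − C_post‖ / ‖C_post − C_pre‖)·100%`; Canny edges on axial
   slices give the modified Hausdorff distance
   `H(A,B) = max(h(A,B), h(B,A))`, `h` the mean-of-minima directed distance.

Because the physical phantom and its CT scans are not distributable, the
package ships a **synthetic phantom generator**: a smoothed-ellipsoid tissue
volume with 23 bright beads (4/12/7 frontal/parietal/occipital, two deep), an
analytic crack-opening ground-truth field (7.0 mm / 6.3 mm blade
displacements), a simulated probe digitisation and a simulated scanner cloud.
Every input of the pipeline is generated with known truth, which makes
parameter-recovery testing possible end to end.

## Worked example

```r
library(retractx)
cfg <- default_config(out_dir = "retractx_out", seed = 1)
report <- run_all(cfg)   # synthesis -> correction -> evaluation
print(report)
```

```
metrics_report
  beads: 23 (2 excluded, zero motion)
  forecast error (mm): mean 1.46, range [0.38, 3.54]
  correction accuracy (%): mean 61.5, range [-16.0, 93.7]
  modified Hausdorff over 19 slices (mm): pre-vs-post 7.61 -> model-vs-post 1.75
```

Reading the numbers: the two deep beads do not move in truth and are
excluded from the accuracy mean; the remaining 21 beads are mispredicted by
1.46 mm on average (under one voxel diagonal at 1 mm voxels); the model
recaptures on average 61.5% of each bead's true motion; and the
model-updated images are about four times closer to the synthetic
post-retraction images (1.75 mm mean modified Hausdorff over 19 axial slices
through the corridor) than the uncorrected pre-retraction images were
(7.61 mm).

All artifacts (NIfTI volumes, bead CSVs, PLY/CSV clouds, crack/truth YAML, a
resolved config copy and a checksum manifest) land in `cfg$out_dir`. The
same stages are available from a shell:

```sh
exec/retractx all --seed 1 --out retractx_out
```

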