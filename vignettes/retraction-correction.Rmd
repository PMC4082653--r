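---
title: "Correcting brain retraction with an enriched finite element model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting brain retraction with an enriched finite element model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retractor blades inserted along the inter-hemispheric fissure stretch brain
tissue apart and open a corridor. For an image-guided neurosurgery system
working from pre-retraction images this is the worst kind of deformation: it
is large (several millimetres) and it changes the topology of the tissue, so
a navigation display built on the old images can become useless exactly where
the surgeon is working. `retractx` estimates the retraction-induced
displacement field from cheap intraoperative measurements (a tracked probe
and a laser range scan of the exposed blades) and renders *model-updated*
images in which both the tissue motion and the opened gap are visible.

## The tissue model

The tissue is modelled as a homogeneous, isotropic, linear elastic solid.
Linearity is adequate for the displacement range of interest here (several
millimetres in a decimetre-scale organ); it is known to degrade for
retractions beyond roughly 13 mm in the stretched zone, where a nonlinear or
viscoelastic law would be needed — that regime is out of scope. The two
material parameters are Young's modulus `E` (default 3000 Pa, the stiffness
of both soft brain tissue and the PVA-C phantoms used to validate such
systems) and Poisson's ratio `ν` (default 0.45, nearly incompressible;
because the model is driven exclusively by Dirichlet data, the computed
displacements are invariant under rescaling of `E`, and experimentation in
the validated range 0.42–0.45 does not change the results appreciably — a
property the test suite asserts).

### Crack representation

The corridor is represented as a planar rectangle ("crack"): a mouth-edge
midpoint, a unit normal `e_n`, an in-plane insertion direction `e_d`, a width
along `e_w = e_n × e_d` and a depth; the interior edge at full depth is the
*crack front*. Planarity reflects how the blades are placed (vertical,
parallel to the falx); curved corridors are out of scope. Two level sets
locate any point relative to the crack: `ψ`, the signed distance to the
plane, and `φ`, the signed in-plane distance to the front (negative over the
cracked region). A point is *on* the crack iff `ψ = 0`, `φ ≤ 0` and its
width coordinate is inside the rectangle.

### Enriched discretisation

The tissue mask is meshed into uniform hexahedra (one element per block of
voxels; an element is kept when at least half of its voxels are in-mask —
the inclusion rule for boundary blocks is a modelling choice, and 0.5 keeps
the mesh volume unbiased). The element size must be an integer multiple of
the voxel size; the default 5 mm puts the reference phantom around 4,000
nodes, the scale at which such systems are run interactively.

Elements completely cut by the crack rectangle contribute their nodes to the
Heaviside set `J`; elements containing the front contribute theirs to the
tip set `M`, and `M` takes precedence on shared nodes so the sets are
disjoint (the precedence rule is ours; only disjointness is dictated by the
formulation). Nodes with `ψ = 0` exactly are assigned to the `+` side, which
makes the double-valued step function single-valued at the tie.

Each `J` node carries 3 extra DOFs multiplying `N_j(x)(H(x) − H(x_j))`; each
`M` node carries 12 extra DOFs multiplying `N_m(x)(F_l(x) − F_l(x_m))`. The
*shifted* form (subtracting the enrichment value at the owning node) spans
the same space as the textbook unshifted field but keeps the standard DOFs
`u_i` equal to the physical nodal displacement on the node's own side, so
nodal Dirichlet data are imposed directly: with both sides prescribed at a
node, `u_i` takes the own-side value and `a_j = (u⁺ − u⁻)/2` (the jump is
`2a_j` in either convention). The tip polar frame takes `θ = 0` on the
in-plane extension beyond the front and `θ = ±π` on the crack faces — the
standard fracture-mechanics convention; only `F_1 = √r sin(θ/2)` jumps
across the faces, by `2√r`.

Numerical choices:

* cut, front and tip-blending elements are integrated with 4³ sub-cells ×
  2×2×2 Gauss points (the sub-division resolves the discontinuous/enriched
  integrand; uncut elements share one analytically assembled 2×2×2 matrix);
* tip enrichment is topological (front-containing elements only), accepting
  the standard blending error rather than introducing a geometric radius;
* constraints are imposed by exact row/column elimination, never penalties,
  so prescribed values are reproduced to machine precision;
* enriched DOFs whose basis function vanishes almost everywhere (far-side
  nodes of an element cut exactly along one of its faces) carry no stiffness
  and are automatically constrained to zero;
* the reduced system is solved by sparse Cholesky; the relative residual is
  recorded in the solution diagnostics.

The solver is verified against a patch test (linear fields reproduced to
1e-8 across materials), the rigid-body kernel of the unconstrained
stiffness, and — for a crack coinciding with element faces — an independent
conforming FEM with explicitly duplicated nodes, which the Heaviside
formulation must match to 1e-6 mm.

## Retractor tracking

The probe digitises the blade corners before retraction; from these the
dense template cloud of both blade faces is built at a configurable pitch
(default 2 mm). After retraction the scanner sees the blade faces sparsely,
with noise, and with a contiguous patch missing where the laser is
obstructed. Tracking proceeds per blade face:

1. **Rigid augmentation.** Trimmed ICP poses the template onto the partial
   scan. Correspondences run in both directions — scan-to-template (immune
   to occlusion, since every scan point has a counterpart on the complete
   template) and template-to-scan with the 70% trim (which penalises the
   template protruding beyond the scan while rejecting occluded
   counterparts). Interior matches are *projective* (the matched point is
   projected onto the local tangent plane, clamped at half the sampling
   pitch): point-to-point matching of a regular lattice locks onto integer
   multiples of the pitch, and the projection removes that aliasing while
   the template boundary still anchors the in-plane pose. The fit is run
   from several coarse starts (identity, centroid shift, principal axes with
   all sign combinations) because a nearly symmetric blade has a
   180°-flipped basin; the best final untrimmed residual wins, with
   near-ties broken toward the smaller rotation. The posed template fills
   the occluded patch (completion of the scan).
2. **Nonrigid CPD.** The template face is registered to the completed scan
   by coherent point drift: the template points are Gaussian-mixture
   centroids, the scan points data. Defaults `β = 2` (kernel width, in units
   of the cloud scale; both clouds are normalised with a *common* centroid
   and scale, because per-cloud normalisation rescales a partial target
   against the full template), `λ = 3` (coherence), `w = 0` (outlier
   weight: the target has already been completed, so no outlier mass is
   expected; `w` remains configurable for raw, un-augmented targets). EM
   stops on a relative log-likelihood change below 1e-8 or when `σ²` falls
   below 1e-5 in normalised units — beyond that point correspondence is
   exact and letting `σ²` collapse only de-regularises the M-step system.

Tracked displacements are converted to boundary conditions by (i) keeping
only the component along the face normal — the tangential motion of a
featureless plane is unobservable from its shape (the aperture problem), so
tangential registration output is artefact, not measurement; (ii) adding the
blade thickness along the outward face normal, because the scanner tracks
the inner blade surface while the tissue in contact rides one thickness
beyond it; (iii) snapping each face point to the nearest Heaviside-enriched
node on the matching `ψ` side, at most one element size away (farther points
are dropped with a log message), averaging multiple points per node and
raising an error on genuinely conflicting prescriptions — averaging
silently across a conflict would hide an acquisition error. The zero
region (phantom base / brain stem) fixes all DOFs of its nodes.

## Model-updated images

For every output voxel centre `x` the crack-aware back-interpolation looks
for a material point `X` with `X + u(X) = x`, separately on each side of the
crack: the fixed-point iteration `X ← x − u_s(X)` uses the one-sided smooth
branch `u_s` of the enriched field (the branch extension is what makes the
iteration a contraction near the faces), with tolerance 1e-3 mm and at most
60 iterations. A converged, in-mesh, side-consistent `X` pulls the
pre-retraction intensity (trilinear by default, nearest for labels); a voxel
with no material source on either side but inside the mesh region lies
between the two deformed crack faces and receives the background intensity —
this is the visible gap; voxels outside the mesh keep their original
intensity so unmodelled surroundings survive. A crack-blind variant (the
traditional back-interpolation: standard nodal field only, no gap
recognition) is provided for comparison; it differs from the crack-aware
result exactly in crack-adjacent voxels.

## Evaluation layer

Bead forecast error is the Euclidean distance between modelled and measured
bead positions. Correction accuracy is reported in the *motion-recapture*
reading, `(1 − ‖C_model − C_post‖/‖C_post − C_pre‖)·100%`: 100% for a
perfect prediction, 0% for no correction. The printed-formula variant with
`‖C_model − C_pre‖` in the numerator grades no-correction as 100% and a
perfect correction as 0%, which contradicts its use as a recapture rate; it
is available behind `printed_form = TRUE` for fidelity studies. Beads with
zero true motion are excluded from accuracy (and logged), not crashed on.

Edge alignment uses a standard Canny detector (Gaussian `σ = 1` px, Sobel
gradients, non-maximum suppression, hysteresis at 0.1/0.2 of the maximum
gradient; the hysteresis linking reuses EBImage's component labelling) on
axial slices through the corridor — 19 evenly spaced slices by default —
and the modified Hausdorff distance, `H(A,B) = max(h(A,B), h(B,A))` with
`h` the *mean* of minimum distances (the robust Dubuisson–Jain form; the
classical max form sits behind `directed = "max"`). When bead positions must
be read from images rather than truth tables, beads are localised as
intensity-weighted centroids of connected bright components.

## The synthetic phantom

The generator replaces a physical PVA-C phantom and its CT scans, providing
every pipeline input with known ground truth:

* **Geometry.** A smoothed ellipsoid (default semiaxes 55 × 45 × 40 mm in a
  128³ / 1 mm grid) stands in for the brain-shaped phantom: the physical
  phantom is itself a simplified brain, and shape realism is not needed to
  exercise the mechanics.
* **Beads.** 23 beads of 1.5 mm diameter, split 4/12/7 across
  frontal/parietal/occipital bands along the anterior–posterior axis, 21 of
  them in a shallow cortical band near the corridor and two deep near the
  centre. The placement bands are chosen so that shallow beads undergo
  measurable truth motion (above ~1.4 mm) while the deep beads do not move —
  mirroring how fiducials behave in the physical experiment. Centers are
  kept in continuous world coordinates; voxelisation happens only when
  painting the spheres, so evaluation truth carries no quantisation.
* **Ground-truth field.** `u(x) = ±d_side · max(0, 1 − |ψ|/decay_radius) ·
  clamp(−φ/front_taper, 0, 1) · e_n`, the simplest C⁰ (linear-taper) opening
  with the reference magnitudes `d_right = 7.0 mm`, `d_left = 6.3 mm`.
  `decay_radius` defaults to 35 mm, the distance from the corridor to the
  fixed base of the phantom — the scale over which a displacement imposed at
  the crack must die out toward the clamped boundary; `front_taper = 10 mm`
  ramps the opening in over the blade-tip zone. The jump across the plane is
  `(d_right + d_left) · clamp(−φ/front_taper, 0, 1)` in closed form, which
  the tests verify to 1e-12.
* **Synthetic post images.** The truth field is applied by exact per-side
  inversion of the analytic map: each material point's intensity appears at
  its displaced location and vacated voxels inside the opened crack receive
  background — the same forward-push semantics as splatting, without splat
  holes, so the synthetic "post CT" shows a clean visible gap.
* **Scanner simulation.** The deformed blade faces (displaced by the truth
  field, *minus* one blade thickness along the face normal, because the
  scanner sees the inner face rather than the tissue contact) are sampled at
  1 mm pitch, randomly subsampled (keep 0.6), perturbed with 0.3 mm
  isotropic Gaussian noise, and one contiguous angular patch holding 30% of
  the points is removed to mimic laser obstruction.

What the generator does **not** emulate: CT physics (noise spectra, beam
hardening, partial-volume blur), inhomogeneous or nonlinear tissue, curved
or multiple corridors, scanner calibration error, and — most importantly —
truly elastic ground-truth motion. The analytic linear taper is *not* the
displacement field of any elastic body: the elastic solution decays
laterally over a scale set by the domain and its clamped base (roughly two
to three times the 35 mm taper in this geometry), so even with boundary
conditions taken exactly from the truth field the model over-predicts motion
at 15–25 mm from the plane. Passing bead tests on this phantom therefore
demonstrates correct mechanics, tracking and warping — not that a linear
elastic model reproduces an arbitrary prescribed field, which it cannot.
This is the main reason the synthetic motion-recapture mean sits around
60–70% depending on the seed, whereas a physical phantom — which *is* an
elastic body — can score higher.

## Problem sizes and reproducibility

The reference experiment runs the full pipeline at 128³ / 1 mm with 5 mm
elements (about 3,400 elements and 12,000 standard DOFs); unit tests use
16³–40³ blocks and a 64³ phantom so the whole suite stays in the
two-minute range. Every stochastic stage draws its seed from the single
configuration seed; a repeated run writes bit-identical artifacts, which the
manifest checksums assert. Transform inputs from navigation (reference-frame
to image space, scanner to image space) are validated 4×4 rigid matrices and
are applied, never estimated, here — their upstream calibration belongs to
the navigation system.

## Known limitations

* Linear elasticity: invalid for retractions much beyond ~13 mm.
* A single planar rectangular crack; no branching, curvature or propagation.
* Topological tip enrichment blends with standard elements, costing accuracy
  in the front-adjacent ring of elements.
* Boundary conditions are transferred by nearest-node snapping; with 5 mm
  elements the snapped node sits up to ~2.5 mm off-plane, and carrying the
  face value there overstates the motion by the truth field's local decay
  (~7% at the defaults). A finer mesh shrinks this quantisation linearly.
* CPD on a featureless plane cannot observe tangential motion (aperture
  problem); only the normal component of the tracked displacement is used.
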