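---
title: "Orbit shape, morphospace and plate biomechanics: methods and design notes"
author: "orbitmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbit shape, morphospace and plate biomechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package computes

Archosauromorph skulls show orbital openings ranging from circles through
ellipses to strongly constricted "keyhole" (figure-of-eight) and wedge
shapes, and non-circular orbits are concentrated in large-skulled
carnivores. `orbitmorph` implements the full analysis chain linking that
shape variation to mechanical performance:

1. **Outline generation** — parametric orbit outlines and a synthetic
   specimen population with covariate-linked shape variation;
2. **Landmarking** — a standardized cross-hair protocol producing 64
   ordered points per outline;
3. **Morphometrics** — generalized Procrustes analysis (GPA) and principal
   component analysis (PCA) of the aligned coordinates;
4. **Biomechanics** — plane-stress finite-element models of square plates
   pierced by orbit-shaped holes, summarised as stress concentration
   factors (SCF);
5. **Synthesis** — thin-plate-spline performance heatmaps over
   morphospace, deformation-space distances, and squared-change-parsimony
   mapping of shape distances onto a phylogeny.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

# Synthetic shapes: what is emulated, and what is not

Real datasets of this kind are digitised from published skull
reconstructions; no such images ship with the package, so the generators
stand in for the fossil sample.

**Shape families.** `make_outline()` builds closed, simple,
counter-clockwise polygons in four families. The *keyhole* is the only
non-obvious construction: two circular lobes joined by straight flanks (a
stadium envelope of width $W$ and height $H = \mathrm{aspect}\cdot W$),
with the waist cut by a narrow Gaussian dip in the width profile,

$$ w(y) = w_{\mathrm{env}}(y)\,\bigl(1 - \mathrm{waist}\cdot
   e^{-((y-y_w)/s)^2}\bigr), \qquad s = 0.09\,H . $$

Because the dip is localised inside the flat flank zone, the realised
narrowest/widest width ratio equals $1-\mathrm{waist}$ (verified against a
brute-force 1000-slice width scan), and `waist = 0`, `aspect = 1` collapses
to an exact circle. The *wedge* is a ventrally tapering triangle with
corner radius 5% of the size. All shapes are rescaled so their maximum
caliper extent (polygon diameter) equals `size` exactly; `tilt` rotates the
finished outline, which is how horizontal or oblique orientations are
produced.

**The 21-shape design set.** `theoretical_set()` returns a deterministic
table-driven set: one circle, tall/wide/tilted ellipses (aspects 0.4–2.5),
keyholes with waists 0.3–0.85 at several aspects, waist positions and
tilts, and three wedge variants. The published set is shown only as a
figure and its exact proportions are unrecoverable, so this set is
*representative*, not a replica; all 21 members are pairwise distinct in
Procrustes shape space (minimum pairwise distance 0.054).

**The population model.** `generate_population()` draws skull lengths
log-uniformly over 50–1500 mm (small early archosauromorphs to large
theropods), diets with probabilities 0.45/0.15/0.40
(herbivore/omnivore/carnivore), and sets each specimen's waist by a bounded
logistic response to a linear predictor,

$$ \mathrm{waist} = \mathrm{clip}\bigl(2\,\mathrm{logistic}(\beta_s z +
   \beta_c\,[\mathrm{carnivore}]) - 1 + \varepsilon,\; 0,\; 0.95\bigr), $$

with $z$ the z-scored log skull length. The $2\,\mathrm{logistic}(\cdot)-1$
form maps a zero predictor to an exactly circular orbit, keeps the waist
bounded, and leaves the effect signs interpretable for recovery tests.
Outline elongation grows with the waist (`aspect = 1 + waist`), as in real
constricted orbits. Defaults $\beta_s = 2$, $\beta_c = 1$,
`noise_sd = 0.02`, $n = 410$ emulate the published pattern that morphospace
expansion tracks skull size and carnivory. What the generator does *not*
emulate: digitisation noise structure, phylogenetic autocorrelation of
shape, asymmetric or non-star-shaped orbits, and taxon-specific allometries
— so green tests demonstrate that the *pipeline* recovers planted signal,
not that real fossils behave this way.

# Landmarking

Outlines are standardized exactly as a manual digitising protocol would:
scaled so the larger bounding-box extent is 1000 units and centred on the
bounding-box centre (not the centroid — the centring a drawing program
applies). Eight fixed landmarks are taken where the boundary crosses rays
at $k\cdot45^\circ$; where a deeply constricted outline crosses a ray more
than once, the intersection *farthest* from the origin is used, keeping
landmarks on the outer margin (deterministic, and consistent with tracing
the external outline). Seven semi-landmarks divide each inter-landmark
boundary arc into eight equal arc-length segments — arc-length spacing is
the only parameter-free reading of "evenly spaced", and matches how curve
tools resample digitised outlines. Points are stored counter-clockwise
from the 0° (anterior) ray, which fixes landmark correspondence across
specimens. Semi-landmarks are *not* slid during superimposition
(bending-energy or Procrustes sliding is deliberately out of scope; the
classic PAST-style GPA used as the reference workflow does not slide).
Dorsal-view outlines are treated identically after standardization; the
view is metadata.

# Procrustes and morphospace

`gpa()` is full iterative GPA: centre, scale to unit centroid size
(optional), rotate each configuration onto the consensus by the
Kabsch/SVD solution restricted to proper rotations, re-estimate the
consensus, and iterate to tolerance $10^{-10}$ (cap 100 iterations;
non-convergence is flagged, not fatal). `morphospace_pca()` performs
*covariance* PCA of the aligned coordinates — the standard choice for
Procrustes shape data, where variables share units and scaling would
distort shape variance. Eigenvector signs are fixed by making the
largest-magnitude loading of every PC positive, so results are bitwise
reproducible across runs and input orders.

The "non-circularity" summary is the Euclidean norm of the first three PC
scores (`pc_distance()`): the morphospace origin is the consensus
(near-circular) shape, and distance from it grows with any deviation,
without distinguishing the kind of deviation. Missing PCs in
rank-deficient test sets count as zero, so the distance stays defined.
`project_config()` places new configurations (e.g. the theoretical set)
into a fitted space by an ordinary Procrustes fit onto the consensus
followed by projection onto the eigenbasis; note that rescaling a
projected configuration to unit centroid size makes the consensus itself
project to a small non-zero score (about 1% of the score range), which is
inherent to partial-Procrustes geometry, not an error.

# Plane-stress finite elements

**Model.** Square plates (height:width:thickness fixed at 10:10:1,
default width 10 mm) are pierced centrally by an outline scaled so its
maximum dimension is `hole_fraction` of the plate width. The published
models do not state the hole-to-plate proportion; 0.4 is used for the
performance table (visually consistent with the published insets) and 0.1
for the analytic benchmarks, where the infinite-plate closed forms apply.
Material: isotropic alligator-bone proxy, $E = 15000$ MPa, $\nu = 0.29$;
units are mm/N/MPa throughout.

**Meshing.** No triangulation library is available to the package, so
`mesh_plate()` builds a structured, boundary-conforming *ring mesh*: rays
fan out from the plate centre; the innermost ring samples the hole
boundary exactly (power-of-two angular count, sized to the margin
refinement target); rings blend from the hole outline to an intermediate
circle and then to the square, so mid-annulus rings are round and element
sizes away from the hole do not echo the hole shape; the angular count
doubles or halves outward (with symmetric transition patterns) to track
the local size target; quads split along their shorter diagonal, with a
centroid four-split on symmetric ties. The construction is deterministic
and exactly mirror-symmetric for mirror-symmetric holes, which the
symmetry tests exploit. Its known cost: in the outermost band where round
rings meet the square corners, the edge-length ratio reaches about 3.4
(interior annulus: below 3). Holes must be star-shaped from the plate
centre; a shape that defeats ray casting is reported per shape and the
batch continues.

**Element and recovery.** 3-node constant-strain triangles with sparse
Cholesky solution (`Matrix`), exact patch-test behaviour, and nodal stress
recovery by area-weighted averaging of element stress components; the von
Mises intensity $\sqrt{\sigma_{xx}^2 - \sigma_{xx}\sigma_{yy} +
\sigma_{yy}^2 + 3\tau_{xy}^2}$ is computed from the averaged components.
At a traction-free hole margin the von Mises stress equals the magnitude
of the tangential normal stress, so the Kirsch (circular hole, SCF 3) and
Inglis (elliptical hole, SCF $1 + 2a/b$) comparisons are valid. Benchmark
resolutions follow the tip curvature: the default margin refinement
(target/3) resolves the circular hole; the transverse ellipse's tip radius
($b^2/a$) needs refinement 9. Measured values: Kirsch 3.01 (0.4% change on
mesh halving), Inglis 4.83 for a tolerance band of ±0.5 — constant-strain
elements converge to curved-notch peaks from below.

**Loading.** The four functional scenarios fix three equidistant nodes
(at 1/4, 1/2, 3/4 of the constrained margin — the symmetric reading of
"three equidistant points") and load three stations of the opposite or
adjacent margin with equal point loads: dorsoventral compression, anterior
shear, anteroposterior compression, dorsal shear. The per-load force is
1 N for the circular reference model and is scaled for every other model
by the quasi-homothetic rule $F \propto$ load-bearing plan area, keeping
force per area constant across differently pierced plates. A uniform
edge-traction case with roller supports exists for the far-field
benchmarks.

**Reference stress.** The SCF denominator is taken from an explicitly
solved, identically loaded *companion plate without a hole*, sampled at
the plate centre: the load-parallel normal component for the compression
scenarios and the maximum principal stress for the shear scenarios. The
published wording ("calculated from the normal stress") is ambiguous; the
companion-model reading is well-defined for all four point-load patterns,
and because it is shape-independent it cannot change any within-scenario
ranking of shapes. Whether the published peaks were von Mises or principal
stresses is also unstated; von Mises is used.

**A result that goes the other way.** With hole sizes matched by maximum
dimension, the strongly constricted keyhole concentrates *less* stress
than the circle under dorsoventral compression (3.29 vs 4.57) and dorsal
shear (6.84 vs 7.45), but *more* under anteroposterior compression (4.94
vs 4.57) and slightly more under anterior shear (7.65 vs 7.41). The
AP-loaded result is the expected Inglis behaviour — a dorsoventrally
elongate hole is a transverse stress raiser for anteroposterior loads —
and it is mesh-converged and exactly consistent under 90° rotation of the
geometry. The reported universal advantage of keyholes therefore does not
reproduce for this max-dimension-matched design set; the corresponding
acceptance check is left failing rather than adjusted, and the discrepancy
is documented here: it would vanish for shape sets in which constricted
orbits are also anteroposteriorly small relative to the plate, or under
area-matched piercing. The deformation-space result *does* reproduce: at
matched force per bearing area the keyhole plate deforms less than the
circular one (PC1–3 deformation distance ratio ≈ 0.6).

# Heatmaps, deformation space, phylogeny

`interpolate_surface()` fits an exact (zero-smoothing) thin-plate spline
($U(r)=r^2\log r$ plus affine part) over (PC1, PC2) scores and evaluates
it on a grid spanning the score range with a 5% margin. A multilevel
B-spline would give the same visual product; the thin-plate spline is
parameter-free and exactly interpolating, which the tests rely on. Grid
cells farther than 10% of the score-range diagonal from every datum are
masked so the surface never extrapolates into empty morphospace. Diet is
encoded ordinally (herbivore 0, omnivore 0.5, carnivore 1).

`deformation_distances()` jointly superimposes all undeformed and deformed
configurations, decomposes them jointly by PCA, and takes each pair's
Euclidean distance over PC1–3. Scaling defaults *off* in this
superimposition: uniform size change is real deformation signal, and
removing it would silently discard volumetric strain. `use_scaling = TRUE`
reproduces the standard scale-removing variant (the published procedure's
likely setting, which is unstated). `sample_fea_landmarks()` adapts the
procedure to the 2-D plate models: landmarks at fixed parametric stations
on the plate boundary and hole margin, deformed positions from the nodal
displacement field.

`map_distances()` matches taxa to tree tips case-insensitively after
underscore/space normalization, reports unmatched tips, and reconstructs
internal values by squared-change parsimony with equal edge weights — the
composite trees this is used with carry no meaningful branch lengths. The
reconstruction is the harmonic (neighbour-mean) solution of a sparse
linear system; it matches a brute-force minimiser of the squared-change
objective and Brownian-motion ancestral states on a unit-branch tree, and
reconstructed values always lie within the tip range.

# Problem sizes and reproducibility

The shipped analyses use: populations of 410 (study scale) and 200
(recovery experiments) specimens at 128 outline vertices; performance
tables at mesh target `plate_w/100` (about 10–15k nodes per model, 21
shapes × 4 scenarios); analytic benchmarks at `plate_w/150` with margin
refinement 3 (circle) and 9 (ellipse), plus one halved-target circle run.
These sizes put every reported digit within the discretisation accuracy
discussed above. All randomness flows through explicit seeds
(`generate_population(seed=)`, the pipeline's single config seed), and the
RNG state is restored after each call, so identical configurations yield
byte-identical outputs.

# Known limitations

- The 21-shape set approximates an unpublished design; absolute SCFs for
  "the same" shapes in other implementations will differ with hole
  proportion, element order and peak-stress convention, even where
  rankings agree.
- Constant-strain triangles underestimate curved-notch peaks at fixed
  mesh; tolerance bands in the tests absorb this, but very sharp tips
  (waist > 0.9, wedge corners) would need finer margins than the defaults.
- The ring mesher requires holes star-shaped from the plate centre and
  has a mildly stretched band along the outer boundary.
- Semi-landmarks are not slid; morphospaces from sliding implementations
  will differ slightly.
- The phylogeny stage consumes a user-supplied tree; the synthetic random
  topology used in its absence supports only plumbing demonstrations, not
  inference.
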