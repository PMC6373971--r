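---
title: "Methods: image-based finite-element analysis of loaded fish vertebrae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite-element analysis of loaded fish vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoflow)
```

## Scientific problem

Advanced teleost fish such as medaka have anosteocytic bone: no osteocytes,
hence no embedded mechanosensor network, yet their vertebrae still add bone
where mechanical demand is highest. The computational argument behind that
observation has three legs, and `osteoflow` implements all three as a
reusable, fully testable pipeline:

1. an image-based finite-element (FE) model of a loaded vertebral centrum,
   built from a segmented micro-CT attenuation volume, which predicts where
   von Mises equivalent strains peak;
2. a nanoindentation analysis (Oliver–Pharr) that calibrates the modulus
   range used by the FE material model and compares trained and untrained
   groups;
3. a ΔΔCt qPCR analysis quantifying load-dependent expression of the
   *sost* / *col1a1* axis against a housekeeping gene.

Because the original specimen scans are not available, the package ships a
synthetic-data module whose outputs have known ground truth. Every
downstream stage is exercised against those generators.

## The phantom vertebra

`phantom_spec()` + `generate_vertebra_phantom()` build a parametric phantom,
not an anatomical replica: a centrum shaped as a surface of revolution whose
radius grows parabolically from a waist toward both articular ends (the
hourglass form of a fish caudal vertebra), plus neural and hemal spines as
cylindrical rods tilted caudally, a cortex shell of elevated attenuation,
and additive Gaussian attenuation noise.

Key defaults and why:

* `grid_shape = 48^3`, `spacing = 1` voxel unit. Large enough that the FE
  field resolves the centrum wall and spines, small enough that the default
  pipeline solves in well under a minute; all geometry scales with the grid.
* `waist_radius = 7`, `end_radius = 14` voxels: a 2:1 end-to-waist ratio
  gives a pronounced hourglass.
* `attenuation_levels = c(background = 50, bulk = 160, cortex = 220)`
  (arbitrary attenuation units). The specimen attenuation distribution is a
  free parameter of the phantom; these values give a realistic bimodal
  bone histogram with a clear background separation.
* `noise_sd = 5`: visible detector-style noise, small relative to the
  background–bulk contrast of 110, so simple thresholding remains honest.
* The noise model is additive, stationary Gaussian — the simplest detector
  stand-in. Beam hardening, phase contrast and partial-volume blur are
  deliberately not simulated; conclusions about segmentation robustness on
  real scans cannot be drawn from these phantoms.

Every generator takes an explicit integer seed and is a pure function of its
spec; global RNG state is saved and restored.

## Segmentation and meshing

Bone is segmented by an inclusive threshold (`segment_bone()`), with Otsu's
between-class-variance criterion as the automatic default standing in for an
operator-chosen threshold, and optional retention of the largest
26-connected component. 26-connectivity is the standard choice for solid
object extraction in 3-D.

The coordinate convention is fixed once: voxel centers sit at
`index * spacing` with 0-based indices. Mesh nodes are voxel corners, so a
voxel spans `(i ± 0.5) spacing`.

`voxels_to_tets()` splits each foreground voxel into 6 tetrahedra by the
Kuhn (Freudenthal) decomposition around one globally consistent main
diagonal. With a single global diagonal direction, the triangulation of
every shared voxel face is identical on both sides, so the mesh is
conforming without parity bookkeeping, and the tetrahedra exactly partition
the voxel: total mesh volume equals foreground count × spacing³ to machine
precision (a tested invariant). No surface smoothing or boundary fitting is
applied — the segmented volume is meshed directly, and smoothing is out of
scope. `to_quadratic()` upgrades to 10-node elements by inserting shared
edge midpoints (node count becomes vertices + unique edges); the element
geometry stays affine, which keeps corner-based volumes exact.

Per-element attenuation is the value of the voxel containing the element
centroid, so all six tetrahedra of a voxel inherit its value — mirroring
per-voxel material assignment.

## Material model

The attenuation range of the meshed elements is divided into 10 equal-width
bins (`calibrate_bins()`), and bin *i* of *n* receives the modulus

\[ E_i = E_{\min} + \frac{i-1}{n-1}\,(E_{\max}-E_{\min}), \]

with defaults \(E_{\min} = 6\), \(E_{\max} = 28\) GPa — the nanoindentation
modulus range for this tissue — and a global Poisson ratio of 0.3. The
literature states that each bin was *assigned* a modulus without giving the
map; equally spaced levels whose extremes equal the calibrated endpoints is
the least-structured choice that realizes both printed endpoints, and it is
exposed as configuration (`E_min`, `E_max`, `n_bins`). Whether bin moduli
should sit at endpoints, bin centers, or per-bin indentation means is
genuinely open; the endpoint-realizing map is the documented default and the
calibration range may alternatively be supplied from `indentation_batch()`
results. Tie-break at interior edges is right-open (a value exactly on an
edge joins the upper bin; the last bin is closed) so binning is exactly
reproducible. A single bin (`n_bins = 1`) cannot realize both endpoints and
receives the midpoint modulus.

## Load case

Boundary constraints and muscle forces for a single loaded vertebra are not
derivable from the source material, so the load case is explicit
configuration with documented defaults:

* **Patches** (`find_patches()`): cranial/caudal articular surfaces are
  boundary nodes within 1.5 voxel edges of the axial extremes; spine
  attachment patches are boundary nodes beyond 70% of the maximal radial
  extent, split by the sign of the offset along the spine axis. Purely
  geometric, hence invariant to node ordering.
* **Bending couple** (`build_bending_couple()`): lateral bending of the
  vertebral column loads the articular surface with compression on one
  lateral half and tension on the other. Totals are distributed equally
  over each half's nodes; with a 1:1 ratio the net axial force vanishes
  identically while the bending moment does not.
* **Muscle tractions** (`build_muscle_loads()`): per-muscle totals
  proportional to relative cross-sections (default 1:1 neural:hemal, as the
  relative areas are not quantified anywhere usable), directed caudally and
  toward the body axis by default.
* **Support** (`fix_support()`): the caudal articular patch is fully fixed.
  One articular surface is the least arbitrary anchor; it is configurable.

Force units are arbitrary. The model is linear, so only relative force
magnitudes matter and all strain outputs are interpreted as relative
distributions — homogeneity of the solution in the loads is a tested
invariant at 1e-10.

## Finite-element solver

Isotropic linear elasticity on tet4 (constant-strain, default) or tet10
elements (4-point Gauss rule, exact for the affine element geometry used
here). tet4 is the fast default; tet10 exists because bending-dominated
benchmarks lock with linear tetrahedra — the cantilever convergence test
reaches the Euler–Bernoulli deflection within 5% (measured: within 0.04%)
only with quadratic elements.

The solver eliminates Dirichlet DOFs and uses sparse Cholesky factorization
up to 250k free DOFs, Jacobi-preconditioned conjugate gradients above
(relative tolerance 1e-10). The contract, checked on every solve, is a
relative residual of at most 1e-8 on the free equations; which mechanism
produced the solution is immaterial. Singular systems (missing or
insufficient constraints) abort with an instruction to check the support.

Strains are the symmetric displacement gradient at the element centroid.
The von Mises equivalent strain uses the strain-based convention

\[ \varepsilon_{vM} = \sqrt{\tfrac{2}{3}\,
   \varepsilon^{dev} : \varepsilon^{dev}}, \]

zero iff the deviatoric part vanishes. The plotted quantity in the source
figures is unitless and its exact convention unstated, so the convention is
pinned here and a multiplicative `scale` argument accommodates
\((1+\nu)\)-scaled variants.

## Surface localization of peak strains

The claim that peak strains sit near external surfaces is qualitative in
the source; `surface_concentration()` operationalizes it with explicit,
configurable thresholds: "peak" = top 5% of elements by ε_vM, "near the
surface" = within 20% of the maximum centroid-to-surface distance. The
report contains the shell fraction, the top-strain-in-shell fraction, their
ratio (enrichment), and median distances, and the acceptance checks assert
only the inequalities (enrichment > 1, top median < global median), not
magnitudes — no quantitative ground truth exists to compare against.
Distances are exact point-to-triangle Euclidean distances to the boundary
triangle set; a brute-force route and a uniform-grid-indexed route compute
identical values (tested) and `"auto"` switches on mesh size.

## Nanoindentation analysis

The forward generator reproduces the instrument's trapezoidal load
function: load to 2.5 mN at 0.5 mN/s, 60 s hold, unload to 0.5 mN at
0.2 mN/s, 20 s hold, final unload at 0.1 mN/s. Depths follow a power-law
contact model constructed to be exactly consistent with the Oliver–Pharr
relations for the requested sample modulus: unloading is
\(P = \alpha (h - h_f)^m\) with \(m \sim U[1.2, 2]\) and residual-depth
ratio \(h_f/h_{\max} \sim U[0.4, 0.7]\) (typical for mineralized tissue),
and \(h_{\max}\) solves the stiffness–area consistency equation. Loading
follows \(P \propto h^2\); holds are creep-free. Noise is additive Gaussian
on the recorded load only.

The inverse (`fit_unloading()`) fits the power law to the first unloading
segment restricted to 20–95% of the maximum load, via a grid-initialised
log-linear search over \(h_f\) polished by Levenberg–Marquardt. Stiffness is
the analytic derivative at maximum depth. `oliver_pharr_modulus()` then
applies \(h_c = h_{\max} - 0.75\,P_{\max}/S\), \(A = 24.5\,h_c^2\),
\(E_r = S\sqrt{\pi}/(2\beta\sqrt{A})\), and the compliance sum with diamond
tip defaults \(E_i = 1141\) GPa, \(\nu_i = 0.07\), \(\beta = 1.034\),
sample \(\nu_s = 0.3\). None of these constants are stated in the source;
they are the standard Berkovich/diamond defaults and all are configurable
(`tip_params()`). Round trips recover the generating modulus to machine
precision on noiseless curves and within 5% at 1% load noise (50-replicate
check). Thermal drift and frame-compliance corrections are not modeled — a
known limitation; the generator produces drift-free curves, so the tests do
not probe robustness to drift.

Group comparisons use the Mann–Whitney test: exact enumeration when the
smaller group has ≤ 8 observations without ties, the tie-corrected normal
approximation otherwise.

## Expression analysis

`delta_delta_ct()` implements classic ΔΔCt with amplification efficiency
exactly 2 (the method is named without efficiency correction in the
source): per sample ΔCt = Ct(target) − Ct(housekeeping), ΔΔCt referenced to
the mean control ΔCt, fold = 2^(−ΔΔCt). Technical replicates are averaged
per sample first (standard practice, unstated in the source). Group
comparisons use the pooled-variance two-sided Student t test on ΔCt, with
Welch available as a switch; zero pooled variance with equal means returns
p = 1, with unequal means it is an error (on noiseless synthetic tables the
fold estimates remain valid and the test statistic is reported as NA).
Because error-bar conventions are ambiguous in this kind of figure, the
summary reports both SD and SEM of the fold. The default `qpcr_design()`
mirrors a 1-hour swim-training comparison (7 control vs 5 trained samples,
*sost* halved, *col1a1* modestly up, stable *rpl7*), with baseline Ct
values of 26/22/18 cycles and 0.3-cycle technical noise — typical qPCR
magnitudes chosen once as the study condition.

## Numerical choices and degenerate inputs

* Bin edges strictly increasing; a degenerate (constant) attenuation range
  is an error rather than a silent single bin.
* Threshold semantics inclusive (≥); empty segmentations report the
  threshold used.
* Element volumes must be strictly positive; the mesher's fixed node
  ordering guarantees it and the assembler re-checks.
* Solver residual contract 1e-8 (verified per solve); CG tolerance 1e-10.
* The unloading fit requires ≥ 5 samples inside the load window and errors
  with the residual if Levenberg–Marquardt fails.
* All file formats used for interchange are plain: NRRD (lossless doubles)
  or TIFF stacks (32-bit samples in [0,1]) for volumes, CSV for curves,
  Ct tables and per-element fields, legacy/XML ASCII VTK for meshes.

## Problem sizes

The default test-suite and acceptance problem sizes are chosen as the
smallest that exercise each property honestly: phantoms at 48³ (pipeline
default) and 32³/24³ (fixtures), the cantilever at 40×4×4 voxels with
quadratic elements, 50 replicate noisy indentation curves, 100 random masks
for volume conservation. The pipeline scales to larger grids; solve time is
dominated by the sparse factorization.

## Known limitations

* The phantom is parametric; none of the results here validate segmentation
  or meshing on real, artifact-laden micro-CT data.
* Muscle attachment regions, directions and relative cross-sections are
  stand-in defaults, not measured anatomy.
* Strain magnitudes are relative; no attempt is made to reproduce
  specimen-specific absolute strains or the published element count.
* Creep, drift and compliance effects are absent from the indentation
  model; hardness is not computed.
* No multiple-testing correction across genes (none is performed in the
  source analysis).
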