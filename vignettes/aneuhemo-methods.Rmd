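---
title: "Methods: hemodynamic wall metrics, vortex cores and wall radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemodynamic wall metrics, vortex cores and wall radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuhemo)
```

`aneuhemo` post-processes CFD results for (thrombosed) intracranial
aneurysms and extracts radiomic texture features of the aneurysm wall, so
that feature–hemodynamics associations can be screened with rank
correlation. This vignette records the models, the numerical conventions,
and the design decisions made where the methodological literature leaves
choices open. Nothing here states an empirical result that the test suite
or the acceptance script does not itself compute.

## Wall-shear-stress metrics

Input: the WSS vector τ(t) = (τx, τy, τz) at each surface point, sampled at
P phases equally spaced over one cardiac cycle of duration T (seconds).
P = 20 and T = 1 s are the defaults, matching the common practice of keeping
20 equally sampled snapshots of the last simulated cycle.

* TAWSS = (1/T)∫|τ|dt, discretized as the plain mean of |τ| over phases.
  For equally spaced samples of a periodic signal the rectangle rule is the
  spectrally accurate choice; a periodic trapezoid rule is available
  (`rule = "trapezoid"`) for non-uniform phase times.
* OSI = ½(1 − ‖∫τdt‖ / ∫|τ|dt). As printed in the methodological
  literature the numerator is a vector; the only well-formed scalar reading
  takes its norm, which is what every implementation uses and what this
  package adopts. OSI is clamped to [0, 0.5]; clamp events (possible only
  through round-off, since ‖mean vector‖ ≤ mean magnitude) are counted and
  reported. A point with zero WSS at every phase carries no directional
  information: its OSI is defined as 0 (no evidence of oscillation) and the
  point is flagged.
* ECAP = OSI/TAWSS and RRT = 1/((1 − 2·OSI)·TAWSS) with a singularity
  guard ε = 1e−12 Pa: where the denominator falls below ε the value is NaN
  and the point flagged. RRT diverges as OSI → 0.5; that is a property of
  the metric, not an error.

Sac summaries (Avg OSI, Avg ECAP, Avg RRT, max/mean TAWSS) are
**area-weighted** by default, using lumped one-third-triangle point areas;
whether published "Average OSI" values are area-weighted is usually
unstated, so a `weighting = "uniform"` mode exists for sensitivity
analysis. Flagged points are excluded from summaries and the exclusion
count is reported.

## Vortex-core metrics

Input: velocities at the nodes of a tetrahedral mesh, per phase. Linear
(P1) interpolation gives a constant velocity-gradient tensor per cell,
exact for affine fields and first-order accurate otherwise; evaluating the
criterion per cell keeps masked volumes exact sums of cell volumes.

The vortex criterion is not standardized across the clinical CFD
literature (papers typically cite earlier methodology rather than printing
a formula). The package defaults to the **Q-criterion** with threshold 0 —
a cell is in a core iff Q = ½(‖W‖²F − ‖S‖²F) > 0 — with **λ₂ < 0** as an
alternative; criterion and threshold are recorded in the output metadata.

Derived quantities per cycle:

* VV(t): sum of masked cell volumes, plus the cycle mean.
* NOC(t): number of face-connected components of masked cells, after
  discarding components smaller than `min_cells` (default 5) as numerical
  speckle; NOC-STD is the population standard deviation over phases
  (sample version by flag).
* DVO: overlap of core regions at adjacent phases,
  V(Cᵢ ∩ Cᵢ₊₁)/V(Cᵢ ∪ Cᵢ₊₁). Jaccard normalization was chosen for symmetry
  (intersection over the smaller region is available by option); pairing
  wraps around the cycle because the cycle is periodic (open-chain by
  option). Two empty masks give DVO 1 (flagged); exactly one empty gives 0.

**A caution on counting cores at threshold 0.** For the synthetic
Gaussian-enveloped rotation blob (below), the exact Q > 0 region is *not*
one compact ball: on the rotation axis Q = (ω·env)² stays positive at every
distance, and weak positive-Q side structure exists with amplitude below
about 1% of the core peak Q = ω². Counting "one core per blob" is therefore
only well-posed at a small positive threshold. The generator records
`suggested_q_threshold = 0.01·min(ω²)` — two orders of magnitude above the
side-lobe amplitude and two below the core peak — and the package's
core-count tests use it. On real CFD fields the same reasoning applies: a
strictly zero threshold counts weak positive-Q debris as cores.

## Morphometrics

The sac is accepted pre-isolated (mesh plus neck plane and inflow
direction); automatic neck detection is out of scope, keeping the module
deterministic. Height is the maximum distance of sac vertices above the
neck plane (the simplest reading of "height" when the original
supplementary definition is unavailable). Width is the maximum caliper
extent perpendicular to the inflow direction, computed by projecting
vertices onto the plane orthogonal to the inflow and taking the diameter of
the projected convex hull. Aspect ratio = height/width and size ratio =
height/parent-vessel diameter (the standard definition; the parent diameter
is a direct input). Enclosed volume uses the divergence-theorem signed
tetra sum and requires a closed surface; surface area is the plain triangle
sum. All metrics are rigid-motion invariant and scale as lengths/areas/
volumes under similarity.

## Radiomics

Features operate on a gray-level discretization of the in-mask voxels. The
source studies rarely print their binning; the default here is
**fixed bin count Ng = 32** (scale-free, convenient for synthetic tests),
with fixed bin width available; the policy, Ng and effective level count
are recorded in the metadata. First-order features use the raw intensities
(intensity shift c = 0 by default, configurable).

Texture conventions (the common reference-implementation defaults):

* GLCM: 13 unique 3-D offsets at Chebyshev distance 1, symmetrized,
  normalized per offset; features per offset, then averaged.
* GLRLM: maximal runs of equal level along the same 13 directions,
  interrupted by the mask; per-direction features averaged.
* GLSZM: zones are 26-connected components of equal level.
* GLDM: dependence = 1 + number of 26-neighbours with |Δlevel| ≤ α (α = 0
  default).
* NGTDM: s_i sums |i − mean 26-neighbourhood level| over voxels of level i
  that have at least one in-mask neighbour. Sentinels for degenerate
  denominators: Coarseness 1e6 when Σp·s = 0, Strength 0 when Σs = 0, so a
  constant region yields finite, comparable values.

Supported features are exactly the ~28 typically reported for wall
enhancement (Mean, Minimum, RMS, Energy, Total Energy; GLCM Contrast, CP,
CS, DA, DV; GLRLM GLN/RLN/HGLRE/SRHGLE/LRHGLE; GLSZM SZN/GLN/GLV/HGLZE/
SAHGLE; GLDM DN/DNN/GLN/HGLE/SDHGLE; NGTDM Coarseness/Complexity/Strength).
Shape descriptors are not re-implemented: the morphology module provides
the reported shape quantities (volume, surface area). Every texture feature
is tested against an independent brute-force enumeration oracle (pair, run,
zone, dependence and neighbourhood enumeration written as plain loops);
the established Python reference implementation is not installable in this
environment, so the enumeration oracles are the verification standard.

## Correlation screening

Spearman ρ is the Pearson correlation of midranks after pairwise deletion
of missing values; the two-sided p-value uses the t approximation
t = ρ√((n−2)/(1−ρ²)) with n−2 df (|ρ| = 1 ⇒ p = 0), with an exact
permutation option for n ≤ 8 (the full-permutation count is impractical in
R beyond that; the t path is the one used for cohort-scale screens).

A "strong" pair is |ρ| > 0.7 with p < 0.05. The published rule is often
stated as signed ρ > 0.7 yet negative strong pairs are reported (e.g.
Coarseness vs vortex volume), so the default applies the threshold to |ρ|;
`mode = "signed"` restores the literal rule. No multiple-testing correction
is applied by default, mirroring the screening practice this package
emulates; Benjamini–Hochberg is available by option. Subgroups with fewer
than 3 cases are skipped with a log message. Cohort screening percentages
are rounded half-up to one decimal, the convention of clinical tables.

## Synthetic data: what it emulates, what it does not

The generators replace patient HR-MRI/CFD data (none are publicly
deposited for this kind of study) with analytically known inputs:

* `make_pulsatile_wss_series`: per-region fixed direction d, positive
  magnitude waveform m(t), and a reversal fraction f of phases carrying
  −m(t)d, so OSI = ½(1 − |1 − 2f|) and TAWSS = mean m(t) in closed form.
  Requested f is rounded to k/P and the achieved value recorded.
* `make_vortex_velocity_series`: superposed blobs
  u = ω(a × (x−c(t)))·exp(−|x−c(t)|²/2σ²) — smooth, compact-ish support, so
  gradients are defined everywhere (a discontinuous solid-body sphere would
  put mesh-dependent artifacts at the jump). Per-phase ω allows cores to
  appear/disappear. Phases where blob supports (3σ) intersect are flagged:
  expected core counts are ambiguous there.
* `make_texture_image`: constant / axis-gradient / checkerboard /
  Gaussian-random-field intensity patterns with named wall masks; the GRF
  smooths white noise with a separable Gaussian kernel (reflective
  padding) and rescales to a target variance.
* `make_coupled_cohort`: Gaussian copula with latent Pearson correlation
  r = 2·sin(πρ*/6), the exact relation making the population Spearman
  correlation equal ρ*; any strictly monotone margin preserves ρ*, and
  subgroup labels carry subgroup-specific ρ*.
* `make_tet_ball`: Kuhn (6-tet) decomposition of a regular grid on the
  bounding cube, vertices mapped radially onto the ball with a blended map
  — identity deep inside, full spherification at the boundary. The blend
  matters: mapping interior vertices with the plain cube-to-ball map
  distorts cells near the cube diagonals enough that P1 gradient noise
  creates spurious positive-Q structures. Boundary vertices lie exactly on
  the sphere, so the total volume converges O(h²) (0.2% error at edge
  r/10).

What a green test does **not** establish: the synthetic fields are not
solutions of the Navier–Stokes equations (no boundary layers, no
physiologic inlet waveforms), the image model has stationary Gaussian
texture rather than contrast-enhancement biophysics, and meshes are
structured rather than boundary-layered CFD meshes. Green tests establish
that the *metrics* are computed correctly on fields with known answers,
not that any clinical association holds.

## Seeds, determinism, reproducibility

Every stochastic generator takes an explicit seed; there is no hidden
global state. `run_pipeline()` writes one directory per run with a manifest
recording the config (and its hash), the derived per-stage seeds, package
version, exercised decisions (weighting, criterion, threshold, binning) and
md5 hashes of all outputs; the same config reproduces identical hashes.

## Known limitations

* No WSS computation from velocity fields, no vortex-axis extraction or
  core tracking across phases, no pressure-based criteria.
* The VTK reader handles the package's own ASCII XML output (plus ASCII
  STL), not arbitrary VTK files; binary/appended encodings are out of
  scope.
* NIfTI support is a minimal NIfTI-1 float32/uint8 single-file
  reader/writer with a spacing-only affine.
* Exact permutation p-values stop at n = 8.
* The rotating-caliper width uses sac vertices; on very coarse meshes the
  width of a smooth shape is slightly underestimated.
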