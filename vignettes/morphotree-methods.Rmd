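---
title: "Branch-level morphometry with morphotree: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-level morphometry with morphotree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotree)
```

# The problem

Digital reconstructions of neurons are distributed as SWC files: a `#`
comment header followed by an *n* × 7 matrix, one row per traced point —
index, structure flag (soma / axon / basal / apical dendrite), x, y, z in
µm, radius in µm, and the parent index (−1 for the root). Two points
connected by a straight line form a *segment*, so a single-root file with
*n* points carries *n* − 1 segments. This Cartesian description is complete
but carries little intuitive information; morphotree compresses it into
branch-level morphometric distributions, and can run the compression in
reverse to grow virtual neurons from those distributions.

# Branches, genealogy, and topological orders

Two connected segments belong to the same **branch** only if (i) the
second's parent index equals the first's index, (ii) both share one
structure flag, and (iii) no other segment shares that parent index. A
branch is a maximal chain under these rules: it ends exactly at a
bifurcation, a flag change, or a tip. Soma (flag 1) segments never join
branches, so dendritic and axonal trees hanging off the soma are roots of
their own trees. Each branch receives a sequential integer **first-name**,
assigned depth-first in file order — an arbitrary but deterministic
labeling, under which a parent always precedes its daughters.

The **full name** of a branch is its parent's full name followed by its own
first-name, routed back to the soma; its length (ancestors + 1) is the
**centrifugal order**. **Strahler order** is the classic stream ordering:
terminal branches are order 1; when two or more daughters of maximal order
*m* meet, the parent is *m* + 1, otherwise the parent continues the largest
daughter order. The rule is purely topological and is implemented for
arbitrary out-degree (trifurcations follow the same "two or more" test).
Both the branch decomposition and the Strahler orders are checked in the
test suite against an independent brute-force implementation that walks the
record adjacency directly, over 200 random trees of up to 100 nodes — a
problem size at which exhaustive comparison stays fast while covering
irregular out-degrees.

# z-smoothing

Several archives carry conspicuous digitization noise in z ("zig-zags" in
the yz view). The filter replaces each z by the mean of the z values whose
**xy-projected arc-length** position lies within ± `window` µm; the
projected distance is the predictor because traced points are not uniformly
spaced. Smoothing branches independently would create z-jumps at
bifurcations, so two synthetic boundary points are concatenated: a
prepended point carrying the average of the parent's final z and the
branch's own first z, and an appended point carrying the average of the
daughters' initial z values (each omitted when the corresponding neighbor
does not exist). The boundary points sit one mean inter-point spacing
outside the branch — this keeps their window weight comparable to interior
points. Within a whole-cell pass, branches are processed root-to-tip, and
each branch's attachment point stays pinned to the parent's already-smoothed
endpoint, so sisters remain continuous.

Design notes, decided here because the method statement leaves them open:

* the window is parameterized as an arc-length half-width (default 5 µm,
  about the spacing of archive points) rather than a point count, which
  honors the predictor-based rationale on non-uniform samplings;
* the prepended boundary value averages the parent's final z with the
  branch's own first z — the reading of the boundary rule most consistent
  with continuity (the alternative readings of "sister" mix in daughters of
  the parent, which the appended point already represents);
* consecutive points with zero xy-spacing (vertical steps) would tie the
  predictor; ties are broken by 10⁻⁶ µm increments;
* `window = 0` is the exact identity, and x, y, radii, indices and topology
  are never touched.

The synthetic fixtures used to validate the filter are built in the
xy-plane, so their noise-free z is identically zero and the z root mean
square error against the noise-free twin is an exact measure; the suite
requires a strict RMSE decrease for noise amplitudes of 1–10 µm.

# Per-branch morphometrics

For a branch with points \(P_0 \dots P_m\) (the attachment point first):

* **length** \(= \sum_k |P_k - P_{k-1}|\) in 3D;
* **DM tortuosity** = path length ÷ \(|P_m - P_0|\), dimensionless, ≥ 1
  with equality exactly for collinear branches; undefined (reported
  missing, with a warning) when the endpoints coincide;
* **SOAM tortuosity**: for each interior point, with
  \(T_1 = P_k - P_{k-1}\), \(T_2 = P_{k+1} - P_k\),
  \(T_3 = P_{k+2} - P_{k+1}\), the in-plane angle
  \(IP_k = \arccos(\hat T_1 \cdot \hat T_2)\) and the torsional angle
  \(TP_k\) = arccos of the dot product of the unit cross products
  \(T_1 \times T_2\) and \(T_2 \times T_3\), both in \([0, \pi]\); the
  combined angle is \(CP_k = \sqrt{IP_k^2 + TP_k^2}\) and SOAM is
  \(\sum CP_k\) divided by path length (rad µm⁻¹), which makes branches of
  different lengths comparable;
* **tapering** = ordinary least-squares slope of point diameter
  (2 × radius) on cumulative 3D arc length, with the per-branch mean
  diameter ± SEM reported alongside;
* **soma distances**: Euclidean (straight line from the soma root point to
  the branch start) and path (summed ancestor branch lengths); the path
  can never be shorter.

Numerical choices: the \(CP_k\) combination is the Euclidean one,
\(\sqrt{IP^2 + TP^2}\), the standard form in the tortuosity literature; a
cross product whose magnitude falls below 10⁻⁹ of \(|T_a||T_b|\) is treated
as a straight continuation contributing zero torsion (an exact-zero test is
wrong under floating point, where a collinear triple can yield a noise
vector whose normalized dot lands at −1 and would inject spurious π terms);
dot products are clamped to \([-1, 1]\) before `acos`; branches with fewer
than 4 points have no combined angle and report SOAM 0 with a `tooShort`
annotation; the tapering abscissa is 3D (not xy-projected) arc length,
matching the length definition.

# Directional vectors, bifurcation angles, Rall exponents

The local direction at a branch ending is estimated over several segments,
not just the terminal one: the first (or last) min(*m*, available)
segments' points are fitted by **total least squares** — the first
principal axis of the centered points — and oriented along increasing arc
length. TLS is preferred over coordinate-wise OLS because no axis is
privileged in 3D. The default *m* = 5 segments; the appropriate *m* grows
with branch tortuosity, and it is exposed as a parameter everywhere.

The **bifurcation angle** between a daughter and its parent is the arccos
of the dot product of the parent's finish vector and the daughter's start
vector, in \([0, \pi]\). The parent vector points in the direction of
growth (away from the soma), so a daughter continuing straight has angle 0.

The **Rall exponent** of a bifurcation generalizes the 3/2 power rule of
the equivalent-cylinder model: it is the \(E\) solving
\(d_{eq}^E = \sum_i d_i^E\), found by bracketed root finding of
\((\sum_i d_i^E)^{1/E} - d_{eq}\) on \(E \in [0.05, 20]\) to relative
tolerance 10⁻⁸ (the objective is monotone decreasing in \(E\), so the
bracket test is exact). When \(d_{eq} \le \max d_i\) no positive root
exists and a missing value with a reason is returned. The parent diameter
is measured at the parent's final point and daughter diameters at each
daughter's first point *after* the bifurcation — the nearest records to the
branch point that are not the shared record itself (the literal first point
of a daughter is the bifurcation point, whose diameter is the parent's).

# Group statistics

The branch table ("vertical compression") holds one row per branch: cell
id, topology, the accumulative metrics, the angle to the parent, and the
Rall exponent of the branch's distal bifurcation, with missing values
propagated. Frequency distributions use **Sturges' rule**,
\(k = \lceil 1 + \log_2 n \rceil\) equal-width bins spanning the data range
(last bin closed on both sides); an all-identical sample is widened by
± 0.5 to avoid a zero-width range, with the same widening applied when the
range is below 10⁻⁹ relative (a floating-point-degenerate range produces
non-increasing edges otherwise). Group summaries report the per-bin mean
count across cells ± SEM, with the standard deviation on the *n* − 1
denominator; a single-cell group reports missing SEMs rather than a
spurious 0. Comparisons across groups on one bin width are made by passing
shared edges computed on the pooled groups — the conservation property
(per-cell counts sum to the number of finite values) is enforced, so
out-of-range values raise an error instead of being clipped.

# The synthetic-fixture factory and the virtual-neuron generator

`makeFixture()` realizes chain, Y, and complete-binary-tree templates with
exactly known ground truth: planar geometry (noise-free z ≡ 0), exact
branch lengths, planned taper, planned ± angle daughters, and daughter
diameters constructed so every bifurcation solves the planned Rall
exponent exactly as measured by the analysis modules. Defaults — 50 µm
branches sampled at 11 points, 2 µm start diameter, exponent 1.5, ± 60°
daughters, z-noise amplitudes spanning 1–10 µm in the smoothing checks —
are ordinary values for hippocampal dendritic arbors at archive sampling
density. What the fixtures deliberately do **not** emulate: multi-point
soma contours, non-planar torsion, heteroscedastic or correlated tracing
noise, and inter-branch diameter variability beyond the Rall construction.
Passing tests therefore demonstrate correctness of the computations on
known geometry, not robustness to every artifact of real archives.

`fitMorphometryModel()` pools branch tables by centrifugal order and keeps
the raw per-order value lists (length, taper, mean diameter, SOAM, angle)
plus the per-order branching probability — the observed fraction of
branches with daughters. `generateVirtualNeuron()` grows trees by direct
resampling of those lists: a branch at order *o* draws its parameters from
order *o*'s lists, is realized as a polyline of 10 equal steps whose
per-step turn angle is scaled so the summed combined angles approximate the
drawn SOAM (turns at uniformly random azimuths, clamped at π/3 per step),
and spawns two daughters with probability equal to the order's branching
probability, tilted off the parent's end direction by next-order angles at
opposite random azimuths. Conditioning on centrifugal order keeps the
genealogy — one of the headline descriptors — in the model. The whole
growth procedure, including the conditioning variable and the termination
rule, is this package's own design: the empirical distributions are the
model, and resampling them is the minimal generator consistent with that
model. Determinism is strict: the RNG is seeded from the growth
configuration and the caller's RNG state is restored, so identical (model,
seed) pairs yield byte-identical SWC files. Closure is verified on a
population of 100 virtual neurons — all must validate as SWC, and the
per-order branch-length Kolmogorov–Smirnov statistic against the model's
input lists must fall below the two-sample α = 0.01 critical value.

# Known limitations

* Column 6 is treated as radius (standard SWC); every diameter-based
  formula uses 2 × radius. Archives that store diameters must be halved on
  ingestion.
* Soma distances use the reconstruction's root record as the soma point;
  for multi-point soma contours the Euclidean distance is measured from the
  root record, which can exceed the ancestor-path distance for branches
  attached far along the contour.
* Shrinkage and refraction corrections are assumed already applied
  upstream; the package never rescales coordinates.
* No between-group hypothesis testing is provided — summaries are
  distributions, means and SEMs only.

# A worked pass

```{r example, eval = FALSE}
fx <- makeFixture(fixtureSpec("btree", depth = 3, znoise = 2, seed = 1))
forest <- branchForest(smoothReconstruction(fx, smoothingConfig(window = 5)))
tab <- verticalCompress(forest, cellId = "demo")
model <- fitMorphometryModel(tab)
vn <- generateVirtualNeuron(model, growthConfig(seed = 42))
validateReconstruction(vn)   # zero findings
```
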