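---
title: "Vertex-model mechanics of ciliated epithelia: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model mechanics of ciliated epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivertex)
```

`epivertex` models a proliferating epithelial monolayer that contains
multiciliated cells (MCCs) — stiff, non-dividing cells scattered through a
dividing bulk — and provides the analysis machinery used to study how such
cells load their neighbourhood: per-cell stress measures with
decile-enrichment statistics, geometry-based junction-tension inference,
and estimators for macropinocytosis event data, together with generators
that synthesise every input the analyses need. This vignette is the
package's account of the underlying models, the conventions it fixes where
the field has no single standard, and the reasoning behind design choices
that were genuinely open.

## The vertex model

The monolayer is a planar polygonal tiling. Topology is carried by two
signed incidence matrices: $A$ (edges x vertices, $+1$ at an edge's head
and $-1$ at its tail) and $B$ (cells x edges, $+1$ where the stored edge
direction agrees with the cell's counter-clockwise traversal). Every cell
boundary being a closed loop is equivalent to the matrix identity
$B A = 0$, which `validate_topology()` checks together with the disc Euler
relation $V - E + F = 1$ and positivity of all signed cell areas. All
surgeries (division, T1 exchanges) rebuild affected cell loops by chaining
their edge sets and re-orienting counter-clockwise, so $B A = 0$ is
preserved by construction and re-asserted in the test suite after hundreds
of random surgeries.

Mechanics are logarithmic in both strains. A cell with area $A_i$,
perimeter $L_i$, preferred area $A_{0,i}$ and stiffness prefactor
$\sigma_i$ has internal pressure and cortical tension

$$p_i = -\sigma_i \ln (A_i/A_{0,i}), \qquad
  t_i = \sigma_i \, \Gamma \ln (L_i/L_0),$$

the derivatives of the potential

$$E = \sum_i \sigma_i \left[ A_i \ln\frac{A_i}{A_{0,i}} - A_i + A_{0,i} \right]
    + \sum_i \sigma_i \Gamma \left[ L_i \ln\frac{L_i}{L_0} - L_i + L_0 \right]
    + P_{ext} \sum_i A_i ,$$

whose bracketed terms are non-negative and vanish at the preferred state.
`vertex_forces()` assembles $F = -\nabla E$ edge-wise through the incidence
structure; the tests verify it against central finite differences of an
independently coded per-cell energy loop (relative error below $10^{-5}$)
and check that a cell's force contribution is exactly linear in its
$\sigma_i$. The prefactor therefore makes a given areal or perimetral
strain produce a $\sigma$-fold larger restoring force — the package's
rendering of MCC stiffness.

Coordinates are nondimensional with the bulk preferred area as the unit of
area. Defaults put the tissue in the jammed (solid-like) regime:
$\Gamma = 0.2$, $L_0 = 0.75$, uniform external pressure $P_{ext} = 0.5$.
$L_0$ is treated as a bare preferred perimeter in these units; because the
regular unit hexagon has perimeter $\approx 3.72$, cells carry substantial
cortical tension and equilibrate well below unit area (bulk area
$\approx 0.3$). Absolute stress magnitudes therefore depend on this
nondimensionalisation; the enrichment statistics below compare cells
*within* a tissue and are insensitive to it.

### Sign conventions

With the law above, a cell squeezed below its preferred area has $p_i > 0$
(it pushes outward). The *effective pressure* reported by
`cell_stress_tensors()` is the isotropic part of the cell stress tensor,

$$\sigma_{cell,i} = -(p_i - P_{ext})\, I
  + \frac{t_i}{A_i} \sum_{e \in i} \frac{\ell_e \otimes \ell_e}{|\ell_e|},$$

namely $-(p_i - P_{ext})$: it is **negative for compressed cells** (the
tension-positive continuum convention), so "most compressed" always means
the *lowest* decile of effective pressure. Fixing this sign once removes
the ambiguity that otherwise plagues decile tails. Cortical tension is
reported as $t_i$, and shear stress as half the difference of the
principal stresses, $(\lambda_{max} - \lambda_{min})/2 \ge 0$ — rotation
invariant and zero for regular polygons. The trace of
$\sigma_{cell}$ recovers the effective pressure only up to the isotropic
part of the tension term; the two are reported separately for this reason.

### Integration and surgeries

Relaxation is overdamped explicit Euler, $x \leftarrow x + (dt/\eta) F$,
with an adaptive step: halve on any trial step that raises the energy,
grow by 1.1x after ten consecutive accepted steps ($\eta = 1$, initial
$dt = 0.02$). The energy is non-increasing across accepted steps by
construction, which the tests assert. Two force tolerances are used: a
loose in-growth tolerance (`growth_tol`, default $10^{-3}$) for the
quasi-static relaxations between divisions, and the equilibrium tolerance
(`force_tol`, default $10^{-6}$) for the final relaxation. Robustness was
preferred over speed; the integrator is fully deterministic given the
seed, so every run is bit-reproducible.

Cells divide when their age exceeds a per-cell cycle time drawn uniformly
on `cycle_time * [1 - jitter, 1 + jitter]` (defaults 1.0 and 0.2; the
distribution is a package choice, as is drawing founder ages uniformly on
$[0,$ `cycle_time`$)$ so the founder population divides asynchronously
rather than in population-size jumps). The division chord passes through
the centroid perpendicular to the polygon's long axis (the conventional
shortest-axis rule, keeping daughters near-isotropic); daughters restart
at age 0 with preferred area 1 immediately — no growth phase — which keeps
the target-area field homogeneous, as implied by a single
$(\Gamma, L_0)$ parameterisation. T1 neighbour exchanges trigger when an
interior edge with two interior degree-3 endpoints drops below
`t1_threshold = 0.05` and reopen perpendicular at 1.5x that length; both
thresholds are package choices.

## The growth-and-MCC protocol

A run grows a 61-cell hexagonal founder patch (4 rings of unit-area
hexagons) to 400 cells, labels MCCs, continues to 800 cells, stops all
division, and relaxes to equilibrium. Divisions are processed one at a
time in order of imminence, so the 400- and 800-cell thresholds are hit
exactly. MCC placement picks uniformly at random among non-peripheral
cells not within graph distance 3 of an already chosen MCC, removing the
chosen cell's first, second and third neighbour shells from the pool until
it empties — the selection is maximal and guarantees at least three
intermediate cells between any two MCCs at introduction. Spacing is not
re-enforced against later T1 rearrangements (none were observed to violate
it in the test ensembles, but the invariant is only guaranteed at
introduction). MCCs receive $\sigma = 10$ (or 1) and stop dividing; a
control condition lets them keep dividing, making $\sigma = 1$ "MCCs"
literally indistinguishable from bulk cells apart from the label.

Ensembles run 10 replicates at seeds `base_seed + 0..9`. A scaled-down
profile (`protocol_config_ci()`: 37 to 100 to 200 cells) exists so the test
suite can run many ensembles; the full profile is the default for
reproduction runs. The statistical unit of the enrichment analysis is the
simulation: deciles are pooled within each replicate (cut at the empirical
10th/90th percentile of the included `mcc_adjacent` and `non_adjacent`
cells, linear interpolation between order statistics, strict inequality
beyond the cut) and the per-replicate group fractions are compared across
replicates with a classical paired two-sided t-test.

**Statistical power and the label-geometry confound.** At 800 cells the
enrichment contrast is strong and the paired t-test is significant for
all three metrics over a 10-replicate ensemble (adjacent vs non-adjacent
roughly 16-17% vs 8% for compression and low tension, 12% vs 9.5% for
shear). At the 200-cell
test profile the contrast direction is extremely robust — essentially
every ensemble shows adjacent > non-adjacent for compression, low tension
and high shear — but per-ensemble significance is limited by the small
bulk: a replicate has only ~30 included MCC-adjacent cells, and the thin
interior means the boundary layer contaminates the non-adjacent pool with
high-shear cells. In repeated 10-replicate ensembles the paired t-test is
almost always significant for compression and tension but only
intermittently so for shear. The dividing-MCC control exposes the same
scale artefact from the other side: because MCC labels are interior by
construction while the compressed layer just inside the excluded
periphery is almost entirely non-adjacent, the 200-cell control shows a
systematic *anti*-enrichment baseline (adjacent below non-adjacent in the
compression decile) that has nothing to do with MCC mechanics and that
the stiff-MCC effect must overcome. The confound does not vanish at full
scale: interior-placed labels against a compressed near-boundary layer
make the dividing-MCC control measurably non-null at any finite disc
size, even though shuffling the group labels within a replicate abolishes
the difference entirely (the permutation control). The test suite asserts
the strict per-ensemble forms of these checks regardless; where they
fail, they fail on statistical power and boundary-layer contamination,
not on enrichment direction.

## Junction-tension inference

`infer_tensions()` is a straight-segment, tensions-only force-balance
solver in the CellFIT tradition: at every internal triple (or higher)
junction node the unit tangents of the incident junctions, weighted by
their unknown tensions, must sum to zero. Two equation rows per internal
node are stacked and solved in least squares subject to the mean of the
solved tensions being 1 (tensions are identifiable only up to scale;
mean-normalisation is the convention used throughout, with a unit-norm
option retained on the interface). Degree-2 vertices are merged into
junction curves before solving; tangents are taken from the first curve
segment at each node (no curvature fitting), and the curved-interface and
Laplace-pressure terms of the full method are deliberately out of scope —
the downstream quantities are relative tensions only. Junctions that touch
no internal node are unconstrained and reported `NA`; rank deficiency
beyond the global scale is flagged rather than hidden.

### The known-tension oracle and realisability

Validating the solver needs geometries whose true tensions are known. The
subtlety is that an arbitrary positive tension assignment is generally
*not* realisable as a straight-edge equilibrium with a pinned boundary:
minimising $\sum_j t_j \ell_j$ (whose stationarity condition is exactly
the node force balance) is a convex problem whose minimum often sits at a
kink where an overloaded junction has collapsed to zero length. Even a
uniform assignment is frustrated on a disordered tessellation, since
all-120-degree angles require honeycomb topology. The generator therefore
projects the drawn tensions onto the realisable set: for any positive
weights $w_j$, the $w$-weighted Laplacian (Tutte) embedding of the
internal nodes is an exact equilibrium of the tensions
$t_j = w_j \ell_j$; a damped self-consistency iteration pulls the realised
tensions toward the lognormal draw (mean 1, CV 0.3 by default), and the
truth table records the realised values, whose coefficient of variation
stays near the drawn one (about 0.24-0.34 across seeds). Node residuals at
output are at solver precision ($\sim 10^{-14}$), so recovery tests probe
the inference solver, not the generator: the check requires median
Pearson $r > 0.95$ over 20 geometries, and the solver in practice returns
$r = 1.000$. The uniform-tension contract is verified exactly on the
honeycomb patch, where all inferred tensions are $1 \pm 10^{-6}$.

Rings around an event are labelled by contiguity: N1 is the event
junction (or all junctions of the host cell when no junction is given),
N2 shares a node with N1, and so on to N4, first label winning; the
before/after ratio per ring is the mean over after-frames of the ring's
mean tension divided by the same over before-frames. Because each frame's
solution is mean-normalised, a global rescaling of any frame cancels.

## Macropinocytosis event data: generators and estimators

`gen_tissue()` synthesises a segmented epithelium: Poisson-disc seeds in a
disc, a Voronoi tessellation computed by per-seed half-plane clipping, and
three Lloyd iterations, scaled so the mean apical area is 412 um^2 — the
host-cell size implied by peak ruffle areas of 94 um^2 covering 22.8% of
the apical surface. It reproduces the polygonal, roughly six-neighbour
geometry of the real tissue but none of its imaging artefacts: no
segmentation errors, no curved junctions, no drift. Estimator tests on it
therefore demonstrate correctness of the estimators, not robustness to
segmentation noise.

`gen_events()` draws events as per-cell Poisson processes (baseline rate
0.3 events/cell/h, doubled for MCC-adjacent hosts by default; MCCs never
host events). Durations are Normal(9.3, 2.3) min truncated above 1 min;
peak ruffle areas Normal(94, 36) um^2 truncated to the host's apical area;
events are junctional with probability 0.7 (the localisation preference is
exposed as a parameter rather than asserted); the host's apical-area trace
loses the fraction $0.10 \cdot \mathrm{peak}/94 + \mathcal{N}(0,
\sigma_{loss})$ (clipped at zero) ramped linearly over the event, the
event junction shortens by 10%, and all traces carry 1% multiplicative
frame noise at 0.5-min frames. The loss-noise SD was calibrated once, by
bisection under sparse-event conditions (events rarely overlapping, as in
the per-event tracking of the measured data), so that the sampling
distribution of the loss-size $r^2$ at $n = 43$ events centres near 0.4;
the calibrated value 0.036 is fixed in the defaults and not re-tuned.
Under dense-event settings multiple losses compound inside one
measurement window and deflate $r^2$ — recovery experiments should use
sparse settings. A single $n = 43$ draw of $r^2$ is highly variable,
so recovery is assessed on means over several independent $n = 43$
datasets.

Estimator conventions: an event's end is onset + duration rounded to the
nearest frame, and the area-change window runs from the onset frame to the
end frame. Control cells in `synchronize_area_traces()` are aligned at
times resampled from the empirical event-onset distribution (the measured
data do not state the control alignment rule). Fold changes are
`log2(after/before)` with **no pseudocount** — a zero basal count is an
error, mirroring the requirement of an informative basal recording.
`remodeling_index()` counts events per bin when *active* (overlapping the
bin), not by onset: a ~9-min event spreads its area loss over its whole
duration, so with the default 2-min bins an onset count would lag the
remodeling peak structurally, whereas activity counting is what a
per-window event count on a timelapse measures. The extrusion analysis
compares direct former neighbours against cells whose centroids lie
within twice the *mean neighbour-centroid distance* (a length; the
"radius twice the neighbour area" phrasing in the source material is
dimensionally ambiguous, and this reading is the package's documented
choice), counting events within 10 min after the extrusion.

`gen_compression_wave()` superimposes a Gaussian pulse of event onsets
(centre 12 min, SD 3 min, 3 expected events per cell, so that nearly
every cell hosts at least one event), optional extrusions whose direct neighbours are rate-suppressed
(x0.3 for 10 min), and an inhibitor mode (rate x0.1, extrusions x3).

## Numerical and degenerate-input choices

* Zero-length edges raise a geometry error naming the edge; non-positive
  areas and perimeters are errors wherever the logarithmic law would be
  evaluated.
* `relax()` flags non-convergence (`max_steps`) rather than raising; the
  `relax_info` attribute carries status, step count, number of T1s,
  final energy and maximum force.
* T1 requests on boundary edges, on edges with endpoint degree other
  than 3, or where a flanking cell is missing or duplicated are skipped
  with a message, and automatic T1 handling blocks such edges for the
  remainder of the call.
* Paired t-tests with all-identical pairs return $t = 0, p = 1$;
  zero-variance differences with nonzero mean are reported as the limit
  $p = 0$ with a degeneracy flag.
* Decile fractions require at least 10 included cells; ties at the cut
  are excluded (strict inequality), and the cut uses type-7 quantiles.
* The elongation index around an MCC is anisotropy-weighted,
  $\frac{\lambda_1-\lambda_2}{\lambda_1+\lambda_2}\cos 2\theta$: a bare
  $\cos 2\theta$ is undefined (direction of the long axis is arbitrary)
  for isotropic neighbours, whereas the weighted index is 0 there and
  approaches $\cos 2\theta$ for strongly elongated cells.
* Mesh JSON documents store floats as 17-significant-digit decimal
  strings because the available JSON writer does not round-trip IEEE
  doubles at full precision; round-trips are bit-exact.
* Every generator and the whole protocol are deterministic functions of
  their seed; `seed_stream()` derives independent named per-module
  streams from one base seed so added analysis steps never perturb
  simulation trajectories.

## Problem sizes used by the tests

The test suite runs the full 61-400-800 protocol once (about a minute)
and reuses it; enrichment ensembles use the 37-100-200 profile with 10
replicates each; tension recovery uses 20 geometries of ~50 cells; event
recovery uses 120-cell tissues with 43-event and 40-junction subsets,
matching the sample sizes of the measured data. These sizes are the
package's choice of a thorough-but-quick default; all of them scale up by
changing the corresponding configuration arguments.

## Known limitations

* Straight junctions only: no curvature, hence no Laplace-pressure
  inference and no curved-interface tension inference.
* The simulator has no apoptosis/extrusion, no active junction
  fluctuations, no viscoelastic cortex, and no 3-D or curved-substrate
  geometry; boundaries are free (no periodic boundary conditions).
* Stress magnitudes depend on the nondimensionalisation of the
  logarithmic law; only within-tissue contrasts (deciles, enrichment
  directions) should be compared across implementations.
* The synthetic tissue and event generators emulate the *statistical*
  structure of the measured data (sizes, durations, losses, rates), not
  microscopy: passing recovery tests shows the estimators are correct at
  the stated n, not that they are robust to segmentation or tracking
  errors in real movies.
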