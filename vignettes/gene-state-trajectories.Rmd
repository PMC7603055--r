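---
title: "Gene-state trajectories on SOM expression landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-state trajectories on SOM expression landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somscape)
```

`somscape` studies differentiation in *gene state space*: instead of
ordering cells along a trajectory, it portrays whole transcriptomes on a
self-organizing map (SOM), segments the resulting expression landscape
into modules, and traces differentiation as paths between the module of
stem-cell genes and the modules of tissue genes. This vignette explains
the models behind each stage, the parameters that matter, and the design
choices made where the method left room.

## Portrayal model

Expression is first centered per gene,

$$\mathrm{logFC}(g, c) = \log_2\!\big(x_{gc} + \delta\big) -
  \frac{1}{n}\sum_{c'} \log_2\!\big(x_{gc'} + \delta\big),$$

with pseudocount $\delta = 1$ by default (configurable; $\delta = 0$ is
allowed for strictly positive matrices). Row-centering makes every
portrait a picture of *relative* regulation: red means above the gene's
own average, blue below. We use base-2 logarithms, the convention of
expression analysis; the base only rescales all values.

The SOM is trained with **genes as samples** and **cells as vector
components**. Each of the $K = \text{rows} \times \text{cols}$ grid
nodes carries a prototype vector ("metagene") of length $n_{cells}$;
after training, a gene's best-matching unit (BMU) is the node with the
nearest prototype in Euclidean distance, and co-expressed genes collect
in the same or neighboring nodes. The $K$ prototype values of one cell
form that cell's portrait.

Training choices, all deterministic:

* **Batch scheme.** Every epoch reassigns all genes to BMUs and
  recomputes each prototype as the Gaussian-neighborhood-weighted mean
  of the gene profiles. Batch training has no sample-order stochasticity
  and makes results bit-reproducible given the seed.
* **Neighborhood.** Gaussian kernel on grid distance; the radius decays
  linearly from $\max(\text{rows}, \text{cols})/2$ to `radius_final`
  (default 0.5) over the epochs. A near-zero final radius turns the last
  passes into plain cluster means; the default keeps a slight smoothing
  that preserves the topological ordering of the map.
* **Initialization.** Prototypes start on the plane spanned by the first
  two principal components of the gene cloud (rank-1 data uses the first
  component only); only degenerate data falls back to seeded uniform
  noise. PCA initialization makes map orientation stable across runs.
* **Quantization error.** The mean gene-to-BMU distance is recorded
  after every epoch's update; this post-update series is non-increasing
  in practice and is asserted in the test suite. The value at
  initialization is *not* part of the series — a wide first smoothing
  pass may be worse than a PCA start.

The package default grid is 60 × 60 (3600 metagenes), a resolution at
which expression modules of data sets with tens of cell types are well
separated; the test suite and the synthetic default use 20 × 20, which
resolves the three planted modules comfortably at a fraction of the
cost.

The signed-log scale used for capacities and "coast-line" coloring is

$$\mathrm{loglogFC}(x) = \mathrm{sign}(x)\,\log_2(1 + |x|).$$

A literal signed $\log|x|$ diverges at $x = 0$ and *reverses* order on
$(-1, 1)$; the $1 + |x|$ form keeps the function odd, strictly
increasing, total on the reals, and zero exactly at fold change one, so
overexpression stays red, underexpression blue, and the coast-line
white — the stated purpose of the scale.

## Segmentation and labels

Overexpression **spots** are detected per group portrait by an upper
quantile threshold (default 0.98) followed by 8-connected components;
each spot's kernel is its highest node. The quantile rule is a
documented, pluggable stand-in for distance-metric spot clustering — the
original spot criterion was not fully specified, and thresholding plus
connectivity reproduces its visible behavior (compact peripheral spots).
Spot detection is monotone in the quantile by construction.

The **space-filling segmentation** runs k-means (Lloyd, k-means++
seeding, best of 10 seeded restarts) on all prototype vectors, k = 32 by
default: enough clusters that each spot receives its own module plus a
margin of low-variant modules, while far larger k mostly produces empty
or redundant clusters. Letters are assigned by descending mean
variance-map value — "A" is the most variant module, and 32 clusters run
"A"…"Z", "A1"…"F1". One module (minimal mean variance) is tagged
`invariant`; modules holding a spot kernel are `spot-variant`; the rest
are `low-variant`. Exactly one invariant module exists by construction.
8-connectivity (Moore neighborhood) is used throughout for spatial
adjacency; the choice matters little on space-filling segmentations and
matches the visual contiguity of portrait spots.

## Gene-state trajectories

Neighboring modules form a network. For a lineage (stem + progenitors +
target tissue cells), edge capacities are

$$c(m_1, m_2) = \bar h(m_1) + \bar h(m_2) - 2\min_m \bar h(m),$$

where $\bar h(m)$ is the module's mean loglogFC in the lineage mean
portrait. The $-2\min$ shift makes capacities non-negative (module
means are routinely negative) while preserving their order. Which cells
weight the capacities is genuinely open; we default to the mean over
all cells of the lineage and expose the portrait argument.

"Connect source and sink along edges of maximum cumulative weight" has
two readings, and both are implemented:

* `max_capacity_path()` — the **widest path** (maximum bottleneck),
  found by max-min Dijkstra relaxation. Among equal-bottleneck paths the
  one with the larger capacity sum wins, then lexicographic order; the
  tie-break is a longest-path subproblem solved by branch-and-bound
  seeded with a Dijkstra widest path and budgeted, so large networks
  degrade gracefully to a valid widest path. This is the default: it is
  polynomial and well-defined on any network.
* `max_sum_path()` — the **maximum capacity sum** over simple paths, an
  NP-hard variant solved exactly by branch-and-bound and therefore
  capped at 40 nodes.

`topographic_path()` instead treats a portrait — typically the stem
minus tissue difference portrait, a Waddington-style landscape — as
elevation. Heights are rescaled $h'(v) = h(v) - \min h + \varepsilon$
with $\varepsilon = 10^{-6}$ (the floor prevents zero-cost plateaus
from degenerating into arbitrary wandering), and a step between
8-neighbors costs its geometric length (1 or $\sqrt 2$) times the mean
endpoint height. Dijkstra yields the least-cost "valley" path; the cost
is invariant to adding a constant to the height, and the test suite
checks the implementation against an independent Dijkstra on the
explicit edge list.

## Cell pseudotime

Cells are ordered by a spectral **diffusion pseudotime**: a kNN graph on
the cells' metagene portraits (k = 15) with Gaussian weights and
per-cell adaptive bandwidth (distance to the ⌈k/2⌉-th neighbor),
symmetrized by the maximum; the normalized transition operator is
eigendecomposed and cells are embedded in the top 10 non-trivial
components scaled by $\lambda/(1-\lambda)$, which aggregates diffusion
over all path lengths. A cell's pseudotime is its distance from the
root-cell centroid in that embedding, shifted and scaled so the root
minimum is exactly 0 and the global maximum exactly 1 (non-root cells
marginally closer to the centroid than any root are clamped to 0).

This deterministic spectral formulation replaces simulated random-walk
pseudotime; it is testable (no Monte-Carlo variance), and the interface
is pluggable should another estimator be preferred. Branch membership is
taken from cell annotations, not inferred: lineages in this workflow are
annotation-driven. On generator output the estimator's rank agreement
with the latent time is asserted in the test suite (Spearman ≥ 0.9 for a
single lineage, n = 500). Module profiles along pseudotime use LOESS
(tricube local regression, span 0.5, degree 1) purely as a guide curve;
fewer than 5 cells yield points only.

## RNA velocity on the grid

Per gene, the degradation/splicing ratio $\gamma$ is fitted by least
squares through the origin of $u$ on $s$ using the cells in the extreme
quantiles (default 0.05 per tail) of spliced abundance — the cells
closest to their steady states, where $u = \gamma s$ holds. The velocity
$v = u - \gamma s$ is positive during induction, negative during
repression. Genes with no spliced signal are flagged unfittable and
excluded. Full kinetic models (per-gene transcription and splicing
rates) are out of scope.

A metagene's velocity is the mean velocity row of its member genes. The
step from that high-dimensional vector to a 2-D grid arrow is the one
methodological gap the package had to fill, and it adopts the
neighbor-difference correlation principle used for cell embeddings,
transposed to the SOM: the weight of neighbor $n$ of node $m$ is the
Pearson correlation between $m$'s velocity vector and the prototype
difference $p_n - p_m$ (undefined correlations count as 0), and the
arrow is the positively-weighted **convex combination** of the unit
directions to the neighbors. Arrow length is therefore at most 1 grid
unit and shrinks where pulls balance — which is exactly what happens at
attractor kernels, so `detect_attractors()` can use a magnitude
tolerance (default 0.3) combined with a strict local maximum of summary
expression. Velocity magnitudes across metagenes are not comparable
after averaging different member counts, which is why direction, not
speed, is the interpretable quantity.

One property of this projection deserves emphasis: it produces an
**attractor field**, not a uniform source-to-sink flow. Genes being
induced point toward their tissue spot; genes being repressed have a
future profile that is *more* specific to the stem spot (their residual
expression concentrates there in relative, logFC terms), so arrows on
the stem side of the landscape point into the stem spot. The two basins
meet at a watershed between the spots. Averaging arrows over a region
symmetric between a stem and a tissue spot therefore cancels to roughly
zero by construction; the meaningful directional statement — made by
`arrow_projection_toward()` and asserted in the tests — is that the
transition zone around a tissue spot flows *into* that spot (mean
projection toward its kernel well above zero), while watershed
trajectories (`velocity_trajectories()`, forward Euler on the bilinearly
interpolated field, step 0.5 grid units) partition starts into basins.

## The synthetic generator

`generate_differentiation()` emulates a stem → multi-tissue snapshot
with full ground truth. Each cell draws a latent time $t \sim U(0,1)$
and a lineage; gene modules are one stem block, one block per lineage,
and an invariant background (65% of genes by default, the share commonly
seen in whole-organism maps). Mean expression is
$\mu = b_g (1 + a_g w(t))$ with quadratic activation $w(t) = (1-t)^2$
for stem genes and $t^2$ for own-lineage tissue genes — smooth curves
that produce the gradual "lava-lamp" transition of real differentiation;
the exponent is configurable. Counts are negative binomial with size
0.5 (strong overdispersion, a realistic stress test; `Inf` gives the
Poisson limit, `NULL` returns exact means for oracle checks).

Spliced/unspliced abundances follow first-order kinetics
$du/dt = \alpha(t) - \beta u$, $ds/dt = \beta u - \gamma s$ in closed
form, with transcription switching at $t = 0.3$ (on for tissue modules,
off for stem). $\beta = 1$ fixes the time unit; $\gamma \sim U(0.5,
1.95)$ excluding a band around 1 keeps the two-exponential solution
well-conditioned; $\alpha_{on} = b_g \gamma$ places the active steady
state at the baseline; the kinetic span of 4 time units brings switched
genes close to their new steady state by $t = 1$. The generator returns
the exact means and true $ds/dt$ alongside the sampled counts, so
steady-state fits and velocity signs can be validated against the ODE
ground truth while the noisy layers exercise the full pipeline.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, library-size variation, bursty transcription, transient
progenitor-specific programs, or realistic organism biology. Passing
tests on this data demonstrate that the algorithms recover planted
structure under heavy count noise — not that they are robust to every
artifact of real single-cell chemistry.

## Problem sizes and numerical choices

The test suite and the acceptance script run the synthetic default —
800 cells × 2000 genes, two lineages, 20 × 20 map, 20 epochs — plus many
small closed-form fixtures; path oracles enumerate all simple paths on
graphs of up to 10 nodes. Ties in BMU assignment break to the lowest
row-major node index; k-means restarts that produce empty clusters are
re-seeded; eigenvalues within $10^{-12}$ of 1 are guarded in the
diffusion scaling; velocity vectors with RMS below $10^{-10}$ are
treated as exactly zero so exact steady-state data yields a vanishing
field.

## Serialization

All artifacts are plain text: MTX + TSV sidecars and dense TSV for
matrices (written at `%.17g`, lossless for doubles), CSV for
annotations and pseudotime, TSV for segmentations and vector fields,
JSON for trajectories, YAML for configurations, and a TSV/YAML bundle
directory for trained models. PNG portrait rendering (one pixel per
node, symmetric blue–white–red) is the only binary output.

## Known limitations

* Gene-state paths are single source → sink chains; branched gene-state
  trees are not constructed.
* The widest-path tie-break is exact only within its search budget on
  very dense equal-capacity networks.
* GSZ profiles use the metagene (BMU prototype) expression as each
  gene's profile, the portrayal-level approximation; gene-level GSZ
  would require keeping the full expression matrix alongside the model.
* The velocity projection inherits the steady-state assumptions of the
  $\gamma$ fit; transient or multi-rate kinetics bias both the fitted
  slopes and the arrows.
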