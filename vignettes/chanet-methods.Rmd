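---
title: "Connectivity hyperalignment and network topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity hyperalignment and network topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chanet)
```

## The problem

Functional brain topography varies across individuals even after careful
anatomical registration: the vertex that carries a given fine-grained signal
in one person is not the vertex that carries it in another.  Any analysis
that compares vertex-level quantities across subjects — inter-subject
correlation, vertex-level network metrics, prediction of a trait from
fine-scale features — is degraded by this residual misalignment.

Connectivity hyperalignment (CHA) addresses this by aligning subjects in a
*functional* space.  Each subject is summarized by a connectome **C**: the
matrix of Pearson correlations between a set of connectivity targets (the
region-averaged time series of a parcellation, `make_targets()`) and every
vertex's time series (`make_connectome()`).  Column *v* of **C** — the
*connectivity profile* of vertex *v* — characterizes that vertex by whom it
talks to, which is comparable across subjects even when vertex identities
are not.  Local orthogonal (Procrustes) transforms then rotate each
subject's vertex basis so that profiles line up across subjects.

`chanet` implements this pipeline end to end and studies its downstream
consequences for graph-theoretic network analysis, exercised on synthetic
multi-subject cohorts with known ground truth.

## Alignment model

The alignment primitive is the orthogonal Procrustes problem: given two
matrices with matched rows, `procrustes(X, Y)` returns the orthogonal `R`
minimizing `||X R - Y||_F`, via the SVD of `X'Y` (`R = U V'`).  Reflections
are permitted and no scaling is applied — scale is handled by the
surrounding z-scoring conventions, so admitting an isotropic scale would be
confounded with them.

A common template is fit by `fit_template()` with a three-pass scheme:
pass 1 initializes with subject 1 and folds in each subsequent subject by
aligning it to the running mean; passes 2 and 3 realign every subject to
the current mean and re-average.  The template is defined only up to a
global orthogonal transform (its *gauge*): if every subject is rotated the
template rotates with them.  For this reason the template is normalized by
column-centering plus a single global root-mean-square scale.  A
column-wise z-scoring here would look natural but is **not**
gauge-equivariant (z-scoring does not commute with right-multiplication by
an orthogonal matrix unless the column covariance is the identity), and
would make the fitted template depend on subject order beyond the gauge.
With the equivariant normalization, templates fit under different subject
orders agree up to an orthogonal transform to machine precision, which the
test suite asserts.

Two scopes are offered:

* **ROI CHA** (`fit_rcha()`): one Procrustes transform per parcellation
  region; the whole-cortex mapper is block-diagonal and never mixes
  vertices across regions.
* **Searchlight CHA** (`fit_scha()`): one transform per searchlight
  (Euclidean neighborhood from `build_searchlights()`), with all local
  transforms summed into a sparse whole-cortex mapper.  Overlapping
  searchlights sum, which scales each column by its overlap count; the
  scaling is removed by re-z-scoring mapped columns (`apply_mapper()` with
  `rezscore = TRUE`).  The plain-sum aggregation is isolated behind this one
  function; when searchlights tile regions exactly, sCHA reproduces rCHA
  after dividing by the overlap count, a correspondence the tests verify.

Mappers are fit on the training run only and applied to held-out runs —
both to connectomes (for ISC validation) and to raw time series (for all
downstream network analysis).  Alignment quality is measured by the
inter-subject correlation (ISC) of connectivity profiles
(`isc_profiles()`): for each vertex, the mean over subject pairs of the
correlation between profiles, averaged over vertices.

A caveat discovered during development and reflected in the tests: because
the connectivity targets are region means of the *same* data, rotating a
region also rotates its target series.  Even noise-free connectomes are
therefore not exactly rotated copies of one another, and mapped connectomes
converge to high but not perfect cross-subject agreement.  The time-series
blocks, by contrast, are exactly rotated copies, and exactness tests are
formulated on them.

## Synthetic cohorts

`synth_config()` / `generate_cohort()` produce the study conditions. For
each region, `n_latents` unit-variance latent sources are mixed into vertex
patterns whose block structure follows planted module labels (each module
has one dominant latent plus Gaussian base loadings of sd 0.3). Subject `s`
observes `template %*% R_s + noise`, with `R_s` drawn per scope unit —
whole regions, or sub-region spatial patches of extent `searchlight_radius`
— either uniformly from the orthogonal group (QR of a Gaussian matrix with
sign-fixed diagonal; the default) or as partial rotations
(`rotation_strength = tau`, a Cayley transform of a skew-symmetric Gaussian
matrix, approaching the identity as `tau -> 0`). Partial rotations emulate
the moderate residual misalignment left by anatomical surface registration,
which is the baseline condition alignment is compared against in practice.
Runs share rotations but redraw latent series and noise. Every stochastic
ingredient draws from its own stream keyed by (subject, run, purpose) via
`substream_seed()`, so enlarging a cohort never changes existing subjects'
data.

Vertices are laid out on a unit-spaced planar grid (a degenerate 3-D grid),
one compact block per region, with wide gaps between regions so Euclidean
searchlights are spatially meaningful and never straddle regions at
realistic radii.

**Trait coupling.**  When `trait_effect_size != 0`, each subject's
within-module mixing weights are modulated *antisymmetrically*: in region
`r`, module `m` is scaled by `1 + delta_r * sign_m` with alternating signs
and `delta_r ~ N(0, 0.3)` per subject.  The trait is a standardized linear
readout, `trait = effect * sum_r(delta_r * lambda_r)/sd + N(0, 1)`.  The
antisymmetry is essential: with independent per-module multipliers the
trait leaks into rotation-*invariant* statistics (the data Gram spectrum
encodes module strengths without vertex identity), so misaligned data
predict the trait as well as aligned data and the generator would fail to
emulate the phenomenon under study — trait information carried by
vertex-identified fine-scale topography.  With the antisymmetric design the
unordered spectrum is uninformative about the trait's sign and only
spatially aligned features support a linear readout.  With
`trait_effect_size = 0` the modulation is disabled entirely, giving a pure
alignment benchmark in which all subjects share the template's
representational geometry exactly (the time-side Gram `D D'` is invariant
under the planted rotations), which several exactness tests rely on.

What the generator deliberately does **not** model: hemodynamics,
autocorrelated noise, spatial noise correlation, geodesic cortical
geometry, or any nonlinear trait coupling.  Passing tests therefore
demonstrate the pipeline's correctness and the direction of its effects
under the stated generative assumptions, not performance on real
resting-state data.

## Networks and metrics

Coarse networks correlate region-mean series (`coarse_network()`); fine
networks correlate one region's vertex series (`fine_network()`); weighted
matrices are symmetric with zero diagonal.  `threshold_density()` binarizes
by keeping the `floor(d * N(N-1)/2)` strongest links by *signed* weight
(negative correlations are thereby excluded at realistic densities), with
ties broken by index order so edge sets are deterministic and nested across
densities.  The default density is 0.15 at full scale; the analysis scripts
use 0.2–0.3 because the scaled-down graphs are small and must stay
connected.

Metric definitions follow the standard brain-connectivity conventions:
characteristic path length over reachable ordered pairs, mean nodal
clustering (degree < 2 contributes 0), global efficiency with disconnected
pairs contributing 0, degree assortativity, seeded Louvain modularity (best
of 20 restarts), and small-worldness sigma against degree-preserving
rewired nulls (10 nulls, 10·|E| swap attempts).  Local metrics: degree,
eigenvector centrality (principal eigenvector scaled to max 1; under
spectral degeneracy, e.g. disconnected graphs, the reported vector is the
deterministic symmetric-eigendecomposition solution), closeness with the
reachable-fraction scaling, nodal clustering, k-core score, and
participation coefficient.  All of these are validated against hand-written
brute-force oracles (BFS, triangle enumeration, exhaustive peeling, direct
formula sums) on hundreds of small random graphs.

`metric_pattern()` assembles the subject-by-feature matrices used for
prediction: per-region recomputation of a global measure on each region's
fine graph (one value per region), or a local metric per vertex within a
region.

## Multilayer community structure

Subjects are layers.  `multilayer_modularity()` maximizes

    Q = (1/2mu) [ sum_l sum_ij (A^l_ij - gamma k^l_i k^l_j / 2m_l) delta(c_il, c_jl)
                  + omega * sum_i sum_{l != l'} delta(c_il, c_il') ]

with categorical (all-to-all) interlayer coupling and `2mu` equal to the
total intralayer edge weight plus the total coupling weight, so Q is
comparable across layer counts.  The optimizer is a greedy node-layer
local-move sweep (seeded shuffled order) alternated with community-merge
passes, restarted from scratch `n_restarts` times; every accepted move
strictly increases Q.  On instances small enough for exhaustive enumeration
of all label partitions the seeded optimizer attains the global optimum in
at least 95 of 100 runs, which the acceptance suite checks.  Negative
weights are clipped to zero by default before forming the modularity matrix
(the configuration-model null assumes nonnegative weights); `negative =
"keep"` is available.  Labels are canonicalized by first appearance so runs
are comparable.

Under this normalization Q is *not* monotone in omega: co-labeling a node's
copies earns coupling reward, so for layers with consistent structure the
optimal omega in a sweep (`sweep_gamma_omega()`) is positive, while layers
with contradictory partitions and low cross-layer label overlap push the
selection to omega = 0.  The test fixture for the latter uses two perfect
matchings with no shared pair, where per-layer modularity (2/3) exceeds the
best attainable relative coupling payoff.

`allegiance_matrix()` averages co-classification across layers (entries are
exact multiples of 1/L); `recruit_integrate()` summarizes each node's mean
allegiance within and outside its predefined region, excluding self-pairs,
with singleton regions defined to have recruitment 1.  On the synthetic
cohorts the detected fine-scale communities reflect the full correlation
structure — the planted modules *and* the shared base loadings — so
recruitment against the planted labels is reported descriptively rather
than expected to reach 1.

## Prediction

`fit_ridge()` standardizes features by training statistics (population
variance) and solves the penalized normal equations via SVD, which at
`alpha = 0` degrades gracefully to the minimum-norm least-squares solution;
the intercept is the training mean.  The default `alpha = 1` on
standardized features is a conventional choice; nothing in the pipeline is
sensitive to it at order-of-magnitude level.  Evaluation is strictly by
run: models are fit on run-1 feature patterns and tested on the remaining
runs (`evaluate()`, MSE).  `chance_baseline()` refits on permuted training
labels to produce the null MSE distribution, and `compare_conditions()`
implements the paired t test with Bonferroni correction and the sign-flip
permutation test (exhaustive when `n <= 20`) with Benjamini–Hochberg
step-up.

## Study-condition sizing

The full-scale study this emulates used 200 subjects, 1,200-frame runs,
59,412 vertices and 360 regions.  The cohorts here are scaled so the entire
suite runs in minutes on one CPU, with sizes chosen to preserve the
*regimes* in which each effect lives rather than raw dimensions:

* **ISC validation**: 8 subjects, 4 regions × 16 vertices, 150 frames,
  noise sd 0.5, region-scope rotations.  The alignment gain is large and
  robust here.
* **Multilayer Q**: 16 subjects (layers), 2 regions × 16 vertices.  The
  interlayer coupling total `omega·N·L·(L-1)` grows quadratically in the
  layer count while intralayer weight grows linearly; with few layers the
  coupling term — the channel through which alignment raises Q — is
  negligible.  Sixteen layers put the coupling at roughly a quarter of the
  total weight, qualitatively matching a many-subject study at
  `omega = 0.1`.  The per-cohort direction at these sizes is modest (the
  aligned mean Q gain is consistent, individual cohorts can go either way).
* **Prediction**: 20 subjects, 8 regions × 16 vertices, 150 frames, noise
  sd 1.5, *searchlight-scope* misalignment with searchlight CHA.  Two
  regimes must be avoided: with whole-region uniform rotations the
  unaligned baseline becomes an artificially strong subject fingerprint
  (enormous, run-stable cross-subject feature spread that ridge memorizes —
  even oracle alignment then looks worse), and with near-identity rotations
  there is nothing for alignment to fix.  Local patch misalignment
  corrected by searchlight CHA — the method's primary variant — is the
  regime in which the alignment gain is real and reproducible, and it is
  also the regime the method was designed for.

## Numerical and degenerate-input conventions

* Zero-variance series correlate as 0 with a warning (never NaN), keeping
  downstream matrices finite.
* z-scoring uses population variance throughout (consistency with the
  Procrustes normalization).
* Procrustes on rank-deficient cross-products returns `U V'` with an
  arbitrary orthogonal completion in the null space; the action on the data
  is well-defined, and exactness tests use full-rank configurations.
* Disconnected graphs: path length is computed over reachable pairs with a
  warning; closeness and efficiency use the conventions above; isolated
  nodes get closeness and participation 0.
* Density thresholds that keep zero edges are an error; tie-breaks are
  deterministic.
* All vertex/region indices are 0-based in every file format; in-memory R
  code uses 1-based column indices internally.

## Known limitations

The generator's linear trait coupling is a modeling choice for
testability, not an empirical claim about how any cognitive variable
relates to topology.  Euclidean searchlights stand in for geodesic ones;
an adapter seam (`read_neuroimaging_timeseries()`) marks where real
surface data would enter.  The multilayer optimizer is exact only in the
exhaustively-checkable regime; at scale it inherits the usual limitations
of greedy modularity maximization.  Recruitment/integration interpretation
depends on how well detected communities track the predefined partition,
which on these synthetic cohorts is partial.
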