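---
title: "Methods: weighted brain-network analysis in caninefc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted brain-network analysis in caninefc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninefc)
```

## The analysis in one paragraph

`caninefc` analyses resting-state functional connectivity in a 30-region
canine brain atlas. Each subject contributes a T x 30 matrix of regional
BOLD time series (TR = 2 s, band-passed to 0.01-0.1 Hz). Pairwise
Pearson correlations give a 30 x 30 connectivity matrix per subject; the
weakest and all negative correlations are removed by thresholding the
matrix to fixed network densities (20% to 50% in 5% steps), and the
surviving correlations are Fisher r-to-z transformed. On each weighted
graph we compute strength (weighted degree), characteristic path length
(Lp), global efficiency (Eglob), Onnela clustering (Cp), local
efficiency (Eloc) and small-worldness (sigma), then average each metric
across the density grid. Patient-control differences are tested with
Mann-Whitney U at three levels (global metrics; nodal metrics in an
a-priori anxiety circuit — amygdala, frontal lobe, hippocampus,
mesencephalon, thalamus — plus the vermis as negative-control region;
and region-level connection strengths within the circuit), each level
corrected with Benjamini-Hochberg FDR. Finally, network features are
correlated with the 13 C-BARQ behaviour scales across patients using
Spearman rank correlation.

## Network construction

* **Pearson correlation.** `correlation_matrix()` is plain `stats::cor`
  with explicit failure on zero-variance regions. The raw matrix is kept
  alongside the thresholded networks because the connection-level
  analysis needs the z values at every density.
* **Density thresholding.** At density d the `k = round(d * 435)`
  largest strictly positive correlations are kept (`435 = 30*29/2`).
  Negative correlations are discarded *before* ranking — only positive
  weights enter the connectome — not ranked by absolute value. Two
  conventions had to be fixed where common toolboxes are silent:
  `k` uses round-half-away-from-zero, and ties at the cutoff are broken
  by lexicographic (row, column) order. Both are arbitrary but
  deterministic, which matters more than the choice itself: edge sets
  are then exactly nested across densities, and repeated runs are
  bit-identical.
* **Fisher transform.** `atanh` on the surviving weights, zeros stay
  zero. Because `atanh` is strictly increasing, thresholding before or
  after the transform selects the same edge set (asserted in the test
  suite). Weights at 1 (numerically degenerate correlations) are
  clipped to `1 - 1e-7` with a warning.

## Graph metrics

Path-based measures use edge lengths `1/w`, so stronger connections are
shorter. Shortest paths are computed by a dense Floyd-Warshall kernel
(compiled) on the 30 x 30 length matrix rather than by repeated calls
into a graph library: the calibration experiments and the rewired null
ensembles evaluate on the order of 10^5 small dense graphs, where
per-call graph-object construction dominates the runtime. The kernel is
validated in the tests against exhaustive path enumeration on all
graphs up to 6 nodes and against `igraph::distances`.

* **Lp** — nodal value: mean finite distance to the other 29 nodes;
  global value: mean over all ordered finite pairs. Unreachable pairs
  are *excluded* from the mean (and counted) rather than imputed with a
  surrogate distance; at 20% density isolated nodes do occur and an
  imputation constant would dominate the statistic.
* **Eglob** — mean inverse distance with `1/Inf = 0`; robust to
  disconnection by construction.
* **Cp** — Onnela's geometric-mean form on weights normalised by the
  network maximum; nodes with fewer than two neighbours score 0. The
  normalisation keeps nodal values in [0, 1] and makes sigma invariant
  to uniform weight rescaling.
* **Eloc** — efficiency of the subgraph induced by a node's neighbours
  (node removed), using the original weights. Of the several weighted
  local-efficiency variants in circulation this is the simplest that is
  directly testable against a brute-force oracle.
* **sigma** — `(Cp/Cp_rand) / (Lp/Lp_rand)` against degree-preserving
  Maslov-Sneppen surrogates: the binary topology is rewired with 10
  edge swaps per edge (via `igraph::rewire`), and the original weights
  are reassigned to the rewired edges in random order. 100 surrogates
  per network by default; surrogates with undefined Lp are redrawn up
  to a retry cap. Sigma is computed per density and then
  density-averaged, like every other metric, rather than on an averaged
  network — consistent with treating each density level as a separate
  graph family.

Density-averaged values are arithmetic means over the seven levels;
nodal values missing at a level (disconnected node) are dropped from
that node's average.

## Group statistics

* **Mann-Whitney U** is reported with the `min(U1, U2)` convention.
  The exact two-sided p uses the tie-free Wilcoxon null distribution;
  with ties the null is a label permutation of the observed data (1e5
  resamples by default). The normal approximation applies tie-corrected
  variance and a continuity correction and agrees with the permutation
  null to within 0.01 at the default group sizes (13 vs 25).
* **FDR families.** Global level: across the tested global metrics.
  Nodal level: within each metric, across the six regions (five circuit
  regions + vermis) — the most literal reading of "correcting between
  nodes". Connection level: across the tested region pairs. Homotopic
  (L-R) pairs are excluded from the group comparison by default and
  available behind a flag, since the homotopic amygdala connection
  belongs to the correlation analysis rather than the contrast.
* **Hemisphere averaging.** Nodal metrics of bilateral regions are
  averaged over L and R before testing; midline regions (mesencephalon,
  diencephalon) pass through. Region-level connection strengths average
  all node pairs spanning the two regions (4, 2 or 1 pairs), with
  sub-threshold zeros included as genuine zeros: a z of zero *means*
  the connection stayed below threshold across the density range.
* **Spearman correlations** use midranks; the two-sided p comes from
  the exact permutation distribution when at most 9 usable pairs remain
  and from the t approximation otherwise. Missing behaviour scores are
  deleted pairwise with the usable n reported; results with fewer than
  5 usable pairs are marked not-computed — the smallest family actually
  analysed (familiar dog aggression) has 8 usable rows, and anything
  below 5 is statistically meaningless. FDR is applied within the
  connection-strength family only by default (the convention this
  analysis design prescribes); `fdr_scope = "all"` corrects everything.
  Trainability's reversed polarity (higher = better) is documentation
  metadata; scores are never numerically flipped.

## The synthetic-cohort generator

Scan data from clinical canine cohorts are rarely shareable, so the
package ships a generator that emulates the *statistical* structure of
such a cohort and makes every downstream stage testable.

* **Signal model.** Each subject's time series is a multivariate
  Gaussian draw (Cholesky factor of the group's target correlation
  matrix) filtered per column with an ideal zero-phase band-pass
  (FFT-domain brick wall, 0.01-0.1 Hz at TR = 2 s) and re-standardised.
  The brick-wall filter was chosen over an IIR design because it is
  exactly zero-phase and exactly band-limited — out-of-band power is
  zero by construction — and avoids filter transients on short (T =
  180) series. Applying the same linear filter to every column leaves
  the cross-regional correlation structure unchanged in expectation.
* **Target correlations.** A compound-symmetric baseline (default 0.3,
  a typical mean level for band-passed regional BOLD) plus implanted
  region-level deltas for the patient group: by default +0.25 on the
  six hyperconnected circuit edges and -0.25 on
  hippocampus-mesencephalon, expanded to all constituent node pairs.
  When the implanted pattern leaves the matrix indefinite it is
  projected onto the nearest correlation matrix (Higham alternating
  projections, `Matrix::nearPD`). A simple eigenvalue clip was tried
  first but distorts the implanted edges by up to 0.06; the projection
  keeps the worst-case distortion below 0.05, and the generator fails
  (naming the offending edges) if any implanted edge is distorted
  beyond that. The realised contrast is therefore slightly shrunk
  (about 0.20-0.24 on the correlation scale), which the recovery tests
  measure against.
* **Scan length.** T defaults to 180 volumes (6 min at TR = 2 s), a
  typical resting-state duration that gives stable 30 x 30
  correlations; T is a free parameter of the emulation.
* **Behaviour scores.** For each configured link (scale, network
  feature, target Spearman rho) the patient's feature value is passed
  through a Gaussian-copula construction: the feature's normal scores
  are mixed with latent Gaussian noise at Pearson correlation
  `r = 2 sin(pi * rho_s / 6)` — the classical identity that makes the
  population Spearman correlation exactly `rho_s` for bivariate
  Gaussians — and mapped monotonically into the 0-5 C-BARQ range. This
  replaces a simulation-based noise calibration with a closed form that
  is exact in population and deterministic. Unlinked scales are
  independent draws on the same scale. Measurement noise (`noise_sd`)
  defaults to 0 so the implanted structure is exactly the stated one;
  positive values attenuate all correlations by `1/(1 + noise_sd^2)`.
* **What the generator does not emulate.** Scanner artefacts, motion,
  anesthesia effects, breed differences, spatial autocorrelation, and
  any voxel-level structure. Passing recovery tests on this generator
  shows the *pipeline* is correct and adequately powered under clean
  conditions; it does not validate the biological findings on real
  scans.

## Calibration and problem sizes

The test suite runs the pipeline at the default cohort conditions (25 + 13
subjects, 30 regions, T = 180): a 500-cohort null simulation checks
that the vermis control region is flagged in at most 7% of cohorts at
nominal 0.05; a 50-seed recovery simulation checks that each of the
seven implanted circuit edges is recovered with the correct sign in at
least 80% of cohorts; 100-seed simulations check that behaviour links
with target rho 0.8-0.9 are recovered within the expected sampling
band. Small-worldness uses 100 surrogates per network in the
full-scale checks and 20-50 in quick property tests. Graph-metric
correctness is established on all random graphs up to 6 nodes (200
seeds) against exhaustive path enumeration, and the statistical
primitives against full-enumeration nulls and the step-up definition of
BH.

## Known limitations

* Exact Mann-Whitney inference with ties falls back to Monte-Carlo
  permutation rather than the exact tie-adjusted distribution.
* The generator's compound-symmetric baseline is a deliberate
  simplification; real connectomes have community structure, which
  would mainly affect the absolute level of clustering, not the group
  contrasts implanted on top.
* Sigma depends on the null ensemble size; with 100 surrogates the
  Monte-Carlo sd of a single subject-density sigma is a few percent,
  which group averaging reduces well below the margin of the
  small-world checks.
* Region 13/27 of the atlas carries its conventional label ("cerebral
  hemisphere"); the package treats all regions purely as graph nodes.
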