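---
title: "Graph-theoretic analysis of drug-induced brain network reconfiguration: methods and design choices"
author: "netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

netpharm implements a binary graph-theoretic pipeline for pharmacological
resting-state fMRI studies, starting from extracted regional (ROI) time
series. Voxel-level preprocessing (realignment, denoising, normalization,
atlas construction) is out of scope: the pipeline's inputs are T x N
tables of regional signals, one per subject-session.

The stages are:

1. **Band-pass filtering** of each regional signal (zero-phase Butterworth,
   default order 2, applied forward-backward). Typical bands are
   0.01-0.15 Hz for human data at TR ~ 1.8 s and 0.01-0.1 Hz for rat data.
   The band must lie below the Nyquist frequency 1/(2 TR); violations are
   errors, not warnings.
2. **Functional connectivity**: Pearson correlation between every pair of
   regional time series, Fisher z-transformed (`atanh`), diagonal forced
   to zero. Constant regions and perfectly correlated pairs are rejected
   with the offending regions named, because z would be infinite.
3. **Proportional thresholding**: for each density d in a grid, the
   top `round(d * N(N-1)/2)` edges by signed z are retained as an
   undirected, unweighted network. Using a fixed edge *count* rather than
   a fixed correlation cutoff normalizes all networks to the same number
   of links and removes global differences in correlation strength between
   subjects and conditions, so topology, not overall coupling, is compared.
4. **Graph metrics** per density: mean clustering coefficient C
   (Watts-Strogatz: per-node triangle fraction, degree < 2 contributing 0),
   characteristic path length L (mean BFS hop distance), global efficiency
   E_glob (mean inverse distance), local efficiency E_loc (mean global
   efficiency of each node's neighbourhood subgraph, node excluded), and
   small-worldness sigma = (C / C_rand) / (L / L_rand) against a
   degree-preserving rewired null ensemble.
5. **Motif census** per density: counts of connected *induced* subgraphs
   on 3 and 4 nodes, classified into the eight isomorphism classes
   (path3, triangle, path4, star4, cycle4, paw, diamond, K4), partitioned
   into cyclic classes (containing a cycle: triangle, cycle4, paw,
   diamond, K4) and acyclic classes (trees: path3, path4, star4).
6. **AUC summarization**: every metric/motif curve over the density grid
   (default 0.05 to 0.20 in steps of 0.01, 16 levels) is reduced to one
   trapezoidal area-under-curve value per subject, avoiding per-density
   multiple testing.
7. **Group inference**: paired t-tests on per-subject AUC differences
   (cross-over designs) or pooled-variance independent t-tests (two-group
   designs), with Benjamini-Hochberg FDR applied within families: the five
   graph metrics, the eight motif classes, and the cyclic/acyclic totals.
8. **Network Based Statistics (NBS)**: edgewise t statistics, a primary
   threshold, connected components of supra-threshold edges, and a
   permutation null of the maximal component size (sign flips of
   per-subject difference matrices for paired designs, group-label
   shuffles for two-group designs) giving family-wise-error-corrected
   p-values per component, plus per-node altered-connection counts.

# Conventions on fragmented networks

At densities of 5-20% thresholded networks fragment. The package adopts:

- **L** is the mean over *reachable* ordered pairs; unreachable pairs are
  excluded and counted (`nUnreachablePairs`), never silently imputed. L on
  an edgeless graph is an error. This makes L sensitive to fragmentation
  (reachable pairs concentrate inside dense components, which can *shorten*
  measured L on badly fragmented graphs).
- **E_glob** counts unreachable pairs as zero efficiency (1/Inf = 0), so it
  degrades smoothly under fragmentation; this asymmetry between L and
  E_glob is deliberate and mirrors standard practice.
- AUC refuses missing values: if a metric is undefined at some density
  (e.g. sigma when the null ensemble has zero clustering), the AUC call
  errors listing the densities, pushing the user to raise the density
  floor rather than paper over the problem. The 0.05 lower bound of the
  default grid exists precisely to keep networks reasonably connected.

# Numerical and algorithmic choices

- Edge ranking is by **signed** z (config-switchable to |z|): at sparse
  densities only the strongest positive couplings should survive. The
  alternative convention is exposed (`rankAbsolute`) because the field is
  not unanimous.
- `round` is R's round-half-even, so edge counts are bit-reproducible.
- Ties straddling the density cutoff are broken by lexicographic
  (row, column) order with a warning.
- The motif census uses ESU-style connected-subgraph enumeration (each
  connected vertex set visited exactly once) with classification by edge
  count plus maximum degree, which separates all eight classes; counts are
  raw frequencies, comparable across conditions because densities are
  matched. Induced (not partial) subgraphs are counted so the eight
  classes partition the connected vertex sets.
- Degree-preserving nulls use double-edge swaps (a-b, c-d -> a-d, c-b),
  rejecting self-loops and multi-edges; the budget is
  `swapsPerEdge * |E|` *attempts* (default 10 per edge) and the realized
  acceptance rate is reported. Connectedness of nulls is *not* enforced:
  rejection sampling for connectedness would bias the ensemble. Ensemble
  means use 100 nulls by default; the package's own benchmark studies
  reduce this (see below).
- Sigma uses ensemble means (not medians) of C_rand and L_rand, with the
  rewired ensemble by default; an ER ensemble matched on nodes and edges
  is available because the convention behind published sigma values is
  often unstated.
- NBS component size is extent (edge count) by default, with intensity
  (summed supra-threshold exceedance) as an option. The primary t
  threshold is a required user input with no default: reported components
  are conditional on it, so it must be an explicit analysis choice.
  p-values use the add-one convention (p >= 1/(B+1)); when 2^n sign
  patterns fit within the permutation budget the enumeration is exhaustive
  (logged). Two-sided tests run both one-sided passes with Bonferroni
  correction across tails. Zero-variance edges get t = 0, never NaN.
- Paired t-tests with all-zero differences return t = 0, p = 1 (no
  evidence); constant *nonzero* differences are a degenerate-input error.

# The synthetic-data generator

Because raw pharmacological fMRI data of this kind are not publicly
deposited, the package ships a generator that emulates the two study
designs at the level of extracted ROI series:

- **Latent covariance**: regions are split into near-equal modules; a
  latent edge exists within modules with probability `pWithin` (weight
  `weightWithin`) and between modules with probability `pBetween` (weight
  `weightBetween`); optional lognormal node-strength factors
  (`nodeStrengthSd`) make the latent network hub-like. The covariance is
  `Sigma = I + c * W / rho(W0)`, where W is the weight matrix after adding
  the condition effect's deltas and rho(W0) is the spectral radius of the
  baseline (zero-delta) weights. Normalizing by the *baseline* radius
  keeps deltas interpretable (a positive within-module delta strictly
  raises within-module covariances); positive definiteness is verified by
  eigendecomposition rather than assumed.
- **Sessions** are AR(1) processes x_t = phi x_{t-1} + eps_t with
  eps_t ~ N(0, Sigma) and a stationary start; phi = 0.3 for all nodes by
  default, the simplest temporal structure that makes the band-pass stage
  consequential.
- **Designs**: paired (two sessions per subject; a per-subject lognormal
  jitter on the coupling, sd 0.1, shared across the subject's sessions, so
  paired contrasts gain power — the cross-over rationale) and two-group
  (one session per subject, independent subjects). All randomness flows
  from one master seed; per-subject jitters and per-session seeds are
  drawn once and recorded in the manifest so any session is reproducible
  in isolation.
- **Condition effect**: the default drug-like effect adds +0.15 to the
  within-module weight and -0.10 to the between-module weight — the
  planted analogue of a shift towards less-integrated, more-segregated
  processing.

Generator defaults (modules of ~12 nodes, pWithin 0.9, pBetween 0.05,
coupling 0.85, weights 1 and 0.2, homogeneous node strengths) were fixed
once, after a design-phase exploration, to give clear planted-effect
recovery at desk scale; they are not calibrated to in-vivo effect sizes,
for which the source literature provides no usable magnitudes. What the
generator does *not* emulate: hemodynamics, scanner or physiological
noise, spatial structure, non-stationarity, and realistic degree
distributions of functional connectivity graphs. Passing recovery tests
therefore demonstrates that the *pipeline* detects planted covariance
reconfigurations of this kind — not that it would behave identically on
real data.

# Reference experiments and problem sizes

The package's validation experiments (used by the test suite and the
acceptance script) run at deliberately reduced sizes, chosen as the
package's own desk-scale conditions:

- **Directional recovery** (`recoveryBenchmark`): 60 nodes, paired n = 20,
  T = 300, 16-density sweep, sigma with 6 nulls per density, 20 replicate
  studies.
- **t-test calibration** (`nullCalibration`): null studies (identical
  condition effects) at 60 nodes, n = 12, T = 150; sigma is excluded here
  since its test statistic is the same paired t on AUC and its null
  ensemble dominates runtime.
- **NBS calibration** (`nbsCalibration`): 60 nodes, n = 12, 500
  permutations, primary threshold t = 2.0. The mild threshold is a design
  choice: with a severe threshold the null maximal-component distribution
  is concentrated on tiny integers and the permutation test becomes very
  conservative, which would make a family-wise-error estimate
  uninformative.
- **NBS recovery** (`plantedComponentStudy`): a synthetic stack of paired
  Fisher-z matrices with a 10-edge path component shifted by +0.3 against
  edgewise noise of sd ~ 0.11, n = 20, 1000 permutations.

# A known, deliberate limitation: the direction of sigma

The benchmark's planted effect robustly reproduces a *decrease in global
efficiency* and an *increase in cyclic-motif counts* under the drug-like
condition. It does **not** reproduce a decrease in small-worldness: under
this generator the same segregation shift that raises clustering raises
sigma. The reason is structural. With proportional thresholding, the
between-module edges suppressed by the effect are replaced, at fixed edge
count, by noise-ranked pairs that are drawn uniformly over the network —
and uniform random edges are just as effective as shortcuts, so L barely
responds, while C rises roughly in proportion to the within-module edge
share; the rewired-null reference terms move little because the degree
sequence barely changes. A more segregated network with a preserved
degree sequence simply has *higher* sigma. Empirical reports of
ketamine-like interventions lowering sigma while clustering is flat or
rises presumably reflect degree-distribution and fragmentation changes of
real functional connectivity that a block-modular covariance cannot
produce. The corresponding recovery assertion is left failing rather than
redefined, and `recoveryBenchmark` reports the sigma direction separately
so the behaviour is visible, not hidden.

# Interfaces

Sessions, matrices and result tables are exchanged as TSV with region
labels as the join key (never positional indices); study directories
carry a manifest (subject, condition, group, seed, file) and a YAML echo
of the generating configuration; NBS results include a JSON summary with
the configuration and seed. `inst/cli/netpharm.R` is a thin command-line
wrapper (simulate / analyze / nbs) over the exported functions, with exit
codes 0 (ok), 2 (configuration error), 3 (data error).
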