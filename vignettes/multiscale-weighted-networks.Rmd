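---
title: "Multiscale self-similarity of weighted geometric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale self-similarity of weighted geometric networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grwnet)
```

## The problem

Structural brain connectomes can be reconstructed at several anatomical
resolutions at once: a hierarchy of parcellations yields a stack of weighted
networks ("layers") describing the same brain at decreasing numbers of
regions. Empirically, the statistical structure of the link weights — the
complementary cumulative weight and strength distributions, the sublinear
strength–degree relation $\bar s(k) \sim a\,k^\eta$ with $\eta$ slightly
below one, the disparity of weights around nodes, and the tendency of weak
links to bridge modules — looks the same at every layer once each observable
is rescaled by its layer average. `grwnet` packages the modelling and
analysis machinery needed to generate, renormalize and interrogate networks
with exactly this phenomenology, so that the multiscale claims can be studied
quantitatively on synthetic data with known ground truth.

## The model

Topology follows the geometric soft configuration model on a circle (S1):
node $i$ has an angular coordinate $\theta_i$ (uniform on $[0, 2\pi)$) and a
hidden degree $\kappa_i$, and a pair is linked independently with the
gravity-law probability

$$p_{ij} = \frac{1}{1 + \chi_{ij}^{\beta}}, \qquad
  \chi_{ij} = \frac{d_{ij}}{\mu\,\kappa_i \kappa_j},$$

where $d_{ij} = R\,\Delta\theta_{ij}$ with $R = N/2\pi$, $\beta > 1$ sets the
clustering (the coupling of topology to the metric space) and $\mu$ the mean
degree. Weights on existing links couple to the *same* latent geometry:

$$w_{ij} = \epsilon_{ij}\,
  \frac{\nu\,\sigma_i \sigma_j}{(\kappa_i \kappa_j)^{1-\tau}\, d_{ij}^{\tau}},$$

with hidden strengths $\sigma_i = a\,\kappa_i^\eta$, coupling
$0 \le \tau < 1$ (at $\tau = 0$ weights ignore geometry; large $\tau$ makes
long links weak), global scale $\nu$, and multiplicative noise $\epsilon$
fixed to 1 in the noiseless default. A single connectivity-and-weighting law
therefore produces weak and strong ties, with weak ties preferentially long
range — the geometric reading of the weak-ties hypothesis.

The renormalization transformation (sup-GRW) coarse-grains $r$ angularly
consecutive nodes into supernodes, links two supernodes when any constituent
pair is linked, and gives the superlink the supremum of the constituent
weights. Iterating produces a layer stack analogous to the multiresolution
parcellation hierarchy; the transformation is an exact semigroup
($r\!\circ\!r = r^2$), which the tests verify bit for bit.

## Generator defaults and what they emulate

The generator's defaults are chosen once to emulate the finest layer of
multiresolution human connectomes and are not tuned per analysis:

* `n_nodes = 2000`, `mean_degree = 25` — a density of about 2.5% at a
  thousand-node parcellation, typical of deterministic-tractography
  structural connectomes; sizes 300–4096 are used in tests depending on the
  property under study.
* `kappa` from a truncated power law with exponent `gamma = 2.7`,
  `kappa_min = 4`, and the natural cutoff
  $\kappa_{\max} = \kappa_{\min} N^{1/(\gamma-1)}$ — heavy-tailed but cutoff
  degree distributions, and the scale-free regime ($\gamma < 3$) in which the
  renormalization flow preserves the degree distribution.
* `beta = 2.5`, `tau = 0.5` — strong but not extreme coupling of topology
  and weights to the latent space; weights then span roughly three to four
  decades, as fiber-density weights do.
* `eta = 0.9`, `a = 1` — the sublinear strength–degree relation observed in
  connectomes (hubs carry less strength than proportionality would give).
* `mu` and `nu` are never free: `mu` is calibrated by root-finding on the
  exact expected mean degree over the sampled node set (initialized at the
  closed form $\beta \sin(\pi/\beta)/(2\pi\langle k\rangle)$), and `nu` by
  the linear condition $\langle s\rangle = \langle\sigma\rangle$.

Cohorts (`generate_cohort()`) share one node set — identities, angles,
3D positions on a 70 mm jittered ring, and hemisphere labels split at
$\theta = \pi$ — and redraw each subject's topology and weights after a
small lognormal jitter (σ = 0.1) of the hidden degrees. Euclidean distances
between the fixed positions stand in for fiber lengths. What the generator
does *not* emulate: true cortical folding geometry, distance-dependent
tractography biases, streamline-count noise, or inter-subject registration
error. Passing tests therefore demonstrate the internal consistency of the
method chain, not fidelity to any particular empirical dataset.

```{r example}
p <- ws1_params(n_nodes = 500, seed = 7)
net <- sample_ws1(p)
summary(net)
stack <- renormalize_flow(net, r = 2, n_steps = 3)
stack
```

## Observables

`ccdf()` evaluates complementary cumulative distributions at observed values
(exact, unbinned; binning via `binned_curve()` is for reporting only, 30
geometric bins by default). `strength_degree_profile()` averages strength per
degree class and fits $\eta$ by unweighted least squares on log-binned
classes, using only bins holding at least three nodes; with fewer than two
usable bins it falls back to the raw classes, and a single degree class
leaves $\eta$ flagged undefined. `disparity_profile()` reports
$\Upsilon(k) = k \sum_j (w_{ij}/s_i)^2 \in [1, k]$ per degree class next to
the analytic moments of the locally-uniform null
($E = 2k/(k+1)$ and the variance of a uniform stick-breaking split), with the
conventional compatibility bound $E + 2V$. `layer_rescale()` divides weights,
strengths and degrees by their layer means, the normalization under which
layers are compared; cross-layer agreement is measured by the two-sample
Kolmogorov–Smirnov distance (`ks_distance()`).

## Weak ties

Modules come from unweighted Louvain (resolution 1, seed exposed; weights are
deliberately ignored so the partition is not contaminated by the quantity
under study, with a weighted mode available). Two nested filters keep the
lowest-`n`% of edges ranked by weight or by disparity-filter confidence
$1 - \alpha$, where per endpoint $\alpha = (1 - w/s)^{k-1}$; an undirected
edge takes the *minimum* $\alpha$ of its two endpoints (the conservative
convention of the disparity-filter literature — the choice matters only for
asymmetric endpoints) and degree-1 endpoints contribute $\alpha = 1$, since a
single weight carries no local heterogeneity information. Ties in either
ranking are broken by the canonical edge index, so retained counts are exact
and seed-independent. The weak-ties spectrum is
$\rho_{\text{inter}}(n) = RE_n / RE_{100}$ with $RE$ the intermodular edge
fraction; a single-module partition leaves it flagged undefined rather than
zero.

## Null models

`cp_wr()` permutes the observed weights over the fixed edge set (per layer,
when applied to a stack), preserving topology and the weight multiset
exactly while destroying weight–geometry coupling: the strength–degree
exponent moves toward 1 and the weak-ties spectrum flattens. `cr_grw()`
permutes the angular coordinates before renormalizing, which scrambles the
coarse-graining blocks and demonstrably breaks the cross-layer overlap of
degree and strength distributions. Ensembles (10 realizations by default in
`run_nulls()`) are summarized pointwise by `ensemble_average()`.

A caveat discovered while validating the generator: on WS1 synthetics with
$\tau > 0$ the *mean* weight decreases slightly along the sup-GRW flow
(about 10% per step at $\tau = 0.5$), because intra-block links are the
shortest-range and hence strongest ones and are absorbed by the
coarse-graining. The by-construction facts — every superlink weight is the
supremum of its bundle, and each coarse weight multiset is contained in the
finer one — hold exactly and are what the tests assert; the per-layer mean
weight is reported, not assumed monotone.

## Embedding

`ws1_fit()` is a deliberately simplified likelihood embedding (the full
published mapping tools are out of scope): $\beta$ by bisection matching
ensemble mean local clustering to the observed value; $\mu$ from the closed
form at the observed mean degree; hidden degrees by a damped fixed point
equating model-expected degrees (Gauss–Legendre quadrature over the angular
separation) to observed degrees within 1%; angles from the leading
non-trivial eigenvector pair of the normalized adjacency, refined by
monotone per-node likelihood sweeps over a *per-node randomly rotated*
candidate grid (a shared grid would collapse distinct nodes onto identical
angles and produce zero distances); then a re-adjustment of the hidden
degrees conditional on the embedded angles, because likelihood embedding
clusters connected pairs and would otherwise inflate regenerated degrees.

Two estimators of the weight–geometry coupling are provided.
`estimate_tau(method = "profile")` minimizes the L2 distance between
log-binned mean log-weight versus distance curves of the data and of
noiselessly regenerated weights on the observed topology (deterministic
given $\tau$, so no replica averaging is needed); it recovers $\tau$
exactly when coordinates are trusted, but attenuates toward zero under
coordinate noise (errors in the distance variable flatten the profile).
`method = "marginal"` instead matches the distribution of regenerated
weights to the observed one by Kolmogorov–Smirnov distance; because
coordinate noise leaves the *distribution* of inferred distances faithful
even when the pairing is noisy, the weight-spread moment still identifies
$\tau$, and this is what `ws1_fit()` uses internally.

Known limitations, measured on synthetic ground truth: the rank correlation
between inferred and true hidden degrees is capped by that between observed
degrees and true hidden degrees (roughly 0.8–0.9 at realistic densities,
because Poisson degree noise scrambles ranks in the heavy low-$\kappa$
bulk); and replica ensembles regenerated from a fit agree with the original
weight/strength/degree distributions to KS distances of a few hundredths —
visually coincident curves — but not within pointwise two-standard-deviation
bands of the ensemble CCDF, whose half-width ($\approx \sqrt{p(1-p)/E}$, under
1%) resolves the small systematic offset left by residual coordinate noise.
The tests assert the KS-level agreement and the pointwise band for the degree
curve, which passes.

## Group representative

The distance-dependent weighted consensus construction bins every edge seen
in any subject by its cohort-average length into 22 bins (equal-width by
default; equal-occupancy is a config switch, as the choice is not canonical),
separately for intra- and inter-hemispheric edges so that long callosal
links are not crowded out. Each bin keeps the `round(n̄)` most frequently
occurring edges, where n̄ is the mean per-subject edge count of the bin
(rounding half-up — a convention; candidates run out before slots only in
pathological cohorts), with occurrence ties broken by higher average weight
and then canonical index. Selected edges take a weight drawn at random from
that edge's subject-level weights — never an average, which would distort
the weight distribution. An identical-subject cohort provably returns the
subject network unchanged, which the tests check literally.

## Numerical choices

* Angular separations use the shorter arc; coincident angles are excluded at
  sampling time by a machine-scale jitter, since the weight law diverges at
  $d = 0$ for $\tau > 0$.
* Supernode angles are arithmetic means of sorted constituent angles (blocks
  are contiguous in the sorted order, so no wraparound arises); supernode
  hidden degrees use the standard $(\sum_j \kappa_j^\beta)^{1/\beta}$ rule of
  unweighted geometric renormalization.
* `mu` calibration brackets the closed-form initial value by a factor of 100
  and solves to a relative tolerance of $10^{-9}$; infeasible targets error.
* Text serialization uses 17 significant digits, so round trips are
  bit-exact.
* Problem sizes in the test suite are chosen so the whole suite runs in a
  few minutes on one core: closed forms at full spec ranges, Monte-Carlo
  oracles at $10^5$ replicates, generator ensembles at $n$ = 2000–4096 with
  5–20 realizations, embedding recovery at $n$ = 300–1000.

## What the pipeline functions produce

`run_self_similarity()`, `run_weak_ties()`, `run_nulls()` and `run_group()`
orchestrate the stages over a single config list (or JSON file) with one
seed fixing every stochastic step, and return report objects whose
summaries are also written as JSON when `out_dir` is set. They are thin
compositions of the exported functions above; nothing is computed there
that cannot be reproduced by calling the pieces directly.
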