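---
title: "Dating whole-genome duplications from concatenated ohnologue pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating whole-genome duplications from concatenated ohnologue pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdchronos)
```

## The problem

A whole-genome duplication (WGD) leaves pairs of paralogous genes
("ohnologues") in the descendant genomes. On a gene tree these pairs
coalesce at the duplication node, so the WGD event is a *datable node*: if
each retained ohnologue pair is placed on a topology in which the
duplicated clade's species tree appears twice as sister copies under the
WGD node (the "mirrored" or duplicated topology), then standard
relaxed-clock machinery with fossil calibrations can estimate the
duplication age alongside the speciation ages. Single loci date the node
imprecisely; concatenating many conformant ohnologue pairs narrows the
posterior substantially, which is the premise of this package.

`wgdchronos` implements the full chain: screening orthogroups for
conformance with the expected paralogy pattern, filtering and summarizing
the concatenated dataset, per-locus likelihood approximation, a Bayesian
MCMC dating engine with two relaxed clocks, posterior and convergence
summaries, precision ("infinite sites") analytics, and a synthetic-study
generator — including a delayed-rediploidization simulator — so that every
stage can be validated against data with known truth.

## The model

### Time scale

Internally every age is in units of 100 Myr (so 277 Ma is 2.77); this is
the usual numerical-conditioning convention of clock-dating software. All
user-facing tables are in Ma.

### Node-age prior

Calibrated nodes get a *hard-minimum / soft-maximum* density: mass
$1 - p_{tail}$ (default 97.5%) spread uniformly over
$[t_{min}, t_{max}]$ — equal probability per unit time — and mass
$p_{tail}$ (2.5%) in an exponential tail above $t_{max}$. The tail rate
$\theta = (1 - p_{tail}) / (p_{tail} (t_{max} - t_{min}))$ makes the
density continuous at $t_{max}$ while carrying exactly the nominal tail
mass. Below $t_{min}$ the density is exactly zero. The continuous
exponential tail with exact mass is this package's own resolution of the
tail shape (other implementations use a heavier default tail); the hard
minimum is likewise exact rather than softened.

Uncalibrated node ages are iid draws from the birth--death-with-species-
sampling kernel conditional on the root age (birth rate $\lambda$, death
rate $\mu$, sampling fraction $\rho$; defaults 1, 1, 0.1). The
$\lambda = \mu$ closed form
$g(t) = (1 + \rho\lambda t_1) / (t_1 (1 + \rho\lambda t)^2)$ is used when
$|\lambda - \mu| < 10^{-8}$; both branches of the kernel and its
closed-form CDF are verified against numerical quadrature in the test
suite. The root must carry a calibration because the kernel conditions on
the root age.

### Relaxed clocks

Two rate models are available per locus:

* **ILN** (independent log-normal): each branch rate is an iid draw with
  $\log r_b \sim N(\log\mu_r - \sigma^2/2, \sigma^2)$, mean-corrected so
  $E[r_b] = \mu_r$.
* **GBM** (geometric Brownian motion): rates live on *nodes*;
  $\log r_{child} \sim N(\log r_{parent} - \sigma^2\Delta t/2,
  \sigma^2\Delta t)$ with $\Delta t$ the parent-minus-child age
  difference, and the branch rate is the arithmetic mean of its endpoint
  node rates. Attaching rates to nodes makes the age difference between
  the two rate realizations the natural time separation for the variance
  term; the geometric-mean branch-rate alternative would change estimates
  only marginally and is not offered.

Expected branch lengths are $b = r\,\Delta t$ (ILN) or
$b = \tfrac{1}{2}(r_{parent} + r_{child})\Delta t$ (GBM), in
substitutions/site, in a canonical branch order (postorder edges of the
dating topology). Scaling all ages by $c$ and all rates by $1/c$ leaves
$b$ unchanged — the classic time-rate non-identifiability that
calibrations resolve and that the sampler's mixing move exploits.

### Hyperpriors

Per-locus mean rates $\mu_{r,i}$ get a gamma prior (default shape 2, rate
40: prior mean 0.05 substitutions/site/100 Myr, a typical vertebrate
amino-acid rate). Per-locus $\sigma^2_i$ gets a gamma prior with shape 1
and rate 10 (exponential, mean 0.1). $\sigma^2$ is per locus, not shared
across loci: loci are expected to differ in how clock-like they are, and
per-locus variances let the concatenation down-weight erratic loci
automatically.

### Likelihood

The exact likelihood is Felsenstein pruning over amino-acid alignments
(20-state models: Poisson for analytic tractability; WAG, LG, JTT
empirical exchangeabilities; optional discrete-gamma rate heterogeneity
with median-of-category discretization normalized to mean 1). Gaps and
`?`/`X` contribute partial likelihood 1 over all residues.

Dating does not re-evaluate the sequence likelihood. Instead each locus is
summarized once by its MLE branch lengths $\hat b$ with the gradient $g$
and Hessian $H$ of the log-likelihood at $\hat b$, and the sampler uses
the second-order expansion
$\ell(b) - \ell(\hat b) \approx g^\top (b - \hat b) +
\tfrac12 (b-\hat b)^\top H (b - \hat b)$
(the normal approximation). The expansion is exact in the infinite-data
limit and accurate within a few standard errors of the MLE; it degrades
for branches whose MLE sits at zero, which is why the optimizer floors
branch lengths at $10^{-6}$ and flags boundary cases.

One structural fact matters here: under a reversible model the likelihood
depends on the two root-adjacent branches only through their sum, so $H$
always has one near-zero eigenvalue. This is a faithful property of the
likelihood, not a defect; the rooted parameterization is kept, the
flat direction is tolerated in the negative-semidefiniteness checks, and
tests compare the root branches by their sum.

## The sampler

A Metropolis-Hastings sampler over node ages, per-locus (log) rates and
per-locus hyperparameters:

* reflected sliding-window moves on each node age, bounded by its parent
  and children;
* a sweep of normal moves on each log rate (branch rates for ILN, node
  rates for GBM), with incremental $O(B)$ likelihood updates;
* random-walk moves on $\mu_{r,i}$ and $\sigma^2_i$;
* three *joint* moves that are essential for mixing: a whole-locus rate
  scale; a joint ($\mu_r$, rates) scale, which leaves the rate-prior term
  invariant; and for ILN a joint ($\sigma^2$, rates) rescale that
  re-standardizes the rates around the prior mean (with the deterministic-
  transform Jacobian $B \log \sqrt{\sigma'^2/\sigma^2}$);
* a whole-tree mixing move (ages $\times c$, rates $\div c$) with
  Jacobian $c^{\,n_{ages} - n_\mu}$ in the (age, log-rate, raw-$\mu$)
  parameterization, under which the expected branch lengths — and hence
  the likelihood — are exactly invariant.

Rates are stored in log space (positivity for free). Step sizes are tuned
toward 20-40% acceptance during burn-in (default 25%) and frozen
afterwards to preserve detailed balance. All randomness flows from one
seed through R's RNG (the compiled sweeps use R's generator), so a seed
fully determines the chain. The per-locus quadratic state
($d = b - \hat b$, $Hd$, per-locus log-likelihood) is maintained
incrementally in compiled code and audited against a from-scratch
recomputation at the end of every run.

Posterior summaries report the mean, the 95% HPD by the
shortest-order-statistic interval, and ESS from the autocorrelation time
(initial positive sequence). Convergence across two seeds uses split-R̂
with a 1.01 flag threshold plus a mean-vs-mean practical-equivalence
check at half the pooled posterior SD; identical sample sets report R̂ = 1
by convention.

## The synthetic-study generator

The generator's defaults emulate the study design the package targets:
12 ray-finned-fish taxa (6 teleosts contributing an ohnologue pair each,
6 non-teleost actinopterygian outgroups), the WGD placed on the stem of
the teleost clade at 277 Ma, 30 loci with lengths $\geq 100$ columns
(negative-binomial around a mean of 576), 3 genes deleted across 3 loci
(so 537 sequences and 27 complete loci), ILN rates with hyperparameters
drawn from the hyperpriors, and soft-bounded calibrations on the root
(365-425 Ma), Neopterygii (300-360 Ma) and both mirrored crown-teleost
nodes (226-310 Ma). The calibration values are synthetic: they are chosen
once to be paleontologically reasonable windows that bracket the published
estimates for these clades, and the same values are used for simulation
and inference.

Chronograms are simulated by drawing the root age from its calibration,
the free node ages iid from the birth-death kernel, and rank-matching them
onto the topology (each free node takes the maximum of the ages allotted
to its subtree; the remainder is split randomly between the child
subtrees). The WGD age is pinned; draws violating the age order or a
calibration window are rejected and resampled, so the truth is always
attainable under the priors used for inference.

Loci can be simulated either as alignments (site-wise evolution down the
tree) or directly as branch-length approximations: $\hat b = b + \epsilon$
with $\epsilon \sim N(0, I(b)^{-1})$, $g = 0$ and $H = -\mathrm{diag}\,
I(\hat b \to b)$, where $I(b)$ is the closed-form per-branch Fisher
information of the 20-state equal-rates model at the locus length. Two
choices deserve note. First, the information is evaluated at the *true*
$b$, not the noisy $\hat b$: evaluating curvature at a near-zero noisy
estimate manufactures arbitrarily strong false precision and collapses
young node ages. Second, the diagonal surrogate ignores the covariance
between branch-length estimates (including the root flat direction), so
synthetic studies are mildly *more* informative about the root than real
ones; coverage results on synthetic data are therefore an optimistic bound
for that node. What passing recovery tests on this generator shows is
that the inference machinery is internally consistent — it does not show
that real alignments satisfy the model (real loci violate clock and
model assumptions in ways the generator does not emulate).

The delayed-rediploidization simulator addresses what the dated WGD node
means when duplicated chromosomes keep recombining after duplication.
During the tetrasomic phase $(t_r, t_{wgd}]$, gene conversion arrives per
site at rate $c$ and homogenizes the two copies; a site's effective
divergence age is the age of its most recent conversion ($t_r$ plus a
truncated-exponential residual), or $t_{wgd}$ if none occurred. As
$c \to 0$ the dated divergence tends to $t_{wgd}$; as $c \to \infty$ it
tends to $t_r$; in between, loci with independent conversion histories
average out. Conversion is symmetric (either copy's state wins with equal
probability) — the simplest neutral reading of the mechanism; selection
and biased conversion are out of scope.

## Numerical choices

* Branch-length floor $10^{-6}$ keeps MLEs interior; finite differences
  use scale-aware central steps $h_i = \max(10^{-4}, 10^{-2}\hat b_i)$,
  shrunk near the floor so evaluation points stay valid.
* First-order optimality is judged by the achievable log-likelihood gain
  ($|g_i| \cdot \max(\hat b_i, h_i)$), not the raw gradient: near-boundary
  flat branches legitimately carry a residual slope the optimizer cannot
  resolve.
* Hessians are symmetrized; asymmetry beyond $10^{-8}$ warns.
* The BV interchange file stores 12 significant digits; branches are
  identified by the sorted tip set of their child clade, so
  approximations re-match to an identically shaped tree regardless of
  node numbering.
* The $\lambda = \mu$ switchover tolerance in the birth-death kernel is
  $10^{-8}$.
* Degenerate cases: zero-duration branches contribute zero expected
  length; $\sigma^2 = 0$ recovers the strict clock as a point mass; a
  paired clock comparison with identical means reports $t = 0$, $P = 1$.

## Problem sizes used in the packaged checks

The test suite exercises the full study design (12 taxa, 30 loci, ILN)
with branch-length-approximation loci of 600 sites and chains of a few
thousand sweeps, 20 replicates for the coverage experiment; the
end-to-end run from sequences (simulate, screen, concatenate, estimate
MLEs and Hessians, date) uses a reduced 3+3-taxon, 8-locus design. These
sizes are the package's own validation choices; all of them scale up by
changing `study_design()` and `n_iter`.

## Limitations

* The normal approximation is unreliable for loci with many near-zero
  branch lengths (few informative sites); such loci should be few or
  long.
* GBM mixing on deep mirrored nodes is slower than ILN; use longer chains
  and check ESS when comparing clocks.
* The conformance screen is strict (topology distance 0 after pruning and
  copy assignment); near-miss gene trees are rejected rather than scored.
* No codon/nucleotide models, no model selection, no tip dating, no
  mixture clocks; homology inference, alignment and trimming are upstream
  of this package.
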