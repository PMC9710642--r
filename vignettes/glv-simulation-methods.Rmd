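---
title: "Simulating longitudinal microbiome studies with gLV dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating longitudinal microbiome studies with gLV dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvsim)
```

## Why simulate

Sequencing-based longitudinal studies observe a community only through
compositional read counts: the latent absolute abundances are normalized
away, counts are shallow multinomial samples, and the system may be far
from any steady state when the measurements of interest are taken.
Closed-form power analysis leans on steady-state and normality
assumptions that such data routinely violate. `glvsim` instead simulates
the whole study — dynamics, individuals, arms, sequencing — so a planned
analysis can be rehearsed end to end on data with known ground truth.

## The generative model

A simulated system is a list of **nodes**, each a data layer (e.g. 50
microbial taxa and 20 metabolites of one gut community) with its own
dimensionality, growth rates and initial abundances. Concatenating all
node dimensions into one vector $z_t \in \mathbb{R}^D_{\ge 0}$, the
latent dynamics are generalized Lotka-Volterra:

$$\frac{dz_t}{dt} \;=\; z_{t-1} \odot \Big(g + M z_t
  + \textstyle\sum_j u_{j,t}\, b_j + \varepsilon\Big),
  \qquad \varepsilon \sim N(0, \sigma I).$$

Every term sits inside the per-capita bracket, so each force scales with
the abundance it acts on and $z_i = 0$ is absorbing: an extinct (or
structurally absent) dimension can never reappear. The interaction matrix
$M$ is oriented target-by-source — entry $(r, c)$ is the effect of
dimension $c$'s abundance on dimension $r$'s per-capita growth — and is
stored block-wise per ordered node pair, so cross-layer couplings (taxa
driving metabolites, say) are first-class.

Observation is a two-step collapse per recorded time point $t$:
relative abundances $X_t = Z_t / \sum Z_t$, then read counts
$Y_t \sim \mathrm{Multinomial}(R, X_t)$ with fixed depth $R$. The triple
$(Z, X, Y)$ is returned for every individual, so analyses can be compared
against the latent truth they estimate.

## Numerical scheme and its edge cases

* **Integrator.** Forward Euler with user step `dt`. The model is stated
  in discrete per-step form and its noise term is redrawn independently
  at every integration step, which makes Euler the scheme whose noise
  semantics are exact rather than an approximation; higher-order or
  adaptive solvers are deliberately out of scope.
* **Noise.** `noise_var` is a *variance*; each coordinate receives an
  independent $N(0, \sqrt{\texttt{noise\_var}})$ draw per step, inside
  the per-capita bracket (so noise, like growth, is proportional to
  abundance).
* **Negativity.** A coarse Euler step can overshoot below zero; results
  are clamped to 0 after each step. Zero is the model's own absorbing
  state, so clamping is the physically meaningful projection. No silent
  capping is applied on the upside: any non-finite value aborts with a
  divergence error naming the step and coordinates.
* **Recording grid.** `burn_in` integration steps run before the first
  recorded sample ("time to first sample"); with `burn_in = 0` the first
  recorded row is the initial state at $t = 0$. Thereafter every
  `downsample`-th step is recorded until `n_timepoints` rows exist.
  Intervention magnitudes are indexed by recorded time point: the steps
  leading to row $t$ use $u_{j,t}$, and burn-in steps use $u_{j,1}$.
* **Degenerate compositions.** A fully extinct community yields all-zero
  $X$ and $Y$ rows with a warning rather than an error, so harsh
  parameter sweeps complete and report rather than abort.

## Default parameter ensembles

When parameters are not supplied, the generator draws
$g_i \sim U(-1, 1)$ and $z_{i,0} \sim \mathrm{Lognormal}(0, 1)$, each
initial coordinate zeroed with probability `p_zero`. The interaction
matrix comes from a random-community ensemble: for each off-diagonal
symmetric position pair, $(M_{ij}, M_{ji})$ is drawn from a bivariate
normal with per-coordinate variance `pair_var` and correlation
`pair_corr`; every off-diagonal entry is then kept with probability `C`
(the connectivity) independently — so a correlated pair can lose one
member — and every diagonal entry is set to $-d$ with
`self_penalty` $= d \ge 0$. The diagonal is set after sparsification and
is never zeroed: every dimension is self-limiting. With `pair_var = 1`
the pair distribution is the unit-variance ensemble; `pair_var` is
exposed separately so the coupling scale can be tuned without changing
the topology.

Two conventions here resolve ambiguities that could be read either way:
the self-interaction magnitude is supplied as a nonnegative number and
*negated* onto the diagonal (a positive diagonal would make every
dimension self-exciting and the ensemble almost surely divergent), and
the bivariate-normal scale is interpreted as a variance.

**Stability.** The ensemble does not rescale $M$ for stability. By the
standard random-matrix criterion a community of effective size $D$ is
stable when roughly $\sqrt{D\,C}\,\sigma < d$; the package's documented
defaults ($C = 0.5$, $\sigma^2 = 1$, $d = 1$) satisfy this only for
small $D$. The package's own larger test communities ($D = 20$ and
$D = 50$) therefore use `pair_var = 0.25`, `self_penalty = 2`, which
sits at that stability boundary and empirically yields persistent,
bounded communities. Users simulating wide communities should scale
similarly; divergence is reported, never hidden.

## Cohorts and case-control studies

A cohort shares $g$ and $M$ across individuals and resamples only the
initial abundances — between-individual variation is variation in where
each person's community starts, not in its ecology. Each individual gets
an independent pair of substream seeds derived from the cohort master
seed, in a prefix-stable layout: extending a cohort leaves the existing
individuals' draws untouched.

A case-control cohort assigns `round(n * case_ratio)` individuals (half
away from zero) to the case arm. One response vector
$b_c \sim U(-s/2, s/2)$ is drawn *per cohort* — drawing per individual
would confound the effect-size semantics — and applied to the cases as
an always-on intervention ($u \equiv 1$ from the very first integration
step, burn-in included) on the chosen node. Controls receive nothing.
`match_seeds = TRUE` gives case $k$ and control $k$ identical seeds, so
at $s = 0$ the two arms are identical draw for draw; the default is
unmatched, matching how independent participants are recruited.

Because relative abundance cancels any common multiplicative factor, a
response vector with nearly equal coordinates has almost no compositional
effect even at large $s$; effect sizes should be judged against the
growth-rate scale (1) *and* against this compositional null direction.

## Parameter inference

Dividing the gLV equation by $z$ linearizes it:
$d(\ln z)/dt = g + Mz + ub$. The fitting routine builds $F$, the matrix
of time-scaled changes between successive recorded points, and a design
$Y_{\mathrm{des}}$ stacking the abundances, a row of ones and the
intervention series, then solves the ridge system
$\theta = F^\top Y_{\mathrm{des}}^\top (Y_{\mathrm{des}} Y_{\mathrm{des}}^\top + \lambda I)^{-1}$
via a symmetric linear solve (never an explicit inverse). $\theta$
unpacks into $\hat M$, $\hat g$ and $\hat b$. Designs from several
individuals are concatenated column-wise before solving, pooling
evidence across a cohort that shares parameters.

Two definitions of "time-scaled change" are exposed:

* `mode = "log"` (default): $F_t = (\ln(Z_{t+1} + c) - \ln(Z_t + c))/\Delta t$.
  This is the natural continuous-time estimator and the right choice for
  externally observed data.
* `mode = "linear"`: $F_t = (Z_{t+1} - Z_t) / (\Delta t\,(Z_t + c))$.
  For data produced by this package's own Euler integrator this form
  inverts the update rule *exactly*, whereas the log form carries an
  $O(dt)$ discretization bias that near-stationary, highly collinear
  designs amplify into substantial parameter error. The package's
  recovery benchmarks therefore use the linear mode; on a noiseless
  3-taxon community with 500 points it recovers $M$ to a fraction of a
  percent in Frobenius norm.

The pseudocount $c$ (default $10^{-6}\times$ the mean positive
abundance) guards the logarithm and the division against exact zeros.
$\lambda$ is a single scalar penalty on all coefficients — the minimal
regularizer that makes the normal matrix invertible; at $\lambda = 0$ a
singular system produces an error advising a positive penalty rather
than a silently unstable solve. The method presumes absolute abundances,
is sensitive to noise, and needs the community to persist: an extinct
taxon contributes an unidentifiable column (the package's benchmarks
reject non-persistent random draws for exactly this reason).
Compositional (relative-abundance-only) inference is intentionally not
implemented.

## Realism metrics

`realism_report()` compares two count datasets along three standard
axes: the distribution of per-sample alpha diversities (Shannon entropy
by default; Gini-Simpson and richness selectable), the fraction of
exactly-zero entries, and per-feature differential relative abundance
with a Wilcoxon rank-sum test, BH-adjusted across features. The test is
deliberately the simplest defensible choice and is documented as
replaceable; the default comparison takes each individual's final
recorded time point (endpoint comparison), with all-points pooling
available. Fully tied features return $p = 1$ (no evidence) rather than
`NaN`.

## Visualization

Stacked-bar plots show one bar per recorded time point, renormalized
*within* the chosen node so that a single layer of a multi-node
simulation remains readable. PCA trajectory plots pool the rows of all
individuals, fit one centered PCA (on $X$ by default — the observable
scale — with $Z$ selectable), and project every trajectory into the
common plane; the axis sign is fixed by making the largest-magnitude
loading positive, so plots are deterministic. Between-arm separation is
measured as the distance between the arms' *endpoint* centroids in this
plane: endpoints are where convergence to distinct attractors shows up,
while averaging over whole trajectories dilutes the signal with the
shared transient.

## What the built-in experiments show — and what they don't

The test-suite experiments run at deliberately modest sizes (3-taxon
recovery benchmarks; cohorts of 10–30 individuals; 20-dim and 50-dim
communities; 25 replicates for power curves) so the full suite completes
in seconds. The power experiment uses a 50-taxon node, 30 participants,
noiseless dynamics, effect size 2, and read depths 30/300/3000: with
~50 features each at ~2% relative abundance, a depth of 30 reads
genuinely starves the test for counts, so detection power rises steeply
and monotonically with depth — the regime the package exists to map out.
Detection uses the cohort's most-affected feature (largest latent
endpoint shift between arms) and a rank-sum test at $p < 0.05$.

Synthetic gLV data emulate longitudinality, compositionality,
multinomial sampling noise, sparsity from structural zeros and
intervention responses. They do *not* emulate sequencing or PCR bias
beyond multinomial sampling, taxonomic correlation structure,
phylogenetic relatedness between dimensions, per-individual variation in
ecology (interactions and growth rates are shared by design), nonuniform
sampling grids, or strongly mutualistic ecosystems (a known failure mode
of gLV). Passing tests certify the generator's own contracts, not that
any particular real dataset is well-described by a gLV system; the
realism metrics exist precisely so users can check the latter against
their own pilot data.
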