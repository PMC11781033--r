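---
title: "Models and methods behind fibercorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibercorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercorr)
```

# The measurement and its summary statistics

Stretched single DNA molecules (DNA combing, optical mapping) carry
replicated tracks — "eyes" — whose layout encodes the local replication
dynamics: how often origins fire and how fast forks move. fibercorr works
from a per-fiber list of replicated intervals, in kb, fiber-local and
0-based, as half-open `[start, end)` intervals. Fibers have no genome
coordinates: combed molecules cannot be anchored to a reference assembly.

Each fiber is binarized at a fixed resolution (default 1 kb per unit; a
unit is 1 when at least half of it is covered by a replicated track —
majority coverage is the symmetric, unbiased sub-unit rounding rule). Three
statistics summarize a fiber:

* the replicated fraction $f$, the mean of the binary signal;
* the initiation rate
  $$I(f) = \frac{N}{L\,(1-f)\,\Delta t},$$
  where $N$ counts replication eyes strictly shorter than 3 kb ("new"
  initiations), $L$ is the fiber length and $\Delta t$ the time window in
  which an initiation remains detectable as a short eye. For combing data
  $\Delta t = 3$ min (a 3 kb eye at a typical fork speed of ~0.5 kb/min);
  for lattice-simulated data `detectability_window()` derives it from the
  growth rule (an eye of age $m$ steps is $2m$ blocks long);
* the auto-correlation profile
  $$C(r) = \frac{1}{n - |r|} \sum_{k} x_{k+r}\,x_k,$$
  the unbiased lagged-product estimator on the binary signal $x$.
  Signals are deliberately **not** mean-centred: only then does
  $C(0) = f$ hold and $C$ stay within $[0, 1]$, which is the scale the
  model below predicts.

Fibers longer than 80 kb are sorted by $f$ into seven half-open bins,
$f_1 = (0, 0.11], \dots, f_7 = (0.64, 0.75]$; fully unreplicated fibers
and fibers above 75% replication are excluded. Per bin we average the
member profiles (uniform weight per fiber — the bin average is not
length-weighted) and the per-fiber initiation rates.

# The nucleation-and-growth model

Replication along a fiber is modelled as a one-dimensional
Kolmogorov–Johnson–Mehl–Avrami (KJMA) process: origins fire stochastically
in unreplicated DNA at rate $I(t) = I_0 t^\alpha$ (per kb per min,
$I_0 \ge 0$, $\alpha \ge 0$, covering the rising part of the universal
bell-shaped initiation curve) and each origin grows bidirectionally at a
constant fork speed $v$. The replicated fraction is

$$f(t) = 1 - \exp\!\left(-\frac{2 v I_0\, t^{\alpha+2}}{(\alpha+1)(\alpha+2)}\right),$$

which inverts analytically (`invert_time()`), so every bin's mean $f$ maps
to a model time without numerical root finding. The two-point correlation
of the replication state is

$$C(r,t) = 1 - 2\varphi + \varphi^2
  \exp\!\left(E \left(1 - \frac{r}{2vt}\right)^{\alpha+2}\right),
  \qquad \varphi = 1 - f(t),\; E = \log\frac{1}{\varphi},$$

valid for $r < \ell_{max} = 2vt$, the longest possible eye. Beyond
$\ell_{max}$ two points are replicated independently and `correlation_theory()`
returns the constant $f^2$ — the exact boundary value and the
independent-points limit; experimental lag grids exceed $2vt$ in low-$f$
bins, so this extension is exercised routinely. Two identities pin the
implementation down exactly: $C(0,t) = f(t)$ and $C(2vt, t) = f(t)^2$.
Numerically the $\varphi^2 e^{E s}$ term is evaluated as $e^{E(s-2)}$,
which stays finite when $f \to 1$.

## Two processes

A single parameter set cannot reproduce fiber populations in which long
sparse eyes and dense short eyes coexist. fibercorr therefore also fits a
mixture

$$C(r, f) = \Theta(f)\, C_1(r, f) + (1 - \Theta(f))\, C_2(r, f),$$

with one free mixing weight $\Theta \in [0,1]$ per replicated-fraction bin
($\Theta$ is a free per-bin parameter, not a parametric curve) and each
component evaluated **at its own time** $t_i = f^{-1}(f; v_i, I_{0,i},
\alpha_i)$. Comparing the processes at equal replicated fraction, not equal
time, is the interpretation that matches plotting $C$ against $f$; it means
the mixture describes which process produced a fiber of a given maturity,
not a race between simultaneous clocks. The same $\Theta$ weights the two
theoretical initiation rates when the initiation curve is fitted jointly.
Constrained variants share the fork speed (`dual_shared_v`, 5 process
parameters) or the whole initiation rate $I_0, \alpha$ (`dual_shared_I`,
4 — "the same initiation rate" fixes both constants).

By convention the component with the larger fitted fork speed is reported
as the *fast* process and $\Theta$ is its weight.

## Identifiability

$(I_0, \alpha)$ enter the observables only through the function
$I(t(f)) = I_0\, t(f)^\alpha$; on mixtures, quite different raw
$(I_0, \alpha)$ pairs can produce nearly identical initiation-rate
functions over the fitted $f$ range. Conclusions should therefore be drawn
from $I(f)$ at matched replicated fractions (what "high" and "low"
initiation mean scientifically), and from the fork speeds, which are well
identified by the decay scale $2vt$ of the correlation profiles. For a
single process fitted jointly to a flat initiation curve, $I_0$ itself is
well constrained. A related subtlety affects the constrained mixtures:
because each component is evaluated at its own inverted time, even the
shared-$v$ variant produces two different correlation lengths
$2 v\, t_i(f)$ through $I_{0,i}$ and $\alpha_i$, so model-comparison
between the free and constrained mixtures discriminates less sharply than
parameter counting suggests.

# Fitting

The objective is the reduced $\chi^2$ over the concatenated residuals of
all bins' mean correlation profiles (lags up to `r_max_fit`, default
40 kb) and the binned initiation curve. Because the fitted curves are bin
*means*, each point is weighted by the standard error of that mean
(across-fiber SD divided by $\sqrt{n}$), floored at 1% of the observable's
dynamic range; the floor only guards degenerate dispersions (single-fiber
bins) and stays below typical sampling error at realistic bin sizes.
Weighting by the raw SD would leave the objective unable to distinguish
good from catastrophic parameters.

## The observable initiation rate

The small-eye estimator undercounts initiations as replication advances: a
new origin that fires within about one eye-threshold of already replicated
DNA merges with its neighbour before it can be counted as a separate short
eye. The model side of the objective therefore predicts what the estimator
measures,

$$I_{obs}(f) = I(t)\,\frac{S_2(\theta, t)}{\varphi(t)},\qquad
S_2(r, t) = \varphi^2 \exp\!\left(E\left(1 - \frac{r}{2vt}\right)^{\alpha+2}\right),$$

where $S_2$ — the two-point survival probability already implicit in
$C(r,t)$ — is evaluated at the eye threshold $\theta$ (3 kb): the
probability that the points flanking a new eye are still unreplicated.
For fast forks ($2vt \gg \theta$) the factor tends to 1. This is a
closed-form consequence of the model, not a tuned correction; the
uncorrected comparison is available with `init_model = "raw"` (appropriate
for noise-free analytic inputs). Without the correction, parameters
recovered from simulated fibers are biased low by roughly the mean merging
loss (~20–30%).

## The genetic algorithm

`ga_minimize()` implements an island-model GA: 10 subpopulations of 10
individuals; per island and generation one elite is kept, 60% of the
children come from scattered (uniform gene mask) crossover between parents
drawn by roulette wheel on linear rank weights, and 40% are uniform
within-bounds mutants; every 50 generations the best 10% of each island
replaces the worst of the next island on a ring. The run stops after 3000
generations or when the best reduced $\chi^2$ reaches 0.5. Search bounds
are $v \in [10^{-10}, 10]$, $I_0 \in [10^{-15}, 1]$, $\alpha \in [0, 5]$,
$\Theta \in [0,1]$; $v$ and $I_0$ are searched in $\log_{10}$ space since
their bounds span 10+ decades. Implementation choices the method
description leaves open: rank-based selection weights (robust to the large
magnitude swings of a $\chi^2$), ring migration topology, and a per-gene
mutation probability of 0.4, chosen from a small convergence study of the
optimizer itself (0.1/0.25/0.4; the highest rate reached the lowest
objective on every replicate — with uniform-in-bounds mutation as the only
source of new gene values, low rates stall refinement). Runs are fully
deterministic given the configuration seed.

# The Monte Carlo simulator

Each fiber is a 1-D array of `n_blocks` blocks (default 150 × 1 kb), 0 =
unreplicated, 1 = replicated. One step lasts the time a fork needs to
cross one block, $dt = \text{block}/v$. Per step, first every active fork
converts its next unreplicated block (forks at fiber ends, or meeting
replicated DNA, terminate — converging forks annihilate); then every
unreplicated block fires independently with probability
$P(t) = \min(1, I(t)\cdot \text{block} \cdot dt)$. A firing origin spawns
a rightward fork at its block and a leftward fork at the block before it,
so the origin becomes visible only at the following step — the critical
nucleus is infinitesimal. Several origins may fire in one step, and
partially visible eyes at fiber ends are counted like any other track.

**Time convention.** The interior expectation of the lattice is
$P(\text{unreplicated after } k \text{ steps}) = (1-p)^{k(k-1)}$ for a
constant $p$, whereas the continuum gives $e^{-vIt^2}$; matching the two
shows that a $k$-step state corresponds to continuum time
$t_{\mathrm{eff}} = \sqrt{k(k-1)}\,dt$ (`lattice_time()`), which is
$\approx (k - \tfrac12)\,dt$ for large $k$ and exactly 0 at $k = 1$ —
firing is invisible for one step, so the first state genuinely is the
$t = 0$ state. Snapshot records are stamped with the simpler mid-step
times (also the points at which time-varying $P(t)$ is evaluated, a
midpoint rule); quantitative lattice-vs-theory comparisons use
$t_{\mathrm{eff}}$, since at the second and third steps the mid-step
approximation still carries a visible offset. The residual discrepancies —
boundary effects (fibers are finite, the theory is for an infinite line)
and the $(1-p)^n$ vs $e^{-pn}$ difference — are well inside sampling
error at the default scale.

**Fidelity condition.** The lattice resolves a process only while
$P \ll 1$ and the per-step change in $f$ is small against the bin width.
A slow, densely initiating process (e.g. $v = 0.2$ kb/min, $I_0 = 0.04$,
$\alpha = 1$) violates both at 1-kb blocks: its 5-minute steps saturate
$P$ (the generator warns) and quantize the visible $f$ so that low bins
can never contain such fibers. Two-process datasets are therefore
generated on 0.25-kb blocks (600 blocks = 150 kb), which restores
$P \ll 1$ and populates every bin with both processes. The constant-rate
validation keeps the canonical 100 × 150 × 1 kb geometry.

**Reproducibility.** Every fiber runs on its own deterministically derived
RNG substream, so enlarging `n_fibers` does not reshuffle earlier fibers,
and identical seeds give bitwise-identical block arrays.

**What the generator does not emulate:** optical noise and track-calling
errors, fiber breakage and length heterogeneity (all fibers share one
length), chromatin-dependent spatial origin preferences, and eye/gap
statistics beyond what the model itself induces. Passing tests on this
synthetic data validate the estimators and the inference chain under the
model's own assumptions; they cannot certify behaviour on artefact-laden
experimental images.

# Clustering and classification

Per bin, profiles are compared by the correlation distance $1 - \rho$
(Pearson, curves on their common lag grid, no interpolation). WPGMA
(weighted-average linkage, `hclust(method = "mcquitty")`) builds the tree,
cut into $k = 2 \dots 5$ clusters; each cut is scored by the mean
silhouette $S_i = (b_i - a_i)/\max(a_i, b_i)$ computed on the same
distance, and the best $k$ wins, ties going to the smallest $k$
(parsimony). Members of singleton clusters get $S_i = 0$ (standard
convention). After a cut, clusters are renumbered so cluster 1 is the
smallest. Constant (zero-variance) profiles have no defined correlation
and are excluded with a warning wherever the distance is needed. PCA on
profile or similarity matrices is mean-centred but not standardized —
columns share units. For the question "how many independent processes
shape the profiles in a bin?" the informative spectrum is that of the
pairwise similarity matrix: on two-process mixtures its top two components
carry ~90% of the variance, while the raw profile matrix spreads
single-fiber sampling noise over many components at low $f$.

Classification assigns each fiber by the similarity distances
$s_{fast} = 1 - \rho(C_{fiber}, C_1)$ and $s_{slow} = 1 - \rho(C_{fiber},
C_2)$, the model curves evaluated at the fiber's bin mean $f$. The default
decision is the strict diagonal ($s_{fast} < s_{slow}$ ⇒ fast); an
optional ambiguity band around the diagonal, default 0, labels
near-diagonal fibers ambiguous. "Normalized correlation coefficients" are
read as plain Pearson coefficients (already normalized to $[-1, 1]$); no
further normalization is applied.

# Problem sizes and numerical conventions

The test-suite and the acceptance script use: 100 fibers × 150 blocks with
six snapshots for single-process recovery; 280–1100 fibers on 0.25-kb
blocks for mixture analyses; 1000 random parameter draws for the analytic
identities (tolerance $10^{-12}$, time-inversion round trip $10^{-10}$);
100 random signals up to length 200 against a brute-force correlation
oracle ($10^{-12}$). Dispersion of a single observation is reported as
missing, never zero, and enters fits only through the sigma floor.

# Known limitations

* The initiation-rate estimator remains biased for eyes that merge within
  the detectability window even after the $S_2$ correction at very high
  local densities; bins above $f = 0.75$ are excluded for this reason and
  because the rising-$I(t)$ form no longer holds when the initiation curve
  turns over late in S phase.
* The KJMA forms assume spatially homogeneous initiation; fibers spanning
  a boundary between regimes are only captured through the mixture weight.
* WPGMA can in principle produce inversions (non-monotone merge heights);
  the clustering tests assert monotonicity on the fixtures and would flag
  an inversion rather than silently reorder.
* The GA is a stochastic global optimizer: with the 0.5 early-stop it
  returns *a* model consistent with the data at the stated tolerance, not
  a unique optimum; see the identifiability note above.
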