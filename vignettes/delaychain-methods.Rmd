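---
title: "Exact reduction of reaction chains with delays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact reduction of reaction chains with delays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaychain)
```

## The problem

Stochastic models of signalling cascades, metabolic chains and receptor
modification frequently contain long runs of monomolecular reactions

$$S_1 \;\underset{c_{1,r}}{\overset{c_1}{\rightleftharpoons}}\; S_2
  \;\rightleftharpoons\; \cdots \;\rightleftharpoons\; S_n$$

whose intermediates are neither observable nor of direct interest. If only a
few *species of interest* (SOIs) matter, the whole intermediate block can be
removed **exactly**: every passage of a molecule through the block is
replaced by a single *consuming delayed reaction* whose rate is the original
outgoing rate weighted by the probability of the passage's outcome, and
whose delay is the corresponding conditional first-passage time. A delay
stochastic simulation algorithm (DSSA) then reproduces the SOI marginals of
the full model in distribution — not approximately, but exactly, because
single-molecule passages through a monomolecular block are independent
continuous-time Markov chains whose first-passage laws we can write down.

`delaychain` implements the whole pipeline: model representation and
classification, closed-form first-arrival/first-return distributions, the
abridgement construction, a direct-method SSA, a rejection-method DSSA, and
the statistical machinery that makes the exactness claim testable.

## First-passage laws of the lumped block

Write $\tilde K$ for the *inner rate matrix*: the generator of the chain
restricted to the intermediates $S_2,\dots,S_{n-1}$ in the column convention
$\mathrm d p/\mathrm d t = \tilde K p$. Outflow towards the absorbing SOI
boundaries and degradation ("killing") appears only on the diagonal;
bypass reactions among intermediates give entries beyond the tridiagonal
band. All eigenvalues $\lambda_k$ of $\tilde K$ have negative real part.

Three nested representations of the conditional delay laws are used, most
specific first:

1. **Stage convolution (hypoexponential).** For a tridiagonal (bypass-free)
   chain, the first-arrival time from one boundary to the other,
   conditioned on arrival, is the convolution of exponentials with rates
   $|\lambda_k|$ — one stage per intermediate. A remarkable consequence of
   this form is *direction independence*: the two first-arrival laws of a
   bi-directional chain are identical even when every forward rate differs
   from its backward partner (the rates move the arrival *probabilities*,
   not the conditional *law*). For strictly uni-directional chains the
   stages are simply the total outflow rates of the visited states, a form
   that remains valid for repeated rates (Erlang-type blocks).

2. **Eigenvalue / residue form.** Everything else with simple eigenvalues
   is handled through the Laplace-transform representation: for a walk
   starting at block index $a$ and absorbing through the rate vector
   $\beta$ (all reactions from intermediates into the target SOI),
   $$ f(t) \;=\; \sum_k w_k e^{\lambda_k t},\qquad
      w_k = \sum_i \beta_i\,(-1)^{a+i}
            \frac{M_{a,i}(\lambda_k)}{\prod_{j\neq k}(\lambda_k-\lambda_j)},$$
   where $M_{a,i}(s)$ is the $(a,i)$-minor of $sI-\tilde K$. First-return
   laws use the corner minors $M_{1,1}$ and $M_{m,m}$, which a tridiagonal
   structure lets us evaluate by three-term continuant recurrences; bypass
   systems fall back to dense determinant evaluation (a small complex LU,
   since base R's `det()` is real-only). Complex eigenvalues occur in
   conjugate pairs and are combined *before* evaluation into real damped
   cosine terms $e^{\alpha t}(A\cos\beta t - B\sin\beta t)$, avoiding
   cancellation; evaluated CDFs are real to $10^{-9}$ by construction. The
   $t\to\infty$ limit of these expressions recovers the event
   probabilities, which we instead compute by the exact linear solve
   $\beta^{\mathsf T}(-\tilde K)^{-1}e_a$ and use to normalize; tests
   verify the two routes agree.

3. **Numeric tabulation.** When eigenvalues are non-simple (relative gap
   below $10^{-8}$ times the spectral radius — the residue coefficients
   become numerically unstable near degeneracy) and the uni-directional
   stage form does not apply, the CDF is tabulated from the matrix
   exponential and flagged as a fallback, never silently substituted.
   The canonical case is the dissociation-time mixture of the kinetic
   proofreading example, whose inner matrix has one eigenvalue of
   multiplicity $N$.

Degradation of intermediates is killing: it changes the arrival and return
probabilities (their complement is the degradation probability,
$p_{deg} = 1 - p_r - p_a$) but requires no modification of the closed
expressions — they are simply evaluated at the eigenvalues of the
degradation-inclusive inner matrix. Note that the *numerical* conditional
laws do change when degradation is added (already for a single
intermediate the conditional delay is $\mathrm{Exp}(c_f+c_b+d)$); what is
invariant is the validity of the formulas.

### The numeric oracle

Every closed form in the package is checked against
`numeric_first_passage_cdf()`, which propagates $p(t) = e^{Kt}e_{start}$ on
the full generator by uniformization (randomization with Poisson weights,
truncation error below $10^{-13}$) and reads the absorbed mass at each
target. The oracle shares no code with the closed forms — no
eigendecomposition, no minors — which is what makes the sup-norm
comparisons in the test suite meaningful. Its auto-grid is geometric with
512 points from $0.01/\max|K_{ii}|$, extended until the remaining transient
mass falls below $10^{-9}$, and doubled until the interpolated CDF changes
by less than $10^{-9}$.

## The abridgement construction

`abridge()` uses one uniform recipe. Given the SOI set, the *block* is every
non-SOI species with unimolecular outflow. Reactions are partitioned into

* **entries** — reactants all SOIs, a single unit-stoichiometry product in
  the block (this includes boundary bimolecular reactions such as receptor
  binding $T + M \to C_0$);
* **exit channels** — reactions from block species whose products lie
  outside the block, grouped by product multiset (all dissociations
  $C_i \to T + M$ feed one channel); degradations form the no-product
  channel;
* **interior moves** — everything among block species, including bypasses;
* **immediate reactions** — entirely among SOIs; carried over verbatim.

Each entry is split over the reachable channels: channel with probability
$p$ and products $P$ yields the consuming delayed reaction
(entry reactants) $\to P$ at rate (entry rate $\times\, p$) with the
channel's conditional first-passage delay. A channel restoring the entry
reactants is a *first-return loop*; one producing another SOI is a
*first-arrival link*. The degradation fraction becomes a delayed *loss*
reaction (reactants removed, no product), so the outgoing rates of every
SOI sum exactly to their original values — conservation is asserted to
$10^{-12}$ in the tests. Probability-zero branches are dropped to keep the
propensity vector minimal.

This single construction specializes to all the classical schemes: two
boundary SOIs give the four delayed reactions (two loops, two links);
a single SOI gives one loop per outgoing reaction whose first-return law
also counts walks through the far chain end (hence it differs from the
two-SOI loop at the same species — the tests assert a sup-norm gap above
0.01 on the worked chain); receptor binding gives the two delayed branches
of the proofreading scheme. Bypass reactions that take an SOI *into* the
block are refused by default; `allow_soi_bypass = TRUE` routes them through
the same general machinery (residue form with general minors, numeric
fallback), which handles arbitrary entry positions.

**Synthesis.** A synthesis producing an SOI is carried over. A synthesis
producing a lumped intermediate $S_i$ is replaced by delayed syntheses, one
per reachable channel, with rates weighted by the arrival probabilities
from $S_i$ and first-arrival-from-$S_i$ delays; the degradation-absorbed
fraction emits nothing.

**Initial conditions.** Molecules sitting on lumped intermediates at time
zero are invisible to the abridged state. `build_initial_history()` turns
each one into a pre-drawn pending update: an outcome drawn from the
absorption probabilities at its species, then a completion time from the
corresponding conditional law. Degradation outcomes are discarded. The
draws consume the same seeded RNG stream as the run, before the main loop,
so a full simulation is reproducible from one `set.seed()`.

## Simulation

`ssa_direct()` is the classical direct method under mass-action
propensities; one declared non-mass-action propensity form is supported
(the saturating autocatalytic law used by the glycolysis example), because
it only requires evaluating a scalar function of one copy number per step.

`dssa_rejection()` implements the rejection DSSA with *consuming* delayed
reactions: firing removes the reactants immediately and enqueues the
products at $t+\tau$. A tentative firing time is drawn from the total
propensity; if a queued completion precedes it, the tentative firing is
rejected, the completion is applied, and the waiting time redrawn — exact
by memorylessness of the exponential clock. Ties between a completion and
a tentative firing (probability zero in exact arithmetic) resolve in favor
of the completion, fixing reproducibility. Pending updates beyond the
horizon are discarded from the reported trajectory: molecules "in transit"
are invisible to SOI marginals by construction. Consuming semantics also
guarantee the queue can never drive a count negative, which the tests
check on event-recorded trajectories.

Both event loops are small C++ kernels (via Rcpp) drawing from R's own RNG,
so `set.seed()` governs history construction, firing times, reaction
selection and delay draws in one documented consumption order. Delay draws
are exact stage-wise exponential sums for the stage form and inverse-CDF
(bracketed bisection to $10^{-10}$ probability tolerance, as for the
R-level `distribution_quantile()`) for the residue and tabulated forms.

## Statistical validation

`walker_first_passage_sample()` is the brute-force oracle: independent
single-molecule jump chains run to absorption, with a mass-leak check that
errors when some transient state cannot reach any stop state.
`ks_compare()` tests sampled times against a closed-form law;
`compare_ensembles()` compares two trajectory ensembles by mean-difference
z-scores with combined standard errors at every checkpoint and a two-sample
chi-square on terminal histograms with adjacent bins merged until expected
counts reach 5.

All stochastic assertions run at $\alpha = 0.01$ (99% intervals). With the
number of simultaneous checks in the suite, occasional nominal failures are
expected; stochastic test blocks therefore retry once with a second fixed
seed, and a second failure is a real failure. A null-calibration test (20
same-model comparisons) keeps the machinery honest.

## The worked systems and study sizes

* **Bi-directional chain with bypasses** — ten species $S_0\ldots S_9$,
  SOIs at the ends, two uni-directional bypasses ($S_2 \to S_6$,
  $S_7 \to S_3$). The rates are the package's documented synthetic
  defaults (forward 1.0, backward 0.7, bypasses 0.5); the validation does
  not depend on the specific values. Ensembles: 1000 runs, horizon 10,
  initial $S_9 = 200$.
* **Minimalist glycolysis** — the published parameter set
  ($V = 500$, $\varphi = 0.5$, $q = 2$, $h = 5$, $\gamma = 2$, $g_i = 2$,
  $g_y = 0.5$, $h_i = 1$, $Y_0 = 100$) with the scheme reconstructed as
  follows, since only the parameters are available in the source text: the
  implicit PFK step consumes $q$ ATP with propensity
  $V(\varphi Y)^q/(1+(\varphi Y)^h)$ — autocatalytic at low ATP, inhibited
  at high ATP; a uni-directional intermediate chain $X_1\ldots X_4$ with
  the four stage rates $g_1\ldots g_4$ (equal by default, which is exactly
  the non-simple-eigenvalue case the stage representation covers); the
  completion step releases the pathway yield $m = 1 + \sum h_i = 4$ ATP at
  once, so that the single-delayed-reaction abridgement
  ($qY \to mY$ with the four-stage convolution delay) is exact; basal ATP
  synthesis at $g_y$ (without it, $Y = 0$ would be absorbing) and
  nonspecific consumption at rate $\gamma Y$. Ensembles: 2000 runs,
  horizon 40.
* **Kinetic proofreading** — $k_1 = 1$, $k_{-1} = 0.25$, $k_p = 5$,
  $N = 6$, $T_0 = M_0 = 200$. Completion probability
  $p = (k_p/(k_p+k_{-1}))^N \approx 0.7462$; completion delay the
  $N$-stage convolution of $\mathrm{Exp}(k_p + k_{-1})$; dissociation
  delay the tabulated mixture. Ensembles: 1000 runs, horizon 6 (binding is
  fast at these counts; the SOI dynamics are essentially settled well
  before then).

These run counts and horizons are the package's documented study sizes;
they give standard errors small enough that a systematic error of a
fraction of a molecule would be caught by the $|z| < 3$ screens.

## What the synthetic generator does and does not emulate

`random_chain()` draws uniform rates in $[0.5, 5]$ over chain lengths
3–12, with optional bypasses between random non-adjacent intermediates and
optional degradation/synthesis on intermediates. That covers the full
structural range of the theory (tridiagonal, bypassed, killed, open) at
rate ratios up to $10$. It does not emulate: strongly separated time
scales (rate ratios of $10^3$ and beyond, where the closed forms are exact
in principle but residue evaluation would need care), bimolecular
interactions inside a block, time-varying rates, or spatial effects.
Passing tests therefore demonstrate correctness of the reduction on
well-mixed monomolecular blocks at moderate rate heterogeneity — which is
the theory's stated domain — and nothing beyond it.

## Numerical choices, in one place

| choice | value | reason |
|---|---|---|
| eigen simplicity tolerance | $10^{-8}\times$ spectral radius | residue stability |
| residue sanity check | $|\sum c_k - 1| < 10^{-7}$, monotone spot grid | fall back rather than be wrong |
| tabulation grid | 512 geometric points, tail mass $<10^{-9}$, refine $\times 2$ until $<10^{-9}$ | smooth interpolation |
| quantile solver | bracketed bisection, $10^{-10}$ probability tolerance | CDF is monotone |
| uniformization truncation | $10^{-14}$ per step | machine-accurate oracle |
| probability conservation | $p_r + p_a + p_{deg} = 1$ to $10^{-10}$ | asserted, not assumed |
| DSSA tie-break | completion wins | reproducibility |

## Known limitations

* Non-simple eigenvalues combined with bypasses use the numeric CDF; the
  symbolic treatment of repeated roots is deliberately out of scope.
* Branching chains (a species with two distinct same-side chain
  neighbours) are rejected rather than guessed at; the supported topology
  is a linear chain plus bypasses, degradations and syntheses, with
  bimolecular reactions only at the SOI boundary.
* The deterministic delay-differential-equation analogue of the reduction
  is not implemented.
* Tabulated delays are sampled by interpolation on a grid whose tail stops
  at CDF $1-10^{-9}$; the corresponding truncation bias is far below the
  resolution of any statistical test in the suite.
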