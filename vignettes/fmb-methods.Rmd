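---
title: "Methods: from perturbed flux samples to a modular causal network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from perturbed flux samples to a modular causal network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmbr)
```

# The problem

A gene knockout does not disturb a metabolic network one reaction at a time:
flux redistributes through whole pathways that rise and fall together. fmbr
asks which groups of reactions respond to a perturbation as coherent
*metabolic modules*, and in which direction influence flows between those
modules. The pipeline turns a stoichiometric model plus a handful of measured
fluxes (intracellular fluxes from isotope-labelling experiments, and culture
rates such as growth and substrate uptake) into:

1. a large sample of steady-state flux distributions under a control and a
   perturbed condition,
2. a reduced set of perturbation-responsive *core reactions*,
3. a partition of those reactions into modules with synchronized
   flux-variation patterns,
4. local and global discrete Bayesian networks whose arcs suggest directions
   of influence among modules, and
5. per-reaction essentiality scores from single-deletion flux balance
   analysis.

# Flux sampling with randomized reconciled constraints

At steady state a flux vector $v$ satisfies $S v = 0$ with bounds
$\alpha \le v \le \beta$ (all fluxes in mmol/gDCW/h). Each measured reaction
$k$ contributes a target $t_k \sim \mathcal{N}(\mu_k, \sigma_k)$ truncated to
$[\mu_k - \sigma_k,\ \mu_k + \sigma_k]$: random errors may not exceed the
reported measurement error. Truncation is by rejection sampling rather than
clipping, so no probability mass piles up at the interval endpoints; a
measurement with $\sigma = 0$ degenerates to its mean. Because many targets
over-determine the LP, the sample is *reconciled* by least absolute
deviation:

$$\min_v \sum_{k} \left| v_k - t_k \right|
  \quad \text{s.t.} \quad S v = 0,\ \alpha \le v \le \beta,$$

solved as a linear program with positive/negative deviation variables. The
LAD optimum is typically degenerate in the unmeasured fluxes, so a secondary
LP holds the measured fluxes at their achieved values and minimizes
$\sum_j |v_j|$ (the parsimonious distribution). This makes each column a
deterministic function of its targets: all sampling variability comes from
the randomized targets, which is the intent of the design. There is no
biomass-maximization term in the sampling objective — the growth rate is
itself one of the measurements.

Repeating this $n$ times per condition (control model, and the model with
the knocked-out reactions' bounds fixed to zero) and merging the columns
gives the flux matrix. Reference settings are 1000 samples per condition;
the package's synthetic study conditions use 200 per condition, which is
ample for the designed effect sizes. Per-column seeds are derived
deterministically from the master seed and the (condition, index) pair, so
either condition can be regenerated independently.

**LP implementation.** All LPs here are small and heavily degenerate. The
package uses its own dense two-phase primal simplex with Bland's
anti-cycling rule: Bland's pivot choice is immune to the cycling that
degenerate reconciliation problems provoke, and it is deterministic, which
the reproducibility contract requires. Fixed variables
($\alpha_j = \beta_j$, e.g. knockouts) are eliminated as constants before
the solve. Exactly met targets are snapped to their target value so solver
epsilon (~1e-12) never leaks into downstream equality tests. The solver is
verified in the test suite against an independent HiGHS formulation on
random instances to 1e-8.

# Core-reaction selection

Three filters, in order:

* **Responsiveness.** A two-sided paired t-test per reaction, pairing the
  i-th control with the i-th perturbed sample; reactions with $P < 10^{-2}$
  pass. The test direction is two-sided because the sign of a perturbation
  response is unknown a priori, and pairing by sample index is exchangeable
  because columns are independently sampled. No multiple-testing correction
  is applied — the threshold is a raw cut, exposed as configuration.
  Reactions whose paired differences are constant at the numerical noise
  level get $p = 1$ (untouched) or $p = 0$ (certain shift) depending on the
  mean difference.
* **Activity.** Keep reactions with non-zero flux (|v| above the global
  zero tolerance of 1e-6) in *strictly more than* 95% of the samples of at
  least one condition.
* **Duplicate collapse.** Stoichiometrically coupled reactions carry
  identical rows and add no information; rows equal within a 1e-9 max-norm
  tolerance are grouped (transitively closed) and only the lexicographically
  smallest id is retained. The removed duplicates are kept in the
  bookkeeping and reinserted into their representative's cluster after
  modularization.

# Modularization by flux-variation pattern

Each core reaction's row is converted to a pattern of +1/0/−1: did the flux
rise, stay (within the 1e-6 tolerance), or fall between consecutive samples?
Since the sample order is arbitrary, the columns are permuted uniformly at
random (Fisher–Yates, via R's seeded generator) and the resulting pattern
matrices are adjoined horizontally; the reference setting is 300
permutations, the synthetic study conditions use 20. Because squared
Euclidean distances add across adjoined blocks, the package accumulates
pairwise distances block by block and never materializes the full adjoined
matrix; the result is contractually identical to the naive construction
(tested).

Rows are clustered by average-linkage agglomeration on Euclidean pattern
distances. The tree is cut with the *inconsistency coefficient* at depth 2
(the link's height compared to the mean and standard deviation of its own
and its direct children's heights) at a cutoff of 1.0. A raw distance cutoff
of 1.0 would be meaningless on pattern rows hundreds of thousands of columns
wide — every row would be a singleton — so the inconsistency criterion is
the semantics that makes a cutoff of 1.0 coherent; a `distance` criterion
remains available for sensitivity analysis. Links merging two singletons
have coefficient 0, and so do links whose local heights are all equal;
clusters are the maximal subtrees all of whose internal links stay at or
below the cutoff. Cluster ids are assigned 1..C ascending by smallest member
row index, making the numbering deterministic.

# Bayesian networks, representatives, essentiality

**Discretization.** All 2·n samples of each clustered reaction (original
flux values, not patterns) are discretized once with a shared equal-frequency
scheme into k = 4 intervals. Tied values are never split across bins: every
occurrence of a value receives the bin of its tie group's mid-rank, so a
knockout's point mass at zero lands in a single bin. Fewer than k distinct
values collapse to the number of distinct values with a warning. Computing
the binning once keeps mutual information and network scores mutually
consistent between local and global learning.

**Scoring.** A structure's score is the minimum description length in bits,

$$\mathrm{MDL} = \frac{\log_2 M}{2}\sum_i q_i (r_i - 1)
  \;-\; \sum_i \sum_{s=1}^{M} \log_2 \hat p(x_{is} \mid \mathrm{pa}_{is}),$$

with $r_i$ observed states of node $i$, $q_i$ parent configurations, and
maximum-likelihood conditional frequencies. The $(\log_2 M)/2$ constant per
free parameter is the standard MDL (BIC-in-bits) choice. Reported
conditional probability tables use Laplace (+1) smoothing, but the
likelihood inside MDL uses unsmoothed ML counts, as MDL theory assumes. The
score decomposes over families, which the search exploits through caching;
family-wise caching is observationally equivalent to full recomputation
(tested).

**Search.** Tabu search over DAG space with arc addition, deletion and
reversal, rejecting cycles and parent sets larger than 4 (a cap that keeps
CPTs supported by ~2000 samples). The inverse of each applied move goes on a
tabu list (length 10); the search accepts the best non-tabu neighbor even
when it worsens the score, escaping local minima, with an aspiration
exception for moves that beat the best score ever seen. The best-ever DAG is
returned. Three restarts (empty graph, then random seeded DAGs) make the
search exact on all 25 three-node structures in the test suite's exhaustive
comparison. The published analysis this design follows used a proprietary
"tabu order" variant; standard score-based tabu search over the same move
set is the package's documented approximation.

**Representatives.** Within each module the total mutual information of a
member is the sum of its pairwise empirical MI (in bits, so identity under
four equal-frequency bins is exactly 2) against all other members; the
member with the highest TMI represents the module, with lexicographic
tie-breaking, and the tie is flagged. MI is computed from the empirical
discretized data rather than from the learned local network's joint — the
source narrative is ambiguous between the two, and the empirical estimate
is the choice that does not depend on the learned structure. The global
network is then learned over the representatives only.

**Essentiality.** For each reaction, maximal growth is computed by FBA with
the measured constraints fixed to their $\mu \pm \sigma$ intervals, the
growth-rate measurement removed (otherwise growth is pinned and every
deletion is trivially neutral or infeasible), and the reaction's bounds set
to zero; then $e = \mathrm{clamp}(1 - g_\Delta / g,\ 0,\ 1)$ where
$g_\Delta$ is the deletion growth and $g$ the intact reference. A deletion
that leaves growth unchanged scores 0, one that stops growth (or makes the
LP infeasible) scores 1, and a growth-increasing deletion is clamped to 0.
The formula's direction follows the stated meaning of the scale (one =
complete stoppage); the source's symbol definitions are internally
inconsistent on this point and the prose was followed.

# The synthetic study conditions

`make_toy_model()` builds the fixture every desk-scale claim is tested on:
a substrate uptake that splits into parallel linear chains reconverging on
one biomass precursor. Design choices, fixed before any test was run:

* Each chain is stoichiometrically coupled, so within-module flux
  correlation is exactly 1 — the idealized version of the coupling that
  makes modules detectable in real networks. One chain reaction doubles its
  product's stoichiometry so that chain members are correlated but not all
  duplicates, exercising both the duplicate collapse and the clustering
  path.
* The uptake exchange (negative by the uptake-sign convention) and the
  growth rate are measured with $\sigma = 0$. These pseudo-reactions are
  therefore pinned to the same value in every sample of both conditions,
  and the paired t-test provably excludes them — the fixture's ground truth
  is exact, not probabilistic.
* All but the last chain's branch reactions carry noisy measurements
  ($\sigma$ = 10% of the branch share); the last chain is the unmeasured
  slack route. Every randomized target set is then exactly achievable, the
  LAD residual is 0, and each reconciled flux stays within $\sigma$ of its
  measured mean — the flux-matrix invariants hold by construction, not by
  tolerance.
* The perturbed condition knocks out the first branch (measured as 0 with
  $\sigma = 0$, as a knockout flux would be) and shifts the remaining
  measured means so flux must reroute through the sibling chains.

Default test scale is 3 modules × 4 reactions, 200 samples per condition
and 20 pattern permutations; the full pipeline on these conditions runs in
a few seconds and recovers the designed modules with adjusted Rand index
1.0 across seeds. What this does *not* show: real flux cones have
correlations strictly between 0 and 1, alternate optima that the
parsimonious tie-break only partially disambiguates, and measurement errors
that are not independent across reactions. Passing the fixture demonstrates
the machinery, not field performance on genome-scale data.

The genome-scale demonstration inputs (the published 979-reaction
*E. coli* model) are external; the packaged
`ecoli_lpda_constraints.csv` carries the published wild-type and
lpdA-knockout measurements so that a user who obtains the model SBML can
reproduce that analysis with `run_fmb()` defaults.

# Numerical conventions

| quantity | value | where |
|---|---|---|
| zero tolerance on fluxes | 1e-6 | activity, pattern ties, t-test degeneracy |
| duplicate-row tolerance | 1e-9 (max-norm) | duplicate collapse |
| target truncation | ±1σ, rejection sampling | constraint randomization |
| LAD tie-break | parsimonious secondary LP | flux sampling |
| clustering cutoff | 1.0, inconsistency, depth 2 | modularization |
| discretization | k = 4, equal frequency, mid-rank ties | Bayesian networks |
| MDL constant | (log₂M)/2 per free parameter | structure score |
| tabu list / restarts / parent cap | 10 / 3 / 4 | structure search |
| essentiality clamp | [0, 1] | deletion FBA |

# Known limitations

* The simplex solver is dense and intended for models up to a few hundred
  reactions; genome-scale models solve but slowly.
* Structure learning over more than a few dozen representatives is
  heuristic; arcs should be read as candidate influences, not causal proof.
* Gene–protein–reaction associations are out of scope: knockouts and
  deletions are reaction-level.
* The SBML reader covers stoichiometry, reversibility and flux bounds only.
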