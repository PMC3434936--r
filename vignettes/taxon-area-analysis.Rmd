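---
title: "Likelihood-based taxon-area analysis: models, choices, limits"
author: "paeML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based taxon-area analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, the parameters that matter, the numerical and design choices made
where the method leaves them open, what the synthetic-data generator does
and does not emulate, and the known limits of the approach.

## The model

The data object is a binary taxon-area matrix: areas in rows, species in
columns, cell = 1 if the species occurs in the area.  Treating each species
as one binary character of the *areas*, relationships among areas are
estimated with standard phylogenetic machinery.  The likelihood engine uses
the two-state Mk model: a reversible continuous-time Markov chain on
{absent, present} with equal gain and loss rates and uniform stationary
frequencies (1/2, 1/2).  With unit base rate and a rate multiplier $r$, the
transition probabilities on a branch of length $t$ have the closed form

$$P_\text{same}(t) = \tfrac12\bigl(1 + e^{-2rt}\bigr), \qquad
  P_\text{diff}(t) = \tfrac12\bigl(1 - e^{-2rt}\bigr),$$

so branch lengths are expected state changes per character.  Biologically a
0→1 change is a colonisation (dispersal into the area) and 1→0 a local
extinction; the package reports direction-resolved change counts and leaves
the biogeographic labels to the user.

Likelihoods are computed by Felsenstein pruning over unique site patterns
(a compiled kernel; a pure-R reference path is kept and cross-checked in the
tests), marginalising the root over the uniform prior.  Because the model is
reversible and symmetric, the likelihood is invariant under rerooting; the
package exploits this by fitting in a canonical rooting (at the
lexicographically first area) so that a fit depends only on the unrooted
topology.

**No ascertainment correction.**  Conditioning on variable characters (the
"Mkv" correction) is deliberately absent: the method's distinctive move is
that all-zero columns carry information under likelihood, which is what
makes hypothetical extinct taxa (appended all-zero columns) a meaningful
perturbation.  Under parsimony the same columns are invisible — constant
characters cost no steps — and this contrast is asserted in the test suite.

## Parameters and defaults

* **Gamma rate heterogeneity (+G).**  Per-character rate multipliers are the
  means of $k$ equal-probability quantile classes of a Gamma($\alpha,
  \alpha$) distribution (unit mean).  $k = 4$ by default — the convention of
  the mainstream likelihood programs this analysis style was built on; the
  category means are computed in closed form from the incomplete-gamma
  identity and match `phangorn::discrete.gamma`.  $\alpha$ is bounded to
  $[0.02, 100]$; an estimate pinned at 100 simply means "no detectable
  heterogeneity".
* **Invariant class (+I).**  A zero-rate class of proportion
  $p_\text{inv} \in [0, 0.99]$ mixed with the gamma classes (gamma means are
  not rescaled; the mixture weights are $p_\text{inv}$ and
  $(1-p_\text{inv})/k$).
* **Branch lengths.**  Bounded to $[10^{-6}, 10]$ expected changes to keep
  the optimiser away from the singular limits $t = 0$ and $t = \infty$.
* **Optimisation.**  On a fixed topology, branch lengths are optimised
  jointly by bounded quasi-Newton search (L-BFGS-B on the log scale) using
  the analytic gradient of the log-likelihood, alternating with Brent line
  searches for $\alpha$ and $p_\text{inv}$, until the relative improvement
  falls below $10^{-8}$.  Optimisation is deterministic; two fixed starts
  (branch lengths from parsimony change counts divided by the character
  count, and uniform 0.1) are tried and the better optimum kept, because the
  branch-length surface of small binary matrices can have local optima.

## Rooting conventions

Two devices are provided, mirroring standard PAE practice.  The *all-zero
artificial outgroup* is realised as an extra area row containing no species,
so ML and MP treat rooting identically through the data rather than through
a constraint.  *Lundberg rooting* instead roots the unrooted optimum
a posteriori on the terminal branch of the area with the fewest occurrences;
the root is placed at the midpoint of that branch (the method does not
specify an attachment point; the midpoint is chosen for determinism, and the
unrooted topology is provably unchanged).  A tie for the minimum is an
error that demands an explicit choice, never a silent pick.

## Tree search and support

Heuristic searches use stepwise random-addition starting trees followed by
hill climbing over NNI or SPR neighbourhoods.  Insertion during random
addition is scored by Fitch parsimony for both objectives: at 13–14 tips
the starting tree only needs to be in the right basin, and scoring every
insertion by optimised likelihood would multiply the cost for no benefit.
The SPR neighbourhood is generated by pruning every split side exactly once
(in a rooting anchored at the first tip outside the pruned set) and
regrafting on every remaining edge; its size matches the known
$2(n-3)(2n-7)$ count and strictly contains the NNI neighbourhood, which the
tests assert.  For parsimony, all equally optimal trees (up to a cap) are
collected by plateau walking; for likelihood the single best topology is
kept and fully re-optimised.  TBR is not implemented: at this problem size
SPR with multiple random starts reaches the same optima, and the tests
verify exhaustive-search equivalence on small instances directly.

Likelihood candidates are scored with full-tolerance fits by default so the
search ranks topologies exactly as the final refit does; a coarse-scoring
control is available for larger problems.

Bootstrap support resamples species columns with replacement (characters
are the sampling units; areas are never resampled), reruns a reduced search
per replicate, and maps bipartition percentages onto the best tree.
Scaled-down defaults (e.g. 100 replicates) keep desk runs fast; the
original-scale 2500 replicates are one flag away.

## Stochastic character mapping

Species histories are sampled from their exact posterior in two steps.
Joint node states: the root state is drawn from its conditional posterior
(pruning partials times the uniform prior) and descendants top-down from
transition probability times subtree partial.  Branch paths: conditioned on
the branch's endpoint states, the number of flips of the symmetric binary
chain is Poisson($rt$) restricted to the parity of the endpoint
disagreement, and flip times are uniform order statistics.  This works
because uniformisation of the two-state symmetric chain with dominating
rate equal to the leaving rate makes every auxiliary event a real flip — so
the sampler is exact for all branch lengths, with no rejection loop and no
approximation.  (A forward-simulation-with-rejection scheme was considered
and dropped: it is exact only where it is also slower.)  The tests validate
the zero-change probability and the conditional mean change count against
the analytic laws, and sampled node-state frequencies against the pruning
marginals.

The rate used for a species' map is, by default, the posterior mean of the
rate-class multiplier given that species' data under the fitted model
(`characterRate()`); a uniform-rate simplification is available.  1000
samples per species is the default — enough for per-branch expectations
with Monte-Carlo error well below the quantities' natural variability.

The MP comparator (`mpAncestralStates()`) returns, per node, the set of
states occurring in at least one minimum-change labelling, by an up/down
dynamic programme over change counts; it is validated against exhaustive
enumeration.  The contrast the mapping literature draws — parsimony
reconstructions cannot place multiple changes on a branch or separate time
from change count — can be reproduced directly by comparing the two outputs
for the same species.

## The synthetic-data generator

`simulateMatrix()` evolves characters forward along a known tree under the
exact model the engines assume, optionally with gamma rates, with full
histories retained for oracle comparisons.  `lvvFixture()` builds a
13-area, 1018-species matrix with 23 narrow endemics emulating the
structure of the Lower Volga Valley flora: a river-valley/delta clade
{P, BK, ZIB, XE, AH, BC}, steppe pairs {VP, ZP} and {A, C}, BAC next, and
BOG sister to everything.

The fixture's generating tree and parameters are fixed constants, chosen
once as follows and not revisited:

* All non-BOG root-to-tip depths are equal (0.5 expected changes).  With
  the root presence probability at 0.8, expected occupancy is then *flat*
  across the ingroup; only BOG's long pendant (1.0) decays towards the
  stationary 50%, making BOG the least-occupied area by a wide margin
  (~100+ species) without confounding occupancy with tree depth.  Early
  drafts that let depth vary produced exactly that confound: under heavy
  all-zero augmentation the fitted $\alpha$ collapses and
  occupancy-similar areas attract, breaking the generating clades.
* Internal branches (0.03–0.18) each expect tens of synapomorphies over
  ~1000 characters — strong signal, so heuristic searches recover the
  generating topology exactly (asserted at RF = 0 in the tests).
* Ordinary characters are re-drawn until present in ≥ 3 areas, so the
  fixture's narrow endemics are exactly its 23 designated columns; 14
  endemics are fixed to the Baer-knoll pair {ZIB, BK}, the rest are
  simulated at low rate from an absent root and re-drawn until they occupy
  one or two non-BOG areas.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring areas, asymmetric gain/loss (real colonisation and extinction
rates differ), species interactions, or any occupancy structure beyond what
the symmetric Mk chain produces.  Passing the recovery tests therefore
shows the estimators are correct *under the model*, not that the model is
adequate for any particular real flora.

## Numerical choices and degenerate inputs

* Site patterns are compressed before likelihood evaluation; per-character
  values are recovered through the pattern index.
* UPGMA agglomeration ties are made deterministic by canonicalising area
  order (lexicographic) before clustering; dendrogram heights are half the
  merge distances, making the output exactly ultrametric.
* A matrix whose characters are all constant has no signal: branch lengths
  are driven to the lower bound with a warning, not an error.
* `?` or any non-binary symbol in input is a validation error naming the
  area and character — missing data is unsupported because the pruning
  engine assumes fully observed tips, and silent coercion would corrupt the
  all-zero-column logic.
* Segment tables of a character map must partition each branch to within
  $10^{-9}$ relative tolerance; SIMMAP round trips are exact.
* All stochastic components (simulation, search restarts, bootstrap,
  mapping) are reproducible from integer seeds; scenario batteries derive
  per-scenario seeds as seed + index.

## Problem sizes used in the checks

The test suite validates the engines by exhaustive oracles at small size
(likelihood vs brute-force enumeration for ≤ 6 tips; searches vs all 105
six-tip topologies; ancestral sets vs exhaustive labellings) and the full
pipeline at study scale (13 areas × 1018 characters for recovery and
augmentation checks; 5000 characters for gamma-shape recovery; $10^5$ draws
for the conditioned path law).  These sizes are the package's own choices:
large enough that Monte-Carlo error is far below the tested tolerances,
small enough that the whole suite runs in minutes.

## Known limitations

* Symmetric rates only: no separate colonisation/extinction rates, no
  covarion-like switching, and no model selection machinery.
* Areas are exchangeable: no spatial adjacency, no DEC-style constrained
  dispersal matrices, and no time calibration — branch lengths are change
  counts, not durations.
* The likelihood treats species as independent characters; correlated
  ranges (shared habitat, vicariance affecting whole communities) violate
  this and will inflate confidence.
* With many appended all-zero columns the fitted gamma shape collapses
  towards its lower range as the rate distribution absorbs the invariant
  mass; scenario results should be read as the model's answer to "what if
  this many species went extinct everywhere", not as robust inference about
  the palaeoflora.
* Heuristic searches carry no optimality guarantee beyond the tested sizes,
  though random restarts plus SPR have always reached the exhaustive
  optimum in the package's own validation.
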