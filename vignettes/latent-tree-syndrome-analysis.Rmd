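---
title: "Latent tree analysis of binary manifestation data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent tree analysis of binary manifestation data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lantree` analyzes a records × symptoms matrix of binary clinical
manifestations (1 = present, 0 = absent) with a *latent tree model* (also
called a hierarchical latent class model): a rooted tree-structured Bayesian
network whose leaves are the observed binary manifestations and whose
internal nodes are unobserved discrete variables. The root carries a marginal
distribution over its states; every other node carries a conditional
probability table (CPT) given its parent. Each latent variable clusters the
records along one dimension, so a model with several latent variables is a
multidimensional clustering of the cohort: different latent variables capture
different co-occurrence patterns among symptoms.

The model's defining quantity is the marginal likelihood of the observed
manifestations, computed exactly by upward message passing on the tree
(`loglikelihood()`). A brute-force enumeration oracle (`enumerate_joint()`)
is part of the package surface: every inferential quantity — record
likelihoods, latent posteriors, and mutual information — is testable against
full enumeration on small models, and the test suite does exactly that at
tolerance 1e-9.

## Parameter estimation

`fit_em()` estimates CPTs for a fixed structure by EM. The E-step is exact
tree inference; the M-step sets each CPT row to its expected-count ratio
with 0.01 pseudo-counts added per cell, which is MAP estimation under a
Dirichlet(1.01) prior and protects sparse cells in cohorts of a few hundred
records from collapsing to zero. Because the M-step maximizes the penalized
objective, the monitored quantity in `loglik_trace` is the data
log-likelihood *plus* the smoothing prior term `0.01 · Σ log θ`; this is the
quantity EM provably never decreases, and it equals the plain log-likelihood
when `smooth = 0`. The trace non-decrease (tolerance 1e-8) is asserted
property-style across random structures in the tests.

The likelihood surface is multimodal, so fits use restarts (default 8) from
symmetric Dirichlet(1) draws; restart seeds derive deterministically from
the user seed. Convergence is a relative objective change below `tol`
(default 1e-6) or `max_iter` (default 500). Ties across restarts resolve to
the highest final objective, then the lowest restart index. During
inference, CPT cells are floored at 1e-12 (configurable) so a
sampling-zero cell cannot produce `log(0)` for an attainable record.

Latent cardinality is bounded to 2–5 by default. Cardinality 1 is also
representable: it degenerates to the independence model, which is useful as
a baseline (its BIC parameter count is exactly the number of manifest
variables).

## Structure search

`search_structure()` learns the tree by greedy hill-climbing on BIC
(`loglik − (d/2)·ln N`, `d` = free CPT parameters), cycling through three
phases until no candidate improves the score:

* **expansion** — introduce a new 2-state latent variable over a
  high-affinity sibling pair, or add a state to an existing latent variable;
* **adjustment** — relocate nodes (manifest leaves or latent subtrees) to
  better-fitting latent parents;
* **simplification** — delete latent states or whole latent nodes.

Candidate moves are scored with a short EM warm-started from the current
parameters (up to 100 iterations; relocations, which only need the moved
edge to adapt, get 40) and each accepted winner is re-fitted at the full
budget — two-stage scoring that keeps search tractable at desk scale. A
fully random restart per candidate was deliberately dropped: it burns its
whole iteration budget without out-scoring the warm start, and tripled the
cost of a 57-column search. Expansion candidates are ranked by
*cost-effectiveness* — BIC improvement per added free parameter — rather
than raw improvement, and when a parent has surplus states a compound
candidate (introduce the new latent and delete one parent state) is also
offered. Both choices prevent parameter-hungry state additions from
inflating the initial latent class variable until no introduction can beat
it, a local optimum observed with raw-BIC greedy ranking.
Sibling pairs and relocation targets are pre-ranked by an empirical
mutual-information affinity between the manifest descendants of the
candidate nodes, and only the top-ranked few are fitted (`k_intro`,
`k_parents`). The adjustment phase scores relocations in isolation and
applies all individually improving moves as a batch, keeping the batch only
if the re-fitted BIC confirms the improvement; otherwise it falls back to
the single best move. Ties between candidates break lexicographically by
(operator, description), and every random draw derives from the
configuration seed, so a search is a deterministic function of
(data, configuration).

The search starts from a single 2-state latent class variable over all
columns (the simplest connected structure). Termination is guaranteed
because accepted moves strictly increase BIC, which is bounded above. On
planted-block data with between-state contrast ≥ 0.6–0.8 and a few thousand
records, the search recovers the planted manifest partition exactly
(adjusted Rand index 1.0); this is asserted over repeated seeds in the
acceptance tests.

## Information curves

A fitted latent variable is interpreted through its information curve
(`information_curve()`): manifest variables are ordered by decreasing
pairwise mutual information with the latent variable (ties broken
alphabetically), and the joint ("cumulative") mutual information of each
prefix is accumulated. The *information coverage* of the first k variables
is the percentage of `I(Y; all variables in scope)` they carry; the
conventional reading truncates the list at 95% coverage
(`select_significant()`), which yields the latent variable's significant
manifestations. `threshold = 0` selects just the first entry (a selection is
never empty by convention), `threshold = 100` selects the whole scope.

MI is computed from the fitted model distribution, not raw cell counts: the
curves describe the model, and the model smooths sampling noise. Pairwise MI
is exact (transfer matrices along the tree path between the two variables).
Cumulative MI is exact by enumeration while `card(Y)·2^k ≤ 2^20`; beyond
that a seeded Monte-Carlo estimator of `E_x[KL(p(y|x) ‖ p(y))]` is used,
with one shared sample across all prefixes of a curve (20 000 draws by
default) and reported standard errors. Joint MI is monotone in the variable
set; the Monte-Carlo draws are made monotone by a running maximum, with the
raw values kept in an attribute. MI is reported in bits; coverage is
scale-free, so the log base cannot affect any selection.

Two scope conventions exist in practice for the coverage denominator: all
manifest variables in the model, or only the latent variable's own manifest
descendants. Both are implemented (`scope = NULL` and `scope = "children"`);
the model-wide scope is the default, and the restriction is available
per-latent and in the pipeline configuration.

## Joint clustering and sub-syndromes

A *syndrome factor* is a named group of latent variables that carry the same
clinical factor; the mapping is declarative configuration
(`syndrome_factor_map()`), shipped as a JSON fixture carrying the
five-factor liver-cancer mapping. For each factor, `build_jcm()` pools the significant
manifestations of the member latent variables, fits one new latent class
variable Z over the pooled columns (the *flat* joint clustering model), and
selects Z's cardinality by BIC within 2–5. The alternative of making Z a
parent of re-fitted member latents is deliberately not the default: the flat
model is identifiable, cheap, and directly yields the factor-level
information curve. Z's curve is computed with the pooled columns as scope,
and the factor's exclusion list — pure expert configuration, never computed —
is removed from the selection while preserving curve order.

When Z has three or more states the factor decomposes into sub-syndromes
(`subdivide()`). In clinical practice such splits are expert judgments, so the package
uses a reproducible quantitative surrogate: the baseline state is the state
with the lowest mean manifestation probability, and each pooled manifest is
assigned to the state maximizing its lift `P(m=1|z=s)/P(m=1)` (lifts ≤ 1
leave the manifest unassigned; ties go to the earlier state index). Each
non-baseline state with assigned manifests becomes a sub-syndrome, re-fitted
as its own flat latent class model with its own curve and selection. The
assignment depends only on the fitted distribution, so it is invariant to
latent-state relabeling.

## The synthetic cohort generator

No patient-level data are distributable, so `plc_cohort_preset()` emulates
the *shape* of the study cohort: 559 records, 57 binary symptoms grouped
into 14 planted blocks (Y0–Y13), sex 482:77 and a six-level stage tag
(66/72/92/171/139/19) generated alongside but excluded from fitting. Block
memberships follow the per-latent symptom groupings reported in
liver-cancer syndrome-differentiation work where stated (43 of the 57
symptoms); the remaining 14 symptoms are assigned to
clinically plausible blocks, and these assignments — like all the preset's
probabilities — are declared synthetic defaults, not estimates (true prevalences for such
cohorts are not available). Member loadings default to 0.6
(`P(present|active) = 0.8` vs `0.2`); the fever block carries three weak
members (rapid pulse, ascites, pale lips and nails; loading 0.25) mirroring
the thin edges drawn for that latent variable.

Nine of the fourteen blocks are tied in a chain with weak latent–latent
coupling (0.1), preserving block identifiability while inducing mild
cross-block dependence. The five deficiency-related blocks (Y2, Y3, Y10,
Y11, Y12) instead hang off a 3-state hub latent with a baseline state and
two deficiency patterns (Y10 active under both; hub-to-block activation
0.97, nearly deterministic, so the three planted conditions rather than
block-level noise dominate the pooled deficiency columns): the deficiency factor of the emulated
cohort exhibits three conditions and two sub-syndromes, and a purely binary chain cannot reproduce that finding, so
the generator plants it explicitly. This is the one deliberate departure
from an all-chain backbone, and it is what makes the end-to-end fixture
meaningful: on the preset, the pipeline learns the block structure, builds
five factor JCMs from the shipped map, assigns the deficiency factor three
states, and splits it into exactly two sub-syndromes.

What the generator does **not** emulate: real symptom prevalences, severity
gradations, inter-rater noise, missing data, or any correlation structure
beyond the planted blocks and their weak coupling. Passing tests therefore
demonstrate that the algorithms recover structure that is genuinely present
under the model class — not that the clinical conclusions of any particular
cohort are correct.

## Numerical and design choices

* All randomness flows from a single master seed through a documented
  derivation (`seed × 69991 + string hash`, kept below 2^31); reruns are
  byte-identical, which the tests assert on full pipeline output.
* Duplicate records are collapsed to weighted unique rows inside EM; the
  sufficient statistics are unchanged and the E-step cost drops with the
  number of distinct profiles.
* Missing cells are rejected by default (`strict = TRUE`); the optional
  lenient mode drops incomplete records with a logged count. EM with missing
  data is deliberately out of scope.
* The frequency-screen cutoff has no default: in practice symptom screening
  combines frequency analysis with literature and expert input whose
  weighting is study-specific, so the cutoff must be an explicit analysis
  choice.
* Problem sizes in the test suite are chosen for a desk-scale run: oracle
  equivalence uses models of ≤ 12 variables, EM recovery n = 5000, structure
  recovery two blocks × four leaves at n = 2000 across 10 seeds, and the
  end-to-end fixture is the full 559 × 57 preset.

## Known limitations

* The structure search is greedy; it follows the expansion/adjustment/
  simplification phase design of the EAST search family but is not a
  bit-for-bit reproduction of any particular implementation, and on weak-signal data it can stop at a local optimum
  (restarts and the seed make this reproducible, not impossible).
* Flat joint clustering conditions on raw columns, not on the base model's
  posteriors; the hierarchical alternative is a documented non-default.
* Expert exclusions and factor membership are configuration, so the
  pipeline's "typical manifestation" lists are only as good as the supplied
  map.
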