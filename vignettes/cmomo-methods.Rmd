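---
title: "Constrained multi-objective molecular optimization: methods and design"
author: "cmomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained multi-objective molecular optimization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lead optimization rarely means improving one number. A candidate must
simultaneously gain drug-likeness (QED), retain similarity to the lead it
came from, improve a physico-chemical or activity score — and at the same
time respect hard medicinal-chemistry criteria that are not gradable
preferences but go/no-go rules: rings outside the five-to-six-atom window
are hard to synthesize or unstable, and structural alerts (nitro groups,
aldehydes, epoxides, Michael acceptors, ...) are grounds for rejection
regardless of how good the scores look. `cmomo` treats the former as
objectives of a multi-objective search and the latter as constraints:

$$\max_x \; F(x) = (f_1(x), \dots, f_m(x)) \quad \text{s.t.}\quad g_i(x) \le 0 ,$$

where $x$ is a molecule. Every objective is stored in maximization
orientation; an objective declared `direction = "minimize"` is negated
once, at evaluation time, and nowhere else. The solution concept is the
*constrained Pareto front* (CPF): the set of non-dominated objective
vectors among feasible molecules.

## Search space: a pluggable latent codec

The optimizer never edits molecular graphs. Molecules are embedded in a
fixed-dimension continuous latent space by an encoder–decoder
(*codec*), variation operates on the vectors, and candidates are decoded
back to SMILES for evaluation. The codec is a plug-in contract
(`encodeMolecule`, `decodeVector`, `codecDim`, `codecBounds`); a
pretrained SMILES autoencoder can be wrapped with `functionCodec()`. The
package does not ship pretrained weights. Instead it provides two
deterministic codecs that make the full pipeline testable:

* `tableCodec()` — exact lookup on a fixed table of molecules; decoding
  returns the nearest entry (Euclidean, ties to the lowest index). Round
  trips are exact on the table; decoding is total and deterministic.
* `identityCodec()` — "molecules" are coordinate strings; used by the
  analytic test problem below.

Decoded batches pass through `decodeValidBatch()`: decode failures and
invalid SMILES are dropped (mirroring validity filtering with RDKit),
survivors are canonicalized, and duplicates are removed within the batch
and — by default — against the parent population. The parent-dedup switch
(`dedupeAgainstParents`) exists because a nearest-neighbour decoder maps
many latent vectors onto few molecules; without it a table-codec
population collapses onto a handful of entries.

## Constraints and violation degrees

Each constraint contributes a raw violation degree $\sigma_c(x) \ge 0$,
zero exactly when satisfied:

* **Ring size** (`ringSizeCV`): over the SSSR ring sizes $r_k$,
  $\sigma_1(x) = \sum_k [\max(r_k - 6, 0) + \max(5 - r_k, 0)]$. SSSR is
  used because the formula presumes an enumerable ring list; fused
  systems can differ under other ring perceptions, which is why the
  choice is fixed and documented.
* **Structural alerts** (`substructureCV`): the number of *distinct*
  alert SMARTS with at least one match. Distinct-pattern counting (rather
  than match instances) reads the violation as "how many kinds of alert
  are present"; a molecule with two nitro groups violates the nitro alert
  once. The packaged list (`inst/extdata/structural_alerts.smarts`,
  28 patterns) is a curated subset of widely used reactive/toxic alerts
  and is user-replaceable; larger published alert collections can be
  dropped in as a file.

For selection, violations are aggregated with max-normalization over the
set $\psi$ of molecules in scope:
$CV(x) = \sum_c \sigma_c(x) / \max_{x_i \in \psi} \sigma_c(x_i)$, with a
zero-maximum column contributing zero (an all-feasible constraint has no
discriminating information; this is the 0/0 convention). $\psi$ is the
union of parents and offspring at the moment of selection — the only
population in scope there; whether a global archive would serve better is
an open question we resolved in favour of locality. Two properties matter
and are tested: aggregation is invariant to rescaling any constraint
column, and *feasibility is always decided on raw sigmas* (all zero), so
normalization can never turn an infeasible molecule feasible.

## Variation: blended crossover plus fragment mutation

Two parents $z_1, z_2$ produce children
$z' = z_1 + (-d + (1 + 2d)\,u)(z_2 - z_1)$ with independent uniform draws
$u_1, u_2$ for the two children. $d = 0$ interpolates strictly between the
parents; the default $d = 0.25$ is the classic blend setting that also
extrapolates a quarter-length beyond either parent. Children are clamped
to the codec bounds.

Mutation is fragment-local, built for long latent vectors (hundreds of
dimensions): the vector is split into `nFrag` contiguous near-equal
fragments (first `D mod nFrag` fragments one gene longer), one fragment is
drawn uniformly, and each gene inside it is perturbed independently with
probability `pM` by additive Gaussian noise. Restricting mutation to one
fragment keeps the effective mutation dimensionality at `D/nFrag`
regardless of `D`. The numeric action of the mutation is not prescribed by
the scheme itself; additive Gaussian noise with standard deviation 0.1 of
the per-dimension bound range (0.1 absolute when unbounded) is standard
real-coded EA practice, and the scale is exposed as `mutationScale`.
Defaults `pM = 0.5`, `nFrag = 8` are package choices (the fragment count
silently drops to the latent dimension for low-dimensional codecs).
Mating is uniform random pairing without self-pairing — no tournament.

## Two-stage selection

**Stage 1 (unconstrained):** classic NSGA-II environmental selection on
the parent∪offspring union — non-dominated sorting, then whole fronts
while they fit, then truncation of the boundary front by smallest crowding
distance. Constraint values are computed and cached for logging but *never
consulted*; a test swaps the constraint evaluators and verifies the
stage-1 trajectory is unchanged. This stage explores property space
without being repelled by the feasibility boundary.

**Stage 2 (constrained):** every union member receives two ranks:

* $S_1$: *property preference* — sort by (Pareto front asc, crowding
  desc); position = rank.
* $S_2$: *constraint preference* — same procedure, but fronts come from
  the **constraint dominance principle**: feasible beats infeasible;
  among infeasible, smaller aggregated CV wins; among feasible, Pareto
  dominance decides. Crowding within CDP fronts is computed on objective
  values (mirroring its NSGA-II role as a density tie-break).

Both are full permutations of $1..N$. They are blended into a
comprehensive score $S = \alpha S_1 + (1 - \alpha) S_2$ (smaller is
better) with the cosine decay
$\alpha(t) = \tfrac12 (1 + \cos(t\pi/T))$, $T$ = configured stage-2
length. $\alpha$ starts at exactly 1 (pure property preference — the
scenario switch does not jolt the search), decays slowly early, fastest
mid-stage, and approaches 0 (pure constraint preference) at the end.
The driver's generation index runs $t = 0, \dots, T-1$; the $t = T$
anchor of the schedule is exercised by the schedule function itself and
its tests. Infeasible but high-property molecules thus survive the early
constrained stage and can carry the search across infeasible gaps toward
disconnected parts of the CPF.

All tie-breaks (crowding ties, score ties) go to the stable input index,
making both selections deterministic functions of the union ordering —
a requirement for the bitwise reproducibility the driver guarantees.

## Initialization: the Bank library

Rather than random starts, the initial population is seeded from a *Bank
library*: the candidate database is screened for molecules with Tanimoto
similarity to the lead at least `simMin` (default 0.2) and screening
property (default QED) at least `propMin`, ranked by property then
similarity then input order, and the top `bankSize` members are encoded.
Each member is blended with the lead by the crossover above; decoded,
valid, distinct children accumulate until `P` molecules exist (retry
budget `10 P` draws, shortfall padded with the lead and recorded in the
bank's provenance). The screening defaults are package choices, recorded
per-run so results are self-describing. For codec worlds without a
molecule database (the analytic problem), `init = "uniform"` draws seeded
uniform latent vectors inside the codec bounds instead.

## Objectives shipped

`qedScore` (Bickerton QED), `penalizedLogP`
($\log P - SA_{raw} - \max(0, \text{largest ring} - 6)$ — the
unstandardized variant, chosen because it needs no external dataset for
z-scoring; a ZINC-standardized variant can be added as a plug-in),
`plogpImprovement` (difference to the lead), `tanimotoSimilarity` (Morgan
radius 2, 2048 bits — the de-facto community default, configurable), and
`normalizedSA` ($(10 - SA_{raw})/9$, mapping the 1–10 Ertl scale to
$[0,1]$ higher-is-easier, which makes filter windows like
$SA \in [0.6, 0.8]$ readable). Activity objectives (docking scores,
target-inhibition surrogates) are deliberately plug-ins: any
`function(smiles, lead) -> real` can be an `objectiveSpec` evaluator.

Descriptor primitives (parsing/canonicalization, QED, Crippen logP, Ertl
SA, ring perception, SMARTS matching, fingerprints) are computed by RDKit
through the bundled Python helper (`inst/python/descriptors.py`), batched
and memoized per session; the evolutionary loop therefore pays one batch
call per generation of genuinely new molecules. R-side code owns all the
optimizer mathematics.

## Metrics

`successRate`: a lead is successfully optimized iff its feasible result
set contains a molecule strictly better than every per-objective
threshold; `SR` is the fraction of such leads and `nSR` the count of
distinct qualifying molecules per lead. Strict inequality reads "better
than the threshold" literally; equality at a threshold does not qualify.
`hypervolume`: exact Lebesgue measure of the dominated region against a
fixed reference point (the zero vector by default), computed by recursive
dimension sweep, practical to $m = 4$. Because objectives can be negative
(e.g. a penalized-logP improvement), boxes are clipped at the reference
instead of raising an error. Raw (unnormalized) objective values are used
against the zero reference; a user can normalize upstream if desired.

## Synthetic test surfaces — what they do and do not show

* **Analytic problem** (`makeAnalyticProblem`): identity codec on
  $[0,1]^2$, objectives $f_1 = z_1$, $f_2 = 1 - z_1$, constraint
  $\sigma = \max(0, 0.3 - z_2) + \max(0, z_2 - 0.7)$. The CPF is the full
  segment $f_1 + f_2 = 1$ with hypervolume exactly $0.5$ at the zero
  reference, so convergence, spread and constraint satisfaction are all
  checkable in closed form. The suite runs it at $P = 40$,
  $G_1 = G_2 = 30$, five seeds.
* **Toy molecule world** (`makeToyWorld`): 60 molecules drawn from a
  curated 125-molecule pool (drug-like members plus deliberate 3-, 4-,
  7-, 8-membered-ring and alert-bearing violators), embedded at seeded
  uniform points of the unit square under a table codec; QED + similarity
  objectives, ring-size + alert constraints; run at $P = 20$,
  $G_1 = G_2 = 15$, three seeds. The embedding is random, *not*
  chemically meaningful: the world exercises the full molecular loop
  (encoding, variation, decoding, descriptor evaluation, constraint
  screening, two-stage selection) without pretrained weights. Passing it
  demonstrates the machinery — population-level constraint purging, HV
  retention, determinism — not chemistry-space generalization: with a
  learned codec the latent geometry is smooth in chemical structure,
  decode failures exist, and candidate molecules are not confined to a
  fixed table.

Problem sizes in the test-suite were chosen to make each property check
run in seconds while leaving the assertions sharp; they are stated above
and in the tests themselves.

## Numerical and degenerate-input choices

* Feasibility tolerance is exact zero on raw sigmas (ring and alert
  sigmas are integers; the analytic sigma is exactly zero inside the
  band).
* A crowding objective with zero range contributes nothing; two-point
  fronts are both boundaries (infinite crowding). Duplicate objective
  vectors are permitted; the middle of three or more identical points
  gets zero crowding.
* Population hypervolume under crowding-thinned elitist selection is not
  strictly monotone: once the whole population sits on the front,
  union-thinning reshuffles interior members and HV oscillates at the
  $10^{-3}$ scale. The guarantee that holds (and is tested) is bounded
  regression — no step loses more than a few percent of the running
  maximum — plus final $\ge$ initial.
* If decoding yields fewer than $P$ valid distinct offspring, selection
  simply proceeds on the smaller union (parents are always present, so
  the union is never smaller than $P$).
* One RNG stream, seeded once from the config, drives bank construction,
  pairing, blend draws, fragment choice and mutation in a fixed order;
  two runs with the same config and seed produce byte-identical output
  files.

## Known limitations

* No pretrained codec is shipped; real-molecule optimization quality
  depends entirely on the plugged-in autoencoder.
* Exact hypervolume beyond four objectives is out of scope, as are
  decomposition-based many-objective selections and external archives
  (the final population is the result; `archiveFeasible` optionally
  collects every feasible molecule seen).
* Only the cosine decay is implemented for $\alpha$; the schedule type is
  an extension point.
* Equality constraints are representable in the violation interface but
  no shipped constraint uses one.
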