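# cmomo — constrained multi-objective molecular optimization in latent space

`cmomo` optimizes small molecules against several conflicting properties at
once while enforcing hard drug-likeness constraints. It is aimed at
computational chemists doing lead optimization: you give it a lead molecule,
a candidate database, objectives (QED, penalized logP improvement,
similarity to the lead, synthetic accessibility, or any plug-in scorer) and
constraints (ring sizes confined to five or six atoms, absence of
structural-alert substructures, or any plug-in violation function), and it
returns a population of feasible molecules trading off the objectives.

## The method

The task is posed as a constrained multi-objective problem

    Maximize F(x) = (f1(x), ..., fm(x))   subject to  gi(x) <= 0,

searched in the continuous latent space of a pluggable molecular
encoder–decoder. Each generation, parents are varied by a blended linear
crossover, `z' = z1 + (-d + (1+2d)u)(z2 - z1)`, followed by a
fragmentation-based mutation that perturbs one randomly chosen contiguous
fragment of the latent vector; offspring are decoded, validity-filtered and
evaluated. Optimization runs in two stages:

1. **Unconstrained stage** — NSGA-II environmental selection
   (non-dominated sorting + crowding distance) on objectives alone, for
   unimpeded exploration of property space.
2. **Constrained stage** — every union member gets a property-preference
   rank `S1` (Pareto fronts + crowding) and a constraint-preference rank
   `S2` (fronts from the constraint dominance principle, using violation
   degrees max-normalized over the union), blended into a comprehensive
   score `S = alpha*S1 + (1-alpha)*S2` with the cosine decay
   `alpha = (1 + cos(t*pi/T))/2`. The weight slides from pure property
   preference (alpha = 1) to pure constraint preference (alpha = 0), so
   high-property but infeasible molecules can ferry the search across
   infeasible gaps before feasibility takes over.

Violation degrees: ring-size `sigma1 = sum_k [max(r_k - 6, 0) +
max(5 - r_k, 0)]` over SSSR rings, and `sigma2` = number of distinct
structural-alert SMARTS matched (a 28-pattern curated alert list is
packaged and user-replaceable). A molecule is feasible iff every raw sigma
is zero. Success rate (SR), per-lead successful-molecule counts (N_SR) and
exact hypervolume against a zero reference are built in.

No pretrained autoencoder is shipped: codecs are a plug-in contract, and
the package includes a deterministic table codec plus a packaged toy
molecule world and an analytic problem with a known constrained Pareto
front, so the entire pipeline is testable end to end. Primitive descriptors
(QED, Crippen logP, Ertl SA, fingerprints, ring perception, SMARTS
matching) are computed with RDKit through a bundled Python helper script;
the system `python` must have RDKit importable.

## Worked example

```r
library(cmomo)

world <- makeToyWorld(seed = 7L, n = 60L)   # packaged 60-molecule world
cfg <- runConfig(lead = world$lead, P = 20L, G1 = 15L, G2 = 15L, seed = 1L,
                 thresholds = c(qed = 0.6, similarity = 0.15))
res <- runCMOMO(cfg, codec = world$codec, problem = world$problem,
                database = world$smiles)
res
#> OptimizationResult: final population 20, feasible 20, 31 logged generation(s)

fs <- res@feasible
fs[order(-fs$qed), c("smiles", "qed", "similarity", "cv")][1:5, ]
#>                    smiles   qed similarity cv
#>   c1ccc2sc(N3CCNCC3)nc2c1 0.791     0.0638  0
#>     COc1cc2ccnc(C)c2cc1OC 0.751     0.0952  0
#>     CC(C)NCC(O)COc1ccccc1 0.744     0.1395  0
#>  O=S(=O)(c1ccccc1)N1CCCC1 0.743     0.1053  0
#>      Clc1cccc(N2CCNCC2)c1 0.737     0.0952  0
```

Starting from the lead `CC(=O)Nc1ccc(O)cc1` (paracetamol, QED 0.595), all
20 final molecules satisfy both constraints (`cv = 0`: no 3-, 4- or
7-membered rings, no structural alerts) and the best members improve QED to
0.74–0.79 while retaining similarity to the lead. Metrics on the final
feasible set:

```r
sr <- successRate(list(list(smiles = fs$smiles,
                            objectives = as.matrix(fs[, c("qed", "similarity")]))),
                  world$thresholds)
c(SR = sr$sr, N_SR = sr$nSR[1])
#> SR = 1, N_SR = 6          # 6 distinct molecules beat both thresholds
range(res@log$hv)[c(1, 2)]
#> initial HV 0.619 -> final HV 0.627
```

`writeResults(res, "outdir")` serializes the final population
(`final_population.csv` with objectives, violation degrees, CV, fronts,
both preference ranks and scores), the feasible SMILES list, a
per-generation JSONL log and a provenance record. Runs are bitwise
reproducible from config + seed.

A command-line front end is installed at
`system.file("scripts", "cmomo.R", package = "cmomo")`:

```sh
Rscript cmomo.R run --config cfg.yaml [--seed N] [--out DIR]
Rscript cmomo.R eval --population final_population.csv --thresholds th.yaml
Rscript cmomo.R fixtures --make toy-world --out DIR
```

## Package layout

* `R/objectives.R`, `R/constraints.R` — property evaluators, violation
  degrees, CV aggregation.
* `R/codec.R` — codec classes and batch decode filtering.
* `R/variation.R` — blend crossover, fragment mutation, Bank library,
  initialization.
* `R/selection.R` — Pareto machinery, constraint dominance, rankings,
  cosine schedule, both environmental selections.
* `R/driver.R` — two-stage loop, config, result I/O.
* `R/metrics.R` — SR/N_SR, hypervolume, analytic problem, toy world.
* `vignettes/cmomo-methods.Rmd` — model, parameters, design decisions,
  limitations.
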