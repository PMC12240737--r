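# Core S4 classes. Objective/constraint specifications, the problem
# definition, codec classes, the Bank library, populations, run
# configuration and results.

#' ObjectiveSpec: one optimization objective
#'
#' A named molecular property with an optimization direction, an evaluator
#' `function(smiles, lead) -> finite real`, and an optional success
#' threshold (maximization orientation) used by [successRate()].
#'
#' @slot name identifier.
#' @slot direction `"maximize"` or `"minimize"`. Internally all objective
#'   math assumes maximization; minimize-direction values are negated once,
#'   at evaluation.
#' @slot evaluator the evaluator function.
#' @slot successThreshold success threshold or `NA`.
#' @export
setClass("ObjectiveSpec",
  representation(name = "character", direction = "character",
                 evaluator = "function", successThreshold = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a non-empty string")
    if (!object@direction %in% c("maximize", "minimize"))
      return("'direction' must be \"maximize\" or \"minimize\"")
    if (length(object@successThreshold) != 1L)
      return("'successThreshold' must be a scalar (possibly NA)")
    TRUE
  })

#' Create an ObjectiveSpec
#'
#' @param name objective identifier. When `evaluator` is omitted, `name`
#'   must be one of the built-in evaluators: `"qed"`, `"plogp"`,
#'   `"plogp_imp"`, `"similarity"`, `"sa"`.
#' @param evaluator a `function(smiles, lead)` returning a finite real, or
#'   a registry name.
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @param successThreshold optional success threshold (maximization scale).
#' @return an [ObjectiveSpec-class] object.
#' @export
objectiveSpec <- function(name, evaluator = name, direction = "maximize",
                          successThreshold = NA_real_) {
  new("ObjectiveSpec", name = name,
      evaluator = resolveObjectiveEvaluator(evaluator, name),
      direction = direction, successThreshold = as.numeric(successThreshold))
}

#' ConstraintSpec: one inequality constraint
#'
#' The evaluator `function(smiles) -> sigma` returns the non-negative
#' violation degree; zero means the constraint is satisfied.
#'
#' @slot name identifier.
#' @slot evaluator the violation-degree function.
#' @export
setClass("ConstraintSpec",
  representation(name = "character", evaluator = "function"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("'name' must be a non-empty string")
    TRUE
  })

#' Create a ConstraintSpec
#'
#' @param name constraint identifier. When `evaluator` is omitted, `name`
#'   must be a built-in: `"ring_size"` (five/six-membered rings only) or
#'   `"alerts"` (no structural-alert substructures; requires `alerts`).
#' @param evaluator a `function(smiles)` returning the violation degree, or
#'   a registry name.
#' @param alerts alert set from [loadAlerts()], needed by `"alerts"`.
#' @return a [ConstraintSpec-class] object.
#' @export
constraintSpec <- function(name, evaluator = name, alerts = NULL) {
  new("ConstraintSpec", name = name,
      evaluator = resolveConstraintEvaluator(evaluator, name, alerts))
}

#' ProblemDefinition: objectives plus constraints
#'
#' @slot objectives ordered list of [ObjectiveSpec-class] objects.
#' @slot constraints ordered list of [ConstraintSpec-class] objects (may be
#'   empty for unconstrained problems).
#' @export
setClass("ProblemDefinition",
  representation(objectives = "list", constraints = "list"),
  validity = function(object) {
    if (length(object@objectives) < 1L)
      return("at least one objective is required")
    if (!all(vapply(object@objectives, is, logical(1), "ObjectiveSpec")))
      return("'objectives' must all be ObjectiveSpec")
    if (!all(vapply(object@constraints, is, logical(1), "ConstraintSpec")))
      return("'constraints' must all be ConstraintSpec")
    on <- vapply(object@objectives, slot, character(1), "name")
    cn <- vapply(object@constraints, slot, character(1), "name")
    if (anyDuplicated(on)) return("duplicate objective names")
    if (anyDuplicated(cn)) return("duplicate constraint names")
    TRUE
  })

#' Create a ProblemDefinition
#'
#' @param objectives list of [ObjectiveSpec-class] objects.
#' @param constraints list of [ConstraintSpec-class] objects.
#' @return a [ProblemDefinition-class].
#' @export
problemDefinition <- function(objectives, constraints = list()) {
  new("ProblemDefinition", objectives = objectives, constraints = constraints)
}

# ---- codecs ----------------------------------------------------------------

#' Virtual base class for latent-space codecs
#'
#' A codec maps molecules (SMILES) to fixed-dimension real latent vectors
#' and back. Bounds, when declared, are a 2 x D matrix (rows lo, hi) used
#' to clamp offspring after variation.
#'
#' @slot dim latent dimension D.
#' @slot bounds 2 x D numeric matrix of per-dimension bounds, or a 0-row
#'   matrix when unbounded.
#' @export
setClass("MolecularCodec",
  representation("VIRTUAL", dim = "integer", bounds = "matrix"))

#' TableCodec: deterministic lookup codec
#'
#' Encoding is exact lookup of a canonical SMILES in a fixed table; decoding
#' returns the nearest entry under Euclidean distance (ties broken by lowest
#' entry index). A test and demonstration stand-in for a pretrained
#' encoder-decoder: round-trip exact on its entries, deterministic
#' everywhere.
#'
#' @slot smiles canonical SMILES of the table entries.
#' @slot latent n x D matrix of entry embeddings (distinct rows).
#' @export
setClass("TableCodec", contains = "MolecularCodec",
  representation(smiles = "character", latent = "matrix"),
  validity = function(object) {
    if (nrow(object@latent) != length(object@smiles))
      return("one latent row per SMILES entry required")
    if (ncol(object@latent) != object@dim)
      return("latent width must equal dim")
    if (anyDuplicated(object@smiles))
      return("table SMILES must be distinct")
    if (anyDuplicated(object@latent, MARGIN = 1))
      return("table latent vectors must be distinct")
    TRUE
  })

#' Create a TableCodec
#'
#' @param smiles character vector of (canonicalizable) SMILES.
#' @param latent numeric matrix, one row per molecule.
#' @param bounds per-dimension bounds; default the unit hypercube.
#' @param canonicalize canonicalize `smiles` through the chemistry backend
#'   (set `FALSE` when entries are known canonical).
#' @return a [TableCodec-class].
#' @export
tableCodec <- function(smiles, latent, bounds = NULL, canonicalize = TRUE) {
  latent <- as.matrix(latent)
  if (canonicalize) smiles <- vapply(smiles, parseSmiles, character(1),
                                     USE.NAMES = FALSE)
  if (is.null(bounds))
    bounds <- rbind(lo = rep(0, ncol(latent)), hi = rep(1, ncol(latent)))
  new("TableCodec", smiles = smiles, latent = latent,
      dim = ncol(latent), bounds = bounds)
}

#' IdentityCodec: coordinate-string codec for analytic problems
#'
#' "Molecules" are strings of comma-separated coordinates; encode parses
#' them, decode formats the vector at full precision. Used by the analytic
#' test problem whose constrained Pareto front is known in closed form.
#'
#' @export
setClass("IdentityCodec", contains = "MolecularCodec")

#' Create an IdentityCodec
#'
#' @param dim latent dimension.
#' @param bounds per-dimension bounds; default the unit hypercube.
#' @return an [IdentityCodec-class].
#' @export
identityCodec <- function(dim = 2L, bounds = NULL) {
  if (is.null(bounds)) bounds <- rbind(lo = rep(0, dim), hi = rep(1, dim))
  new("IdentityCodec", dim = as.integer(dim), bounds = bounds)
}

#' FunctionCodec: plug-in codec from user functions
#'
#' Adapter for external encoder-decoders (for instance a pretrained
#' SMILES autoencoder exposed through a wrapper). `decodeFun` may return
#' `NA` to signal a decode failure; failures are filtered by
#' [decodeValidBatch()].
#'
#' @slot encodeFun `function(smiles) -> numeric(D)`.
#' @slot decodeFun `function(z) -> SMILES or NA`.
#' @export
setClass("FunctionCodec", contains = "MolecularCodec",
  representation(encodeFun = "function", decodeFun = "function"))

#' Create a FunctionCodec
#'
#' @param dim latent dimension.
#' @param encodeFun,decodeFun the plug-in encode/decode functions.
#' @param bounds optional 2 x D bounds matrix (0-row matrix = unbounded).
#' @return a [FunctionCodec-class].
#' @export
functionCodec <- function(dim, encodeFun, decodeFun, bounds = NULL) {
  if (is.null(bounds)) bounds <- matrix(numeric(0), nrow = 0, ncol = dim)
  new("FunctionCodec", dim = as.integer(dim), bounds = bounds,
      encodeFun = encodeFun, decodeFun = decodeFun)
}

# ---- populations and results ----------------------------------------------

#' BankLibrary: screened seed molecules for initialization
#'
#' @slot smiles canonical SMILES of the bank members (distinct).
#' @slot latent member embeddings, one row per molecule.
#' @slot provenance list recording the screening criteria and any shortfall.
#' @export
setClass("BankLibrary",
  representation(smiles = "character", latent = "matrix",
                 provenance = "list"),
  validity = function(object) {
    if (nrow(object@latent) != length(object@smiles))
      return("one latent row per member required")
    if (anyDuplicated(object@smiles)) return("bank members must be distinct")
    TRUE
  })

#' MoleculePopulation: an evaluated population
#'
#' Ordered multiset of candidate molecules with their latent vectors,
#' maximization-oriented objective values, raw per-constraint violation
#' degrees, aggregated CV, and (when produced by a selection step) ranking
#' statistics.
#'
#' @slot smiles canonical SMILES, one per member.
#' @slot latent N x D latent matrix.
#' @slot objectives N x m objective matrix (maximization orientation).
#' @slot sigmas N x C raw violation matrix (C may be 0).
#' @slot cv aggregated constraint violation per member.
#' @slot ranking data.frame with columns `front`, `crowding`, `s1`, `s2`,
#'   `score` (NA where not applicable).
#' @export
setClass("MoleculePopulation",
  representation(smiles = "character", latent = "matrix",
                 objectives = "matrix", sigmas = "matrix", cv = "numeric",
                 ranking = "data.frame"),
  validity = function(object) {
    n <- length(object@smiles)
    if (nrow(object@latent) != n) return("latent rows != population size")
    if (nrow(object@objectives) != n) return("objective rows != population size")
    if (nrow(object@sigmas) != n) return("sigma rows != population size")
    if (length(object@cv) != n) return("cv length != population size")
    if (nrow(object@ranking) != n) return("ranking rows != population size")
    if (any(object@sigmas < 0)) return("violation degrees must be >= 0")
    TRUE
  })

#' RunConfig: all parameters of an optimization run
#'
#' @slot lead lead molecule SMILES.
#' @slot databasePath path to a SMILES database for Bank screening ("" when
#'   initialization is not Bank-based).
#' @slot alertsPath path to a structural-alert SMARTS file ("" = packaged
#'   default list).
#' @slot codecSpec codec description, e.g. `"table:<csv path>"` or
#'   `"identity:<dim>"` (ignored when a codec object is passed to
#'   [runCMOMO()] directly).
#' @slot P population size (>= 2).
#' @slot G1,G2 generations in the unconstrained and constrained stages.
#' @slot d blend-crossover interpolation/extrapolation parameter (>= 0).
#' @slot pM per-gene mutation probability.
#' @slot nFrag number of contiguous latent fragments for mutation.
#' @slot mutationScale standard deviation of the Gaussian mutation step;
#'   `NA` = 0.1 of the per-dimension bound range (0.1 absolute if unbounded).
#' @slot bankSize Bank library capacity.
#' @slot simMin,propMin Bank screening thresholds (similarity to lead,
#'   screening property).
#' @slot seed RNG seed; one stream drives the whole run.
#' @slot objectiveNames,constraintNames registry names used to assemble the
#'   problem when none is supplied.
#' @slot thresholds named per-objective success thresholds.
#' @slot init `"bank"` or `"uniform"` population initialization.
#' @slot dedupeAgainstParents drop offspring decoding to a SMILES already in
#'   the parent population.
#' @slot archiveFeasible also accumulate every feasible molecule ever seen.
#' @slot outputDir default output directory for [writeResults()].
#' @export
setClass("RunConfig",
  representation(lead = "character", databasePath = "character",
                 alertsPath = "character", codecSpec = "character",
                 P = "integer", G1 = "integer", G2 = "integer",
                 d = "numeric", pM = "numeric", nFrag = "integer",
                 mutationScale = "numeric", bankSize = "integer",
                 simMin = "numeric", propMin = "numeric", seed = "integer",
                 objectiveNames = "character", constraintNames = "character",
                 thresholds = "numeric", init = "character",
                 dedupeAgainstParents = "logical",
                 archiveFeasible = "logical", outputDir = "character"),
  validity = function(object) {
    if (object@P < 2L) return("'P' must be at least 2")
    if (object@G1 < 0L || object@G2 < 0L)
      return("generation counts must be >= 0")
    if (object@d < 0) return("'d' must be >= 0")
    if (object@pM < 0 || object@pM > 1) return("'pM' must lie in [0, 1]")
    if (object@nFrag < 1L) return("'nFrag' must be >= 1")
    if (!object@init %in% c("bank", "uniform"))
      return("'init' must be \"bank\" or \"uniform\"")
    TRUE
  })

#' OptimizationResult: output of a full run
#'
#' @slot finalPopulation the final [MoleculePopulation-class].
#' @slot feasible data.frame of feasible final molecules (all raw violation
#'   degrees zero), a subset of the final population.
#' @slot log per-generation metrics (stage, generation, hypervolume,
#'   feasible fraction, alpha, per-objective best/mean).
#' @slot provenance list with config, seed, package and R versions.
#' @export
setClass("OptimizationResult",
  representation(finalPopulation = "MoleculePopulation",
                 feasible = "data.frame", log = "data.frame",
                 provenance = "list"))
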