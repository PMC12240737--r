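# Evaluation metrics (success rate, hypervolume) and the synthetic test
# surfaces: an analytic constrained problem with a closed-form constrained
# Pareto front, and a toy molecule world with a deterministic table codec.

#' Hypervolume indicator (maximization, fixed reference point)
#'
#' Lebesgue measure of the union of axis-aligned boxes spanned between the
#' reference point and each objective vector. Coordinates at or below the
#' reference contribute nothing: boxes are clipped at the reference rather
#' than raising an error, so objective values below the zero reference
#' (e.g. negative penalized-logP improvements) are handled gracefully.
#' Exact for any dimension via recursive dimension sweep; intended for
#' m <= 4.
#'
#' @param points N x m matrix (or vector for one point) of objective
#'   vectors, maximization orientation.
#' @param ref reference point; default the zero vector.
#' @return non-negative hypervolume.
#' @export
hypervolume <- function(points, ref = NULL) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  m <- ncol(points)
  if (is.null(ref)) ref <- rep(0, m)
  if (length(ref) != m)
    cmomoStop("dimensionMismatch", "reference point dimension mismatch")
  clipped <- pmax(points, matrix(ref, nrow(points), m, byrow = TRUE))
  keep <- rowSums(clipped > matrix(ref, nrow(points), m, byrow = TRUE)) == m
  .hvRecursive(clipped[keep, , drop = FALSE], ref)
}

# Dimension-sweep hypervolume: slice along the last objective at the sorted
# distinct levels; each slab's volume is its height times the (m-1)-dim
# hypervolume of the points reaching that level.
.hvRecursive <- function(points, ref) {
  n <- nrow(points)
  if (n == 0L) return(0)
  m <- ncol(points)
  if (m == 1L) return(max(points[, 1L]) - ref[1L])
  levels <- sort(unique(points[, m]), decreasing = TRUE)
  lower <- c(levels[-1L], ref[m])
  vol <- 0
  for (i in seq_along(levels)) {
    active <- points[points[, m] >= levels[i], -m, drop = FALSE]
    vol <- vol + (levels[i] - lower[i]) *
      .hvRecursive(active, ref[-m])
  }
  vol
}

#' Optimization success rate over a set of lead molecules
#'
#' A lead counts as successfully optimized iff its final feasible set
#' contains at least one molecule whose every objective value is strictly
#' better than (greater than, in maximization orientation) the
#' corresponding threshold. `SR` is the fraction of successful leads;
#' `nSR` counts the distinct successful molecules per lead.
#'
#' @param perLeadResults list with one element per lead; each element a
#'   list/data.frame with `smiles` and an objective matrix `objectives`
#'   (rows = feasible molecules; zero rows allowed).
#' @param thresholds named numeric vector of per-objective thresholds
#'   (maximization orientation), matching the objective columns.
#' @return list with `sr` (scalar in \[0, 1\]) and `nSR` (integer per lead).
#' @export
successRate <- function(perLeadResults, thresholds) {
  if (!length(perLeadResults))
    cmomoStop("emptyInput", "no per-lead result sets supplied")
  nSR <- vapply(perLeadResults, function(res) {
    F <- as.matrix(res$objectives)
    if (nrow(F) == 0L) return(0L)
    if (!is.null(names(thresholds)) && !is.null(colnames(F)))
      F <- F[, names(thresholds), drop = FALSE]
    ok <- rowSums(F > matrix(thresholds, nrow(F), length(thresholds),
                             byrow = TRUE)) == length(thresholds)
    length(unique(res$smiles[ok]))
  }, integer(1))
  list(sr = mean(nSR > 0L), nSR = nSR)
}

#' Analytic constrained test problem
#'
#' A two-dimensional coordinate world on the unit square with an
#' [identityCodec()]: objectives `f1 = z1` and `f2 = 1 - z1` (so every
#' point lies on the line `f1 + f2 = 1`), and one constraint confining the
#' second coordinate to the band \[0.3, 0.7\]
#' (`sigma = max(0, 0.3 - z2) + max(0, z2 - 0.7)`). The constrained Pareto
#' front is the full segment `{(a, 1 - a)}`, attained at any feasible
#' `z2`, with hypervolume 0.5 against the zero reference.
#'
#' @return list with `problem` ([ProblemDefinition-class]), `codec`
#'   ([IdentityCodec-class]), `lead` (a feasible coordinate string) and
#'   `trueHV` (0.5).
#' @export
makeAnalyticProblem <- function() {
  codec <- identityCodec(2L)
  coordOf <- function(s) {
    v <- .parseCoords(s, 2L)
    if (is.null(v)) cmomoStop("evaluationError",
                              sprintf("bad coordinate string '%s'", s))
    v
  }
  problem <- problemDefinition(
    objectives = list(
      objectiveSpec("f1", function(smiles, lead) coordOf(smiles)[1L]),
      objectiveSpec("f2", function(smiles, lead) 1 - coordOf(smiles)[1L])),
    constraints = list(
      constraintSpec("band", function(smiles) {
        z2 <- coordOf(smiles)[2L]
        max(0, 0.3 - z2) + max(0, z2 - 0.7)
      })))
  list(problem = problem, codec = codec,
       lead = .formatCoords(c(0.5, 0.5)), trueHV = 0.5)
}

#' Packaged toy molecule world
#'
#' Draws `n` molecules deterministically (by `seed`) from the packaged
#' curated pool — drug-like molecules plus deliberate ring-size and
#' structural-alert violators — and embeds them at seeded uniform points of
#' the unit hypercube to form a [TableCodec-class]. The embedding is
#' random, not chemically meaningful: the world exercises the full
#' molecular loop (encode, vary, decode, evaluate, select) without
#' pretrained autoencoder weights.
#'
#' @param seed integer seed controlling both the draw and the embedding.
#' @param n number of molecules (at most the pool size).
#' @param dim latent dimension of the embedding.
#' @param alerts alert set for the substructure constraint; default the
#'   packaged list.
#' @return list with `smiles`, `codec`, `problem` (QED + similarity
#'   objectives, ring-size + alert constraints), `lead` (a feasible,
#'   mid-QED member), `thresholds` (success thresholds satisfiable by some
#'   but not all members) and `alerts`.
#' @export
makeToyWorld <- function(seed = 1L, n = 60L, dim = 2L, alerts = loadAlerts()) {
  pool <- readSmilesFile(system.file("extdata", "toy_pool.smi",
                                     package = "cmomo"))
  chemDescriptors(pool)                 # one backend batch for the pool
  if (n > length(pool))
    cmomoStop("badParams",
              sprintf("n (%d) exceeds the packaged pool size (%d)",
                      n, length(pool)))
  # keep the function pure: restore the caller's RNG state afterwards
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()),
          add = TRUE)
  set.seed(seed)
  chosen <- sort(sample.int(length(pool), n))
  smiles <- vapply(pool[chosen], parseSmiles, character(1), USE.NAMES = FALSE)
  dup <- duplicated(smiles)
  smiles <- smiles[!dup]
  latent <- matrix(stats::runif(length(smiles) * dim), ncol = dim)
  codec <- tableCodec(smiles, latent, canonicalize = FALSE)
  problem <- problemDefinition(
    objectives = list(
      objectiveSpec("qed", "qed", successThreshold = 0.6),
      objectiveSpec("similarity", "similarity", successThreshold = 0.15)),
    constraints = list(
      constraintSpec("ring_size"),
      constraintSpec("alerts", alerts = alerts)))
  # lead: a feasible member with mid-range QED, leaving headroom to optimize
  warmDescriptorCache(smiles, problem)
  sig <- sigmaMatrix(smiles, problem)
  qeds <- vapply(smiles, qedScore, numeric(1), USE.NAMES = FALSE)
  feas <- which(isFeasible(sig))
  lead <- smiles[feas[order(abs(qeds[feas] - stats::median(qeds[feas])))[1L]]]
  list(smiles = smiles, codec = codec, problem = problem, lead = lead,
       thresholds = c(qed = 0.6, similarity = 0.15), alerts = alerts)
}
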