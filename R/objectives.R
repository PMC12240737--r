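# Molecular property objectives. All user-facing scores follow the
# maximization convention used throughout the optimizer: minimize-direction
# objectives are negated exactly once, at evaluation time.

#' Parse and canonicalize a SMILES string
#'
#' @param s a single non-empty SMILES string.
#' @return the canonical SMILES (character scalar). Canonicalization is
#'   idempotent: `parseSmiles(parseSmiles(s)) == parseSmiles(s)`.
#' @examples
#' \dontrun{parseSmiles("c1ccccc1")}
#' @export
parseSmiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    cmomoStop("usageError", "'s' must be a single SMILES string")
  if (!nzchar(s))
    cmomoStop("usageError", "empty SMILES string")
  .descriptor1(s)$canonical
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Bickerton's QED, in \[0, 1\], higher is more drug-like.
#'
#' @param smiles a valid SMILES string.
#' @return QED value clamped to \[0, 1\].
#' @export
qedScore <- function(smiles) {
  v <- .descriptor1(smiles)$qed
  min(max(v, 0), 1)
}

#' Penalized logP
#'
#' `logP - SA_raw - max(0, largest ring size - 6)`, with Crippen logP and
#' the Ertl synthetic-accessibility score on its native 1-10 scale. This is
#' the unstandardized variant (no dataset-derived z-scoring); see the
#' methods vignette for the rationale.
#'
#' @param smiles a valid SMILES string.
#' @return penalized logP (unbounded real, higher is better).
#' @export
penalizedLogP <- function(smiles) {
  rec <- .descriptor1(smiles)
  rings <- unlist(rec$ring_sizes)
  penalty <- if (length(rings)) max(0, max(rings) - 6) else 0
  rec$logp - rec$sa - penalty
}

#' Penalized-logP improvement over a lead molecule
#'
#' @param smiles,lead valid SMILES strings.
#' @return `penalizedLogP(smiles) - penalizedLogP(lead)`.
#' @export
plogpImprovement <- function(smiles, lead) {
  penalizedLogP(smiles) - penalizedLogP(lead)
}

#' Tanimoto similarity on Morgan fingerprints
#'
#' `|A n B| / |A u B|` on binary circular fingerprints (default radius 2,
#' 2048 bits — the de-facto community default).
#'
#' @param smiles,lead valid SMILES strings.
#' @param fpRadius,fpBits fingerprint radius and bit width.
#' @return similarity in \[0, 1\]; symmetric; 1 for identical molecules.
#' @export
tanimotoSimilarity <- function(smiles, lead, fpRadius = 2L, fpBits = 2048L) {
  a <- unlist(.descriptor1(smiles, fpRadius = fpRadius, fpBits = fpBits)$fp)
  b <- unlist(.descriptor1(lead, fpRadius = fpRadius, fpBits = fpBits)$fp)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Normalized synthetic accessibility
#'
#' Maps the raw Ertl SA score (1 = easy, 10 = hard) onto \[0, 1\] with
#' higher meaning easier to synthesize: `(10 - SA_raw) / 9`.
#'
#' @param smiles a valid SMILES string.
#' @return normalized SA in \[0, 1\].
#' @export
normalizedSA <- function(smiles) {
  sa <- .descriptor1(smiles)$sa
  min(max((10 - sa) / 9, 0), 1)
}

# ---- evaluator registry ----------------------------------------------------

# Built-in objective evaluators, each (smiles, lead) -> finite real on the
# scale natural to the property (direction handled by the ObjectiveSpec).
.objectiveRegistry <- list(
  qed        = function(smiles, lead) qedScore(smiles),
  plogp      = function(smiles, lead) penalizedLogP(smiles),
  plogp_imp  = function(smiles, lead) plogpImprovement(smiles, lead),
  similarity = function(smiles, lead) tanimotoSimilarity(smiles, lead),
  sa         = function(smiles, lead) normalizedSA(smiles)
)

resolveObjectiveEvaluator <- function(evaluator, name = "") {
  if (is.function(evaluator)) return(evaluator)
  if (is.character(evaluator) && length(evaluator) == 1L &&
      evaluator %in% names(.objectiveRegistry))
    return(.objectiveRegistry[[evaluator]])
  cmomoStop("configError",
            sprintf("objective '%s': unresolvable evaluator", name))
}

#' Evaluate all objectives of a problem for one molecule
#'
#' Applies every [ObjectiveSpec] evaluator and returns the objective vector
#' in maximization orientation (minimize-direction values are negated here,
#' and only here).
#'
#' @param smiles molecule to evaluate.
#' @param problem a [ProblemDefinition].
#' @param lead the lead molecule's SMILES (passed to every evaluator).
#' @return numeric vector, one finite value per objective, named.
#' @export
evaluateObjectives <- function(smiles, problem, lead) {
  specs <- objectives(problem)
  vals <- vapply(specs, function(sp) {
    v <- tryCatch(sp@evaluator(smiles, lead), error = function(e)
      cmomoStop("evaluationError",
                sprintf("objective '%s' failed for '%s': %s",
                        sp@name, smiles, conditionMessage(e))))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      cmomoStop("evaluationError",
                sprintf("objective '%s' returned a non-finite value", sp@name))
    if (sp@direction == "minimize") -v else v
  }, numeric(1))
  names(vals) <- vapply(specs, slot, character(1), "name")
  vals
}

# Objective matrix for a vector of molecules (rows = molecules).
objectiveMatrix <- function(smilesVec, problem, lead) {
  m <- t(vapply(smilesVec, evaluateObjectives, problem = problem,
                lead = lead, FUN.VALUE = numeric(nObjectives(problem))))
  rownames(m) <- NULL
  if (nObjectives(problem) == 1L) m <- matrix(m, ncol = 1L,
                                              dimnames = list(NULL, objectiveNames(problem)))
  m
}
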