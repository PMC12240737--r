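# Constraint violation degrees and their population-normalized aggregation.
#
# Each constraint evaluator returns a raw violation degree sigma >= 0 with
# sigma == 0 exactly when the constraint is satisfied. Feasibility is always
# decided on raw sigmas; the max-normalized aggregate CV only orders
# infeasible molecules relative to the population in scope.

#' Ring-size constraint violation
#'
#' Rings must have five or six atoms. Over the smallest set of smallest
#' rings (SSSR) with sizes `r_k`, the violation degree is
#' `sum(max(r_k - 6, 0) + max(5 - r_k, 0))`; acyclic molecules score 0.
#'
#' @param smiles a valid SMILES string.
#' @return non-negative violation degree.
#' @export
ringSizeCV <- function(smiles) {
  rings <- unlist(.descriptor1(smiles)$ring_sizes)
  if (!length(rings)) return(0)
  sum(pmax(rings - 6, 0) + pmax(5 - rings, 0))
}

#' Load a structural-alert SMARTS file
#'
#' One SMARTS per line, optional tab-separated label, `#` comments. Every
#' pattern is compiled by the chemistry backend at load time; a pattern that
#' fails to compile raises an error naming the offending SMARTS and line.
#'
#' @param path alert file; default the packaged alert subset.
#' @return an alert set: data.frame with columns `smarts`, `label`, plus a
#'   content hash used for caching.
#' @export
loadAlerts <- function(path = system.file("extdata", "structural_alerts.smarts",
                                          package = "cmomo")) {
  if (!file.exists(path))
    cmomoStop("configError", sprintf("alert file not found: '%s'", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) & !grepl("^\\s*#", raw))
  parts <- strsplit(raw[keep], "\t", fixed = TRUE)
  alerts <- data.frame(
    smarts = trimws(vapply(parts, `[[`, character(1), 1L)),
    label = vapply(parts, function(p)
      if (length(p) > 1L) trimws(p[[2L]]) else "", character(1)),
    line = keep,
    stringsAsFactors = FALSE)
  if (!nrow(alerts))
    cmomoStop("configError", sprintf("alert file '%s' has no patterns", path))
  chk <- .validateAlerts(alerts)
  if (!isTRUE(chk$ok)) {
    e <- chk$errors[1L, ]
    cmomoStop("badAlertPattern",
              sprintf("bad SMARTS '%s' (%s, line %d of temp copy; source line %d)",
                      e$smarts, e$message, e$line, alerts$line[match(e$smarts, alerts$smarts)]))
  }
  attr(alerts, "md5") <- as.character(tools::md5sum(path))
  attr(alerts, "path") <- path
  alerts
}

.validateAlerts <- function(alerts) {
  f <- tempfile(fileext = ".smarts")
  on.exit(unlink(f))
  writeLines(alerts$smarts, f)
  out <- system2(pythonBin(), shQuote(c(backendScript(), "alerts",
                                        "--alerts", f)),
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyDataFrame = TRUE)
}

#' Structural-alert constraint violation
#'
#' Number of *distinct* alert patterns with at least one substructure match
#' in the molecule (each pattern counts at most once, however many times it
#' matches).
#'
#' @param smiles a valid SMILES string.
#' @param alerts an alert set from [loadAlerts()].
#' @return non-negative integer violation degree.
#' @export
substructureCV <- function(smiles, alerts) {
  if (is.null(alerts) || !nrow(alerts)) return(0L)
  n <- .descriptor1(smiles, alerts = alerts)$n_alerts
  as.integer(n)
}

# Built-in constraint evaluators.
resolveConstraintEvaluator <- function(evaluator, name = "", alerts = NULL) {
  if (is.function(evaluator)) return(evaluator)
  if (identical(evaluator, "ring_size"))
    return(function(smiles) ringSizeCV(smiles))
  if (identical(evaluator, "alerts")) {
    if (is.null(alerts)) alerts <- loadAlerts()
    force(alerts)
    f <- function(smiles) substructureCV(smiles, alerts)
    attr(f, "alerts") <- alerts   # lets batch evaluation pre-warm the cache
    return(f)
  }
  cmomoStop("configError",
            sprintf("constraint '%s': unresolvable evaluator", name))
}

#' Evaluate all constraint violation degrees for one molecule
#'
#' @param smiles molecule to evaluate.
#' @param problem a [ProblemDefinition-class].
#' @return non-negative numeric vector, one sigma per constraint, named;
#'   length 0 for unconstrained problems.
#' @export
evaluateSigmas <- function(smiles, problem) {
  specs <- constraints(problem)
  vals <- vapply(specs, function(sp) {
    v <- tryCatch(sp@evaluator(smiles), error = function(e)
      cmomoStop("evaluationError",
                sprintf("constraint '%s' failed for '%s': %s",
                        sp@name, smiles, conditionMessage(e))))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      cmomoStop("evaluationError",
                sprintf("constraint '%s' returned an invalid violation degree",
                        sp@name))
    as.numeric(v)
  }, numeric(1))
  names(vals) <- vapply(specs, slot, character(1), "name")
  vals
}

# One backend batch per descriptor variant needed by a problem's
# evaluators, so per-molecule evaluation afterwards is pure cache lookup.
# Callers must only pass genuine SMILES (not coordinate-world strings).
warmDescriptorCache <- function(smilesVec, problem = NULL) {
  if (!length(smilesVec)) return(invisible(NULL))
  smi <- unique(smilesVec)
  chemDescriptors(smi)
  if (!is.null(problem))
    for (sp in constraints(problem)) {
      alerts <- attr(sp@evaluator, "alerts")
      if (!is.null(alerts)) chemDescriptors(smi, alerts)
    }
  invisible(NULL)
}

# Sigma matrix for a vector of molecules (rows = molecules; 0 columns when
# the problem is unconstrained).
sigmaMatrix <- function(smilesVec, problem) {
  k <- nConstraints(problem)
  if (k == 0L)
    return(matrix(numeric(0), nrow = length(smilesVec), ncol = 0L))
  m <- t(vapply(smilesVec, evaluateSigmas, problem = problem,
                FUN.VALUE = numeric(k)))
  rownames(m) <- NULL
  if (k == 1L) m <- matrix(m, ncol = 1L,
                           dimnames = list(NULL, constraintNames(problem)))
  m
}

#' Aggregate constraint violations over a molecule set
#'
#' Max-normalized aggregation: each constraint column is divided by its
#' maximum over the set psi (the molecules in scope at selection time) and
#' the normalized terms are summed per molecule. A column whose maximum is
#' zero — the constraint is satisfied by every molecule in psi — carries no
#' discriminating information and contributes 0. Aggregate values lie in
#' `[0, number of constraints]`, and a molecule has CV 0 exactly when all
#' its raw sigmas are 0.
#'
#' @param sigmaMat N x C matrix of raw violation degrees for the set psi.
#' @return numeric vector of N aggregated CV degrees.
#' @export
aggregateCV <- function(sigmaMat) {
  sigmaMat <- as.matrix(sigmaMat)
  if (nrow(sigmaMat) == 0L)
    cmomoStop("emptyPopulation", "cannot aggregate CV over an empty set")
  if (any(sigmaMat < 0))
    cmomoStop("badParams", "violation degrees must be non-negative")
  if (ncol(sigmaMat) == 0L) return(numeric(nrow(sigmaMat)))
  colMax <- apply(sigmaMat, 2L, max)
  scale <- ifelse(colMax > 0, 1 / colMax, 0)
  as.numeric(sigmaMat %*% scale)
}

#' Feasibility from raw violation degrees
#'
#' A molecule is feasible iff every raw sigma is zero. Feasibility is
#' invariant to the max-normalization of [aggregateCV()], which rescales
#' but never changes the zero pattern.
#'
#' @param sigmas numeric vector (one molecule) or matrix (rows = molecules)
#'   of raw violation degrees.
#' @return logical scalar or vector.
#' @export
isFeasible <- function(sigmas) {
  if (is.matrix(sigmas)) return(rowSums(sigmas > 0) == 0L)
  all(sigmas <= 0)
}
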