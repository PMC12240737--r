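# RDKit descriptor backend. Primitive per-molecule descriptors (validity,
# canonical SMILES, QED, Crippen logP, Ertl SA score, SSSR ring sizes,
# Morgan fingerprint on-bits, structural-alert match counts) are computed by
# the bundled helper script inst/python/descriptors.py, run with the system
# Python's RDKit. Calls are batched (one process per batch of unseen
# molecules) and memoized for the session, so evolutionary loops touching
# the same molecules repeatedly stay cheap.

.chemCache <- new.env(parent = emptyenv())

backendScript <- function() {
  p <- system.file("python", "descriptors.py", package = "cmomo")
  if (!nzchar(p))
    cmomoStop("evaluationError", "bundled descriptor script not found")
  p
}

pythonBin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    cmomoStop("evaluationError", "no 'python' executable on PATH")
  p
}

#' Check that the RDKit descriptor backend is usable
#'
#' Runs the bundled helper once on a trivial molecule and caches the result
#' for the session.
#'
#' @return `TRUE` invisibly if the backend works; otherwise an error.
#' @export
chemBackendAvailable <- function() {
  if (isTRUE(.chemCache$.available)) return(invisible(TRUE))
  res <- try(chemDescriptors("C"), silent = TRUE)
  if (inherits(res, "try-error"))
    cmomoStop("evaluationError",
              paste("RDKit Python backend unavailable:",
                    attr(res, "condition")$message))
  assign(".available", TRUE, envir = .chemCache)
  invisible(TRUE)
}

.descKey <- function(smiles, alertsKey, fpRadius, fpBits) {
  paste(smiles, alertsKey, fpRadius, fpBits, sep = "\r")
}

.alertsKey <- function(alerts) {
  if (is.null(alerts)) return("")
  attr(alerts, "md5")
}

# Write the SMARTS of an alert set to a temp file for the helper script.
.alertsTempFile <- function(alerts) {
  f <- tempfile(fileext = ".smarts")
  writeLines(alerts$smarts, f)
  f
}

.parseBackendRecord <- function(line) {
  jsonlite::fromJSON(line, simplifyVector = TRUE)
}

.runBackend <- function(smiles, alerts, fpRadius, fpBits) {
  smiFile <- tempfile(fileext = ".smi")
  outFile <- tempfile(fileext = ".ndjson")
  on.exit(unlink(c(smiFile, outFile)), add = TRUE)
  writeLines(smiles, smiFile)
  args <- c(backendScript(), "desc", "--smiles-file", smiFile,
            "--fp-radius", fpRadius, "--fp-bits", fpBits, "--out", outFile)
  alertFile <- NULL
  if (!is.null(alerts)) {
    alertFile <- .alertsTempFile(alerts)
    on.exit(unlink(alertFile), add = TRUE)
    args <- c(args, "--alerts", alertFile)
  }
  err <- tempfile()
  on.exit(unlink(err), add = TRUE)
  status <- system2(pythonBin(), shQuote(args), stdout = FALSE, stderr = err)
  if (!identical(status, 0L))
    cmomoStop("evaluationError",
              paste("descriptor backend failed:",
                    paste(readLines(err, warn = FALSE), collapse = "; ")))
  lines <- readLines(outFile, warn = FALSE)
  if (length(lines) != length(smiles))
    cmomoStop("evaluationError", "descriptor backend returned short output")
  lapply(lines, .parseBackendRecord)
}

#' Batched molecular descriptors
#'
#' Computes (or retrieves from the session cache) the primitive descriptors
#' for a vector of SMILES strings. Invalid SMILES are reported, not errors:
#' downstream policy differs between parsing (error) and batch decoding
#' (silent filtering).
#'
#' @param smiles character vector of SMILES strings.
#' @param alerts an alert set from [loadAlerts()], or `NULL` to skip
#'   substructure screening.
#' @param fpRadius,fpBits Morgan fingerprint radius and bit width.
#' @return a list of per-molecule records with fields `valid`, `canonical`,
#'   `qed`, `logp`, `sa`, `ring_sizes`, `fp` and (when `alerts` is given)
#'   `n_alerts`.
#' @keywords internal
chemDescriptors <- function(smiles, alerts = NULL, fpRadius = 2L,
                            fpBits = 2048L) {
  if (!is.character(smiles))
    cmomoStop("badParams", "'smiles' must be a character vector")
  aKey <- .alertsKey(alerts)
  keys <- .descKey(smiles, aKey, fpRadius, fpBits)
  miss <- !vapply(keys, exists, logical(1), envir = .chemCache)
  if (any(miss)) {
    todo <- unique(smiles[miss])
    recs <- .runBackend(todo, alerts, fpRadius, fpBits)
    for (i in seq_along(todo)) {
      rec <- recs[[i]]
      assign(.descKey(todo[i], aKey, fpRadius, fpBits), rec,
             envir = .chemCache)
      # canonical form maps to the same record: round-trips are free
      if (isTRUE(rec$valid) && !is.null(rec$canonical)) {
        ck <- .descKey(rec$canonical, aKey, fpRadius, fpBits)
        if (!exists(ck, envir = .chemCache)) assign(ck, rec, envir = .chemCache)
      }
    }
  }
  lapply(keys, get, envir = .chemCache)
}

# Single-molecule descriptor record; errors on invalid input.
.descriptor1 <- function(smiles, alerts = NULL, fpRadius = 2L,
                         fpBits = 2048L) {
  rec <- chemDescriptors(smiles, alerts, fpRadius, fpBits)[[1L]]
  if (!isTRUE(rec$valid))
    cmomoStop("invalidSmiles", sprintf("invalid SMILES: '%s'", smiles))
  if (!is.null(rec$error))
    cmomoStop("evaluationError",
              sprintf("descriptor failure for '%s': %s", smiles, rec$error))
  rec
}
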