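# Run configuration, the two-stage optimization loop, and result I/O.

#' Create a run configuration
#'
#' All parameters of an optimization run with validated defaults. See
#' [RunConfig-class] for the meaning of each field.
#'
#' @param lead lead molecule SMILES (or coordinate string).
#' @param databasePath,alertsPath,codecSpec,outputDir file-system wiring;
#'   empty strings mean "not set" (packaged defaults apply where they
#'   exist).
#' @param P,G1,G2,bankSize,seed,nFrag integer parameters.
#' @param d,pM,mutationScale,simMin,propMin numeric parameters.
#' @param objectives,constraints registry names used to assemble the
#'   problem when [runCMOMO()] is not given one explicitly.
#' @param thresholds named numeric success thresholds.
#' @param init `"bank"` or `"uniform"`.
#' @param dedupeAgainstParents,archiveFeasible logical switches.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(lead, databasePath = "", alertsPath = "",
                      codecSpec = "", P = 20L, G1 = 15L, G2 = 15L,
                      d = 0.25, pM = 0.5, nFrag = 8L,
                      mutationScale = NA_real_, bankSize = 20L,
                      simMin = 0.2, propMin = 0, seed = 1L,
                      objectives = c("qed", "similarity"),
                      constraints = c("ring_size", "alerts"),
                      thresholds = numeric(0), init = "bank",
                      dedupeAgainstParents = TRUE, archiveFeasible = FALSE,
                      outputDir = "cmomo-results") {
  thresholds <- unlist(thresholds)          # lists arrive from YAML configs
  if (is.null(thresholds)) thresholds <- numeric(0)
  tryCatch(
    new("RunConfig", lead = lead, databasePath = databasePath,
        alertsPath = alertsPath, codecSpec = codecSpec, P = as.integer(P),
        G1 = as.integer(G1), G2 = as.integer(G2), d = as.numeric(d),
        pM = as.numeric(pM), nFrag = as.integer(nFrag),
        mutationScale = as.numeric(mutationScale),
        bankSize = as.integer(bankSize), simMin = as.numeric(simMin),
        propMin = as.numeric(propMin), seed = as.integer(seed),
        objectiveNames = as.character(objectives),
        constraintNames = as.character(constraints),
        thresholds = thresholds, init = init,
        dedupeAgainstParents = isTRUE(dedupeAgainstParents),
        archiveFeasible = isTRUE(archiveFeasible), outputDir = outputDir),
    error = function(e) cmomoStop("configError", conditionMessage(e)))
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected with a field-level message; missing keys take
#' the [runConfig()] defaults.
#'
#' @param path YAML file path.
#' @return a validated [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    cmomoStop("configError", sprintf("config file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$lead))
    cmomoStop("configError", "config must be a mapping with a 'lead' key")
  known <- names(formals(runConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    cmomoStop("configError",
              sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(raw$thresholds)) raw$thresholds <- unlist(raw$thresholds)
  do.call(runConfig, raw)
}

#' Serialize a run configuration
#'
#' @param config a [RunConfig-class].
#' @param path optional YAML output path.
#' @return the config as a plain named list (invisibly when writing).
#' @export
configAsList <- function(config, path = NULL) {
  fields <- c(lead = "lead", databasePath = "databasePath",
              alertsPath = "alertsPath", codecSpec = "codecSpec", P = "P",
              G1 = "G1", G2 = "G2", d = "d", pM = "pM", nFrag = "nFrag",
              mutationScale = "mutationScale", bankSize = "bankSize",
              simMin = "simMin", propMin = "propMin", seed = "seed",
              objectives = "objectiveNames", constraints = "constraintNames",
              thresholds = "thresholds", init = "init",
              dedupeAgainstParents = "dedupeAgainstParents",
              archiveFeasible = "archiveFeasible", outputDir = "outputDir")
  out <- lapply(fields, function(sl) slot(config, sl))
  out$thresholds <- as.list(out$thresholds)
  if (!is.null(path)) {
    yaml::write_yaml(out, path)
    return(invisible(out))
  }
  out
}

#' Read a SMILES list file
#'
#' UTF-8, one SMILES per line, optional tab-separated ID column, `#`
#' comment lines and blank lines ignored.
#'
#' @param path file path.
#' @return character vector of SMILES.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path))
    cmomoStop("configError", sprintf("SMILES file not found: '%s'", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(raw)) & !grepl("^\\s*#", raw)
  vapply(strsplit(raw[keep], "\t", fixed = TRUE), function(p) trimws(p[[1L]]),
         character(1))
}

.resolveCodec <- function(config) {
  spec <- config@codecSpec
  if (!nzchar(spec))
    cmomoStop("configError", "no codec given: set codecSpec or pass one")
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  kind <- parts[1L]
  arg <- if (length(parts) > 1L) paste(parts[-1L], collapse = ":") else ""
  switch(kind,
    table = readTableCodec(arg),
    identity = identityCodec(as.integer(arg)),
    cmomoStop("configError", sprintf("unknown codec spec '%s'", spec)))
}

.resolveProblem <- function(config) {
  alerts <- if (nzchar(config@alertsPath)) loadAlerts(config@alertsPath)
            else loadAlerts()
  th <- config@thresholds
  obj <- lapply(config@objectiveNames, function(nm)
    objectiveSpec(nm, successThreshold = if (nm %in% names(th)) th[[nm]]
                                         else NA_real_))
  con <- lapply(config@constraintNames, function(nm)
    constraintSpec(nm, alerts = alerts))
  problemDefinition(obj, con)
}

# Evaluate a set of molecules; returns list(objectives, sigmas). For
# chemical worlds the descriptor cache is warmed in one backend batch per
# variant first.
.evaluateSet <- function(smiles, problem, lead, chemical = TRUE) {
  if (chemical) warmDescriptorCache(smiles, problem)
  list(objectives = objectiveMatrix(smiles, problem, lead),
       sigmas = sigmaMatrix(smiles, problem))
}

.uniformInit <- function(codec, P) {
  bounds <- codecBounds(codec)
  if (is.null(bounds))
    cmomoStop("initializationFailed",
              "uniform initialization needs codec bounds")
  dim <- codecDim(codec)
  smiles <- character(0)
  latent <- matrix(numeric(0), ncol = dim)
  draws <- 0L
  while (length(smiles) < P && draws < 10L * P) {
    k <- P - length(smiles)
    Z <- matrix(stats::runif(k * dim, rep(bounds[1L, ], each = k),
                             rep(bounds[2L, ], each = k)), ncol = dim)
    hits <- decodeValidBatch(codec, Z)
    draws <- draws + k
    if (nrow(hits)) {
      smiles <- c(smiles, hits$smiles)
      latent <- rbind(latent, Z[hits$index, , drop = FALSE])
    }
  }
  if (length(smiles) < 1L)
    cmomoStop("initializationFailed", "uniform initialization found nothing")
  while (length(smiles) < P) {        # pad by recycling the first member
    smiles <- c(smiles, smiles[1L])
    latent <- rbind(latent, latent[1L, ])
  }
  list(smiles = smiles[seq_len(P)], latent = latent[seq_len(P), , drop = FALSE])
}

.logRow <- function(stage, gen, F, sig, alpha) {
  feasFrac <- if (ncol(sig)) mean(isFeasible(sig)) else 1
  row <- data.frame(stage = stage, generation = gen,
                    hv = hypervolume(F), feasibleFraction = feasFrac,
                    alpha = alpha)
  for (j in seq_len(ncol(F))) {
    row[[paste0("best_", colnames(F)[j])]] <- max(F[, j])
    row[[paste0("mean_", colnames(F)[j])]] <- mean(F[, j])
  }
  row
}

#' Run the full two-stage constrained molecular optimization
#'
#' Initializes a population (Bank-library crossover seeding, or seeded
#' uniform draws for codecs without a molecule database), then evolves it
#' with blend crossover + fragment mutation in latent space. Selection is
#' NSGA-II environmental selection during the first (unconstrained) stage
#' and ranking aggregation with the cosine-decayed weight during the second
#' (constrained) stage; the constrained-stage generation index t runs from
#' 0 (weight 1, pure property preference) with T equal to the configured
#' stage length. The whole run is reproducible from the config seed.
#'
#' @param config a [RunConfig-class].
#' @param codec optional codec object (otherwise resolved from
#'   `config@codecSpec`).
#' @param problem optional [ProblemDefinition-class] (otherwise assembled
#'   from the config's registry names).
#' @param database optional character vector of candidate SMILES for Bank
#'   screening (otherwise read from `config@databasePath` when Bank
#'   initialization is requested).
#' @return an [OptimizationResult-class].
#' @export
runCMOMO <- function(config, codec = NULL, problem = NULL, database = NULL) {
  if (is.null(codec)) codec <- .resolveCodec(config)
  if (is.null(problem)) problem <- .resolveProblem(config)
  P <- config@P
  set.seed(config@seed)
  # the fragment count cannot exceed the latent dimension; low-dimensional
  # codecs (analytic worlds) silently get fewer fragments
  params <- variationParams(config@d, config@pM,
                            min(config@nFrag, codecDim(codec)),
                            config@mutationScale)
  bounds <- codecBounds(codec)

  if (config@init == "bank") {
    if (is.null(database)) {
      if (!nzchar(config@databasePath))
        cmomoStop("configError", "Bank initialization needs a database")
      database <- readSmilesFile(config@databasePath)
    }
    bank <- buildBank(config@lead, database, codec,
                      bankSize = config@bankSize, simMin = config@simMin,
                      propMin = config@propMin)
    pop <- initializePopulation(config@lead, bank, codec, P, params)
  } else {
    pop <- .uniformInit(codec, P)
  }
  lead <- canonicalizeInput(codec, config@lead)
  chemical <- !is(codec, "IdentityCodec")
  ev <- .evaluateSet(pop$smiles, problem, lead, chemical)
  pop$objectives <- ev$objectives
  pop$sigmas <- ev$sigmas

  log <- .logRow("init", 0L, pop$objectives, pop$sigmas, NA_real_)
  archive <- if (config@archiveFeasible)
    unique(pop$smiles[isFeasible(pop$sigmas)]) else character(0)
  lastSel <- NULL

  step <- function(pop, stage, t) {
    Z <- generateOffspring(pop$latent, params, bounds)
    exclude <- if (config@dedupeAgainstParents) pop$smiles else character(0)
    hits <- decodeValidBatch(codec, Z, exclude = exclude)
    if (nrow(hits)) {
      oev <- .evaluateSet(hits$smiles, problem, lead, chemical)
      uSmiles <- c(pop$smiles, hits$smiles)
      uLatent <- rbind(pop$latent, Z[hits$index, , drop = FALSE])
      uF <- rbind(pop$objectives, oev$objectives)
      uSig <- rbind(pop$sigmas, oev$sigmas)
    } else {
      uSmiles <- pop$smiles; uLatent <- pop$latent
      uF <- pop$objectives; uSig <- pop$sigmas
    }
    if (stage == 1L) {
      sel <- environmentalSelectionStage1(uF, P)
      selInfo <- NULL
    } else {
      cv <- aggregateCV(uSig)
      res <- environmentalSelectionStage2(uF, cv, P, t, config@G2)
      sel <- res$selected
      selInfo <- res
    }
    if (config@archiveFeasible)
      archive <<- unique(c(archive, uSmiles[isFeasible(uSig)]))
    lastSel <<- selInfo
    list(smiles = uSmiles[sel], latent = uLatent[sel, , drop = FALSE],
         objectives = uF[sel, , drop = FALSE],
         sigmas = uSig[sel, , drop = FALSE])
  }

  for (g in seq_len(config@G1)) {
    pop <- step(pop, 1L, NA_integer_)
    log <- rbind(log, .logRow("stage1", g, pop$objectives, pop$sigmas,
                              NA_real_))
  }
  if (config@G2 > 0L) {
    for (t in 0:(config@G2 - 1L)) {
      pop <- step(pop, 2L, t)
      log <- rbind(log, .logRow("stage2", t,
                                pop$objectives, pop$sigmas, lastSel$alpha))
    }
  }

  finalPop <- .finalizePopulation(pop, config@G2)
  feasible <- extractFeasible(finalPop)
  if (config@archiveFeasible)
    attr(feasible, "archive") <- archive
  new("OptimizationResult", finalPopulation = finalPop, feasible = feasible,
      log = log,
      provenance = list(
        config = configAsList(config), seed = config@seed,
        packageVersion = as.character(utils::packageVersion("cmomo")),
        rVersion = R.version.string))
}

# Attach final ranking statistics: Pareto front/crowding, both preference
# ranks, and the comprehensive score at the end of the schedule (weight 0
# after a constrained stage, 1 when no constrained stage ran).
.finalizePopulation <- function(pop, G2) {
  F <- pop$objectives
  front <- fastNonDominatedSort(F)
  crowd <- .crowdingByFront(F, front)
  s1 <- .rankFrontCrowding(front, crowd)
  cv <- aggregateCV(pop$sigmas)
  s2 <- constraintPreferenceRanking(F, cv)
  alpha <- if (G2 > 0L) 0 else 1
  score <- comprehensiveScore(s1, s2, alpha)
  new("MoleculePopulation", smiles = pop$smiles, latent = pop$latent,
      objectives = F, sigmas = pop$sigmas, cv = cv,
      ranking = data.frame(front = front, crowding = crowd, s1 = s1,
                           s2 = s2, score = score))
}

#' Extract the feasible records of a population
#'
#' Records whose every raw violation degree is zero, order preserved. An
#' empty result is reported, not an error.
#'
#' @param pop a [MoleculePopulation-class].
#' @return data.frame with `smiles`, objective columns, sigma columns and
#'   `cv`.
#' @export
extractFeasible <- function(pop) {
  keep <- which(isFeasible(pop@sigmas))
  df <- data.frame(smiles = pop@smiles[keep], stringsAsFactors = FALSE)
  obj <- pop@objectives[keep, , drop = FALSE]
  for (j in seq_len(ncol(obj))) df[[colnames(obj)[j]]] <- obj[, j]
  sig <- pop@sigmas[keep, , drop = FALSE]
  for (j in seq_len(ncol(sig)))
    df[[paste0("sigma_", colnames(sig)[j])]] <- sig[, j]
  df$cv <- pop@cv[keep]
  df
}

#' Write run results to a directory
#'
#' Writes `final_population.csv` (all members with objectives, violation
#' degrees, CV, feasibility and ranking statistics), `feasible.smi`,
#' `generations.jsonl` (one JSON object per logged generation) and
#' `provenance.json`. Output is a deterministic function of the result
#' object: identical runs produce byte-identical files.
#'
#' @param result an [OptimizationResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeResults <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- result@finalPopulation
  df <- data.frame(smiles = pop@smiles, stringsAsFactors = FALSE)
  F <- pop@objectives
  for (j in seq_len(ncol(F))) df[[colnames(F)[j]]] <- F[, j]
  sig <- pop@sigmas
  for (j in seq_len(ncol(sig)))
    df[[paste0("sigma_", colnames(sig)[j])]] <- sig[, j]
  df$cv <- pop@cv
  df$feasible <- isFeasible(sig)
  df <- cbind(df, pop@ranking)
  utils::write.csv(df, file.path(dir, "final_population.csv"),
                   row.names = FALSE)
  writeLines(result@feasible$smiles, file.path(dir, "feasible.smi"))
  con <- file(file.path(dir, "generations.jsonl"), "w")
  for (i in seq_len(nrow(result@log)))
    writeLines(jsonlite::toJSON(as.list(result@log[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  close(con)
  jsonlite::write_json(result@provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read back a written final population
#'
#' @param path `final_population.csv` as written by [writeResults()].
#' @return data.frame.
#' @export
readFinalPopulation <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
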