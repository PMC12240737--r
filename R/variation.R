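# Latent-space reproduction: blended linear crossover plus
# fragmentation-based mutation, Bank library screening, and population
# initialization. All randomness is drawn from the session RNG stream; the
# driver seeds it once per run so whole runs replay bit-for-bit.

#' Variation parameters
#'
#' @param d blend extrapolation parameter (>= 0); `d = 0` restricts children
#'   to the segment between their parents, `d > 0` extrapolates beyond it.
#' @param pM per-gene mutation probability within the chosen fragment.
#' @param nFrag number of contiguous latent fragments; one is chosen
#'   uniformly per mutation call.
#' @param mutationScale standard deviation of the additive Gaussian step;
#'   `NA` = 0.1 of the per-dimension bound range (0.1 absolute when
#'   unbounded).
#' @return a list of class `"VariationParams"`.
#' @export
variationParams <- function(d = 0.25, pM = 0.5, nFrag = 8L,
                            mutationScale = NA_real_) {
  assertScalarNumber(d, "d")
  assertScalarNumber(pM, "pM")
  if (d < 0) cmomoStop("badParams", "'d' must be >= 0")
  if (pM < 0 || pM > 1) cmomoStop("badParams", "'pM' must lie in [0, 1]")
  if (!is.numeric(nFrag) || length(nFrag) != 1L || nFrag < 1)
    cmomoStop("badParams", "'nFrag' must be a positive integer")
  structure(list(d = d, pM = pM, nFrag = as.integer(nFrag),
                 mutationScale = as.numeric(mutationScale)),
            class = "VariationParams")
}

# Per-dimension Gaussian step scale, resolved against codec bounds.
.mutationSigma <- function(params, bounds, dim) {
  if (is.finite(params$mutationScale)) return(rep(params$mutationScale, dim))
  if (is.null(bounds)) rep(0.1, dim) else 0.1 * (bounds[2L, ] - bounds[1L, ])
}

clampToBounds <- function(z, bounds) {
  if (is.null(bounds)) return(z)
  pmin(pmax(z, bounds[1L, ]), bounds[2L, ])
}

#' Blended linear crossover
#'
#' Both children are blends anchored at the first parent:
#' `z1 + (-d + (1 + 2d) u) (z2 - z1)` with a scalar blend factor per child
#' (`u = u1` and `u = u2`). `u1`, `u2` are uniform draws in \[0, 1\]; pass
#' them explicitly for reproducible single calls, or omit to draw from the
#' session RNG.
#'
#' @param z1,z2 parent latent vectors of equal length.
#' @param d extrapolation parameter (>= 0).
#' @param u1,u2 blend draws in \[0, 1\].
#' @param bounds optional 2 x D bounds matrix; children are clamped to it.
#' @return list with children `z1` and `z2`.
#' @export
blendCrossover <- function(z1, z2, d = 0.25, u1 = stats::runif(1),
                           u2 = stats::runif(1), bounds = NULL) {
  assertSameLength(z1, z2, "parent vectors")
  if (d < 0) cmomoStop("badParams", "'d' must be >= 0")
  diff <- z2 - z1
  c1 <- z1 + (-d + (1 + 2 * d) * u1) * diff
  c2 <- z1 + (-d + (1 + 2 * d) * u2) * diff
  list(z1 = clampToBounds(c1, bounds), z2 = clampToBounds(c2, bounds))
}

# Contiguous near-equal partition: the first (D mod nFrag) fragments get
# one extra gene.
fragmentBoundaries <- function(dim, nFrag) {
  if (nFrag > dim)
    cmomoStop("badParams",
              sprintf("nFrag (%d) exceeds latent dimension (%d)", nFrag, dim))
  base <- dim %/% nFrag
  sizes <- rep(base, nFrag) + c(rep(1L, dim %% nFrag),
                                rep(0L, nFrag - dim %% nFrag))
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

#' Fragmentation-based mutation
#'
#' Partitions the latent vector into `nFrag` contiguous near-equal
#' fragments, draws one fragment uniformly, and perturbs each gene inside
#' it independently with probability `pM` by adding Gaussian noise; genes
#' outside the chosen fragment are untouched. The result is clamped to the
#' bounds when given.
#'
#' @param z latent vector.
#' @param params a [variationParams()] object.
#' @param bounds optional 2 x D bounds matrix.
#' @return mutated latent vector of the same length.
#' @export
fragmentMutation <- function(z, params, bounds = NULL) {
  dim <- length(z)
  bnd <- fragmentBoundaries(dim, params$nFrag)
  frag <- sample.int(nrow(bnd), 1L)
  idx <- bnd[frag, "start"]:bnd[frag, "end"]
  hit <- stats::runif(length(idx)) < params$pM
  if (any(hit)) {
    sigma <- .mutationSigma(params, bounds, dim)
    z[idx[hit]] <- z[idx[hit]] +
      stats::rnorm(sum(hit), mean = 0, sd = sigma[idx[hit]])
  }
  clampToBounds(z, bounds)
}

#' Generate an offspring batch
#'
#' Repeats ceiling(P/2) times: draw two distinct parents uniformly, apply
#' [blendCrossover()] with fresh uniform blend draws, then
#' [fragmentMutation()] to both children; the collected children are
#' truncated to exactly P offspring.
#'
#' @param parents P x D matrix of parent latent vectors (P >= 2).
#' @param params a [variationParams()] object.
#' @param bounds optional 2 x D bounds matrix.
#' @return P x D matrix of offspring latent vectors.
#' @export
generateOffspring <- function(parents, params, bounds = NULL) {
  parents <- as.matrix(parents)
  P <- nrow(parents)
  if (P < 2L) cmomoStop("badParams", "need at least 2 parents")
  children <- matrix(NA_real_, nrow = 2L * ceiling(P / 2), ncol = ncol(parents))
  row <- 1L
  for (k in seq_len(ceiling(P / 2))) {
    pair <- sample.int(P, 2L, replace = FALSE)
    cr <- blendCrossover(parents[pair[1L], ], parents[pair[2L], ],
                         d = params$d, u1 = stats::runif(1),
                         u2 = stats::runif(1), bounds = bounds)
    children[row, ] <- fragmentMutation(cr$z1, params, bounds)
    children[row + 1L, ] <- fragmentMutation(cr$z2, params, bounds)
    row <- row + 2L
  }
  children[seq_len(P), , drop = FALSE]
}

#' Build a Bank library by screening a molecule database
#'
#' Keeps database molecules similar enough to the lead
#' (`tanimotoSimilarity >= simMin`) with a screening property at least
#' `propMin`, ranks survivors by descending property, then descending
#' similarity, then input order, and returns the top `bankSize` members
#' encoded into latent space. A shortfall (fewer survivors than requested)
#' is recorded in the provenance, not an error.
#'
#' @param lead lead molecule SMILES.
#' @param database character vector of candidate SMILES (invalid entries are
#'   dropped).
#' @param codec codec used to embed the members.
#' @param bankSize capacity B (>= 1).
#' @param simMin,propMin screening thresholds.
#' @param property screening property function `function(smiles) -> real`;
#'   default [qedScore()].
#' @return a [BankLibrary-class].
#' @export
buildBank <- function(lead, database, codec, bankSize = 20L, simMin = 0.2,
                      propMin = 0, property = qedScore) {
  if (!length(database))
    cmomoStop("emptyDatabase", "candidate database is empty")
  if (!is(codec, "IdentityCodec"))
    chemDescriptors(unique(c(lead, database)))  # one backend batch up front
  leadCanon <- parseSmiles(lead)
  canon <- vapply(database, function(s) canonicalizeInput(codec, s),
                  character(1), USE.NAMES = FALSE)
  keepValid <- which(!is.na(canon))
  canon <- canon[keepValid]
  dupFirst <- !duplicated(canon)
  canon <- canon[dupFirst]
  if (!length(canon))
    cmomoStop("emptyDatabase", "no valid molecules in the database")
  sims <- vapply(canon, tanimotoSimilarity, numeric(1), lead = leadCanon,
                 USE.NAMES = FALSE)
  props <- vapply(canon, property, numeric(1), USE.NAMES = FALSE)
  surv <- which(sims >= simMin & props >= propMin)
  if (!length(surv))
    cmomoStop("noSurvivors", "screening eliminated every database molecule")
  ord <- surv[order(-props[surv], -sims[surv], surv)]
  top <- head(ord, bankSize)
  latent <- t(vapply(canon[top], function(s) encodeMolecule(codec, s),
                     numeric(codecDim(codec))))
  rownames(latent) <- NULL
  new("BankLibrary", smiles = canon[top], latent = latent,
      provenance = list(lead = leadCanon, bankSize = as.integer(bankSize),
                        simMin = simMin, propMin = propMin,
                        screened = length(canon), survivors = length(surv),
                        shortfall = max(0L, as.integer(bankSize) - length(top))))
}

#' Initialize a population from the Bank library
#'
#' Cycles over Bank members, crossing each with the lead via
#' [blendCrossover()] (two children per draw with fresh blend draws),
#' decoding children through [decodeValidBatch()], and accumulating
#' distinct valid molecules until `P` are collected or the retry budget
#' (`10 * P` draws) is exhausted; any remaining places are padded with
#' copies of the lead.
#'
#' @param lead lead molecule SMILES.
#' @param bank a [BankLibrary-class].
#' @param codec codec for encoding/decoding.
#' @param P target population size.
#' @param params a [variationParams()] object.
#' @return list with `smiles` (length P) and `latent` (P x D matrix).
#' @export
initializePopulation <- function(lead, bank, codec, P, params) {
  if (!length(bank@smiles))
    cmomoStop("initializationFailed", "Bank library is empty")
  leadCanon <- tryCatch(canonicalizeInput(codec, lead),
                        error = function(e) NA_character_)
  leadZ <- tryCatch(encodeMolecule(codec, lead), error = function(e) NULL)
  if (is.na(leadCanon) || is.null(leadZ))
    cmomoStop("initializationFailed", "lead molecule is not usable")
  bounds <- codecBounds(codec)
  smiles <- character(0)
  latent <- matrix(numeric(0), ncol = codecDim(codec))
  draws <- 0L
  member <- 0L
  while (length(smiles) < P && draws < 10L * P) {
    member <- member %% length(bank@smiles) + 1L
    cr <- blendCrossover(leadZ, bank@latent[member, ], d = params$d,
                         u1 = stats::runif(1), u2 = stats::runif(1),
                         bounds = bounds)
    draws <- draws + 2L
    batch <- rbind(cr$z1, cr$z2)
    hits <- decodeValidBatch(codec, batch, exclude = smiles)
    if (nrow(hits)) {
      smiles <- c(smiles, hits$smiles)
      latent <- rbind(latent, batch[hits$index, , drop = FALSE])
    }
  }
  if (length(smiles) > P) {
    smiles <- smiles[seq_len(P)]
    latent <- latent[seq_len(P), , drop = FALSE]
  }
  while (length(smiles) < P) {        # pad with the lead
    smiles <- c(smiles, leadCanon)
    latent <- rbind(latent, leadZ)
  }
  rownames(latent) <- NULL
  list(smiles = smiles, latent = latent)
}
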