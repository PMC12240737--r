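# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately use different algorithms/code paths than the package
# implementations they check.

# Pairwise Pareto dominance, written out longhand.
oracleDominates <- function(a, b) {
  ge <- TRUE
  gt <- FALSE
  for (j in seq_along(a)) {
    if (a[j] < b[j]) ge <- FALSE
    if (a[j] > b[j]) gt <- TRUE
  }
  ge && gt
}

# Front numbers by repeatedly extracting the maximal set (O(N^2 m) scan).
oracleFronts <- function(F) {
  n <- nrow(F)
  front <- rep(NA_integer_, n)
  k <- 0L
  while (anyNA(front)) {
    k <- k + 1L
    open <- which(is.na(front))
    for (i in open) {
      dominated <- FALSE
      for (j in open)
        if (j != i && oracleDominates(F[j, ], F[i, ])) {
          dominated <- TRUE
          break
        }
      if (!dominated) front[i] <- k
    }
  }
  front
}

# Crowding distance recomputed with a per-objective rank walk.
oracleCrowding <- function(F) {
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(F))) {
    ord <- order(F[, j])
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    span <- F[ord[n], j] - F[ord[1L], j]
    if (span > 0)
      for (i in 2:(n - 1L))
        d[ord[i]] <- d[ord[i]] + (F[ord[i + 1L], j] - F[ord[i - 1L], j]) / span
  }
  d
}

# NSGA-II environmental selection recomposed from the two oracles.
oracleStage1 <- function(F, P) {
  front <- oracleFronts(F)
  picked <- integer(0)
  for (k in sort(unique(front))) {
    idx <- which(front == k)
    if (length(picked) + length(idx) <= P) {
      picked <- c(picked, idx)
    } else {
      cd <- oracleCrowding(F[idx, , drop = FALSE])
      picked <- c(picked, idx[order(-cd, idx)][seq_len(P - length(picked))])
      break
    }
  }
  sort(picked)
}

# Monte-Carlo hypervolume (maximization, zero reference): fraction of
# uniform samples in the bounding box dominated by some point.
oracleHypervolumeMC <- function(points, n = 1e6) {
  points <- pmax(points, 0)
  upper <- apply(points, 2L, max)
  if (any(upper <= 0)) return(0)
  m <- ncol(points)
  samp <- matrix(runif(n * m, 0, rep(upper, each = n)), ncol = m)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(points))) {
    inside <- rep(TRUE, n)
    for (j in seq_len(m)) inside <- inside & samp[, j] <= points[i, j]
    covered <- covered | inside
  }
  mean(covered) * prod(upper)
}

# Programmatic generator of syntactically valid SMILES: random heteroatom
# chains with optional branches and ring decorations.
randomValidSmiles <- function(n) {
  atoms <- c("C", "N", "O")
  rings <- c("", "c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1")
  vapply(seq_len(n), function(i) {
    chain <- paste(sample(atoms, sample(2:6, 1L), replace = TRUE),
                   collapse = "")
    branch <- if (runif(1) < 0.4) "(C)" else ""
    ring <- sample(rings, 1L)
    paste0("C", branch, chain, ring)
  }, character(1))
}

# Memoized shared fixtures (built once per test run).
.fixtures <- new.env()

toyWorldFixture <- function() {
  if (is.null(.fixtures$world))
    .fixtures$world <- makeToyWorld(seed = 7L, n = 60L)
  .fixtures$world
}

analyticFixture <- function() {
  if (is.null(.fixtures$analytic))
    .fixtures$analytic <- makeAnalyticProblem()
  .fixtures$analytic
}

runToy <- function(seed, P = 20L, G1 = 15L, G2 = 15L, ...) {
  w <- toyWorldFixture()
  cfg <- runConfig(lead = w$lead, P = P, G1 = G1, G2 = G2, seed = seed, ...)
  runCMOMO(cfg, codec = w$codec, problem = w$problem, database = w$smiles)
}

runAnalytic <- function(seed, P = 40L, G1 = 30L, G2 = 30L) {
  ap <- analyticFixture()
  cfg <- runConfig(lead = ap$lead, P = P, G1 = G1, G2 = G2, seed = seed,
                   init = "uniform", objectives = c("f1", "f2"),
                   constraints = "band")
  runCMOMO(cfg, codec = ap$codec, problem = ap$problem)
}
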