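# Blended linear crossover, fragmentation-based mutation, Bank screening
# and population initialization.

test_that("blend crossover reproduces the linear blend exactly", {
  z1 <- c(0, 0)
  z2 <- c(2, 2)
  # blend factor 0 and 1 reproduce the parents when d = 0
  expect_equal(blendCrossover(z1, z2, d = 0, u1 = 0, u2 = 1)$z1, z1)
  expect_equal(blendCrossover(z1, z2, d = 0, u1 = 0, u2 = 1)$z2, z2)
  # hand case: factor = -0.25 + 1.5 * 0.5 = 0.5
  out <- blendCrossover(z1, z2, d = 0.25, u1 = 0.5, u2 = 0.5)
  expect_equal(out$z1, c(1, 1))
  # equal draws give identical children
  expect_equal(out$z1, out$z2)
  # extrapolation beyond the segment when d > 0, clamped when bounds given
  ext <- blendCrossover(z1, z2, d = 0.25, u1 = 0, u2 = 1)
  expect_equal(ext$z1, c(-0.5, -0.5))
  bnd <- rbind(lo = c(0, 0), hi = c(2, 2))
  expect_equal(blendCrossover(z1, z2, d = 0.25, u1 = 0, u2 = 1,
                              bounds = bnd)$z1, c(0, 0))
  expect_error(blendCrossover(c(1, 2), c(1, 2, 3), d = 0),
               class = "dimensionMismatch")
})

test_that("fragments partition the vector contiguously and near-equally", {
  expect_equal(unname(cmomo:::fragmentBoundaries(8L, 4L)[, "end"] -
                      cmomo:::fragmentBoundaries(8L, 4L)[, "start"] + 1L),
               c(2L, 2L, 2L, 2L))
  b <- cmomo:::fragmentBoundaries(10L, 3L)
  expect_equal(unname(b[, "end"] - b[, "start"] + 1L), c(4L, 3L, 3L))
  expect_equal(unname(b[1, "start"]), 1L)
  expect_equal(unname(b[3, "end"]), 10L)
  expect_error(cmomo:::fragmentBoundaries(2L, 8L), class = "badParams")
})

test_that("mutation touches only one fragment and respects p_m", {
  p0 <- variationParams(pM = 0)
  z <- runif(16)
  set.seed(1)
  expect_identical(fragmentMutation(z, p0), z)   # p_m = 0: no gene moves

  # locality: with D = 512 and 8 fragments, changes stay within one
  # contiguous 64-gene block
  p1 <- variationParams(pM = 1, nFrag = 8L, mutationScale = 0.5)
  z <- runif(512)
  for (s in 1:100) {
    set.seed(s)
    out <- fragmentMutation(z, p1)
    changed <- which(out != z)
    expect_lte(max(changed) - min(changed) + 1L, 64L)
    expect_equal((min(changed) - 1L) %/% 64L, (max(changed) - 1L) %/% 64L)
  }

  # expected number of changed genes ~ p_m * fragment length
  pHalf <- variationParams(pM = 0.5, nFrag = 4L, mutationScale = 0.3)
  z <- runif(16)
  set.seed(7)
  changed <- replicate(1e4, sum(fragmentMutation(z, pHalf) != z))
  expect_true(all(changed <= 4))
  # mean of 1e4 draws from Binomial(4, 0.5): 3 sigma band around 2
  expect_lt(abs(mean(changed) - 2), 3 * sqrt(4 * 0.25 / 1e4))
})

test_that("offspring generation meets the count, determinism and geometry contracts", {
  set.seed(3)
  parents <- matrix(runif(10 * 4), nrow = 10)
  pars <- variationParams(nFrag = 4L)
  set.seed(5)
  off1 <- generateOffspring(parents, pars)
  expect_equal(dim(off1), dim(parents))
  set.seed(5)
  expect_identical(generateOffspring(parents, pars), off1)
  expect_error(generateOffspring(parents[1, , drop = FALSE], pars),
               class = "badParams")

  # with d = 0 and p_m = 0 every child lies in the parent bounding segment
  flat <- variationParams(d = 0, pM = 0, nFrag = 2L)
  for (trial in 1:100) {
    set.seed(trial)
    par2 <- matrix(runif(8), nrow = 4)
    set.seed(trial + 1000)
    off <- generateOffspring(par2, flat)
    lo <- apply(par2, 2, min)
    hi <- apply(par2, 2, max)
    expect_true(all(off >= matrix(lo, nrow(off), 2, byrow = TRUE) - 1e-12))
    expect_true(all(off <= matrix(hi, nrow(off), 2, byrow = TRUE) + 1e-12))
  }

  # declared bounds are never violated even under heavy mutation
  wild <- variationParams(d = 1, pM = 1, nFrag = 2L, mutationScale = 2)
  bnd <- rbind(lo = c(0, 0), hi = c(1, 1))
  set.seed(9)
  off <- generateOffspring(matrix(runif(40), ncol = 2), wild, bounds = bnd)
  expect_true(all(off >= 0 & off <= 1))
})

test_that("Bank screening ranks survivors like an exhaustive sort oracle", {
  w <- toyWorldFixture()
  lead <- w$lead
  db <- w$smiles[1:20]
  bank <- buildBank(lead, db, w$codec, bankSize = 8L, simMin = 0, propMin = 0)
  expect_lte(length(bank@smiles), 8L)
  # oracle: rank by property desc, similarity desc, input order
  canon <- vapply(db, parseSmiles, character(1), USE.NAMES = FALSE)
  canon <- canon[!duplicated(canon)]
  props <- vapply(canon, qedScore, numeric(1), USE.NAMES = FALSE)
  sims <- vapply(canon, tanimotoSimilarity, numeric(1), lead = lead,
                 USE.NAMES = FALSE)
  ord <- order(-props, -sims, seq_along(canon))
  expect_identical(bank@smiles, canon[head(ord, 8L)])

  # screening thresholds apply before ranking
  strict <- buildBank(lead, db, w$codec, bankSize = 20L,
                      simMin = 0, propMin = 0.6)
  expect_true(all(vapply(strict@smiles, qedScore, numeric(1)) >= 0.6))

  # shortfall is recorded, not an error; a lone lead survives its own screen
  solo <- buildBank(lead, lead, w$codec, bankSize = 5L, simMin = 0.9,
                    propMin = 0)
  expect_identical(solo@smiles, lead)
  expect_equal(solo@provenance$shortfall, 4L)
  expect_error(buildBank(lead, character(0), w$codec),
               class = "emptyDatabase")
  expect_error(buildBank(lead, db, w$codec, simMin = 1.01),
               class = "noSurvivors")
})

test_that("population initialization fills to P deterministically from the Bank", {
  w <- toyWorldFixture()
  pars <- variationParams(d = 0, pM = 0.5, nFrag = 2L)
  bank <- buildBank(w$lead, w$smiles, w$codec, bankSize = 10L,
                    simMin = 0, propMin = 0)
  set.seed(21)
  pop <- initializePopulation(w$lead, bank, w$codec, P = 15L, pars)
  expect_length(pop$smiles, 15L)
  expect_equal(nrow(pop$latent), 15L)
  set.seed(21)
  pop2 <- initializePopulation(w$lead, bank, w$codec, P = 15L, pars)
  expect_identical(pop, pop2)

  # with d = 0 every pre-decode latent lies on a lead-to-member segment
  leadZ <- encodeMolecule(w$codec, w$lead)
  onSegment <- function(z) {
    any(vapply(seq_along(bank@smiles), function(i) {
      m <- bank@latent[i, ]
      seg <- m - leadZ
      t <- if (abs(seg[1]) > abs(seg[2])) (z[1] - leadZ[1]) / seg[1]
           else (z[2] - leadZ[2]) / seg[2]
      t >= -1e-9 && t <= 1 + 1e-9 &&
        sqrt(sum((leadZ + t * seg - z)^2)) < 1e-9
    }, logical(1)))
  }
  expect_true(all(apply(pop$latent, 1, onSegment)))
})
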