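# Pareto machinery, constraint dominance, preference rankings and the two
# environmental selection procedures.

test_that("Pareto dominance is strict and direction-consistent", {
  expect_true(dominates(c(2, 2), c(1, 1)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(1, 1)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), class = "dimensionMismatch")
})

test_that("non-dominated sorting matches the brute-force peeling oracle", {
  expect_equal(fastNonDominatedSort(matrix(c(1, 1), nrow = 1)), 1L)
  expect_equal(fastNonDominatedSort(rbind(c(2, 2), c(1, 1))), c(1L, 2L))
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    m <- sample(2:4, 1)
    F <- matrix(round(runif(n * m), 2), ncol = m)  # rounding makes ties
    expect_equal(fastNonDominatedSort(F), oracleFronts(F))
  }
})

test_that("crowding distance marks boundaries infinite and sums normalized gaps", {
  expect_equal(crowdingDistance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  F <- rbind(c(0, 2), c(1, 1), c(2, 0))
  expect_equal(crowdingDistance(F), c(Inf, 2, Inf))
  # with three identical interior points the middle one has both sorted
  # neighbours equal to itself, so its gaps vanish
  dupF <- rbind(c(0, 2), c(1, 1), c(1, 1), c(1, 1), c(2, 0))
  cd <- crowdingDistance(dupF)
  expect_equal(cd[3], 0)
  expect_true(all(cd[c(2, 4)] > 0))
  # a zero-range objective contributes nothing
  flat <- rbind(c(0, 5), c(1, 5), c(2, 5))
  expect_equal(crowdingDistance(flat), c(Inf, 1, Inf))
  set.seed(29)
  for (rep in 1:20) {
    F <- matrix(runif(24), ncol = 3)
    expect_equal(crowdingDistance(F), oracleCrowding(F))
  }
})

test_that("constraint dominance follows the three-clause principle", {
  # feasible always beats infeasible, whatever the objectives
  expect_true(constrainedDominates(c(0, 0), 0, c(9, 9), 0.3))
  expect_false(constrainedDominates(c(9, 9), 0.3, c(0, 0), 0))
  # among infeasible, smaller CV wins regardless of objectives
  expect_true(constrainedDominates(c(0, 0), 0.2, c(9, 9), 0.5))
  expect_false(constrainedDominates(c(9, 9), 0.5, c(0, 0), 0.2))
  # equal CV infeasible pairs are incomparable
  expect_false(constrainedDominates(c(2, 2), 0.4, c(1, 1), 0.4))
  # both feasible: plain Pareto dominance
  expect_true(constrainedDominates(c(2, 2), 0, c(1, 1), 0))
  expect_false(constrainedDominates(c(1, 2), 0, c(2, 1), 0))
})

test_that("both preference rankings are permutations; they coincide when all feasible", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    F <- matrix(runif(n * 3), ncol = 3)
    cv <- ifelse(runif(n) < 0.5, 0, rexp(n))
    s1 <- propertyPreferenceRanking(F)
    s2 <- constraintPreferenceRanking(F, cv)
    expect_setequal(s1, seq_len(n))
    expect_setequal(s2, seq_len(n))
    expect_identical(constraintPreferenceRanking(F, rep(0, n)), s1)
  }
  # a lone feasible molecule always tops the constraint ranking
  F <- matrix(runif(12), ncol = 2)
  cv <- c(0.5, 0.2, 0, 1, 0.8, 0.1)
  expect_equal(constraintPreferenceRanking(F, cv)[3], 1L)
})

test_that("ranking follows (front asc, crowding desc) with stable ties", {
  # one front-1 boundary, one front-1 interior, one front-2 point
  F <- rbind(c(0, 3), c(1, 1.8), c(2, 2), c(3, 0), c(0.5, 0.5))
  front <- fastNonDominatedSort(F)
  s1 <- propertyPreferenceRanking(F)
  expect_true(all(s1[front == 1] < min(s1[front > 1])))
  # all in one front: order is purely by crowding
  G <- rbind(c(0, 4), c(1, 3), c(2.5, 1.2), c(4, 0))
  cd <- crowdingDistance(G)
  expect_equal(order(propertyPreferenceRanking(G)),
               order(-cd, seq_len(4)))
})

test_that("the cosine schedule anchors at 1, 1/2 and 0 and never increases", {
  sched <- alphaSchedule(30L)
  expect_equal(alphaWeight(0, sched), 1.0)
  expect_equal(alphaWeight(30, sched), 0.0)
  expect_equal(alphaWeight(15, sched), 0.5)
  expect_error(alphaWeight(-1, sched), class = "badParams")
  expect_error(alphaWeight(31, sched), class = "badParams")
  for (T in c(1L, 2L, 7L, 40L)) {
    a <- vapply(0:T, alphaWeight, numeric(1), schedule = alphaSchedule(T))
    expect_true(all(diff(a) <= 1e-12))
    expect_equal(a[1], 1)
    expect_equal(a[T + 1], 0)
  }
})

test_that("comprehensive scores blend the two ranks linearly", {
  expect_equal(comprehensiveScore(3, 7, 1), 3)
  expect_equal(comprehensiveScore(3, 7, 0), 7)
  expect_equal(comprehensiveScore(3, 7, 0.5), 5.0)
  expect_error(comprehensiveScore(1, 1, 1.2), class = "badParams")
})

test_that("stage-1 selection fills front by front and truncates by crowding", {
  # N = P: identity
  F <- matrix(runif(12), ncol = 2)
  expect_equal(environmentalSelectionStage1(F, 6L), 1:6)
  # whole-front admission: two front-1 points fit exactly
  F2 <- rbind(c(2, 2.5), c(2.5, 2), c(1, 1), c(0.5, 0.5))
  expect_equal(environmentalSelectionStage1(F2, 2L), c(1L, 2L))
  expect_error(environmentalSelectionStage1(F2, 9L), class = "badParams")
  # random instances against the independently composed reference
  set.seed(41)
  for (rep in 1:30) {
    F <- matrix(round(runif(40 * 3), 2), ncol = 3)
    expect_equal(environmentalSelectionStage1(F, 20L), oracleStage1(F, 20L))
  }
})

test_that("stage-2 selection reduces to the pure rankings at the schedule ends", {
  set.seed(43)
  F <- matrix(runif(60), ncol = 3)
  cv <- ifelse(runif(20) < 0.4, 0, rexp(20))
  s1 <- propertyPreferenceRanking(F)
  s2 <- constraintPreferenceRanking(F, cv)
  T <- 10L
  # t = 0: alpha = 1, selection by property ranks
  r0 <- environmentalSelectionStage2(F, cv, 8L, 0, T)
  expect_equal(r0$alpha, 1)
  expect_setequal(r0$selected, which(s1 <= 8))
  # t = T: alpha = 0, selection by constraint ranks
  rT <- environmentalSelectionStage2(F, cv, 8L, T, T)
  expect_equal(rT$alpha, 0)
  expect_setequal(rT$selected, which(s2 <= 8))
})

test_that("a mixed-alpha selection matches exhaustive score enumeration", {
  # hand-built union of 6: three feasible on one front, three infeasible
  F <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1),
             c(2, 2), c(3, 3), c(1.5, 1.5))
  cv <- c(0, 0, 0, 0.2, 0.1, 0.4)
  T <- 2L                                 # t = 1 gives alpha = 0.5
  s1 <- propertyPreferenceRanking(F)
  s2 <- constraintPreferenceRanking(F, cv)
  score <- 0.5 * s1 + 0.5 * s2
  want <- sort(order(score, s2, seq_len(6))[1:3])
  res <- environmentalSelectionStage2(F, cv, 3L, 1, T)
  expect_equal(res$selected, want)
  expect_equal(res$score, score)
})

test_that("at alpha = 0 no infeasible molecule displaces a feasible one", {
  set.seed(47)
  for (rep in 1:20) {
    n <- 24L
    F <- matrix(runif(n * 2), ncol = 2)
    cv <- ifelse(runif(n) < 0.5, 0, rexp(n))
    P <- 12L
    sel <- environmentalSelectionStage2(F, cv, P, 10L, 10L)$selected
    if (sum(cv == 0) >= P) {
      expect_true(all(cv[sel] == 0))
    } else {
      expect_true(all(which(cv == 0) %in% sel))
    }
  }
})
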