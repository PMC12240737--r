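# Pareto machinery, the constraint dominance principle, the two preference
# rankings, the cosine-decayed comprehensive score, and the environmental
# selection procedures of the two optimization stages.
#
# All objective matrices are maximization-oriented. Tie-breaking everywhere
# is by stable input index, so both selections are deterministic functions
# of the union ordering.

#' Pareto dominance (maximization)
#'
#' @param a,b objective vectors of equal length.
#' @return `TRUE` iff `a >= b` in every objective and `a > b` in at least
#'   one.
#' @export
dominates <- function(a, b) {
  assertSameLength(a, b, "objective vectors")
  all(a >= b) && any(a > b)
}

#' Constraint dominance principle
#'
#' `a` dominates `b` iff (i) both are feasible and `a` Pareto-dominates `b`;
#' (ii) `a` is feasible and `b` is not; or (iii) both are infeasible and
#' `a` has the smaller CV degree. Infeasible molecules with equal CV are
#' incomparable.
#'
#' @param fa,fb objective vectors.
#' @param cva,cvb aggregated CV degrees (feasible iff 0).
#' @return logical.
#' @export
constrainedDominates <- function(fa, cva, fb, cvb) {
  feasA <- cva <= 0
  feasB <- cvb <= 0
  if (feasA && feasB) return(dominates(fa, fb))
  if (feasA != feasB) return(feasA)
  cva < cvb
}

# N x N logical dominance matrix under plain Pareto dominance, vectorized.
.dominanceMatrix <- function(F) {
  n <- nrow(F)
  geq <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(F))) {
    cmp <- outer(F[, j], F[, j], `-`)
    geq <- geq & (cmp >= 0)
    gt <- gt | (cmp > 0)
  }
  geq & gt
}

# Dominance matrix under the constraint dominance principle.
.cdpDominanceMatrix <- function(F, cv) {
  feas <- cv <= 0
  dom <- matrix(FALSE, nrow(F), nrow(F))
  if (any(feas))
    dom[feas, feas] <- .dominanceMatrix(F[feas, , drop = FALSE])
  dom[feas, !feas] <- TRUE
  if (any(!feas)) {
    inf <- which(!feas)
    dom[inf, inf] <- outer(cv[inf], cv[inf], `<`)
  }
  dom
}

# Front numbers by iterative peeling of a dominance matrix (Deb's
# domination counts, updated front by front).
.frontsFromDominance <- function(dom) {
  n <- nrow(dom)
  count <- colSums(dom)
  front <- integer(n)
  k <- 0L
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    k <- k + 1L
    cur <- remaining & count == 0L
    if (!any(cur)) # cycles impossible under a strict partial order
      cmomoStop("badParams", "dominance relation is not acyclic")
    front[cur] <- k
    remaining[cur] <- FALSE
    count <- count - colSums(dom[cur, , drop = FALSE])
  }
  front
}

#' Fast non-dominated sorting
#'
#' Partitions rows of an objective matrix into successive non-dominated
#' fronts: front 1 is the non-dominated set, front k the non-dominated set
#' after removing fronts < k.
#'
#' @param F N x m objective matrix (maximization orientation).
#' @return integer vector of front numbers (1-based), one per row.
#' @export
fastNonDominatedSort <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) == 0L) return(integer(0))
  .frontsFromDominance(.dominanceMatrix(F))
}

# Fronts under the constraint dominance principle.
cdpSort <- function(F, cv) {
  F <- as.matrix(F)
  .frontsFromDominance(.cdpDominanceMatrix(F, cv))
}

#' Crowding distance within one front
#'
#' Per objective, members are sorted; the boundary members receive infinite
#' distance and interior members accumulate the normalized gap between
#' their sorted neighbours. Objectives with zero range contribute nothing
#' (duplicate points therefore get 0 from every objective).
#'
#' @param F objective matrix of the members of a single front.
#' @return numeric vector of crowding distances.
#' @export
crowdingDistance <- function(F) {
  F <- as.matrix(F)
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (j in seq_len(ncol(F))) {
    ord <- order(F[, j])
    rng <- F[ord[n], j] - F[ord[1L], j]
    dist[ord[c(1L, n)]] <- Inf
    if (rng > 0)
      dist[ord[2:(n - 1L)]] <- dist[ord[2:(n - 1L)]] +
        (F[ord[3:n], j] - F[ord[1:(n - 2L)], j]) / rng
  }
  dist
}

# Crowding distances computed front-wise over a whole population.
.crowdingByFront <- function(F, front) {
  crowd <- numeric(length(front))
  for (k in unique(front)) {
    idx <- which(front == k)
    crowd[idx] <- crowdingDistance(F[idx, , drop = FALSE])
  }
  crowd
}

# Rank 1..N by (front asc, crowding desc, input index asc).
.rankFrontCrowding <- function(front, crowd) {
  ord <- order(front, -crowd, seq_along(front))
  rank <- integer(length(front))
  rank[ord] <- seq_along(front)
  rank
}

#' Property-preference ranking
#'
#' Ranks the union by Pareto front number (ascending) then crowding
#' distance (descending), ties by input index: every molecule receives a
#' unique rank in 1..N considering only property values.
#'
#' @param F N x m objective matrix of the union.
#' @return integer permutation of 1..N (rank 1 = best).
#' @export
propertyPreferenceRanking <- function(F) {
  F <- as.matrix(F)
  front <- fastNonDominatedSort(F)
  .rankFrontCrowding(front, .crowdingByFront(F, front))
}

#' Constraint-preference ranking
#'
#' Identical procedure to [propertyPreferenceRanking()] except that front
#' numbers come from non-dominated sorting under the constraint dominance
#' principle; crowding is computed on objective values within CDP fronts.
#' When every molecule is feasible this reduces exactly to the property
#' ranking.
#'
#' @param F N x m objective matrix of the union.
#' @param cv aggregated CV degrees over the same union (see
#'   [aggregateCV()]).
#' @return integer permutation of 1..N (rank 1 = best).
#' @export
constraintPreferenceRanking <- function(F, cv) {
  F <- as.matrix(F)
  assertSameLength(seq_len(nrow(F)), cv, "objective rows and CV degrees")
  front <- cdpSort(F, cv)
  .rankFrontCrowding(front, .crowdingByFront(F, front))
}

#' Cosine decay schedule for the ranking-aggregation weight
#'
#' `alpha(t) = (1 + cos(t * pi / T)) / 2`: equals 1 at `t = 0`, 0 at
#' `t = T`, decays slowly early, fastest mid-schedule, slowly again late.
#'
#' @param T total number of constrained-stage generations (>= 1).
#' @param form decay form; only `"cosine"` is implemented.
#' @return an `AlphaSchedule` list.
#' @export
alphaSchedule <- function(T, form = c("cosine")) {
  form <- match.arg(form)
  if (!is.numeric(T) || length(T) != 1L || T < 1)
    cmomoStop("badParams", "'T' must be a positive integer")
  structure(list(T = as.integer(T), form = form), class = "AlphaSchedule")
}

#' Ranking-aggregation weight at generation t
#'
#' @param t generation index within the constrained stage, `0 <= t <= T`.
#' @param schedule an [alphaSchedule()] (or a plain integer T).
#' @return alpha in \[0, 1\].
#' @export
alphaWeight <- function(t, schedule) {
  if (!inherits(schedule, "AlphaSchedule")) schedule <- alphaSchedule(schedule)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > schedule$T)
    cmomoStop("badParams", sprintf("'t' must lie in [0, %d]", schedule$T))
  0.5 * (1 + cos(t * pi / schedule$T))
}

#' Comprehensive score
#'
#' `alpha * s1 + (1 - alpha) * s2`; lower is better. At `alpha = 1` the
#' score is the property-preference rank, at `alpha = 0` the
#' constraint-preference rank.
#'
#' @param s1,s2 property- and constraint-preference ranks (>= 1).
#' @param alpha aggregation weight in \[0, 1\].
#' @return numeric scores.
#' @export
comprehensiveScore <- function(s1, s2, alpha) {
  if (alpha < 0 || alpha > 1)
    cmomoStop("badParams", "'alpha' must lie in [0, 1]")
  alpha * s1 + (1 - alpha) * s2
}

#' Environmental selection, unconstrained stage (NSGA-II)
#'
#' Admits whole fronts while the cumulative count stays within P, then
#' truncates the boundary front by repeatedly removing its
#' smallest-crowding member (ties: the later input index is removed first).
#' Constraint information is never consulted.
#'
#' @param F N x m objective matrix of the union (N >= P).
#' @param P number of survivors.
#' @return integer indices of the selected rows, in input order.
#' @export
environmentalSelectionStage1 <- function(F, P) {
  F <- as.matrix(F)
  N <- nrow(F)
  if (N < P) cmomoStop("badParams", "union smaller than P")
  if (N == P) return(seq_len(N))
  front <- fastNonDominatedSort(F)
  crowd <- .crowdingByFront(F, front)
  selected <- integer(0)
  for (k in sort(unique(front))) {
    idx <- which(front == k)
    if (length(selected) + length(idx) <= P) {
      selected <- c(selected, idx)
      if (length(selected) == P) break
    } else {
      room <- P - length(selected)
      # remove the smallest-crowding members; on ties drop later index first,
      # i.e. keep by (crowding desc, index asc)
      keep <- idx[order(-crowd[idx], idx)][seq_len(room)]
      selected <- c(selected, keep)
      break
    }
  }
  sort(selected)
}

#' Environmental selection, constrained stage (ranking aggregation)
#'
#' Computes the property-preference and constraint-preference ranks on the
#' union, aggregates them with the cosine-decayed weight `alpha(t)`, and
#' keeps the P smallest comprehensive scores (ties: smaller
#' constraint-preference rank, then input index).
#'
#' @param F N x m objective matrix of the union (N >= P).
#' @param cv aggregated CV degrees over the union.
#' @param P number of survivors.
#' @param t generation index within the constrained stage.
#' @param schedule an [alphaSchedule()] (or plain integer T).
#' @return list with `selected` (indices in input order), `s1`, `s2`,
#'   `score`, `alpha`, and `front`/`crowding` from the property ranking.
#' @export
environmentalSelectionStage2 <- function(F, cv, P, t, schedule) {
  F <- as.matrix(F)
  N <- nrow(F)
  if (N < P) cmomoStop("badParams", "union smaller than P")
  front <- fastNonDominatedSort(F)
  crowd <- .crowdingByFront(F, front)
  s1 <- .rankFrontCrowding(front, crowd)
  s2 <- constraintPreferenceRanking(F, cv)
  alpha <- alphaWeight(t, schedule)
  score <- comprehensiveScore(s1, s2, alpha)
  selected <- sort(order(score, s2, seq_len(N))[seq_len(P)])
  list(selected = selected, s1 = s1, s2 = s2, score = score, alpha = alpha,
       front = front, crowding = crowd)
}
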