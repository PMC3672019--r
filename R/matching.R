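#' Matchings extracted from a similarity matrix
#'
#' All matchers return a `net_matching`: a tibble with one row per matched
#' pair and columns `i`, `j` (1-based row/column indices into the score
#' matrix), `node_a`, `node_b` (labels, taken from the matrix dimnames when
#' present) and `score` (the original, unscaled score of the pair).
#' Attributes record the total `weight` (sum of member scores), the
#' `method` and its parameters. A matching is injective in both
#' coordinates: no two pairs share a row or a column.
#'
#' @name net_matching
#' @keywords internal
NULL

new_matching <- function(ij, X, method, params = list(), extra = list()) {
  ij <- matrix(as.integer(ij), ncol = 2)
  rn <- rownames(X) %||% as.character(seq_len(nrow(X)))
  cn <- colnames(X) %||% as.character(seq_len(ncol(X)))
  score <- if (nrow(ij)) X[ij] else numeric()
  out <- tibble::tibble(i = ij[, 1], j = ij[, 2],
                        node_a = rn[ij[, 1]], node_b = cn[ij[, 2]],
                        score = as.numeric(score))
  out <- dplyr::arrange(out, .data$i)
  attr(out, "weight") <- sum(out$score)
  attr(out, "method") <- method
  attr(out, "params") <- params
  attr(out, "problem_dim") <- dim(X)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("net_matching", class(tibble::tibble()))
  out
}

#' Total weight of a matching
#' @param matching a `net_matching`.
#' @return sum of the matched pairs' scores.
#' @export
matching_weight <- function(matching) attr(matching, "weight")

#' Matrix-based greedy half-approximation matching
#'
#' Repeatedly selects the largest entry of a working copy of the score
#' matrix, records its (row, column) pair, and zeroes that row and column,
#' until no strictly positive entry remains. Only positive entries produce
#' pairs. Ties are broken to the smallest row index, then the smallest
#' column index. The result is a maximal matching whose weight is at least
#' half the maximum-weight matching's.
#'
#' @param X non-negative finite numeric score matrix (e.g. an
#'   [isorank_iterate()] result).
#' @return a `net_matching` (see [matching_weight()]).
#' @export
#' @examples
#' greedy_match(matrix(c(1, 0.9, 0.9, 0), 2, 2, byrow = TRUE))
greedy_match <- function(X) {
  W <- as_score_matrix(X)
  ij <- matrix(0L, min(dim(W)), 2)
  k <- 0L
  while (TRUE) {
    m <- max(W)
    if (m <= 0) break
    hits <- which(W == m, arr.ind = TRUE, useNames = FALSE)
    best <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
    k <- k + 1L
    ij[k, ] <- best
    W[best[1], ] <- 0
    W[, best[2]] <- 0
  }
  new_matching(ij[seq_len(k), , drop = FALSE], X, "greedy")
}

#' Auction matching with a fixed bidding increment
#'
#' Treats rows as buyers and columns as objects with prices starting at
#' zero. Scores are integerized as `round(score * scale)`. Each unassigned
#' buyer with a positive-profit object bids `u - v + epsilon` on its most
#' profitable object, where `u` is its best profit `max_j (w_ij - p_j)` and
#' `v` the second-best; the object moves to the bidder and its price rises
#' by the bid. Rounds repeat until every buyer that still has a
#' positive-profit object is assigned. For integer scaled weights and
#' `epsilon < 1/min(dim)` the assignment attains the maximum matching
#' weight of the scaled problem.
#'
#' @param X non-negative finite score matrix.
#' @param epsilon bidding increment on the scaled problem (> 0); default
#'   `1 / (min(dim(X)) + 1)`, inside the exactness regime.
#' @param scale integerization factor applied before bidding (default
#'   `1e6`); reported scores are the original, unscaled values.
#' @return a `net_matching` with attributes `prices` (final object prices)
#'   and `price_monotone` (TRUE when no price ever decreased).
#' @export
auction_match <- function(X, epsilon = NULL, scale = 1e6) {
  W <- as_score_matrix(X)
  if (is.null(epsilon)) epsilon <- 1 / (min(dim(W)) + 1)
  stopifnot(epsilon > 0, scale >= 1)
  res <- run_auction(round(W * scale), epsilon,
                     growth = NULL, delta = NULL)
  new_matching(res$ij, X, "auction",
               params = list(epsilon = epsilon, scale = scale),
               extra = list(prices = res$prices,
                            price_monotone = res$monotone))
}

#' Adaptive epsilon-scaling auction matching with greedy completion
#'
#' Runs the auction of [auction_match()] but starts from a small bidding
#' increment and grows it whenever an inner bidding round assigns fewer
#' than `delta` new buyers, trading optimality for speed while prices (and
#' hence the partial solution) are retained across increment phases. After
#' the auction terminates, [complete_matching()] pairs any remaining
#' unmatched buyers with unmatched objects so the result has maximum
#' cardinality `min(dim(X))`.
#'
#' @inheritParams auction_match
#' @param epsilon0 initial increment on the scaled problem; default
#'   `1 / (min(dim(X)) + 1)`.
#' @param growth multiplier (> 1) applied to the increment after a slow
#'   round (default 4).
#' @param delta minimum number of assignments per inner round before the
#'   increment is escalated; default `max(1, ceiling(0.01 * min(dim(X))))`.
#' @return a `net_matching`; cardinality is always `min(dim(X))`.
#' @export
adaptive_auction_match <- function(X, epsilon0 = NULL, growth = 4,
                                   delta = NULL, scale = 1e6) {
  W <- as_score_matrix(X)
  n <- min(dim(W))
  if (is.null(epsilon0)) epsilon0 <- 1 / (n + 1)
  if (is.null(delta)) delta <- max(1L, ceiling(0.01 * n))
  stopifnot(epsilon0 > 0, growth > 1, delta >= 1)
  res <- run_auction(round(W * scale), epsilon0, growth = growth,
                     delta = delta)
  partial <- new_matching(res$ij, X, "adaptive-auction",
                          params = list(epsilon0 = epsilon0, growth = growth,
                                        delta = delta, scale = scale),
                          extra = list(prices = res$prices,
                                       price_monotone = res$monotone))
  complete_matching(partial, X)
}

# Gauss-Seidel auction on an integer-weight matrix. Buyers are rows if
# nrow <= ncol, otherwise the problem is transposed and results mapped
# back. Returns assignment pairs (in the original orientation), final
# prices, and a monotonicity flag for the price updates.
run_auction <- function(W, eps, growth = NULL, delta = NULL) {
  flipped <- nrow(W) > ncol(W)
  if (flipped) W <- t(W)
  nb <- nrow(W)
  no <- ncol(W)
  p <- numeric(no)
  assigned <- integer(nb)   # object owned by buyer i, 0 = none
  owner <- integer(no)      # buyer owning object j, 0 = none
  monotone <- TRUE
  repeat {
    newly <- 0L
    progressed <- FALSE
    for (b in which(assigned == 0L)) {
      profit <- W[b, ] - p
      u <- max(profit)
      if (u <= 0) next
      ji <- which.max(profit)
      v <- if (no > 1L) max(profit[-ji]) else 0
      bid <- u - v + eps
      if (bid < 0) monotone <- FALSE
      p[ji] <- p[ji] + bid
      prev <- owner[ji]
      if (prev > 0L) assigned[prev] <- 0L else newly <- newly + 1L
      owner[ji] <- b
      assigned[b] <- ji
      progressed <- TRUE
    }
    if (!progressed) break
    # net progress of the round: objects that went from unowned to owned
    if (!is.null(growth) && newly < delta) eps <- eps * growth
  }
  ij <- cbind(which(assigned > 0L), assigned[assigned > 0L])
  if (flipped) ij <- ij[, 2:1, drop = FALSE]
  list(ij = ij, prices = p, monotone = monotone)
}

#' Complete a partial matching to maximum cardinality
#'
#' Pairs every unmatched row index, in ascending order, with the first
#' still-unmatched column index. The added pairs contribute their (possibly
#' zero) scores, so the weight never decreases and the output cardinality
#' is `min(dim(X))`. Used after the adaptive auction, whose bidding phase
#' leaves zero-profit buyers unassigned.
#'
#' @param partial a `net_matching` on `X`'s index sets.
#' @param X the score matrix the matching refers to.
#' @return a `net_matching` of cardinality `min(dim(X))`.
#' @export
complete_matching <- function(partial, X) {
  stopifnot(inherits(partial, "net_matching"))
  W <- as_score_matrix(X)
  free_i <- setdiff(seq_len(nrow(W)), partial$i)
  free_j <- setdiff(seq_len(ncol(W)), partial$j)
  k <- min(length(free_i), length(free_j))
  add <- cbind(free_i[seq_len(k)], free_j[seq_len(k)])
  new_matching(rbind(cbind(partial$i, partial$j), add), X,
               attr(partial, "method"), params = attr(partial, "params"),
               extra = list(prices = attr(partial, "prices"),
                            price_monotone = attr(partial, "price_monotone"),
                            completed = TRUE))
}

#' Exact maximum-weight matching by exhaustive enumeration
#'
#' Enumerates every maximum-cardinality injection between rows and columns
#' and returns one of maximum total weight (first in lexicographic order of
#' the assignment on ties). Intended as a reference for validating the
#' heuristic matchers; guarded to small problems.
#'
#' @param X finite numeric score matrix with `min(dim(X)) <= 9`.
#' @return a `net_matching` with `method = "brute-force"`.
#' @export
brute_force_optimal <- function(X) {
  W <- as_score_matrix(X, allow_negative = TRUE)
  flipped <- nrow(W) > ncol(W)
  if (flipped) W <- t(W)
  m <- nrow(W)
  n <- ncol(W)
  if (m > 9) stop("brute_force_optimal is limited to min(dim(X)) <= 9")
  if (choose(n, m) * factorial(m) > 2e6) {
    stop("brute_force_optimal: too many injections to enumerate")
  }
  perms <- permutations_of(m)
  subsets <- utils::combn(n, m)
  best_w <- -Inf
  best <- NULL
  rows <- seq_len(m)
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    assign_cols <- matrix(cols[perms], nrow(perms), m)
    w <- rowSums(matrix(W[cbind(rep(rows, each = nrow(perms)),
                                as.vector(assign_cols))],
                        nrow(perms), m))
    idx <- which(w > best_w)
    if (length(idx)) {
      # among strict improvements, keep the lexicographically smallest
      # assignment of the best weight (deterministic tie-break)
      top <- idx[w[idx] == max(w[idx])]
      lex <- assign_cols[top, , drop = FALSE]
      pick <- top[do.call(order, as.data.frame(lex))[1]]
      best_w <- w[pick]
      best <- assign_cols[pick, ]
    }
  }
  ij <- cbind(rows, best)
  if (flipped) ij <- ij[, 2:1, drop = FALSE]
  new_matching(ij, X, "brute-force")
}

# all permutations of 1..m, rows in lexicographic order
permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(m - 1L)
  out <- matrix(0L, factorial(m), m)
  r <- nrow(sub)
  for (k in seq_len(m)) {
    rest <- setdiff(seq_len(m), k)
    out[((k - 1L) * r + 1L):(k * r), ] <-
      cbind(k, matrix(rest[sub], r, m - 1L))
  }
  out
}

as_score_matrix <- function(X, allow_negative = FALSE) {
  W <- unclass(X)
  attributes(W) <- attributes(W)[c("dim", "dimnames")]
  if (!is.numeric(W) || !is.matrix(W)) stop("X must be a numeric matrix")
  if (any(!is.finite(W))) stop("X must be finite")
  if (!allow_negative && any(W < 0)) stop("X must be non-negative")
  W
}

`%||%` <- function(a, b) if (is.null(a)) b else a
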