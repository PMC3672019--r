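#' Column-stochastic normalization of a network's adjacency matrix
#'
#' For a symmetric adjacency matrix A this divides each column by the degree
#' of its node, so that column sums are 1 for connected nodes and 0 for
#' isolated ones. The result is the transition operator used by the
#' diffusion iteration of [isorank_iterate()].
#'
#' @param net a [as_ppi_net()] object.
#' @return a sparse matrix with entries in `[0, 1]` and column sums in
#'   `{0, 1}`.
#' @export
#' @examples
#' net <- as_ppi_net(data.frame(a = "u", b = "v"))
#' as.matrix(normalize_adjacency(net))
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "ppi_net"))
  deg <- Matrix::colSums(net$adj)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  # column scaling: A %*% diag(1/deg); equals a_ji / sum_i a_ji for symmetric A
  out <- net$adj %*% Matrix::Diagonal(net$n, inv)
  dimnames(out) <- dimnames(net$adj)
  out
}

#' Diffusion-based node-pair similarity between two networks
#'
#' Iterates the blended similarity update
#' \deqn{X \gets \alpha\, \tilde A X \tilde B^\top + (1-\alpha) H,}
#' where `X[i, j]` scores the similarity of node i of `netA` to node j of
#' `netB`, the tilde matrices are the column-stochastic operators of
#' [normalize_adjacency()], and H holds the elemental (e.g. sequence)
#' similarities. Topological similarity diffuses through neighbourhoods —
#' two nodes score high when their neighbours score high — and is blended
#' with the elemental prior by weight `alpha`. H is normalized to unit
#' 1-norm once at setup, X is initialized to that normalized H, and after
#' every iteration `vec(X)` is renormalized to unit 1-norm, so entries stay
#' interpretable as a probability distribution over node pairs.
#'
#' @param netA,netB the two networks (`ppi_net`).
#' @param H non-negative elemental similarity matrix, `netA$n` rows by
#'   `netB$n` columns, with at least one positive entry.
#' @param alpha blending weight in `[0, 1]`: weight of topological
#'   similarity versus the elemental prior (default 0.8).
#' @param iterations fixed number of iterations (default 20).
#' @param early_stop_tol optional 1-norm tolerance on successive iterates;
#'   `NULL` (default) disables early stopping.
#' @return a dense `netA$n` by `netB$n` matrix of class `isorank_sim` with
#'   attributes `alpha`, `iterations` (iterations actually performed) and
#'   `iteration_mass` (the total score mass recorded after each completed
#'   iteration). Entries are non-negative and sum to 1.
#' @export
isorank_iterate <- function(netA, netB, H, alpha = 0.8, iterations = 20,
                            early_stop_tol = NULL) {
  stopifnot(inherits(netA, "ppi_net"), inherits(netB, "ppi_net"))
  check_iteration_args(netA, netB, H, alpha, iterations)
  At <- normalize_adjacency(netA)
  Bt <- normalize_adjacency(netB)
  Hn <- H / sum(abs(H))
  X <- Hn
  done <- 0L
  mass <- numeric(iterations)
  for (it in seq_len(iterations)) {
    Xnew <- alpha * as.matrix(At %*% X %*% Matrix::t(Bt)) + (1 - alpha) * Hn
    s <- sum(abs(Xnew))
    # alpha = 1 with isolated nodes can absorb all mass; keep the previous
    # (normalized) iterate instead of dividing by zero
    if (s == 0) Xnew <- X else Xnew <- Xnew / s
    delta <- sum(abs(Xnew - X))
    X <- Xnew
    mass[it] <- sum(X)
    done <- it
    if (!is.null(early_stop_tol) && delta < early_stop_tol) break
  }
  if (anyNA(X) || any(X < 0)) {
    stop("internal error: diffusion produced NaN or negative scores")
  }
  out <- new_isorank_sim(X, netA, netB, alpha, done)
  attr(out, "iteration_mass") <- mass[seq_len(done)]
  out
}

#' Kronecker-operator reference computation of the similarity matrix
#'
#' Runs the same diffusion as [isorank_iterate()] but on the stacked vector
#' `x = vec(X)` with the explicit Kronecker operator, using the identity
#' `vec(A X B) = (B' \%x\% A) vec(X)`:
#' \deqn{x \gets \alpha (\tilde B \otimes \tilde A)\, x + (1-\alpha) h.}
#' Builds the full `(nA*nB) x (nA*nB)` operator, so it is restricted to
#' small verification problems; use [isorank_iterate()] for real inputs.
#'
#' @inheritParams isorank_iterate
#' @return same as [isorank_iterate()]; the two agree entrywise to
#'   round-off.
#' @export
kronecker_oracle <- function(netA, netB, H, alpha = 0.8, iterations = 20) {
  stopifnot(inherits(netA, "ppi_net"), inherits(netB, "ppi_net"))
  check_iteration_args(netA, netB, H, alpha, iterations)
  if (netA$n * netB$n > 1e4) {
    stop("problem too large for the explicit Kronecker operator; ",
         "use isorank_iterate()")
  }
  At <- as.matrix(normalize_adjacency(netA))
  Bt <- as.matrix(normalize_adjacency(netB))
  K <- kronecker(Bt, At)
  h <- as.vector(H) / sum(abs(H))
  x <- h
  for (it in seq_len(iterations)) {
    xnew <- as.vector(alpha * (K %*% x) + (1 - alpha) * h)
    s <- sum(abs(xnew))
    x <- if (s == 0) x else xnew / s
  }
  X <- matrix(x, netA$n, netB$n, dimnames = list(netA$nodes, netB$nodes))
  new_isorank_sim(X, netA, netB, alpha, iterations)
}

new_isorank_sim <- function(X, netA, netB, alpha, iterations) {
  dimnames(X) <- list(netA$nodes, netB$nodes)
  structure(X, class = c("isorank_sim", "matrix", "array"),
            alpha = alpha, iterations = iterations,
            net_a = netA$name, net_b = netB$name)
}

#' @export
print.isorank_sim <- function(x, ...) {
  cat(sprintf("<isorank_sim>  %d x %d node pairs (%s vs %s), alpha=%g, %d iterations\n",
              nrow(x), ncol(x), attr(x, "net_a"), attr(x, "net_b"),
              attr(x, "alpha"), attr(x, "iterations")))
  invisible(x)
}

check_iteration_args <- function(netA, netB, H, alpha, iterations) {
  if (!is.matrix(H) || nrow(H) != netA$n || ncol(H) != netB$n) {
    stop(sprintf("H must be a %d x %d matrix matching the two networks",
                 netA$n, netB$n))
  }
  if (any(H < 0) || anyNA(H)) stop("H must be non-negative and finite")
  if (all(H == 0)) stop("H must have at least one positive entry")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  if (iterations < 1) stop("iterations must be >= 1")
  invisible(TRUE)
}
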