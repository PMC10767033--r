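#' Fit a factorization machine by alternating least squares
#'
#' Second-order FM on binary inputs,
#' \eqn{\hat y(x) = w_0 + \sum_i w_i x_i + \sum_{i<j}\langle v_i,v_j\rangle x_i x_j},
#' fitted to minimize the L2-penalized squared error
#' \eqn{\sum_n (\hat y(x_n) - y_n)^2 + \lambda\|\theta\|^2}.  Every
#' parameter is linear in the model given the others, so coordinate
#' updates have closed form (alternating least squares); the fit is
#' deterministic given \code{seed}, which controls only the
#' initialization of the factor matrix.
#'
#' @param X n x d binary (0/1) matrix of inputs.
#' @param y numeric length-n regression targets (finite).
#' @param rank number of factor dimensions r.
#' @param lambda L2 penalty (applied to w and V; the bias is
#'   unpenalized).
#' @param seed seed for the factor initialization.
#' @param sweeps maximum full coordinate sweeps.
#' @param tol stop early once the largest parameter change in a sweep
#'   falls below this.
#' @return a \linkS4class{FactorizationMachine}.
#' @export
fitFactorizationMachine <- function(X, y, rank = 8L, lambda = 1e-3,
                                    seed = 1L, sweeps = 400L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (!n) stop("no training rows")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (!all(is.finite(y))) stop("targets must be finite")
  if (!all(X %in% c(0, 1))) stop("X must be binary 0/1")
  rank <- as.integer(rank)
  w0 <- mean(y)
  w <- numeric(d)
  ## moderate init scale: near-zero factor inits sit at a saddle of
  ## the alternating updates, very large ones in poor local optima
  V <- .withSeed(seed, matrix(rnorm(d * rank, sd = 0.1), d, rank))
  S <- X %*% V                       # n x r cache of factor sums
  e <- .fmPredictRaw(X, w0, w, V, S) - y
  for (sw in seq_len(sweeps)) {
    change <- 0
    ## bias
    new0 <- w0 - sum(e) / n
    change <- max(change, abs(new0 - w0))
    e <- e + (new0 - w0); w0 <- new0
    ## linear weights
    for (i in seq_len(d)) {
      h <- X[, i]
      hh <- sum(h)
      if (hh == 0) next
      wi <- (w[i] * hh - sum(h * e)) / (hh + lambda)
      change <- max(change, abs(wi - w[i]))
      e <- e + (wi - w[i]) * h
      w[i] <- wi
    }
    ## factors
    for (f in seq_len(rank)) {
      for (i in seq_len(d)) {
        h <- X[, i] * (S[, f] - X[, i] * V[i, f])
        hh <- sum(h * h)
        if (hh + lambda == 0) next
        vif <- (V[i, f] * hh - sum(h * e)) / (hh + lambda)
        delta <- vif - V[i, f]
        if (delta != 0) {
          change <- max(change, abs(delta))
          e <- e + delta * h
          S[, f] <- S[, f] + delta * X[, i]
          V[i, f] <- vif
        }
      }
    }
    if (change < tol) break
  }
  new("FactorizationMachine", w0 = w0, w = w, V = V)
}

.fmPredictRaw <- function(X, w0, w, V, S = X %*% V) {
  w0 + drop(X %*% w) + 0.5 * rowSums(S^2 - (X %*% V^2))
}

#' @describeIn fitFactorizationMachine predict FM values for binary
#'   input rows.
#' @param object a \linkS4class{FactorizationMachine}.
#' @param newdata n x d binary matrix (or a single vector).
#' @export
setMethod("predict", "FactorizationMachine", function(object, newdata) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(X) != length(object@w))
    stop("input dimension ", ncol(X), " != model dimension ",
         length(object@w))
  .fmPredictRaw(X, object@w0, object@w, object@V)
})

#' Compile a factorization machine into a QUBO
#'
#' The FM prediction is itself a quadratic pseudo-Boolean function, so
#' it maps exactly onto a QUBO.  Annealers minimize energy while the
#' surrogate is maximized, so the sign is flipped once here:
#' \code{Q[i,i] = -w[i]}, \code{Q[i,j] = -<v_i, v_j>} for i < j, offset
#' \code{-w0}.  Minimizing the QUBO energy is then identical to
#' maximizing the FM prediction, and \code{energy(x) == -prediction(x)}
#' for every binary x.
#'
#' @param fm a \linkS4class{FactorizationMachine}.
#' @return a \linkS4class{QUBOModel}.
#' @export
fmToQubo <- function(fm) {
  stopifnot(is(fm, "FactorizationMachine"))
  d <- length(fm@w)
  G <- tcrossprod(fm@V)              # <v_i, v_j>
  Q <- -G
  Q[lower.tri(Q, diag = TRUE)] <- 0
  diag(Q) <- -fm@w
  new("QUBOModel", Q = Q, offset = -fm@w0)
}

#' QUBO energy of binary vectors
#'
#' @param qubo a \linkS4class{QUBOModel}.
#' @param x binary vector or n x d matrix of rows.
#' @return numeric vector of energies \eqn{x^T Q x + offset}.
#' @export
quboEnergy <- function(qubo, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != nrow(qubo@Q))
    stop("input dimension mismatch with QUBO")
  rowSums((X %*% qubo@Q) * X) + qubo@offset
}

#' Sample low-energy states of a QUBO by simulated annealing
#'
#' Single-flip Metropolis dynamics with a geometric cooling schedule,
#' restarted \code{nSamples} times from independent random states; each
#' restart contributes the best state it visited.  Results are sorted
#' by ascending energy (duplicates allowed) and are deterministic given
#' \code{seed}.  Simulated annealing is the sampler backend here; the
#' QUBO interface is sampler-agnostic, so a hardware annealer could be
#' substituted.
#'
#' @param qubo a \linkS4class{QUBOModel}.
#' @param nSamples number of restarts / returned states.
#' @param sweeps full single-flip sweeps per restart.
#' @param seed RNG seed.
#' @return list with \code{states} (nSamples x d 0/1 matrix, ascending
#'   energy) and \code{energies}.
#' @export
annealSample <- function(qubo, nSamples = 50L, sweeps = 1000L, seed = 1L) {
  stopifnot(is(qubo, "QUBOModel"))
  d <- nrow(qubo@Q)
  if (d < 1L) stop("QUBO must have at least one variable")
  S <- qubo@Q + t(qubo@Q)
  diag(S) <- 0
  dg <- diag(qubo@Q)
  scale <- max(abs(c(dg, S)), 1e-9)
  res <- .withSeed(seed,
    anneal_qubo_cpp(S, dg, as.integer(nSamples), as.integer(sweeps),
                    10 * scale, 0.01 * scale))
  ord <- order(res$energies)
  list(states = res$states[ord, , drop = FALSE],
       energies = res$energies[ord] + qubo@offset)
}
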