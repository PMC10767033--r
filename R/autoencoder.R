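#' Training configuration for the binary autoencoder
#'
#' @param epochs full-batch Adam steps over the training set.
#' @param learning_rate Adam step size.
#' @param seed seed for weight initialization.
#' @param l2 L2 weight penalty.
#' @return named list.
#' @export
autoencoderConfig <- function(epochs = 1500L, learning_rate = 0.02,
                              seed = 1L, l2 = 1e-5) {
  stopifnot(epochs >= 1L, learning_rate > 0)
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       seed = as.integer(seed), l2 = l2)
}

#' Train a binary-latent autoencoder over fixed-length sequences
#'
#' One affine encoder layer maps the one-hot sequence to d latent
#' logits; the latent code is the hard threshold (logit > 0) and the
#' decoder maps the bits back to per-position residue logits with a
#' softmax cross-entropy loss.  Training uses the straight-through
#' estimator: the forward pass uses the same hard bits that generation
#' uses, gradients flow through the sigmoid slope.  Encoding and
#' decoding are therefore deterministic functions, which the QUBO
#' search relies on.
#'
#' @param sequences training sequences (uniform length, >= 50
#'   recommended).
#' @param latentDim number of latent bits d.
#' @param config an \code{\link{autoencoderConfig}}.
#' @param alphabet residue alphabet; its order is the argmax tie-break
#'   order at decode time.
#' @return a \linkS4class{BinaryAutoencoder}.
#' @export
trainBinaryAutoencoder <- function(sequences, latentDim = 16L,
                                   config = autoencoderConfig(),
                                   alphabet = aminoAcids()) {
  m <- .seqMatrix(sequences, alphabet)
  L <- ncol(m); A <- length(alphabet)
  X <- .oneHot(sequences, alphabet)
  n <- nrow(X); D <- L * A; d <- as.integer(latentDim)
  par <- .withSeed(config$seed, list(
    Wenc = matrix(rnorm(d * D, sd = 0.1), d, D), benc = numeric(d),
    Wdec = matrix(rnorm(D * d, sd = 0.1), D, d), bdec = numeric(D)))
  mom <- lapply(par, function(x) x * 0)
  vel <- lapply(par, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (step in seq_len(config$epochs)) {
    Z <- X %*% t(par$Wenc) + rep(par$benc, each = n)   # n x d logits
    Sg <- .sigmoid(Z)
    Hh <- (Z > 0) * 1                                  # hard bits
    Logit <- Hh %*% t(par$Wdec) + rep(par$bdec, each = n)  # n x LA
    ## per-position softmax
    P <- matrix(0, n, D)
    for (p in seq_len(L)) {
      cols <- (p - 1L) * A + seq_len(A)
      E <- exp(Logit[, cols] - apply(Logit[, cols], 1L, max))
      P[, cols] <- E / rowSums(E)
    }
    dLogit <- (P - X) / n
    g <- list(
      Wdec = t(dLogit) %*% Hh + config$l2 * par$Wdec,
      bdec = colSums(dLogit),
      Wenc = NULL, benc = NULL)
    dH <- dLogit %*% par$Wdec
    dZ <- dH * Sg * (1 - Sg)                           # straight-through
    g$Wenc <- t(dZ) %*% X + config$l2 * par$Wenc
    g$benc <- colSums(dZ)
    for (nm in names(par)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
      par[[nm]] <- par[[nm]] - config$learning_rate *
        (mom[[nm]] / (1 - b1^step)) /
        (sqrt(vel[[nm]] / (1 - b2^step)) + eps)
    }
  }
  new("BinaryAutoencoder",
      Wenc = par$Wenc, benc = par$benc,
      Wdec = par$Wdec, bdec = par$bdec,
      alphabet = alphabet, seqLength = as.integer(L),
      latentDim = d, config = config)
}

#' Encode sequences to binary latent vectors
#'
#' Deterministic: latent bit i is 1 iff encoder logit i is positive.
#'
#' @param ae a \linkS4class{BinaryAutoencoder}.
#' @param sequences character vector (matching length/alphabet).
#' @return n x d 0/1 matrix.
#' @export
encodeSequences <- function(ae, sequences) {
  X <- .oneHot(sequences, ae@alphabet, ae@seqLength)
  Z <- X %*% t(ae@Wenc) + rep(ae@benc, each = nrow(X))
  (Z > 0) * 1
}

#' Decode binary latent vectors to sequences
#'
#' Deterministic: per position, the residue with the highest decoder
#' logit; ties broken by alphabet order (first residue wins).
#'
#' @param ae a \linkS4class{BinaryAutoencoder}.
#' @param latent 0/1 matrix (rows = codes) or single vector.
#' @return character vector of sequences.
#' @export
decodeLatent <- function(ae, latent) {
  H <- if (is.matrix(latent)) latent else matrix(latent, nrow = 1L)
  if (ncol(H) != ae@latentDim)
    stop("latent dimension ", ncol(H), " != autoencoder latent size ",
         ae@latentDim)
  Logit <- H %*% t(ae@Wdec) + rep(ae@bdec, each = nrow(H))
  A <- length(ae@alphabet)
  out <- character(nrow(H))
  for (i in seq_len(nrow(H))) {
    res <- vapply(seq_len(ae@seqLength), function(p) {
      cols <- (p - 1L) * A + seq_len(A)
      ae@alphabet[which.max(Logit[i, cols])]
    }, character(1))
    out[i] <- paste0(res, collapse = "")
  }
  out
}

#' Round-trip identity rate of an autoencoder
#'
#' Fraction of sequences reproduced exactly by decode(encode(.)).
#'
#' @param ae a \linkS4class{BinaryAutoencoder}.
#' @param sequences character vector.
#' @return scalar in [0,1].
#' @export
reconstructionRate <- function(ae, sequences) {
  mean(decodeLatent(ae, encodeSequences(ae, sequences)) == sequences)
}
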