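#' Configuration for a sequence-activity predictor
#'
#' Defaults follow the reference protocol for this assay: a recurrent
#' model with one hidden layer of size 10, trained for 25 epochs at
#' learning rate 0.001 on one-hot encoded sequences.  The
#' \code{"logistic"} architecture is a ridge-penalized logistic
#' regression on the same one-hot features, fitted by iteratively
#' reweighted least squares capped at \code{epochs} iterations; it is
#' deterministic without minibatching and is the fast default for
#' testing and desk-scale runs.  \code{learning_rate} and
#' \code{batch_size} apply to the gradient-trained \code{"birnn"}
#' architecture.
#'
#' @param hidden_size hidden vector size of the recurrent model.
#' @param epochs training epochs (IRLS iteration cap for "logistic").
#' @param learning_rate Adam step size for "birnn".
#' @param architecture "logistic" or "birnn".
#' @param seed seed for weight initialization and batch order.
#' @param l2 L2 penalty (ridge) strength.
#' @param batch_size minibatch size for "birnn".
#' @return named list of class settings.
#' @export
predictorConfig <- function(hidden_size = 10L, epochs = 25L,
                            learning_rate = 0.001,
                            architecture = c("logistic", "birnn"),
                            seed = 1L, l2 = 1e-4, batch_size = 32L) {
  architecture <- match.arg(architecture)
  stopifnot(hidden_size >= 1L, epochs >= 1L, learning_rate > 0)
  list(hidden_size = as.integer(hidden_size),
       epochs = as.integer(epochs),
       learning_rate = learning_rate,
       architecture = architecture,
       seed = as.integer(seed),
       l2 = l2,
       batch_size = as.integer(batch_size))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- logistic architecture (ridge IRLS) -----------------------------------

.trainLogistic <- function(X, y, config) {
  n <- nrow(X)
  Xa <- cbind(1, X)
  d <- ncol(Xa)
  beta <- numeric(d)
  lambda <- config$l2
  pen <- diag(rep(lambda, d)); pen[1, 1] <- 0  # don't penalize intercept
  for (it in seq_len(config$epochs)) {
    eta <- drop(Xa %*% beta)
    p <- .sigmoid(eta)
    wgt <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / wgt
    XtW <- t(Xa * wgt)
    beta_new <- tryCatch(
      drop(solve(XtW %*% Xa + pen, XtW %*% z)),
      error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(beta = beta)
}

.predictLogistic <- function(params, X) {
  .sigmoid(drop(cbind(1, X) %*% params$beta))
}

## ---- bidirectional recurrent architecture ---------------------------------

## one hidden layer per direction (Elman cells, tanh), final forward and
## initial backward hidden states concatenated into a sigmoid readout.
## Trained by minibatch Adam with analytic backprop through time.

.birnnInit <- function(A, H, seed) {
  .withSeed(seed, {
    s <- function(r, c, scale) matrix(rnorm(r * c, sd = scale), r, c)
    list(Wf = s(H, A, 0.3), Uf = s(H, H, 0.3), bf = numeric(H),
         Wb = s(H, A, 0.3), Ub = s(H, H, 0.3), bb = numeric(H),
         v = rnorm(2 * H, sd = 0.3), c = 0)
  })
}

.birnnForward <- function(par, idx) {
  n <- nrow(idx); L <- ncol(idx); H <- nrow(par$Wf)
  Hf <- array(0, c(H, n, L + 1L))
  Hb <- array(0, c(H, n, L + 1L))
  for (t in seq_len(L)) {
    Hf[, , t + 1L] <- tanh(par$Wf[, idx[, t], drop = FALSE] +
                             par$Uf %*% Hf[, , t] + par$bf)
  }
  for (t in rev(seq_len(L))) {
    Hb[, , t] <- tanh(par$Wb[, idx[, t], drop = FALSE] +
                        par$Ub %*% Hb[, , t + 1L] + par$bb)
  }
  feat <- rbind(Hf[, , L + 1L, drop = TRUE], Hb[, , 1L, drop = TRUE])
  if (n == 1L) feat <- matrix(feat, ncol = 1L)
  p <- .sigmoid(drop(crossprod(feat, matrix(par$v))) + par$c)
  list(Hf = Hf, Hb = Hb, feat = feat, p = p)
}

.birnnGrad <- function(par, idx, y, A) {
  fw <- .birnnForward(par, idx)
  n <- nrow(idx); L <- ncol(idx); H <- nrow(par$Wf)
  dlogit <- (fw$p - y) / n                       # 1 x n (cross-entropy)
  g <- lapply(par, function(x) x * 0)
  g$v <- drop(fw$feat %*% dlogit)
  g$c <- sum(dlogit)
  dHf_next <- matrix(par$v[seq_len(H)], H, n) * rep(dlogit, each = H)
  dHb_prev <- matrix(par$v[H + seq_len(H)], H, n) * rep(dlogit, each = H)
  onehot <- function(t) {
    M <- matrix(0, n, A); M[cbind(seq_len(n), idx[, t])] <- 1; M
  }
  dh <- dHf_next
  for (t in rev(seq_len(L))) {
    h <- fw$Hf[, , t + 1L, drop = TRUE]
    if (n == 1L) h <- matrix(h, ncol = 1L)
    delta <- dh * (1 - h^2)
    g$Wf <- g$Wf + delta %*% onehot(t)
    g$Uf <- g$Uf + delta %*% t(matrix(fw$Hf[, , t], H, n))
    g$bf <- g$bf + rowSums(delta)
    dh <- crossprod(par$Uf, delta)
  }
  dh <- dHb_prev
  for (t in seq_len(L)) {
    h <- fw$Hb[, , t, drop = TRUE]
    if (n == 1L) h <- matrix(h, ncol = 1L)
    delta <- dh * (1 - h^2)
    g$Wb <- g$Wb + delta %*% onehot(t)
    g$Ub <- g$Ub + delta %*% t(matrix(fw$Hb[, , t + 1L], H, n))
    g$bb <- g$bb + rowSums(delta)
    dh <- crossprod(par$Ub, delta)
  }
  g
}

.trainBirnn <- function(idx, y, A, config) {
  par <- .birnnInit(A, config$hidden_size, config$seed)
  m <- lapply(par, function(x) x * 0)
  v2 <- lapply(par, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(idx)
  .withSeed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        g <- .birnnGrad(par, idx[rows, , drop = FALSE], y[rows], A)
        step <- step + 1
        for (nm in names(par)) {
          g[[nm]] <- g[[nm]] + config$l2 * par[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
          v2[[nm]] <- b2 * v2[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v2[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - config$learning_rate * mhat /
            (sqrt(vhat) + eps)
        }
      }
    }
  })
  par
}

## ---- public surface -------------------------------------------------------

#' Train one sequence-activity predictor
#'
#' Maps a fixed-length sequence to the probability of the positive
#' (binding) class.  Training is deterministic given
#' \code{config$seed}.
#'
#' @param sequences character vector of training sequences (one fixed
#'   length).
#' @param labels 0/1 integer vector; both classes must be present.
#' @param config a \code{\link{predictorConfig}}.
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @return a \linkS4class{SequencePredictor}.
#' @export
trainPredictor <- function(sequences, labels, config = predictorConfig(),
                           alphabet = aminoAcids()) {
  if (!length(sequences)) stop("empty training split")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training split contains a single class")
  m <- .seqMatrix(sequences, alphabet)
  L <- ncol(m)
  params <- switch(config$architecture,
    logistic = .trainLogistic(.oneHot(sequences, alphabet), labels, config),
    birnn = {
      idx <- matrix(match(m, alphabet), nrow = nrow(m))
      .trainBirnn(idx, labels, length(alphabet), config)
    },
    stop("unknown architecture: ", config$architecture))
  new("SequencePredictor", architecture = config$architecture,
      params = params, alphabet = alphabet,
      seqLength = as.integer(L), config = config)
}

#' @describeIn trainPredictor predict class probabilities for new
#'   sequences (errors on a length or alphabet mismatch).
#' @param object a trained \linkS4class{SequencePredictor}.
#' @param newdata character vector of sequences.
#' @export
setMethod("predict", "SequencePredictor", function(object, newdata) {
  m <- .seqMatrix(newdata, object@alphabet, object@seqLength)
  p <- switch(object@architecture,
    logistic = .predictLogistic(object@params,
                                .oneHot(newdata, object@alphabet,
                                        object@seqLength)),
    birnn = {
      idx <- matrix(match(m, object@alphabet), nrow = nrow(m))
      .birnnForward(object@params, idx)$p
    })
  pmin(pmax(as.numeric(p), 0), 1)
})

#' Train the predictor ensemble over the negative splits
#'
#' Fits one predictor per training split of the dataset (all positives
#' plus one disjoint negative subset), so that the spread of member
#' predictions measures how much the model depends on which negatives
#' it saw.
#'
#' @param dataset a \linkS4class{LabeledDataset} with splits populated
#'   (see \code{\link{splitNegatives}}).
#' @param config a \code{\link{predictorConfig}}; member i trains with
#'   \code{seed + i - 1}.
#' @param alphabet residue alphabet.
#' @return a \linkS4class{PredictorEnsemble}.
#' @export
trainEnsemble <- function(dataset, config = predictorConfig(),
                          alphabet = aminoAcids()) {
  splits <- trainingSplits(dataset)
  if (!length(splits))
    stop("dataset has no training splits; call splitNegatives() first")
  members <- lapply(seq_along(splits), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    trainPredictor(splits[[i]]$sequence, splits[[i]]$label, cfg, alphabet)
  })
  new("PredictorEnsemble", members = members,
      alphabet = alphabet, seqLength = members[[1]]@seqLength)
}

#' Ensemble mean prediction and prediction instability
#'
#' For each sequence, returns the arithmetic mean of the k member
#' probabilities and their standard deviation.  The default standard
#' deviation is the population form (divisor k): the ensemble is a
#' finite set of models, not a sample from one.  Set
#' \code{sdType = "sample"} for the divisor k-1 form.
#'
#' @param ensemble a \linkS4class{PredictorEnsemble}.
#' @param sequences character vector.
#' @param sdType "population" (default) or "sample".
#' @return data.frame(sequence, mean, sd).
#' @export
ensemblePredict <- function(ensemble, sequences,
                            sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  stopifnot(is(ensemble, "PredictorEnsemble"))
  if (!length(members(ensemble))) stop("untrained ensemble")
  P <- vapply(members(ensemble), function(m) predict(m, sequences),
              numeric(length(sequences)))
  P <- matrix(P, nrow = length(sequences))
  mu <- rowMeans(P)
  k <- ncol(P)
  if (sdType == "population") {
    s <- sqrt(rowMeans((P - mu)^2))
  } else {
    s <- apply(P, 1L, sd)
  }
  data.frame(sequence = sequences, mean = mu, sd = s,
             stringsAsFactors = FALSE)
}
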