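## Shared fixtures, built once per test run and cached.  Everything is
## generated in code from the synthetic landscape module.

.fx <- new.env(parent = emptyenv())

fxAlphabet <- function() c("A", "C", "D", "E")

## the reference toy study: length-12 motif landscape, two-pool panning
fxLandscape <- function() {
  if (is.null(.fx$landscape))
    .fx$landscape <- toyLandscape(length = 12L, alphabet = fxAlphabet(),
                                  nMotif = 6L, bonus = 1.5,
                                  noiseSd = 0.1, seed = 11L)
  .fx$landscape
}

fxPanning <- function() {
  if (is.null(.fx$panning))
    .fx$panning <- simulatePanning(fxLandscape(), 400L, 40000L, seed = 11L)
  .fx$panning
}

fxDataset <- function() {
  if (is.null(.fx$dataset)) {
    ds <- suppressMessages(labelSequences(filterByReads(fxPanning()$counts)))
    .fx$dataset <- splitNegatives(ds, 5L, seed = 11L)
  }
  .fx$dataset
}

fxEnsemble <- function() {
  if (is.null(.fx$ensemble))
    .fx$ensemble <- trainEnsemble(fxDataset(),
                                  predictorConfig(seed = 11L, l2 = 1),
                                  fxAlphabet())
  .fx$ensemble
}

fxScorer <- function() solubilityScorer("toy_hydropathy", toySolubility)

fxAutoencoder <- function() {
  if (is.null(.fx$ae)) {
    train <- unique(c(positives(fxDataset()), negatives(fxDataset())))
    .fx$ae <- trainBinaryAutoencoder(train, 32L,
                                     autoencoderConfig(seed = 11L),
                                     fxAlphabet())
  }
  .fx$ae
}

## a minimal length-39 amino-acid ensemble for the selection filters
fxVhhEnsemble <- function() {
  if (is.null(.fx$vhh)) {
    set.seed(21)
    seqs <- randomGenerate(40L, 39L, aminoAcids(), seed = 21L)
    labels <- rep(c(1L, 0L), 20L)
    cfg <- predictorConfig(epochs = 5L, seed = 21L, l2 = 1)
    .fx$vhh <- new("PredictorEnsemble",
                   members = list(trainPredictor(seqs, labels, cfg)),
                   alphabet = aminoAcids(), seqLength = 39L)
  }
  .fx$vhh
}

## independent O(n^2) dominance oracle used against the fast paths
bruteNonDominated <- function(X) {
  n <- nrow(X)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(X[j, ] >= X[i, ]) && any(X[j, ] > X[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

## exhaustive binary enumeration for small QUBO/FM oracles
allBinary <- function(d) as.matrix(expand.grid(rep(list(0:1), d)))
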