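#' @import methods
#' @importFrom stats rnorm runif rmultinom sd setNames predict
#' @importFrom utils read.csv read.delim write.csv head
#' @useDynLib quboseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Labeled training set with subsampled negative splits
#'
#' Holds the positive and negative sequences derived from enrichment
#' scoring, plus the k training splits used to fit the predictor
#' ensemble.  Each split contains every positive sequence and one
#' disjoint subset of the negatives, so the ensemble members disagree
#' only through the negatives they saw.
#'
#' @slot positives character vector of positive-class sequences.
#' @slot negatives character vector of negative-class sequences.
#' @slot splits list of k data.frames (sequence, label) or empty before
#'   \code{splitNegatives} is called.
#' @slot seed integer seed used for the negative partition (NA before).
#' @export
setClass("LabeledDataset",
  representation(
    positives = "character",
    negatives = "character",
    splits    = "list",
    seed      = "integer"
  ),
  prototype(splits = list(), seed = NA_integer_)
)

setValidity("LabeledDataset", function(object) {
  msg <- character()
  if (anyDuplicated(object@positives))
    msg <- c(msg, "duplicate positive sequences")
  if (length(object@splits)) {
    negs <- unlist(lapply(object@splits, function(s)
      s$sequence[s$label == 0L]), use.names = FALSE)
    if (anyDuplicated(negs))
      msg <- c(msg, "negative subsets are not disjoint")
    if (!setequal(negs, object@negatives))
      msg <- c(msg, "union of negative subsets != negatives")
    sizes <- vapply(object@splits, function(s) sum(s$label == 0L), 0L)
    if (diff(range(sizes)) > 1L)
      msg <- c(msg, "negative subset sizes differ by more than 1")
    for (s in object@splits)
      if (!all(object@positives %in% s$sequence[s$label == 1L])) {
        msg <- c(msg, "a split is missing positive sequences")
        break
      }
  }
  if (length(msg)) msg else TRUE
})

#' A single trained sequence-activity predictor
#'
#' @slot architecture "logistic" or "birnn".
#' @slot params list of fitted weights (architecture-specific).
#' @slot alphabet character vector of residues the model accepts.
#' @slot seqLength integer, fixed sequence length.
#' @slot config the PredictorConfig list used for training.
#' @export
setClass("SequencePredictor",
  representation(
    architecture = "character",
    params       = "list",
    alphabet     = "character",
    seqLength    = "integer",
    config       = "list"
  )
)

#' Ensemble of k predictors trained on subsampled splits
#'
#' @slot members list of \linkS4class{SequencePredictor}.
#' @slot alphabet shared residue alphabet.
#' @slot seqLength shared sequence length.
#' @export
setClass("PredictorEnsemble",
  representation(
    members   = "list",
    alphabet  = "character",
    seqLength = "integer"
  )
)

setValidity("PredictorEnsemble", function(object) {
  msg <- character()
  if (!length(object@members))
    msg <- c(msg, "ensemble has no members")
  for (m in object@members) {
    if (!is(m, "SequencePredictor")) {
      msg <- c(msg, "members must be SequencePredictor objects")
      break
    }
    if (!identical(m@alphabet, object@alphabet) ||
        !identical(m@seqLength, object@seqLength)) {
      msg <- c(msg, "members disagree on alphabet or sequence length")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pluggable per-sequence solubility scorer
#'
#' Wraps any deterministic sequence -> real scoring function so the
#' solubility objective and the solubility selection filter can be
#' swapped independently (e.g. a protein-language-model score table
#' produced by an external tool, or the built-in hydropathy toy scorer).
#'
#' @slot name identifier of the scorer.
#' @slot scoreFun function(character vector of sequences) -> numeric.
#' @export
setClass("SolubilityScorer",
  representation(name = "character", scoreFun = "function")
)

#' Factorization-machine surrogate
#'
#' Quadratic pseudo-Boolean surrogate
#' \eqn{\hat y(x) = w_0 + \sum_i w_i x_i + \sum_{i<j} \langle v_i, v_j\rangle x_i x_j}
#' with low-rank pairwise weights; maps one-to-one onto a QUBO.
#'
#' @slot w0 numeric scalar bias.
#' @slot w numeric length-d linear weights.
#' @slot V d x r matrix of factor vectors.
#' @export
setClass("FactorizationMachine",
  representation(w0 = "numeric", w = "numeric", V = "matrix")
)

setValidity("FactorizationMachine", function(object) {
  msg <- character()
  if (length(object@w0) != 1L || !is.finite(object@w0))
    msg <- c(msg, "w0 must be a finite scalar")
  if (!all(is.finite(object@w))) msg <- c(msg, "w must be finite")
  if (!all(is.finite(object@V))) msg <- c(msg, "V must be finite")
  if (nrow(object@V) != length(object@w))
    msg <- c(msg, "nrow(V) must equal length(w)")
  if (length(msg)) msg else TRUE
})

#' Quadratic unconstrained binary optimization problem
#'
#' Energy of a binary vector x is \eqn{x^T Q x + \mathrm{offset}} with Q
#' upper-triangular (diagonal = linear terms).  Annealers minimize this
#' energy.
#'
#' @slot Q upper-triangular d x d matrix.
#' @slot offset numeric scalar added to every energy.
#' @export
setClass("QUBOModel",
  representation(Q = "matrix", offset = "numeric")
)

setValidity("QUBOModel", function(object) {
  msg <- character()
  if (nrow(object@Q) != ncol(object@Q)) msg <- c(msg, "Q must be square")
  if (any(object@Q[lower.tri(object@Q)] != 0))
    msg <- c(msg, "Q must be upper-triangular (lower triangle zero)")
  if (!all(is.finite(object@Q))) msg <- c(msg, "Q must be finite")
  if (length(msg)) msg else TRUE
})

#' Binary-latent autoencoder over fixed-length sequences
#'
#' Encoder: one-hot sequence -> d logits -> deterministic threshold at
#' 0.5 gives a bit vector.  Decoder: bit vector -> per-position residue
#' logits -> argmax (lexicographically first residue on ties).  Trained
#' with a straight-through estimator so the hard-threshold code used at
#' generation time is the code being optimized.
#'
#' @slot Wenc,benc encoder affine map (d x L*A, d).
#' @slot Wdec,bdec decoder affine map (L*A x d, L*A).
#' @slot alphabet residue alphabet (sorted; argmax tie-break order).
#' @slot seqLength fixed sequence length L.
#' @slot latentDim number of latent bits d.
#' @slot config training configuration (epochs, seed, learning rate).
#' @export
setClass("BinaryAutoencoder",
  representation(
    Wenc = "matrix", benc = "numeric",
    Wdec = "matrix", bdec = "numeric",
    alphabet = "character", seqLength = "integer",
    latentDim = "integer", config = "list"
  )
)

#' Non-dominated archive with hypervolume history
#'
#' Maintains the Pareto front of evaluated sequences under a
#' maximize-all convention, the hypervolume trace and per-objective
#' best-so-far traces (the optimization progress curves), plus a side
#' list of sequences whose objective vector duplicates an archived one.
#'
#' @slot objectives n x d matrix of front objective vectors.
#' @slot sequences front sequences (first seen per objective vector).
#' @slot referencePoint per-objective lower bounds for hypervolume.
#' @slot hvHistory data.frame(evaluation, hypervolume).
#' @slot bestSoFar matrix of per-objective running maxima (one row per
#'   insertion attempt).
#' @slot duplicates data.frame of (sequence, matched) duplicate vectors.
#' @export
setClass("ParetoArchive",
  representation(
    objectives     = "matrix",
    sequences      = "character",
    referencePoint = "numeric",
    hvHistory      = "data.frame",
    bestSoFar      = "matrix",
    duplicates     = "data.frame"
  )
)

setValidity("ParetoArchive", function(object) {
  msg <- character()
  n <- nrow(object@objectives)
  if (n != length(object@sequences))
    msg <- c(msg, "objectives/sequences length mismatch")
  if (n && ncol(object@objectives) != length(object@referencePoint))
    msg <- c(msg, "dimension mismatch with reference point")
  if (n > 1L && !all(pareto_filter_cpp(object@objectives)))
    msg <- c(msg, "archive contains a dominated entry")
  hv <- object@hvHistory$hypervolume
  if (length(hv) > 1L && any(diff(hv) < -1e-9))
    msg <- c(msg, "hypervolume history must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' State of one optimization run
#'
#' @slot evaluated data.frame: sequence, f_mean, f_stab, f_sol,
#'   evaluation index, origin ("initial" or "generated").
#' @slot archive the \linkS4class{ParetoArchive} built during the run.
#' @slot budget total generated-sequence evaluations allowed.
#' @slot used generated-sequence evaluations consumed.
#' @slot seed run seed.
#' @export
setClass("RunState",
  representation(
    evaluated = "data.frame",
    archive   = "ParetoArchive",
    budget    = "integer",
    used      = "integer",
    seed      = "integer"
  )
)

setValidity("RunState", function(object) {
  msg <- character()
  if (anyDuplicated(object@evaluated$sequence))
    msg <- c(msg, "evaluated sequences must be unique (never re-scored)")
  if (object@used > object@budget)
    msg <- c(msg, "evaluation budget exceeded")
  if (length(msg)) msg else TRUE
})

#' Motif-based synthetic fitness landscape
#'
#' Ground truth for testing: fitness is a baseline plus a fixed bonus
#' per matched motif position plus seeded per-sequence noise, standing
#' in for a true binding landscape.
#'
#' @slot length sequence length.
#' @slot alphabet residue alphabet.
#' @slot motifPositions positions carrying a preferred residue.
#' @slot motifResidues the preferred residue at each motif position.
#' @slot bonus fitness bonus per matched position.
#' @slot baseline fitness of a zero-match sequence.
#' @slot noiseSd sd of the per-sequence noise term.
#' @slot seed seed controlling the noise lookup.
#' @export
setClass("ToyLandscape",
  representation(
    length = "integer", alphabet = "character",
    motifPositions = "integer", motifResidues = "character",
    bonus = "numeric", baseline = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("ToyLandscape", function(object) {
  msg <- character()
  if (length(object@motifPositions) != length(object@motifResidues))
    msg <- c(msg, "motif positions/residues length mismatch")
  if (any(object@motifPositions < 1L | object@motifPositions > object@length))
    msg <- c(msg, "motif positions out of range")
  if (!all(object@motifResidues %in% object@alphabet))
    msg <- c(msg, "motif residues outside alphabet")
  if (length(msg)) msg else TRUE
})
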