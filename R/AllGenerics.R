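#' @rdname LabeledDataset-class
#' @param object a LabeledDataset
#' @export
setGeneric("positives", function(object) standardGeneric("positives"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("negatives", function(object) standardGeneric("negatives"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("trainingSplits", function(object) standardGeneric("trainingSplits"))

#' @rdname PredictorEnsemble-class
#' @param object a PredictorEnsemble
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname ParetoArchive-class
#' @param object a ParetoArchive
#' @export
setGeneric("archiveFront", function(object) standardGeneric("archiveFront"))

#' @rdname ParetoArchive-class
#' @export
setGeneric("hvHistory", function(object) standardGeneric("hvHistory"))

#' @rdname ParetoArchive-class
#' @export
setGeneric("bestSoFar", function(object) standardGeneric("bestSoFar"))

#' @rdname ParetoArchive-class
#' @export
setGeneric("referencePoint", function(object) standardGeneric("referencePoint"))

#' @rdname RunState-class
#' @param object a RunState
#' @export
setGeneric("evaluatedTable", function(object) standardGeneric("evaluatedTable"))

setMethod("positives", "LabeledDataset", function(object) object@positives)
setMethod("negatives", "LabeledDataset", function(object) object@negatives)
setMethod("trainingSplits", "LabeledDataset", function(object) object@splits)
setMethod("members", "PredictorEnsemble", function(object) object@members)
setMethod("archiveFront", "ParetoArchive", function(object) {
  data.frame(sequence = object@sequences,
             object@objectives, check.names = FALSE,
             row.names = NULL)
})
setMethod("hvHistory", "ParetoArchive", function(object) object@hvHistory)
setMethod("bestSoFar", "ParetoArchive", function(object) object@bestSoFar)
setMethod("referencePoint", "ParetoArchive", function(object) object@referencePoint)
setMethod("evaluatedTable", "RunState", function(object) object@evaluated)

#' @rdname RunState-class
#' @export
setGeneric("runArchive", function(object) standardGeneric("runArchive"))
setMethod("runArchive", "RunState", function(object) object@archive)

setMethod("show", "LabeledDataset", function(object) {
  cat("LabeledDataset:", length(object@positives), "positives,",
      length(object@negatives), "negatives,",
      length(object@splits), "splits\n")
})

setMethod("show", "PredictorEnsemble", function(object) {
  cat("PredictorEnsemble: k =", length(object@members),
      "(", object@members[[1]]@architecture, "),",
      "alphabet size", length(object@alphabet),
      ", sequence length", object@seqLength, "\n")
})

setMethod("show", "SequencePredictor", function(object) {
  cat("SequencePredictor <", object@architecture, ">, length",
      object@seqLength, ", alphabet size", length(object@alphabet), "\n")
})

setMethod("show", "FactorizationMachine", function(object) {
  cat("FactorizationMachine: d =", length(object@w),
      ", rank =", ncol(object@V), "\n")
})

setMethod("show", "QUBOModel", function(object) {
  cat("QUBOModel: d =", nrow(object@Q),
      ", offset =", format(object@offset), "\n")
})

setMethod("show", "BinaryAutoencoder", function(object) {
  cat("BinaryAutoencoder: L =", object@seqLength,
      ", |alphabet| =", length(object@alphabet),
      ", latent bits =", object@latentDim, "\n")
})

setMethod("show", "ParetoArchive", function(object) {
  cat("ParetoArchive:", nrow(object@objectives), "front points,",
      nrow(object@hvHistory), "hypervolume updates\n")
  if (nrow(object@hvHistory))
    cat("  current hypervolume:",
        format(object@hvHistory$hypervolume[nrow(object@hvHistory)]), "\n")
})

setMethod("show", "RunState", function(object) {
  cat("RunState: budget", object@budget, ", used", object@used,
      ",", nrow(object@evaluated), "evaluated sequences,",
      nrow(object@archive@objectives), "on the front\n")
})

setMethod("show", "ToyLandscape", function(object) {
  cat("ToyLandscape: length", object@length,
      ", |alphabet|", length(object@alphabet),
      ",", length(object@motifPositions), "motif positions, bonus",
      object@bonus, "\n")
})

setMethod("show", "SolubilityScorer", function(object) {
  cat("SolubilityScorer:", object@name, "\n")
})
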