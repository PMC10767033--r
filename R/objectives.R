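## Kyte-Doolittle hydropathy index, one value per residue
.KD <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
         G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
         M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
         S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' Construct a solubility scorer
#'
#' @param name identifier.
#' @param scoreFun deterministic function(character vector) -> numeric.
#' @return a \linkS4class{SolubilityScorer}.
#' @export
solubilityScorer <- function(name, scoreFun) {
  new("SolubilityScorer", name = name, scoreFun = scoreFun)
}

#' Hydropathy-based toy solubility score
#'
#' Mean Kyte-Doolittle hydropathy of the residues, sign-flipped so that
#' hydrophilic-rich sequences score higher.  Scale: roughly [-4.5, 4.5]
#' (from all-Ile to all-Arg).  This is a deterministic stand-in for an
#' external solubility predictor behind the same scorer interface; it
#' captures the hydrophilicity trend, not a trained model.
#'
#' @param sequences character vector of amino-acid sequences.
#' @return numeric vector of scores.
#' @export
#' @examples
#' toySolubility("ACD")  # -(1.8 + 2.5 - 3.5)/3
toySolubility <- function(sequences) {
  m <- .seqMatrix(sequences, names(.KD))
  vals <- matrix(.KD[m], nrow = nrow(m))
  -rowMeans(vals)
}

#' @describeIn toySolubility the toy scorer wrapped as a
#'   \linkS4class{SolubilityScorer}.
#' @export
toySolubilityScorer <- function() {
  solubilityScorer("toy_hydropathy", toySolubility)
}

#' Solubility scorer backed by an external score table
#'
#' Adapter for external tools (e.g. protein-language-model solubility
#' predictors): any program that can emit a two-column TSV of
#' (sequence, score) plugs in here.  Scoring a sequence absent from the
#' table is an error.
#'
#' @param path TSV file with columns \code{sequence} and \code{score}.
#' @param name identifier for the scorer.
#' @return a \linkS4class{SolubilityScorer}.
#' @export
tableScorer <- function(path, name = paste0("table:", basename(path))) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("sequence", "score") %in% names(tab)))
    stop("score table needs columns 'sequence' and 'score': ", path)
  lookup <- setNames(as.numeric(tab$score), tab$sequence)
  solubilityScorer(name, function(sequences) {
    s <- lookup[sequences]
    if (anyNA(s))
      stop("no tabulated score for sequence(s): ",
           paste(head(sequences[is.na(s)], 3L), collapse = ", "))
    as.numeric(s)
  })
}

#' Evaluate the three design objectives for sequences
#'
#' Returns, per sequence, the maximize-all objective vector:
#' \describe{
#'   \item{f_mean}{ensemble mean predicted binding probability, in
#'     [0,1];}
#'   \item{f_stab}{negated ensemble standard deviation, in [-0.5, 0]
#'     (0 = perfectly stable prediction).  The sd is negated rather
#'     than inverted so all objectives share one maximization
#'     convention;}
#'   \item{f_sol}{solubility score from the configured scorer.}
#' }
#'
#' @param sequences character vector.
#' @param ensemble a trained \linkS4class{PredictorEnsemble}.
#' @param scorer a \linkS4class{SolubilityScorer}.
#' @return data.frame(sequence, f_mean, f_stab, f_sol).
#' @export
evaluateObjectives <- function(sequences, ensemble, scorer) {
  stopifnot(is(scorer, "SolubilityScorer"))
  ep <- ensemblePredict(ensemble, sequences)
  sol <- tryCatch(scorer@scoreFun(sequences), error = function(e)
    stop("solubility scorer '", scorer@name, "' failed: ",
         conditionMessage(e)))
  if (!all(is.finite(sol)))
    stop("solubility scorer '", scorer@name,
         "' returned non-finite score(s)")
  data.frame(sequence = sequences,
             f_mean = ep$mean,
             f_stab = -ep$sd,
             f_sol  = as.numeric(sol),
             stringsAsFactors = FALSE)
}

#' Names of the objective columns
#' @return character vector c("f_mean", "f_stab", "f_sol").
#' @export
objectiveNames <- function() c("f_mean", "f_stab", "f_sol")
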