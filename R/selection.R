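#' Hamming distance between two equal-length sequences
#'
#' @param a,b character strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hammingDistance: sequences have different lengths (",
         nchar(a), " vs ", nchar(b), ")")
  sum(strsplit(a, "", fixed = TRUE)[[1]] !=
        strsplit(b, "", fixed = TRUE)[[1]])
}

#' Minimum Hamming distance from a sequence to a set
#'
#' Novelty measure: how many mutations separate a designed sequence
#' from the closest training sequence.
#'
#' @param sequence a single sequence.
#' @param set character vector of sequences of the same length.
#' @return integer minimum distance.
#' @export
minDistanceToSet <- function(sequence, set) {
  if (!length(set)) stop("minDistanceToSet: empty reference set")
  lens <- unique(nchar(set))
  if (length(lens) != 1L || lens != nchar(sequence))
    stop("minDistanceToSet: sequences must share one length")
  q <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(set, "", fixed = TRUE), use.names = FALSE),
              nrow = length(set), byrow = TRUE)
  as.integer(min(rowSums(m != rep(q, each = length(set)))))
}

#' Wild-type VHH CDRs and the validated designed variants
#'
#' The reference data this package was exercised against: the
#' concatenated CDR1/CDR2/CDR3 sequence (13 + 10 + 16 = 39 residues)
#' of the wild-type anti-galectin-3 VHH scaffold (PDB 3DWT) and the
#' five designed variants that passed all selection filters, with
#' their reported Hamming distance to the closest training sequence.
#'
#' @return list with \code{wt_cdrs} (named character vector cdr1, cdr2,
#'   cdr3), \code{wt} (concatenated string) and \code{variants}
#'   (data.frame: name, sequence, reported_distance).
#' @export
vhhReference <- function() {
  wt_cdrs <- c(cdr1 = "GGSEYSYSTFSLG",
               cdr2 = "AIASMGGLTY",
               cdr3 = "VRGYFMRLPSSHNFRY")
  variants <- data.frame(
    name = c("VHH1832", "VHH1834", "VHH1835", "VHH1836", "VHH1837"),
    sequence = c(
      "SNQNNSNYNSYDYYFYNNSSYSYDSFNYYDDNNFDDYRR",
      "ANGDNYNASYSDNYNYCDYSYSYDDYFNYYYNNNDDDRF",
      "DNQNLNSYNDNNSFSYNSYYGSYDDYYYSYYNNFDNDRA",
      "NNNDNSNNYSYYDSFYGDFNFYYNNQPNDDHYDVYDHNS",
      "NQANFNSHRSYSSNNGSYYDDSFVNPPNDDHYDVYDHNS"),
    reported_distance = c(23L, 23L, 22L, 16L, 18L),
    stringsAsFactors = FALSE)
  list(wt_cdrs = wt_cdrs,
       wt = paste0(wt_cdrs, collapse = ""),
       variants = variants)
}

#' Selection criteria for designed CDR sequences
#'
#' The candidate funnel: (1) exact combined-CDR length; (2) no
#' homopolymer run of \code{maxHomopolymer} or more identical
#' consecutive residues; (3) ensemble mean score strictly above
#' \code{minMeanScore}; (4) filter-solubility strictly above
#' \code{minSolubility}; (5) each CDR segment at Hamming distance of
#' at least \code{minCdrDistance} from the wild-type segment.
#'
#' @param requiredLength combined CDR length (default 39).
#' @param maxHomopolymer shortest forbidden identical-residue run
#'   (default 5).
#' @param minMeanScore mean-score threshold, strict (default 0.6).
#' @param minSolubility solubility threshold, strict (default 0.0).
#' @param minCdrDistance per-CDR distance from wild type (default 3).
#' @param cdrLengths lengths of CDR1/2/3 partitioning the sequence
#'   (default c(13, 10, 16)).
#' @param wildType concatenated wild-type CDR string.
#' @param homopolymerOnly if TRUE (default) rule 2 forbids
#'   identical-residue runs; if FALSE it forbids any tandem-repeated
#'   k-mer covering >= maxHomopolymer residues.
#' @return a named list of criteria.
#' @export
selectionCriteria <- function(requiredLength = 39L, maxHomopolymer = 5L,
                              minMeanScore = 0.6, minSolubility = 0.0,
                              minCdrDistance = 3L,
                              cdrLengths = c(13L, 10L, 16L),
                              wildType = vhhReference()$wt,
                              homopolymerOnly = TRUE) {
  if (sum(cdrLengths) != requiredLength)
    stop("CDR lengths must partition the required length")
  if (nchar(wildType) != requiredLength)
    stop("wild-type length != required length")
  list(requiredLength = as.integer(requiredLength),
       maxHomopolymer = as.integer(maxHomopolymer),
       minMeanScore = minMeanScore,
       minSolubility = minSolubility,
       minCdrDistance = as.integer(minCdrDistance),
       cdrLengths = as.integer(cdrLengths),
       wildType = wildType,
       homopolymerOnly = homopolymerOnly)
}

## split a concatenated CDR string by the criteria's segment lengths
.cdrSegments <- function(sequence, cdrLengths) {
  ends <- cumsum(cdrLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(seq_along(cdrLengths), function(i)
    substr(sequence, starts[i], ends[i]), character(1))
}

.hasRepeat <- function(sequence, maxRun, homopolymerOnly = TRUE) {
  if (homopolymerOnly) return(.maxRun(sequence) >= maxRun)
  ## tandem-repeat reading: any k-mer repeated back-to-back spanning
  ## >= maxRun residues
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (k in seq_len(maxRun %/% 1)) {
    reps <- ceiling(maxRun / k)
    span <- k * reps
    if (span > n) next
    for (s in seq_len(n - span + 1L)) {
      unit <- ch[s:(s + k - 1L)]
      if (all(ch[s:(s + span - 1L)] == rep(unit, reps))) return(TRUE)
    }
  }
  FALSE
}

#' Apply the selection funnel to candidate sequences
#'
#' Evaluates each rule independently and returns per-rule pass/fail
#' flags for audit plus the combined verdict.  Mean score and
#' solubility are recomputed from the supplied ensemble and scorer.
#' Candidates of the wrong length fail rule 1 (and rule 5, which is
#' undefined for them) rather than raising an error.
#'
#' @param candidates character vector of sequences, or a data.frame
#'   with a \code{sequence} column.
#' @param criteria a \code{\link{selectionCriteria}} list.
#' @param ensemble trained \linkS4class{PredictorEnsemble} (rule 3).
#' @param scorer \linkS4class{SolubilityScorer} for the filter (rule
#'   4); distinct from the optimization-time solubility objective.
#' @return data.frame with sequence, the recomputed mean score and
#'   solubility, logical columns pass_length, pass_repeat, pass_score,
#'   pass_solubility, pass_cdr_distance, and \code{selected}.
#' @export
applyFilters <- function(candidates, criteria, ensemble, scorer) {
  seqs <- if (is.data.frame(candidates)) candidates$sequence
          else as.character(candidates)
  L <- criteria$requiredLength
  okLen <- nchar(seqs) == L
  meanScore <- rep(NA_real_, length(seqs))
  sol <- rep(NA_real_, length(seqs))
  if (any(okLen)) {
    ep <- ensemblePredict(ensemble, seqs[okLen])
    meanScore[okLen] <- ep$mean
    sol[okLen] <- scorer@scoreFun(seqs[okLen])
  }
  passRepeat <- !vapply(seqs, .hasRepeat, logical(1),
                        maxRun = criteria$maxHomopolymer,
                        homopolymerOnly = criteria$homopolymerOnly)
  wtSeg <- .cdrSegments(criteria$wildType, criteria$cdrLengths)
  passCdr <- vapply(seq_along(seqs), function(i) {
    if (!okLen[i]) return(FALSE)
    seg <- .cdrSegments(seqs[i], criteria$cdrLengths)
    all(mapply(hammingDistance, seg, wtSeg) >= criteria$minCdrDistance)
  }, logical(1))
  res <- data.frame(
    sequence = seqs,
    mean_score = meanScore,
    solubility = sol,
    pass_length = okLen,
    pass_repeat = passRepeat,
    pass_score = !is.na(meanScore) & meanScore > criteria$minMeanScore,
    pass_solubility = !is.na(sol) & sol > criteria$minSolubility,
    pass_cdr_distance = passCdr,
    stringsAsFactors = FALSE)
  res$selected <- res$pass_length & res$pass_repeat & res$pass_score &
    res$pass_solubility & res$pass_cdr_distance
  rownames(res) <- NULL
  res
}

#' Novelty report: distance of each selected sequence to the training
#' set
#'
#' @param selected character vector of selected sequences.
#' @param trainingSet character vector of training sequences (same
#'   length).
#' @return data.frame(sequence, min_distance).
#' @export
noveltyReport <- function(selected, trainingSet) {
  if (!length(selected)) stop("no selected sequences")
  data.frame(
    sequence = selected,
    min_distance = vapply(selected, minDistanceToSet, integer(1),
                          set = trainingSet),
    row.names = NULL, stringsAsFactors = FALSE)
}
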