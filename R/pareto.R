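## internal unchecked dominance (maximize-all)
.dominates <- function(a, b) all(a >= b) && any(a > b)

#' Pareto dominance under the maximize-all convention
#'
#' \code{a} dominates \code{b} iff a >= b in every objective and a > b
#' in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("objective vectors have different dimensions: ",
         length(a), " vs ", length(b))
  .dominates(a, b)
}

#' Non-dominated rows of an objective matrix
#'
#' @param X numeric matrix, one objective vector per row.
#' @return logical vector: TRUE for rows not dominated by any other
#'   row (duplicated rows are all retained).
#' @export
nonDominated <- function(X) {
  X <- as.matrix(X)
  pareto_filter_cpp(X)
}

#' Hypervolume dominated by a front
#'
#' Lebesgue measure of the union of boxes [reference, point] for the
#' points of a maximize-all front.  Exact for 1-3 objectives (sweep
#' algorithm); a seeded Monte-Carlo estimate is used beyond three.
#'
#' @param front numeric matrix (rows = points) or a single vector.
#' @param ref numeric reference point; every front point must dominate
#'   it (be strictly greater in all coordinates), otherwise an error.
#' @param mcSamples Monte-Carlo sample count for d > 3.
#' @param mcSeed seed for the Monte-Carlo estimate.
#' @return non-negative scalar.
#' @export
#' @examples
#' hypervolume(rbind(c(2, 1), c(1, 2)), c(0, 0))  # 3
hypervolume <- function(front, ref, mcSamples = 1e5, mcSeed = 1L) {
  P <- if (is.matrix(front)) front else matrix(front, nrow = 1L)
  if (ncol(P) != length(ref))
    stop("front and reference point dimension mismatch")
  if (!nrow(P)) return(0)
  if (any(t(P) <= ref))
    stop("every front point must strictly dominate the reference point")
  d <- ncol(P)
  if (d <= 3L) return(hv_exact_cpp(P, as.numeric(ref)))
  ## Monte-Carlo fallback: sample the bounding box, count dominated
  upper <- apply(P, 2L, max)
  vol <- prod(upper - ref)
  .withSeed(mcSeed, {
    U <- matrix(runif(mcSamples * d), ncol = d)
    U <- sweep(sweep(U, 2L, upper - ref, `*`), 2L, ref, `+`)
    inside <- vapply(seq_len(nrow(U)), function(i)
      any(apply(P, 1L, function(p) all(p >= U[i, ]))), logical(1))
    vol * mean(inside)
  })
}

## hv where points may fail to dominate ref: clip (non-dominating
## coordinates contribute zero volume); used for archive bookkeeping
.hvClipped <- function(P, ref) {
  keep <- colSums(t(P) > ref) == length(ref)
  if (!any(keep)) return(0)
  hypervolume(P[keep, , drop = FALSE], ref)
}

#' Create an empty Pareto archive
#'
#' The reference point is the per-objective lower bound for
#' hypervolume; fix it once (e.g. at the minima of the initial
#' evaluations minus a margin) so the hypervolume history of a run is
#' monotone and comparable.
#'
#' @param referencePoint numeric vector of per-objective lower bounds.
#' @return an empty \linkS4class{ParetoArchive}.
#' @export
newArchive <- function(referencePoint) {
  d <- length(referencePoint)
  new("ParetoArchive",
      objectives = matrix(numeric(0), 0L, d,
                          dimnames = list(NULL, names(referencePoint))),
      sequences = character(0),
      referencePoint = as.numeric(referencePoint),
      hvHistory = data.frame(evaluation = integer(0),
                             hypervolume = numeric(0)),
      bestSoFar = matrix(numeric(0), 0L, d,
                         dimnames = list(NULL, names(referencePoint))),
      duplicates = data.frame(sequence = character(0),
                              matched = character(0)))
}

#' Insert a candidate into a Pareto archive
#'
#' The candidate enters the front iff no archived entry dominates it;
#' entries it dominates are removed.  A candidate whose objective
#' vector exactly duplicates an archived one is recorded in a side
#' list, not the front.  The hypervolume history and per-objective
#' best-so-far traces gain one row per call regardless of acceptance,
#' so they align with the evaluation stream.
#'
#' @param archive a \linkS4class{ParetoArchive}.
#' @param sequence candidate identifier (sequence string).
#' @param objective numeric objective vector (maximize-all).
#' @return the updated archive.
#' @export
updateArchive <- function(archive, sequence, objective) {
  stopifnot(is(archive, "ParetoArchive"))
  objective <- as.numeric(objective)
  d <- length(archive@referencePoint)
  if (length(objective) != d)
    stop("objective vector has dimension ", length(objective),
         ", archive expects ", d)
  P <- archive@objectives
  seqs <- archive@sequences
  dup <- archive@duplicates
  n <- nrow(P)
  dominated <- FALSE
  if (n) {
    tP <- t(P)
    exact <- which(colSums(tP == objective) == d)
    if (length(exact)) {
      if (!sequence %in% seqs)
        dup <- rbind(dup, data.frame(sequence = sequence,
                                     matched = seqs[exact[1L]]))
      dominated <- TRUE              # point already represented
    } else {
      ge <- colSums(tP >= objective) == d
      gt <- colSums(tP > objective) > 0
      dominated <- any(ge & gt)
    }
  }
  if (!dominated) {
    if (n) {
      tP <- t(P)
      le <- colSums(tP <= objective) == d
      lt <- colSums(tP < objective) > 0
      kill <- le & lt
      P <- P[!kill, , drop = FALSE]
      seqs <- seqs[!kill]
    }
    P <- rbind(P, objective)
    seqs <- c(seqs, sequence)
  }
  rownames(P) <- NULL
  ev <- nrow(archive@bestSoFar) + 1L
  hv <- .hvClipped(P, archive@referencePoint)
  prev <- if (nrow(archive@bestSoFar))
    archive@bestSoFar[nrow(archive@bestSoFar), ] else rep(-Inf, d)
  best <- pmax(prev, objective)
  bsf <- rbind(archive@bestSoFar, best)
  rownames(bsf) <- NULL
  initialize(archive, objectives = P, sequences = seqs,
             hvHistory = rbind(archive@hvHistory,
                               data.frame(evaluation = ev,
                                          hypervolume = hv)),
             bestSoFar = bsf, duplicates = dup)
}

#' Write an archive's front, hypervolume and best-so-far traces as CSV
#'
#' @param archive a \linkS4class{ParetoArchive}.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
writeArchive <- function(archive, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(front = file.path(dir, "archive.csv"),
             hv = file.path(dir, "hv_history.csv"),
             best = file.path(dir, "best_so_far.csv"))
  write.csv(archiveFront(archive), paths["front"], row.names = FALSE)
  write.csv(hvHistory(archive), paths["hv"], row.names = FALSE)
  bsf <- data.frame(evaluation = seq_len(nrow(bestSoFar(archive))),
                    bestSoFar(archive), check.names = FALSE)
  write.csv(bsf, paths["best"], row.names = FALSE)
  invisible(paths)
}
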