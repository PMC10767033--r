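#' Read a two-pool phage-display count table
#'
#' Reads a CSV/TSV table with columns \code{sequence},
#' \code{count_eluted}, \code{count_ns} (reads of each variant in the
#' target-eluted pool and the non-specifically bound pool) and derives
#' per-pool frequencies from the column totals, plus the enrichment
#' score.  Frequencies are computed from the full table, before any
#' read filtering, so the score of a record does not depend on which
#' other records are later retained.
#'
#' @param path file path.
#' @param format "csv" or "tsv"; guessed from the file extension by
#'   default.
#' @return data.frame with columns sequence, count_eluted, count_ns,
#'   freq_eluted, freq_ns, score — one row per input row, input order
#'   preserved.  score is \code{Inf} when freq_ns is 0 with a positive
#'   eluted frequency and \code{NA} when both frequencies are 0.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("sequence,count_eluted,count_ns", "ACDA,5,5"), tmp)
#' readCountTable(tmp)
readCountTable <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count table not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  tab <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = TRUE,
                    strip.white = TRUE)
  need <- c("sequence", "count_eluted", "count_ns")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("count table is missing column(s): ",
         paste(missing, collapse = ", "))
  ce <- suppressWarnings(as.numeric(tab$count_eluted))
  cn <- suppressWarnings(as.numeric(tab$count_ns))
  bad <- which(is.na(ce) | is.na(cn) | ce < 0 | cn < 0 |
                 ce != floor(ce) | cn != floor(cn))
  if (length(bad))
    stop("malformed count at line ", bad[1] + 1L,
         " of ", path, " (counts must be non-negative integers)")
  if (anyDuplicated(tab$sequence)) {
    d <- tab$sequence[duplicated(tab$sequence)][1]
    stop("duplicate sequence in count table (counts must be ",
         "pre-aggregated): ", d)
  }
  countRecords(tab$sequence, as.integer(ce), as.integer(cn))
}

#' Build count records from vectors of counts
#'
#' Computes per-pool frequencies from the totals of the supplied
#' vectors and the enrichment score per record.
#'
#' @param sequence character vector of variant sequences.
#' @param count_eluted,count_ns non-negative integer read counts.
#' @return data.frame as described in \code{\link{readCountTable}}.
#' @export
countRecords <- function(sequence, count_eluted, count_ns) {
  stopifnot(length(sequence) == length(count_eluted),
            length(sequence) == length(count_ns))
  if (any(count_eluted < 0) || any(count_ns < 0))
    stop("counts must be non-negative")
  te <- sum(as.double(count_eluted))
  tn <- sum(as.double(count_ns))
  fe <- if (te > 0) count_eluted / te else rep(0, length(sequence))
  fn <- if (tn > 0) count_ns / tn else rep(0, length(sequence))
  data.frame(
    sequence     = as.character(sequence),
    count_eluted = as.integer(count_eluted),
    count_ns     = as.integer(count_ns),
    freq_eluted  = fe,
    freq_ns      = fn,
    score        = enrichmentScore(fe, fn),
    stringsAsFactors = FALSE
  )
}

#' Enrichment score of a variant
#'
#' The binding score of a displayed variant is its frequency in the
#' target-eluted pool divided by its frequency in the non-specifically
#' bound (N.S.) pool.  A variant absent from the N.S. pool but present
#' in the eluted pool has infinite enrichment (\code{Inf}); a variant
#' absent from both pools is undefined (\code{NA}).
#'
#' @param freq_eluted,freq_ns frequencies in [0,1]; vectorized.
#' @return numeric vector of scores (may contain Inf/NA).
#' @export
#' @examples
#' enrichmentScore(0.001, 0.0002)  # 5
enrichmentScore <- function(freq_eluted, freq_ns) {
  if (any(freq_eluted < 0) || any(freq_ns < 0))
    stop("frequencies must be non-negative")
  s <- ifelse(freq_ns > 0, freq_eluted / freq_ns,
              ifelse(freq_eluted > 0, Inf, NA_real_))
  as.numeric(s)
}

#' Retain variants with enough reads in either pool
#'
#' Keeps records whose read count is strictly greater than
#' \code{minReads} in the eluted pool or in the N.S. pool.  The
#' default, more than three reads, matches the usual deep-sequencing
#' noise floor for this assay.  Frequencies and scores are not
#' recomputed after filtering.
#'
#' @param records data.frame from \code{\link{readCountTable}}.
#' @param minReads integer threshold; retain if count > minReads.
#' @return filtered data.frame, input order preserved.
#' @export
filterByReads <- function(records, minReads = 3L) {
  keep <- records$count_eluted > minReads | records$count_ns > minReads
  records[keep, , drop = FALSE]
}

#' Label variants as binders / non-binders by enrichment score
#'
#' Scores at or above \code{posThreshold} (default 5) are the positive
#' (binding) class; scores below \code{negThreshold} (default 1) are
#' the negative class.  Records in between, and records with undefined
#' score, are dropped from the labeled set; their count is reported via
#' \code{message}.  Infinite scores are positive.
#'
#' @param records data.frame with a \code{score} column.
#' @param posThreshold,negThreshold class thresholds.
#' @return a \linkS4class{LabeledDataset} (splits not yet populated).
#' @export
labelSequences <- function(records, posThreshold = 5, negThreshold = 1) {
  sc <- records$score
  pos <- !is.na(sc) & sc >= posThreshold
  neg <- !is.na(sc) & sc < negThreshold
  dropped <- sum(!(pos | neg))
  message("labelSequences: ", sum(pos), " positives, ", sum(neg),
          " negatives, ", dropped, " dropped (ambiguous or undefined score)")
  new("LabeledDataset",
      positives = records$sequence[pos],
      negatives = records$sequence[neg])
}

#' Partition the negatives into k disjoint training splits
#'
#' Shuffles the negative sequences with the given seed and slices them
#' into k contiguous subsets whose sizes differ by at most one; each
#' training split is all positives plus one negative subset.  This is
#' the subsampling that makes the predictor ensemble disagree, and
#' hence gives the prediction-instability objective meaning.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param k number of splits (default 5).
#' @param seed integer seed; the partition is deterministic given it.
#' @return the dataset with \code{trainingSplits} populated.
#' @export
splitNegatives <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(is(dataset, "LabeledDataset"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  negs <- dataset@negatives
  if (k > length(negs))
    stop("k (", k, ") exceeds the number of negatives (", length(negs), ")")
  perm <- .withSeed(seed, sample.int(length(negs)))
  shuffled <- negs[perm]
  sizes <- rep(length(negs) %/% k, k)
  extra <- length(negs) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  splits <- lapply(seq_len(k), function(i) {
    sub <- shuffled[starts[i]:ends[i]]
    data.frame(
      sequence = c(dataset@positives, sub),
      label    = c(rep(1L, length(dataset@positives)),
                   rep(0L, length(sub))),
      stringsAsFactors = FALSE
    )
  })
  initialize(dataset, splits = splits, seed = as.integer(seed %% 2147483647))
}

#' Write positives and negatives as FASTA
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeLabeledFasta <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(positives = file.path(dir, "positives.fasta"),
             negatives = file.path(dir, "negatives.fasta"))
  pos <- Biostrings::AAStringSet(setNames(dataset@positives,
    paste0("pos_", seq_along(dataset@positives))))
  neg <- Biostrings::AAStringSet(setNames(dataset@negatives,
    paste0("neg_", seq_along(dataset@negatives))))
  Biostrings::writeXStringSet(pos, paths["positives"])
  Biostrings::writeXStringSet(neg, paths["negatives"])
  invisible(paths)
}
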