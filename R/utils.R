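#' The 20 canonical amino acids
#'
#' Alphabetical one-letter codes; this ordering is also the argmax
#' tie-break order used by the autoencoder decoder.
#' @return character vector of length 20.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## split sequences into an n x L character matrix, validating alphabet
.seqMatrix <- function(sequences, alphabet, seqLength = NULL) {
  if (!length(sequences)) stop("no sequences supplied")
  lens <- nchar(sequences)
  if (!is.null(seqLength) && any(lens != seqLength))
    stop("sequence length mismatch: expected ", seqLength,
         ", got ", paste(unique(lens[lens != seqLength]), collapse = ", "))
  if (length(unique(lens)) > 1L)
    stop("sequences have mixed lengths: ",
         paste(sort(unique(lens)), collapse = ", "))
  m <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = length(sequences), byrow = TRUE)
  bad <- setdiff(unique(as.vector(m)), alphabet)
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  m
}

## one-hot encode to an n x (L * |alphabet|) numeric matrix
.oneHot <- function(sequences, alphabet, seqLength = NULL) {
  m <- .seqMatrix(sequences, alphabet, seqLength)
  L <- ncol(m)
  A <- length(alphabet)
  idx <- matrix(match(m, alphabet), nrow = nrow(m))
  X <- matrix(0, nrow(m), L * A)
  for (p in seq_len(L)) {
    X[cbind(seq_len(nrow(m)), (p - 1L) * A + idx[, p])] <- 1
  }
  X
}

## deterministic 31-bit hash of a string mixed with a seed; used for
## seeded per-sequence noise lookups
.stringHash <- function(s, seed) {
  codes <- utf8ToInt(s)
  h <- (as.double(seed) %% 2147483647) + 1
  for (v in codes) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

## run an expression with a temporary RNG state (restores on exit)
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

## longest run of identical consecutive characters
.maxRun <- function(sequence) {
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  max(r$lengths)
}
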