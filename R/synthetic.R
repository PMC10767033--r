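#' Construct a motif-based toy fitness landscape
#'
#' Ground truth for end-to-end testing: a sequence's fitness is a
#' baseline, plus a fixed bonus for every motif position carrying its
#' preferred residue, plus seeded per-sequence Gaussian noise.  The
#' maximal-fitness sequence is known in closed form (preferred residue
#' at every motif position), so recovery can be checked exactly.  The
#' noise is a deterministic lookup keyed on (seed, sequence), so
#' fitness is reproducible across calls.
#'
#' @param length sequence length.
#' @param alphabet residue alphabet.
#' @param nMotif number of motif positions (evenly spread) — ignored
#'   when \code{motifPositions} is given.
#' @param motifPositions,motifResidues explicit motif definition.
#' @param bonus fitness bonus per matched position.
#' @param baseline fitness with zero matches.
#' @param noiseSd sd of the per-sequence noise (0 for none).
#' @param seed seed for the motif draw and the noise lookup.
#' @return a \linkS4class{ToyLandscape}.
#' @export
toyLandscape <- function(length = 12L, alphabet = c("A", "C", "D", "E"),
                         nMotif = 6L, motifPositions = NULL,
                         motifResidues = NULL, bonus = 1, baseline = 0,
                         noiseSd = 0.1, seed = 1L) {
  length <- as.integer(length)
  if (is.null(motifPositions)) {
    motifPositions <- .withSeed(seed,
      sort(sample.int(length, min(nMotif, length))))
    motifResidues <- .withSeed(seed + 1L,
      sample(alphabet, base::length(motifPositions), replace = TRUE))
  }
  new("ToyLandscape", length = length, alphabet = alphabet,
      motifPositions = as.integer(motifPositions),
      motifResidues = as.character(motifResidues),
      bonus = bonus, baseline = baseline, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' True fitness of sequences under a toy landscape
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param sequences character vector.
#' @return numeric fitness values.
#' @export
landscapeFitness <- function(landscape, sequences) {
  m <- .seqMatrix(sequences, landscape@alphabet, landscape@length)
  hits <- if (length(landscape@motifPositions)) {
    sub <- m[, landscape@motifPositions, drop = FALSE]
    rowSums(sub == rep(landscape@motifResidues, each = nrow(m)))
  } else rep(0, nrow(m))
  noise <- if (landscape@noiseSd > 0) {
    vapply(sequences, function(s)
      .withSeed(.stringHash(s, landscape@seed), rnorm(1)), numeric(1))
  } else rep(0, length(sequences))
  unname(landscape@baseline + landscape@bonus * hits +
           landscape@noiseSd * noise)
}

#' @describeIn landscapeFitness the sequence with maximal fitness
#'   (noise aside): preferred residue at motif positions, first
#'   alphabet residue elsewhere.
#' @export
landscapeOptimum <- function(landscape) {
  res <- rep(landscape@alphabet[1L], landscape@length)
  res[landscape@motifPositions] <- landscape@motifResidues
  paste0(res, collapse = "")
}

#' Simulate a two-pool biopanning count table over a toy landscape
#'
#' Draws \code{nVariants} distinct random variants, then samples read
#' counts: the non-specific pool is multinomial with uniform weights
#' (no selection), the eluted pool multinomial with weights
#' proportional to \code{exp(fitness)} (softmax selection), so the
#' expected enrichment score is log-linear in true fitness.  The
#' four experimental selection rounds are collapsed into one effective
#' enrichment.
#'
#' @param landscape a \linkS4class{ToyLandscape}.
#' @param nVariants number of distinct variants (>= 10).
#' @param readsPerPool total reads per pool (>= 10 * nVariants
#'   recommended).
#' @param seed RNG seed.
#' @return list with \code{counts} (data.frame from
#'   \code{\link{countRecords}}) and \code{truth} (data.frame sequence,
#'   fitness).
#' @export
simulatePanning <- function(landscape, nVariants = 1000L,
                            readsPerPool = 100000L, seed = 1L) {
  if (nVariants < 10L) stop("need at least 10 variants")
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < nVariants && tries < 50L) {
    tries <- tries + 1L
    seqs <- unique(c(seqs,
      randomGenerate(nVariants, landscape@length, landscape@alphabet,
                     seed = seed + 31L * tries)))
  }
  seqs <- head(seqs, nVariants)
  fit <- landscapeFitness(landscape, seqs)
  wE <- exp(fit - max(fit))
  cE <- .withSeed(seed + 1L,
    drop(rmultinom(1L, readsPerPool, wE / sum(wE))))
  cN <- .withSeed(seed + 2L,
    drop(rmultinom(1L, readsPerPool, rep(1 / length(seqs), length(seqs)))))
  list(counts = countRecords(seqs, cE, cN),
       truth = data.frame(sequence = seqs, fitness = fit,
                          stringsAsFactors = FALSE))
}
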