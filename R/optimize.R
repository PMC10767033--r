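#' Hypervolume improvement of a candidate over the current front
#'
#' The scalar acquisition value regressed by the surrogate: how much
#' the archive's hypervolume would grow if the candidate were added.
#' Zero for candidates dominated by (or duplicating) the front.
#'
#' @param objective numeric objective vector (maximize-all).
#' @param archive a \linkS4class{ParetoArchive} (reference point set).
#' @return non-negative scalar.
#' @export
#' @examples
#' a <- newArchive(c(0, 0))
#' a <- updateArchive(a, "s1", c(2, 1))
#' a <- updateArchive(a, "s2", c(1, 2))
#' acquisitionHVI(c(2, 2), a)  # 4 - 3 = 1
acquisitionHVI <- function(objective, archive) {
  stopifnot(is(archive, "ParetoArchive"))
  objective <- as.numeric(objective)
  if (length(objective) != length(archive@referencePoint))
    stop("objective dimension mismatch with archive")
  P <- archive@objectives
  ref <- archive@referencePoint
  .hvClipped(rbind(P, objective), ref) - .hvClipped(P, ref)
}

## leave-one-out hypervolume targets for every evaluated point: front
## members get their hypervolume contribution, dominated points their
## (zero) improvement -- gives the FM a graded signal over the front
## `scale` puts the objectives on comparable ranges before measuring
## hypervolume, so no single objective dominates the acquisition
.hviTargets <- function(M, archive, scale = rep(1, ncol(M))) {
  ref <- archive@referencePoint * scale
  P <- sweep(archive@objectives, 2L, scale, `*`)
  Ms <- sweep(M, 2L, scale, `*`)
  hvFull <- .hvClipped(P, ref)
  d <- length(ref)
  ## every evaluated point is either on the front (its target is its
  ## leave-one-out hypervolume contribution) or dominated by it (its
  ## hypervolume improvement is exactly 0) -- no union recomputation
  contrib <- vapply(seq_len(nrow(P)), function(i)
    hvFull - .hvClipped(P[-i, , drop = FALSE], ref), numeric(1))
  key <- function(X) apply(X, 1L, paste, collapse = "\r")
  idx <- match(key(Ms), key(P))
  out <- numeric(nrow(Ms))
  hit <- !is.na(idx)
  out[hit] <- contrib[idx[hit]]
  out
}

## Pareto-rank scalarization (alternative acquisition): negated
## non-dominated-sorting rank, front = 0
.rankTargets <- function(M) {
  n <- nrow(M)
  rank <- integer(n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    nd <- nonDominated(M[remaining, , drop = FALSE])
    rank[remaining[nd]] <- level
    remaining <- remaining[!nd]
    level <- level + 1L
  }
  -as.numeric(rank)
}

#' Generate uniform random sequences
#'
#' The random-generation reference baseline: i.i.d. uniform residues.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param alphabet residue alphabet.
#' @param seed RNG seed.
#' @return character vector of n sequences.
#' @export
randomGenerate <- function(n, length, alphabet = aminoAcids(), seed = 1L) {
  stopifnot(n >= 1L, length >= 1L)
  .withSeed(seed, {
    m <- matrix(sample(alphabet, n * length, replace = TRUE), nrow = n)
    apply(m, 1L, paste0, collapse = "")
  })
}

## random k-point substitutions of one sequence
.mutateSequences <- function(sequence, n, k, alphabet) {
  L <- nchar(sequence)
  vapply(seq_len(n), function(j) {
    x <- sequence
    for (p in sample.int(L, min(k, L))) {
      substr(x, p, p) <- sample(setdiff(alphabet, substr(x, p, p)), 1L)
    }
    x
  }, character(1))
}

## uniform crossover of two equal-length sequences
.crossSequences <- function(a, b, n) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  vapply(seq_len(n), function(j) {
    m <- runif(length(ca)) < 0.5
    paste0(ifelse(m, ca, cb), collapse = "")
  }, character(1))
}

## up to nmax incumbents by objective `obj`, greedily kept pairwise
## >= minDist apart so their neighborhoods do not overlap
.diverseParents <- function(evaluated, M, obj, nmax = 4L, minDist = 2L) {
  ord <- order(M[, obj], decreasing = TRUE)
  parents <- character(0)
  for (i in ord) {
    s <- evaluated$sequence[i]
    if (!length(parents) ||
        all(vapply(parents, hammingDistance, 0L, b = s) >= minDist))
      parents <- c(parents, s)
    if (length(parents) >= nmax) break
  }
  parents
}

#' Run the surrogate-guided multi-objective generation loop
#'
#' One optimization run: train (or reuse) a binary autoencoder over the
#' labeled sequences, evaluate an initial pool (the training sequences
#' plus \code{nInitRandom} decoded random latents), then iterate
#' \enumerate{
#'   \item compute an acquisition target for every evaluated sequence
#'     (hypervolume improvement/contribution by default, measured on
#'     range-normalized objectives so no single objective dominates);
#'   \item fit the factorization-machine surrogate on (latent code,
#'     acquisition) pairs;
#'   \item compile the FM to a QUBO and sample low-energy latent codes
#'     by simulated annealing;
#'   \item assemble a batch of unseen sequences: decoded annealer
#'     samples and their latent-space neighborhoods (surrogate-guided
#'     global moves), plus local refinement of the incumbent extremes
#'     (point mutations and uniform crossovers of a small
#'     Hamming-diverse parent set, cycling through the objectives), a
#'     random fill-in if short;
#'   \item evaluate the objectives of the batch and update the archive;
#' }
#' until \code{budget} generated sequences have been evaluated.
#' Everything is deterministic given \code{seed}.  The archive's
#' reference point is fixed at the per-objective minimum of the initial
#' pool minus a small margin, so the hypervolume history is monotone
#' within the run.
#'
#' @param dataset a \linkS4class{LabeledDataset} (used for the
#'   autoencoder and the initial pool).
#' @param ensemble trained \linkS4class{PredictorEnsemble}.
#' @param scorer a \linkS4class{SolubilityScorer}.
#' @param budget generated-sequence evaluations (initial pool excluded).
#' @param seed run seed.
#' @param latentDim latent bits d; should be at least the sequence
#'   entropy (length x log2 alphabet size) if the decoder is to span
#'   sequence space.
#' @param batchSize decoded samples evaluated per iteration.
#' @param rank,lambda FM hyperparameters.
#' @param sweeps annealing sweeps per restart.
#' @param nInitRandom random latents added to the initial pool.
#' @param acquisition "hvi" (hypervolume improvement, default) or
#'   "rank" (negated Pareto rank).
#' @param autoencoder optionally, a pre-trained
#'   \linkS4class{BinaryAutoencoder} to reuse across runs.
#' @param aeConfig autoencoder training configuration.
#' @return a \linkS4class{RunState}.
#' @export
optimizeSequences <- function(dataset, ensemble, scorer, budget = 2000L, seed = 1L,
                    latentDim = 64L, batchSize = 20L, rank = 8L,
                    lambda = 1e-3, sweeps = 300L, nInitRandom = 100L,
                    acquisition = c("hvi", "rank"),
                    autoencoder = NULL,
                    aeConfig = autoencoderConfig(seed = seed)) {
  acquisition <- match.arg(acquisition)
  budget <- as.integer(budget)
  batchSize <- as.integer(batchSize)
  if (budget > 0L && budget < batchSize)
    stop("budget (", budget, ") is smaller than the batch size (",
         batchSize, ")")
  train <- unique(c(positives(dataset), negatives(dataset)))
  if (!length(train)) stop("dataset has no sequences")
  alphabet <- ensemble@alphabet
  ae <- if (is.null(autoencoder)) {
    trainBinaryAutoencoder(train, latentDim, aeConfig, alphabet)
  } else autoencoder
  if (ae@latentDim != latentDim) latentDim <- ae@latentDim

  ## initial pool: training sequences + decoded random latents
  initLatent <- .withSeed(seed * 7L + 1L,
    matrix(as.numeric(runif(nInitRandom * latentDim) < 0.5),
           nrow = nInitRandom))
  pool <- unique(c(train, if (nInitRandom > 0L) decodeLatent(ae, initLatent)))
  ev <- evaluateObjectives(pool, ensemble, scorer)
  M <- as.matrix(ev[, objectiveNames()])
  ref <- apply(M, 2L, min) - 1e-6
  objScale <- 1 / pmax(apply(M, 2L, max) - ref, 1e-9)
  archive <- newArchive(setNames(ref, objectiveNames()))
  for (i in seq_len(nrow(ev)))
    archive <- updateArchive(archive, ev$sequence[i], M[i, ])
  evaluated <- data.frame(ev, evaluation = seq_len(nrow(ev)),
                          origin = "initial", stringsAsFactors = FALSE)

  used <- 0L
  iter <- 0L
  while (used < budget) {
    iter <- iter + 1L
    iseed <- as.integer((seed * 1000L + iter) %% 2147483647L)
    allSeqs <- evaluated$sequence
    X <- encodeSequences(ae, allSeqs)
    Mall <- as.matrix(evaluated[, objectiveNames()])
    y <- if (acquisition == "hvi") .hviTargets(Mall, archive, objScale)
         else .rankTargets(Mall)
    fm <- fitFactorizationMachine(X, y, rank = rank, lambda = lambda,
                                  seed = iseed)
    qubo <- fmToQubo(fm)
    samp <- annealSample(qubo, nSamples = max(2L * batchSize, 20L),
                         sweeps = sweeps, seed = iseed)
    d <- ncol(samp$states)
    ## surrogate-guided candidates: annealed codes plus random
    ## bit-flip neighborhoods of the lowest-energy ones
    nTop <- min(5L, nrow(samp$states))
    nb <- .withSeed(iseed + 11L, do.call(rbind,
      lapply(seq_len(nTop), function(r) {
        t(vapply(seq_len(6L), function(j) {
          b <- samp$states[r, ]
          flips <- sample.int(d, sample.int(4L, 1L))
          b[flips] <- 1 - b[flips]
          b
        }, numeric(d)))
      })))
    candGuided <- setdiff(unique(decodeLatent(ae, rbind(samp$states, nb))),
                          allSeqs)
    ## local refinement: mutations and crossovers of a Hamming-diverse
    ## parent set, cycling through the objectives across iterations
    obj <- ((iter - 1L) %% ncol(Mall)) + 1L
    parents <- .diverseParents(evaluated, Mall, obj)
    candLocal <- .withSeed(iseed + 13L, {
      muts <- unlist(lapply(parents, function(p)
        c(.mutateSequences(p, 8L, 1L, alphabet),
          .mutateSequences(p, 3L, 2L, alphabet))))
      xo <- if (length(parents) >= 2L) {
        unlist(lapply(seq_len(5L), function(j) {
          pr <- sample.int(length(parents), 2L)
          .crossSequences(parents[pr[1L]], parents[pr[2L]], 2L)
        }))
      } else character(0)
      unique(c(muts, xo))
    })
    candLocal <- setdiff(candLocal, allSeqs)
    take <- min(batchSize, budget - used)
    cand <- head(unique(c(head(candGuided, ceiling(0.4 * take)),
                          candLocal)), take)
    if (length(cand) < take) {       # exploration fill-in
      extra <- randomGenerate(4L * take, ae@seqLength, alphabet,
                              seed = iseed + 1L)
      extra <- setdiff(unique(extra), c(allSeqs, cand))
      cand <- c(cand, head(extra, take - length(cand)))
    }
    if (!length(cand)) break
    evNew <- evaluateObjectives(cand, ensemble, scorer)
    Mnew <- as.matrix(evNew[, objectiveNames()])
    for (i in seq_len(nrow(evNew)))
      archive <- updateArchive(archive, evNew$sequence[i], Mnew[i, ])
    evaluated <- rbind(evaluated,
      data.frame(evNew,
                 evaluation = nrow(evaluated) + seq_len(nrow(evNew)),
                 origin = "generated", stringsAsFactors = FALSE))
    used <- used + nrow(evNew)
  }
  new("RunState", evaluated = evaluated, archive = archive,
      budget = budget, used = used,
      seed = as.integer(seed %% 2147483647))
}

#' Merge several optimization runs into one deduplicated table
#'
#' Union of all evaluated sequences across runs; exact string
#' deduplication keeps the first occurrence (run order, then
#' evaluation order).  If the same sequence carries different objective
#' vectors in different runs (possible only if model state differed),
#' the first is kept and a message reports the discrepancy count.
#'
#' @param states list of \linkS4class{RunState}.
#' @param generatedOnly if TRUE (default) keep only generated
#'   sequences, dropping the shared initial pools.
#' @return data.frame(sequence, f_mean, f_stab, f_sol, run).
#' @export
mergeRuns <- function(states, generatedOnly = TRUE) {
  if (!length(states)) stop("no runs to merge")
  tabs <- lapply(seq_along(states), function(i) {
    tab <- evaluatedTable(states[[i]])
    if (generatedOnly) tab <- tab[tab$origin == "generated", , drop = FALSE]
    if (nrow(tab)) tab$run <- i
    tab
  })
  all <- do.call(rbind, tabs)
  dupes <- duplicated(all$sequence)
  if (any(dupes)) {
    first <- all[!dupes, , drop = FALSE]
    conflict <- 0L
    idx <- match(all$sequence[dupes], first$sequence)
    for (j in seq_len(sum(dupes))) {
      a <- all[dupes, , drop = FALSE][j, objectiveNames()]
      b <- first[idx[j], objectiveNames()]
      if (any(abs(as.numeric(a) - as.numeric(b)) > 1e-12))
        conflict <- conflict + 1L
    }
    if (conflict)
      message("mergeRuns: ", conflict,
              " duplicate sequence(s) had conflicting objective ",
              "vectors; kept first occurrence")
    all <- first
  }
  rownames(all) <- NULL
  all[, c("sequence", objectiveNames(), "run")]
}
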