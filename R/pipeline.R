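#' Default run configuration
#'
#' All knobs of the end-to-end pipeline in one serializable list; a
#' saved config plus its seeds reproduces every deterministic stage
#' bit-identically.  Per-run optimization seeds are derived as
#' \code{seed_base + run index}.
#'
#' @param ... named overrides of the defaults.
#' @return named list (class "quboseq_config").
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    counts = NULL,              # path to a count table; NULL = simulate
    min_reads = 3L,
    pos_threshold = 5,
    neg_threshold = 1,
    k = 5L,
    seed_base = 100L,
    predictor = list(architecture = "logistic", hidden_size = 10L,
                     epochs = 25L, learning_rate = 0.001, l2 = 1),
    solubility = "toy",         # "toy" or "table:<path>"
    runs = 2L,
    budget = 60L,
    batch_size = 20L,
    latent_dim = 32L,
    fm_rank = 6L,
    fm_lambda = 1e-3,
    sweeps = 300L,
    synth = list(length = 12L, alphabet = c("A", "C", "D", "E"),
                 n_motif = 6L, bonus = 1.5, noise_sd = 0.1,
                 variants = 400L, reads = 40000L),
    selection = list(required_length = NULL,  # NULL = synth length
                     max_homopolymer = 5L, min_mean_score = 0.6,
                     min_solubility = -99, min_cdr_distance = 0L)
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "quboseq_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are an error; missing keys take defaults.
#'
#' @param path YAML file.
#' @return config list as from \code{\link{defaultConfig}}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- defaultConfig()
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(raw)) {
    if (is.list(base[[nm]]) && is.list(raw[[nm]])) {
      base[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      base[[nm]] <- raw[[nm]]
    }
  }
  base
}

.scorerFromConfig <- function(cfg, alphabet) {
  spec <- cfg$solubility
  if (identical(spec, "toy")) {
    if (identical(sort(alphabet), sort(aminoAcids())))
      return(toySolubilityScorer())
    ## restricted alphabets still score through the hydropathy table
    return(solubilityScorer("toy_hydropathy", toySolubility))
  }
  if (startsWith(spec, "table:"))
    return(tableScorer(sub("^table:", "", spec)))
  stop("unknown solubility scorer: ", spec)
}

#' Run the full design pipeline from a configuration
#'
#' Stages: obtain a count table (read from \code{config$counts} or
#' simulate from the configured toy landscape), score and label,
#' split negatives and train the predictor ensemble, run the
#' surrogate-guided optimization \code{runs} times with seeds
#' \code{seed_base + 1 .. seed_base + runs}, merge and deduplicate,
#' apply the selection filters and write all artifacts (CSV tables,
#' FASTA, config manifest) into \code{outDir}.
#'
#' @param config a config list (see \code{\link{defaultConfig}} /
#'   \code{\link{readRunConfig}}).
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with the labeled dataset, ensemble, run
#'   states, merged table and selection table.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, verbose = TRUE) {
  say <- function(...) if (verbose) message("[quboseq] ", ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seedBase <- as.integer(config$seed_base)

  ## stage 1: counts
  landscape <- NULL
  if (!is.null(config$counts)) {
    say("reading counts from ", config$counts)
    counts <- readCountTable(config$counts)
    alphabet <- sort(unique(unlist(
      strsplit(counts$sequence, "", fixed = TRUE))))
  } else {
    say("simulating panning counts (", config$synth$variants,
        " variants)")
    landscape <- toyLandscape(
      length = config$synth$length, alphabet = config$synth$alphabet,
      nMotif = config$synth$n_motif, bonus = config$synth$bonus,
      noiseSd = config$synth$noise_sd, seed = seedBase)
    sim <- simulatePanning(landscape, config$synth$variants,
                           config$synth$reads, seed = seedBase)
    counts <- sim$counts
    alphabet <- config$synth$alphabet
    write.csv(sim$truth, file.path(outDir, "truth.csv"),
              row.names = FALSE)
  }
  write.csv(counts, file.path(outDir, "counts.csv"), row.names = FALSE)

  ## stage 2: score, filter, label, split
  kept <- filterByReads(counts, config$min_reads)
  say(nrow(kept), "/", nrow(counts), " variants pass the read filter")
  dataset <- labelSequences(kept, config$pos_threshold,
                            config$neg_threshold)
  dataset <- splitNegatives(dataset, config$k, seed = seedBase)
  writeLabeledFasta(dataset, file.path(outDir, "labeled"))

  ## stage 3: ensemble
  pcfg <- predictorConfig(
    hidden_size = config$predictor$hidden_size,
    epochs = config$predictor$epochs,
    learning_rate = config$predictor$learning_rate,
    architecture = config$predictor$architecture,
    seed = seedBase,
    l2 = if (is.null(config$predictor$l2)) 1 else config$predictor$l2)
  say("training ", config$k, " ", pcfg$architecture, " predictors")
  ensemble <- trainEnsemble(dataset, pcfg, alphabet)
  scorer <- .scorerFromConfig(config, alphabet)

  ## stage 4: optimization runs (shared autoencoder, per-run seeds)
  ae <- trainBinaryAutoencoder(
    unique(c(positives(dataset), negatives(dataset))),
    config$latent_dim, autoencoderConfig(seed = seedBase), alphabet)
  states <- lapply(seq_len(config$runs), function(r) {
    say("optimization run ", r, "/", config$runs,
        " (seed ", seedBase + r, ")")
    optimizeSequences(dataset, ensemble, scorer,
                      budget = config$budget, seed = seedBase + r,
                      latentDim = config$latent_dim,
                      batchSize = config$batch_size,
                      rank = config$fm_rank, lambda = config$fm_lambda,
                      sweeps = config$sweeps, autoencoder = ae)
  })
  for (r in seq_along(states))
    writeArchive(runArchive(states[[r]]),
                 file.path(outDir, sprintf("run%02d", r)))
  merged <- mergeRuns(states)
  write.csv(merged, file.path(outDir, "merged.csv"), row.names = FALSE)
  gen <- Biostrings::AAStringSet(setNames(merged$sequence,
    sprintf("gen_%05d", seq_len(nrow(merged)))))
  Biostrings::writeXStringSet(gen, file.path(outDir, "generated.fasta"))
  say(nrow(merged), " unique generated sequences")

  ## stage 5: selection
  sel <- config$selection
  reqLen <- if (is.null(sel$required_length)) nchar(merged$sequence[1])
            else sel$required_length
  wt <- if (reqLen == 39L) vhhReference()$wt
        else paste(rep(alphabet[1L], reqLen), collapse = "")
  cdrLens <- if (reqLen == 39L) c(13L, 10L, 16L) else reqLen
  criteria <- selectionCriteria(
    requiredLength = reqLen, maxHomopolymer = sel$max_homopolymer,
    minMeanScore = sel$min_mean_score,
    minSolubility = sel$min_solubility,
    minCdrDistance = sel$min_cdr_distance,
    cdrLengths = cdrLens, wildType = wt)
  flags <- applyFilters(merged, criteria, ensemble, scorer)
  training <- c(positives(dataset), negatives(dataset))
  passed <- flags$sequence[flags$selected]
  if (length(passed)) {
    nov <- noveltyReport(passed, training)
    flags$min_distance <- nov$min_distance[match(flags$sequence,
                                                 nov$sequence)]
  } else flags$min_distance <- NA_integer_
  write.csv(flags, file.path(outDir, "selected.csv"), row.names = FALSE)
  say(sum(flags$selected), " candidates pass all filters")

  ## manifest
  manifest <- config
  class(manifest) <- NULL
  manifest$package_version <- as.character(utils::packageVersion("quboseq"))
  yaml::write_yaml(manifest, file.path(outDir, "config.yaml"))

  invisible(list(counts = counts, dataset = dataset,
                 ensemble = ensemble, landscape = landscape,
                 states = states, merged = merged, selection = flags))
}
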