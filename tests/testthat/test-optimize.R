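test_that("hypervolume-improvement acquisition matches inclusion-exclusion", {
  a <- newArchive(c(0, 0))
  a <- updateArchive(a, "s1", c(2, 1))
  a <- updateArchive(a, "s2", c(1, 2))
  expect_equal(acquisitionHVI(c(2, 2), a), 1)     # 4 - 3
  expect_equal(acquisitionHVI(c(0.5, 0.5), a), 0) # dominated
  empty <- newArchive(c(0, 0))
  expect_equal(acquisitionHVI(c(2, 3), empty), 6) # box volume
  expect_error(acquisitionHVI(c(1, 2, 3), a), "dimension")
})

test_that("random generation is uniform, seeded and well-formed", {
  one <- randomGenerate(1L, 5L, aminoAcids(), seed = 1L)
  expect_equal(nchar(one), 5L)
  expect_true(all(strsplit(one, "")[[1]] %in% aminoAcids()))
  expect_identical(randomGenerate(10L, 8L, seed = 3L),
                   randomGenerate(10L, 8L, seed = 3L))
  ## per-position residue frequencies within 3 sigma binomial bands
  n <- 10000L
  seqs <- randomGenerate(n, 4L, aminoAcids(), seed = 5L)
  m <- matrix(unlist(strsplit(seqs, "")), ncol = 4L, byrow = TRUE)
  p <- 1 / 20
  band <- 3 * sqrt(p * (1 - p) / n)
  for (pos in 1:4) {
    freq <- table(factor(m[, pos], levels = aminoAcids())) / n
    expect_true(all(abs(freq - p) < band + 1e-12))
  }
})

test_that("a zero budget evaluates only the initial pool", {
  rs <- suppressMessages(
    optimizeSequences(fxDataset(), fxEnsemble(), fxScorer(), budget = 0L,
            seed = 1L, latentDim = 32L, autoencoder = fxAutoencoder()))
  tab <- evaluatedTable(rs)
  expect_true(all(tab$origin == "initial"))
  expect_equal(rs@used, 0L)
  expect_gt(nrow(tab), 0L)
})

test_that("runs are deterministic and respect the budget", {
  args <- list(fxDataset(), fxEnsemble(), fxScorer(), budget = 60L,
               seed = 42L, latentDim = 32L, batchSize = 20L, rank = 4L,
               sweeps = 150L, autoencoder = fxAutoencoder())
  r1 <- suppressMessages(do.call(optimizeSequences, args))
  r2 <- suppressMessages(do.call(optimizeSequences, args))
  expect_identical(evaluatedTable(r1), evaluatedTable(r2))
  expect_identical(hvHistory(runArchive(r1)), hvHistory(runArchive(r2)))
  expect_equal(r1@used, 60L)
  expect_equal(sum(evaluatedTable(r1)$origin == "generated"), 60L)
  ## traces are monotone
  hv <- hvHistory(runArchive(r1))$hypervolume
  expect_true(all(diff(hv) >= -1e-12))
  bsf <- bestSoFar(runArchive(r1))
  expect_true(all(apply(bsf, 2, function(x) all(diff(x) >= -1e-12))))
  expect_error(optimizeSequences(fxDataset(), fxEnsemble(), fxScorer(),
                       budget = 5L, batchSize = 20L,
                       autoencoder = fxAutoencoder()),
               "batch size")
})

## fabricate a RunState directly (cheap stand-in for a full run)
mkRunState <- function(seqs, seed = 1L) {
  ov <- data.frame(sequence = seqs,
                   f_mean = seq_along(seqs) / (length(seqs) + 1),
                   f_stab = 0, f_sol = 1,
                   evaluation = seq_along(seqs), origin = "generated",
                   stringsAsFactors = FALSE)
  arch <- newArchive(c(0, -1, 0))
  for (i in seq_len(nrow(ov)))
    arch <- updateArchive(arch, ov$sequence[i],
                          as.numeric(ov[i, objectiveNames()]))
  new("RunState", evaluated = ov, archive = arch,
      budget = length(seqs), used = length(seqs), seed = seed)
}

test_that("merged runs deduplicate by exact sequence identity", {
  r1 <- mkRunState(c("AAA", "CCC", "GGG"))
  r2 <- mkRunState(c("TTT", "CCC", "NNN", "QQQ"))
  m <- suppressMessages(mergeRuns(list(r1, r2)))
  expect_equal(nrow(m), 6L)                   # CCC counted once
  expect_equal(m$run[m$sequence == "CCC"], 1L)

  ## 10 runs of 50 with planted overlap vs an independent set oracle
  set.seed(50)
  pools <- lapply(1:10, function(i) {
    fresh <- randomGenerate(40L, 6L, fxAlphabet(), seed = 100L + i)
    shared <- randomGenerate(10L, 6L, fxAlphabet(), seed = 999L)
    unique(c(fresh, shared))
  })
  states <- lapply(pools, mkRunState)
  m2 <- suppressMessages(mergeRuns(states))
  expect_equal(nrow(m2), length(unique(unlist(pools))))
  expect_error(mergeRuns(list()), "no runs")
})
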