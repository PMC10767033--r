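test_that("Hamming distance counts mismatching positions", {
  expect_equal(hammingDistance("ACD", "ACD"), 0L)
  expect_equal(hammingDistance("AAA", "AAB"), 1L)
  expect_error(hammingDistance("AA", "AAA"), "different lengths")
  set.seed(14)
  for (rep in 1:100) {
    a <- randomGenerate(1L, 10L, seed = rep)
    b <- randomGenerate(1L, 10L, seed = rep + 1000L)
    manual <- sum(substring(a, 1:10, 1:10) != substring(b, 1:10, 1:10))
    expect_equal(hammingDistance(a, b), manual)
  }
})

test_that("Hamming distance is a metric on fixed-length strings", {
  set.seed(15)
  trip <- replicate(30, randomGenerate(3L, 8L, fxAlphabet(),
                                       seed = sample.int(1e6, 1)),
                    simplify = FALSE)
  for (t in trip) {
    expect_equal(hammingDistance(t[1], t[2]), hammingDistance(t[2], t[1]))
    expect_equal(hammingDistance(t[1], t[1]), 0L)
    expect_lte(hammingDistance(t[1], t[3]),
               hammingDistance(t[1], t[2]) + hammingDistance(t[2], t[3]))
  }
})

test_that("minimum distance to a set equals an exhaustive scan", {
  expect_equal(minDistanceToSet("AAAA", c("CCCC", "AAAA")), 0L)
  expect_equal(minDistanceToSet("AAAT", "AAAA"), 1L)
  expect_error(minDistanceToSet("AAAA", character(0)), "empty")
  set.seed(16)
  pool <- unique(randomGenerate(500L, 9L, fxAlphabet(), seed = 90L))
  q <- randomGenerate(5L, 9L, fxAlphabet(), seed = 91L)
  for (s in q) {
    brute <- min(vapply(pool, hammingDistance, 0L, a = s))
    expect_equal(minDistanceToSet(s, pool), brute)
  }
})

test_that("the validated VHH variants satisfy the published constraints", {
  ref <- vhhReference()
  expect_equal(nchar(ref$wt), 39L)
  expect_equal(unname(nchar(ref$wt_cdrs)), c(13L, 10L, 16L))
  expect_true(all(nchar(ref$variants$sequence) == 39L))
  crit <- selectionCriteria()
  flags <- applyFilters(ref$variants$sequence, crit, fxVhhEnsemble(),
                        fxScorer())
  expect_true(all(flags$pass_length))          # rule 1
  expect_true(all(flags$pass_repeat))          # rule 2
  expect_true(all(flags$pass_cdr_distance))    # rule 5
})

test_that("homopolymer runs of five or more residues are rejected", {
  filler <- strrep("Y", 34)
  crit <- selectionCriteria()
  bad <- paste0("AAAAA", filler)
  good <- paste0("AAAAC", filler)   # run of 4 A then broken
  flags <- applyFilters(c(bad, good), crit, fxVhhEnsemble(), fxScorer())
  expect_false(flags$pass_repeat[1])
  ## the all-Y filler itself is a run of 34
  expect_false(flags$pass_repeat[2])
  ok <- paste(rep(c("A", "C", "D"), 13), collapse = "")
  expect_true(applyFilters(ok, crit, fxVhhEnsemble(),
                           fxScorer())$pass_repeat)
})

## independent rule-by-rule recount used against applyFilters
bruteFlags <- function(seqs, crit, ensemble, scorer) {
  sapply(seqs, function(s) {
    if (nchar(s) != crit$requiredLength) return(FALSE)
    r <- rle(strsplit(s, "")[[1]])
    if (max(r$lengths) >= crit$maxHomopolymer) return(FALSE)
    if (!(ensemblePredict(ensemble, s)$mean > crit$minMeanScore))
      return(FALSE)
    if (!(scorer@scoreFun(s) > crit$minSolubility)) return(FALSE)
    ends <- cumsum(crit$cdrLengths)
    starts <- c(1, head(ends, -1) + 1)
    for (i in seq_along(ends)) {
      dist <- hammingDistance(substr(s, starts[i], ends[i]),
                              substr(crit$wildType, starts[i], ends[i]))
      if (dist < crit$minCdrDistance) return(FALSE)
    }
    TRUE
  })
}

test_that("the filter funnel matches a brute-force recount", {
  set.seed(18)
  ens <- fxVhhEnsemble()
  sc <- fxScorer()
  wt <- vhhReference()$wt
  cand <- randomGenerate(300L, 39L, aminoAcids(), seed = 44L)
  ## plant violations: runs, near-WT sequences, wrong lengths
  plant <- function(s, p, res, k) {
    substr(s, p, p + k - 1) <- strrep(res, k); s
  }
  cand[1:30] <- vapply(cand[1:30], plant, "", p = 7L, res = "L", k = 5L)
  nearWT <- vapply(1:20, function(i) {
    s <- wt
    substr(s, i, i) <- "W"
    s
  }, "")
  cand <- c(cand, nearWT, substr(cand[31:40], 1, 20))
  crit <- selectionCriteria()
  flags <- applyFilters(cand, crit, ens, sc)
  expect_equal(flags$selected, unname(bruteFlags(cand, crit, ens, sc)))
  ## per-rule audit flags recombine into the verdict
  expect_equal(flags$selected,
               flags$pass_length & flags$pass_repeat & flags$pass_score &
                 flags$pass_solubility & flags$pass_cdr_distance)
  ## wrong length fails rather than erroring
  expect_false(any(flags$pass_length[nchar(cand) != 39]))
})

test_that("filtering is order-independent and threshold-monotone", {
  set.seed(19)
  cand <- randomGenerate(100L, 39L, aminoAcids(), seed = 55L)
  crit <- selectionCriteria()
  ens <- fxVhhEnsemble()
  f1 <- applyFilters(cand, crit, ens, fxScorer())
  perm <- sample(length(cand))
  f2 <- applyFilters(cand[perm], crit, ens, fxScorer())
  expect_equal(f2$selected, f1$selected[perm])
  ## relaxing a threshold can only grow the pass set
  relax <- selectionCriteria(minMeanScore = 0.2, minSolubility = -5,
                             minCdrDistance = 1L)
  f3 <- applyFilters(cand, relax, ens, fxScorer())
  expect_true(all(f3$selected >= f1$selected))
})

test_that("novelty reports the distance to the closest training sequence", {
  train <- randomGenerate(50L, 39L, aminoAcids(), seed = 66L)
  rep1 <- noveltyReport(train[1], train)
  expect_equal(rep1$min_distance, 0L)
  far <- paste(rep("W", 39), collapse = "")
  train2 <- gsub("W", "A", train)             # no W anywhere
  rep2 <- noveltyReport(far, train2)
  expect_equal(rep2$min_distance, 39L)
  expect_error(noveltyReport(character(0), train), "no selected")
})
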