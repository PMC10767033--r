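writeCounts <- function(df, sep = ",", ext = ".csv") {
  path <- tempfile(fileext = ext)
  lines <- c(paste("sequence", "count_eluted", "count_ns", sep = sep),
             paste(df$sequence, df$count_eluted, df$count_ns, sep = sep))
  writeLines(lines, path)
  path
}

test_that("count tables normalize frequencies per pool", {
  p <- writeCounts(data.frame(sequence = "ACDA", count_eluted = 5,
                              count_ns = 5))
  tab <- readCountTable(p)
  expect_equal(tab$freq_eluted, 1)
  expect_equal(tab$freq_ns, 1)
  expect_equal(tab$score, 1)

  p2 <- writeCounts(data.frame(sequence = c("AAAA", "CCCC"),
                               count_eluted = c(3, 1),
                               count_ns = c(2, 2)))
  tab2 <- readCountTable(p2)
  expect_equal(tab2$freq_eluted, c(0.75, 0.25))
  expect_equal(tab2$sequence, c("AAAA", "CCCC"))  # input order kept

  ## tsv path
  p3 <- writeCounts(data.frame(sequence = c("AA", "CC"),
                               count_eluted = c(1, 1),
                               count_ns = c(1, 3)), sep = "\t",
                    ext = ".tsv")
  expect_equal(readCountTable(p3)$freq_ns, c(0.25, 0.75))
})

test_that("count table errors name the offending line or sequence", {
  p <- writeCounts(data.frame(sequence = c("AA", "CC"),
                              count_eluted = c(1, -2),
                              count_ns = c(1, 1)))
  expect_error(readCountTable(p), "line 3")
  p2 <- writeCounts(data.frame(sequence = c("AA", "AA"),
                               count_eluted = c(1, 2),
                               count_ns = c(1, 1)))
  expect_error(readCountTable(p2), "duplicate sequence")
  expect_error(readCountTable(tempfile()), "not found")
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("sequence,count_eluted", "AA,1"), p3)
  expect_error(readCountTable(p3), "count_ns")
})

test_that("synthetic table frequencies sum to one per pool", {
  counts <- fxPanning()$counts
  expect_equal(sum(counts$freq_eluted), 1, tolerance = 1e-12)
  expect_equal(sum(counts$freq_ns), 1, tolerance = 1e-12)
})

test_that("read filter keeps records with more than minReads in either pool", {
  tab <- countRecords(c("AA", "CC", "GG", "TT"),
                      c(3, 4, 0, 10), c(3, 0, 4, 10))
  kept <- filterByReads(tab, 3L)
  expect_equal(kept$sequence, c("CC", "GG", "TT"))  # (3,3) removed
  expect_equal(nrow(filterByReads(tab[0, ], 3L)), 0L)

  counts <- fxPanning()$counts
  kept2 <- filterByReads(counts, 3L)
  ## brute-force row scan as an independent oracle
  manual <- sum(vapply(seq_len(nrow(counts)), function(i)
    counts$count_eluted[i] > 3 || counts$count_ns[i] > 3, logical(1)))
  expect_equal(nrow(kept2), manual)
  ## frequencies untouched by filtering
  expect_equal(kept2$freq_eluted,
               counts$freq_eluted[counts$count_eluted > 3 |
                                    counts$count_ns > 3])
})

test_that("enrichment score is the eluted/NS frequency ratio", {
  expect_equal(enrichmentScore(0.001, 0.0002), 5)
  x <- c(0.1, 0.25, 1e-6)
  expect_equal(enrichmentScore(x, x), rep(1, 3))
  expect_identical(enrichmentScore(0.004, 0), Inf)
  expect_true(is.na(enrichmentScore(0, 0)))
  expect_error(enrichmentScore(-0.1, 0.5), "non-negative")
})

test_that("labeling applies the score thresholds and drops the middle band", {
  tab <- data.frame(sequence = c("A", "B", "C", "D", "E"),
                    score = c(5, 0.99, 2, Inf, NA))
  expect_message(ds <- labelSequences(tab), "2 dropped")
  expect_setequal(positives(ds), c("A", "D"))  # Inf enrichment is positive
  expect_equal(negatives(ds), "B")

  flat <- countRecords(c("AA", "CC"), c(5, 5), c(5, 5))
  ds2 <- suppressMessages(labelSequences(flat))
  expect_length(positives(ds2), 0L)
  expect_length(negatives(ds2), 0L)
})

test_that("raising an eluted count never demotes a record", {
  ## monotonicity of label o score under recomputed frequencies
  set.seed(4)
  for (rep in 1:20) {
    ce <- sample(0:50, 8, replace = TRUE)
    cn <- sample(1:50, 8, replace = TRUE)
    tab1 <- countRecords(paste0("s", 1:8), ce, cn)
    i <- sample(8, 1)
    ce2 <- ce; ce2[i] <- ce2[i] + sample(1:20, 1)
    tab2 <- countRecords(paste0("s", 1:8), ce2, cn)
    ## the record's own enrichment score can only grow, so a positive
    ## can never become negative
    expect_gte(tab2$score[i], tab1$score[i])
  }
})

test_that("motif-bearing sequences are enriched among the positives", {
  ## permutation oracle: the fraction of high-fitness sequences among
  ## positives must beat 1000 label shuffles
  sim <- fxPanning()
  kept <- filterByReads(sim$counts)
  ds <- suppressMessages(labelSequences(kept))
  fit <- setNames(sim$truth$fitness, sim$truth$sequence)
  lab <- c(rep(1, length(positives(ds))), rep(0, length(negatives(ds))))
  f <- fit[c(positives(ds), negatives(ds))]
  hi <- f > stats::median(f)
  obs <- mean(hi[lab == 1])
  set.seed(99)
  null <- replicate(1000, mean(hi[sample(lab) == 1]))
  expect_gt(obs, stats::quantile(null, 0.99))
})

test_that("negative splits form a balanced disjoint partition", {
  ds <- new("LabeledDataset", positives = c("PP", "QQ"),
            negatives = sprintf("N%02d", 1:10))
  sp <- splitNegatives(ds, 5L, seed = 3L)
  negs <- lapply(trainingSplits(sp), function(s) s$sequence[s$label == 0])
  expect_equal(lengths(negs), rep(2L, 5))
  expect_equal(sort(unlist(negs)), sort(negatives(ds)))
  expect_equal(anyDuplicated(unlist(negs)), 0L)
  for (s in trainingSplits(sp))
    expect_true(all(positives(ds) %in% s$sequence[s$label == 1]))

  ds11 <- new("LabeledDataset", positives = "PP",
              negatives = sprintf("N%02d", 1:11))
  sizes <- vapply(trainingSplits(splitNegatives(ds11, 5L, seed = 1L)),
                  function(s) sum(s$label == 0), 0L)
  expect_equal(sort(sizes, decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
})

test_that("splitting is seed-deterministic", {
  ds <- new("LabeledDataset", positives = "PP",
            negatives = sprintf("N%02d", 1:20))
  a <- splitNegatives(ds, 4L, seed = 7L)
  b <- splitNegatives(ds, 4L, seed = 7L)
  expect_identical(trainingSplits(a), trainingSplits(b))
  c <- splitNegatives(ds, 4L, seed = 8L)
  expect_false(identical(trainingSplits(a), trainingSplits(c)))
  expect_error(splitNegatives(ds, 21L, seed = 1L), "exceeds")
  expect_error(splitNegatives(ds, 1L, seed = 1L), "at least 2")
})
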