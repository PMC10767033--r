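## a linearly separable toy: class decided by one residue at position 1
separableToy <- function(n = 40L, L = 8L, alphabet = fxAlphabet()) {
  set.seed(17)
  base <- replicate(n, paste(sample(alphabet[-1], L - 1, replace = TRUE),
                             collapse = ""))
  labels <- rep(c(1L, 0L), each = n / 2)
  seqs <- paste0(ifelse(labels == 1, "A", "C"), base)
  list(sequences = seqs, labels = labels)
}

test_that("logistic members separate a one-residue toy within 25 epochs", {
  toy <- separableToy()
  p <- trainPredictor(toy$sequences, toy$labels,
                      predictorConfig(architecture = "logistic"),
                      fxAlphabet())
  pr <- predict(p, toy$sequences)
  expect_equal(mean((pr > 0.5) == toy$labels), 1)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("predictor training is deterministic and input-checked", {
  toy <- separableToy()
  cfg <- predictorConfig(seed = 5L)
  p1 <- trainPredictor(toy$sequences, toy$labels, cfg, fxAlphabet())
  p2 <- trainPredictor(toy$sequences, toy$labels, cfg, fxAlphabet())
  expect_equal(predict(p1, toy$sequences), predict(p2, toy$sequences),
               tolerance = 1e-6)
  expect_error(trainPredictor(toy$sequences, rep(1L, 40), cfg,
                              fxAlphabet()), "single class")
  expect_error(predict(p1, "ACDE"), "length")
  expect_error(predict(p1, paste(rep("Z", 8), collapse = "")), "residue")
})

test_that("the recurrent architecture trains, stays in [0,1] and is seeded", {
  toy <- separableToy(n = 20L, L = 6L)
  cfg <- predictorConfig(architecture = "birnn", epochs = 25L,
                         learning_rate = 0.01, seed = 3L)
  p1 <- trainPredictor(toy$sequences, toy$labels, cfg, fxAlphabet())
  pr1 <- predict(p1, toy$sequences)
  expect_true(all(pr1 >= 0 & pr1 <= 1))
  expect_gt(mean((pr1 > 0.5) == toy$labels), 0.5)   # better than chance
  p2 <- trainPredictor(toy$sequences, toy$labels, cfg, fxAlphabet())
  expect_equal(pr1, predict(p2, toy$sequences), tolerance = 1e-6)
})

## helper: wrap fixed-output logistic members into an ensemble
constEnsemble <- function(outputs, L = 4L, alphabet = fxAlphabet()) {
  D <- L * length(alphabet)
  members <- lapply(outputs, function(o) {
    b <- stats::qlogis(min(max(o, 1e-12), 1 - 1e-12))
    new("SequencePredictor", architecture = "logistic",
        params = list(beta = c(b, numeric(D))),
        alphabet = alphabet, seqLength = L,
        config = predictorConfig())
  })
  new("PredictorEnsemble", members = members, alphabet = alphabet,
      seqLength = L)
}

test_that("ensemble mean and instability follow their closed forms", {
  seqs <- randomGenerate(5L, 4L, fxAlphabet(), seed = 2L)
  same <- constEnsemble(rep(0.7, 4))
  ep <- ensemblePredict(same, seqs)
  expect_equal(ep$sd, rep(0, 5))                  # identical members
  expect_equal(ep$mean, rep(0.7, 5), tolerance = 1e-9)

  both <- constEnsemble(c(0, 1))                  # k = 2, outputs {0,1}
  ep2 <- ensemblePredict(both, seqs)
  expect_equal(ep2$mean, rep(0.5, 5), tolerance = 1e-9)
  expect_equal(ep2$sd, rep(0.5, 5), tolerance = 1e-9)
  ## sample sd uses divisor k-1
  ep3 <- ensemblePredict(both, seqs, sdType = "sample")
  expect_equal(ep3$sd, rep(sqrt(0.5), 5), tolerance = 1e-9)
})

test_that("ensemble summaries equal a direct loop over members", {
  ens <- fxEnsemble()
  seqs <- randomGenerate(50L, 12L, fxAlphabet(), seed = 8L)
  ep <- ensemblePredict(ens, seqs)
  P <- sapply(members(ens), function(m) predict(m, seqs))
  expect_equal(ep$mean, rowMeans(P), tolerance = 1e-12)
  expect_equal(ep$sd, apply(P, 1, function(x)
    sqrt(mean((x - mean(x))^2))), tolerance = 1e-12)
  expect_true(all(ep$sd <= 0.5 + 1e-12))
  ## member order is irrelevant
  perm <- new("PredictorEnsemble", members = rev(members(ens)),
              alphabet = ens@alphabet, seqLength = ens@seqLength)
  ep2 <- ensemblePredict(perm, seqs)
  expect_equal(ep$mean, ep2$mean)
  expect_equal(ep$sd, ep2$sd)
})

test_that("ensemble mean tracks true fitness on held-out sequences", {
  ens <- fxEnsemble()
  held <- randomGenerate(200L, 12L, fxAlphabet(), seed = 303L)
  mu <- ensemblePredict(ens, held)$mean
  fit <- landscapeFitness(fxLandscape(), held)
  expect_gt(stats::cor(mu, fit, method = "spearman"), 0.3)
})

test_that("ensembles train one member per split", {
  ens <- fxEnsemble()
  expect_length(members(ens), 5L)
  expect_error(trainEnsemble(new("LabeledDataset", positives = "AA",
                                 negatives = c("CC", "DD"))),
               "splitNegatives")
})
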