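test_that("the agreement indicator generalizes the binary product", {
  expect_equal(agreementIndicator(2, 2), 1L)
  expect_equal(agreementIndicator(3, 1), 0L)
  # a real label never agrees with the artificial label 0
  expect_equal(agreementIndicator(1, 0), 0L)
  expect_equal(agreementIndicator(c(1, 2, 2), c(1, 0, 2)), c(1L, 0L, 1L))
})

test_that("modified predictions return 0 / the zero vector for absent samples", {
  ds <- tinyIncompleteDataset()
  v2 <- getView(ds, "v2")               # covers {b, d} only
  y <- sampleLabels(ds)
  h <- fitWeakLearner(featureMatrix(v2), y[sampleIds(v2)], c(1, 1), 2,
                      "v2", learnerSpec("tree"), seed = 1)
  n <- allSamples(ds)
  mp <- modifiedPredict(h, v2, n)
  expect_equal(unname(mp[c("a", "c")]), c(0L, 0L))
  expect_true(all(mp[c("b", "d")] %in% 1:2))
  pp <- modifiedProba(h, v2, n)
  expect_equal(unname(pp["a", ]), c(0, 0))      # zero vector, not uniform
  expect_equal(rowSums(pp)[c("b", "d")], c(b = 1, d = 1), tolerance = 1e-9)
  # on a complete view the artificial label never appears
  v1 <- getView(ds, "v1")
  h1 <- fitWeakLearner(featureMatrix(v1), y[sampleIds(v1)], rep(1, 3), 2,
                       "v1", learnerSpec("tree"), seed = 1)
  expect_true(all(modifiedPredict(h1, v1, sampleIds(v1)) != 0L))
})

test_that("the edge evaluates the weighted agreement sum", {
  w <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  y <- c(a = 1L, b = 2L, c = 1L, d = 2L)
  # correct on the first two only, complete view:
  pred <- c(a = 1L, b = 2L, c = 2L, d = 1L)
  expect_equal(computeEdge(w, pred, y), 0.4)  # 2(0.2+0.15-0.1-0.05)
  # all correct: edge equals the present weight mass (1 on a complete view)
  expect_equal(computeEdge(w, y, y), 1)
  # absent samples (artificial 0) contribute exactly nothing
  pred2 <- c(a = 1L, b = 2L, c = 0L, d = 0L)
  expect_equal(computeEdge(w, pred2, y), 0.7)
})

test_that("the weighted agreement form equals the +/-1 product exhaustively", {
  # for every labeling y and hypothesis h in {-1,+1}^n, n <= 8:
  # sum w y h == 2 sum w (I - 1/2), to machine precision
  set.seed(21)
  for (n in c(2L, 5L, 8L)) {
    w <- runif(n); w <- w / sum(w); names(w) <- paste0("s", 1:n)
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (iy in seq_len(nrow(grid))) {
      y <- grid[iy, ]
      ycode <- stats::setNames(ifelse(y > 0, 2L, 1L), names(w))
      for (ih in seq_len(nrow(grid))) {
        h <- grid[ih, ]
        hcode <- stats::setNames(ifelse(h > 0, 2L, 1L), names(w))
        expect_identical(computeEdge(w, hcode, ycode),
                         sum(w * y * h))
      }
    }
  }
})

test_that("the vote weight is the half log odds of the clipped edge", {
  expect_equal(computeAlpha(0), 0)
  expect_equal(computeAlpha(0.4), 0.5 * log(1.4 / 0.6))  # ~0.4236
  a1 <- computeAlpha(1)
  expect_true(is.finite(a1) && a1 > 11)  # clipped, large but finite
  expect_equal(computeAlpha(-0.4), -computeAlpha(0.4))
})

test_that("weight updates reweight present samples and renormalize", {
  w <- c(a = 0.5, b = 0.5)
  y <- c(a = 1L, b = 2L)
  pred <- c(a = 1L, b = 1L)            # a correct, b wrong
  w2 <- updateWeights(w, 0.5, pred, y)
  expect_equal(unname(w2), c(exp(-0.5), exp(0.5)) /
                 (exp(-0.5) + exp(0.5)), tolerance = 1e-12)
  expect_equal(round(unname(w2), 4), c(0.2689, 0.7311))
  # alpha = 0 leaves weights unchanged
  expect_equal(updateWeights(w, 0, pred, y), w)
  # an absent sample's weight changes only through renormalization
  w3 <- c(a = 0.25, b = 0.25, c = 0.5)
  y3 <- c(a = 1L, b = 2L, c = 1L)
  pred3 <- c(a = 1L, b = 2L, c = 0L)   # c absent from the winning view
  w4 <- updateWeights(w3, 0.7, pred3, y3)
  expect_equal(sum(w4), 1, tolerance = 1e-12)
  # c's weight relative to total scaled only by the normalizer
  expect_equal(unname(w4["c"]),
               0.5 / (0.25 * exp(-0.7) * 2 + 0.5), tolerance = 1e-12)
})

test_that("a single-view fit selects that view every round", {
  ds <- restrictToSamples(completeBinaryDataset(n = 30, K = 1, seed = 2),
                          sprintf("s%03d", 1:30))
  ens <- fitIrboost(ds, T = 8, spec = learnerSpec("tree"), seed = 1)
  expect_equal(unname(winnerCounts(ens)), 8L)
  expect_equal(sum(winnerCounts(ens)), nRounds(ens))
})

test_that("fits are bit-reproducible under a fixed seed", {
  ds <- completeBinaryDataset(n = 40, K = 2, seed = 5)
  e1 <- fitIrboost(ds, T = 6, spec = learnerSpec("rf", 10), seed = 9)
  e2 <- fitIrboost(ds, T = 6, spec = learnerSpec("rf", 10), seed = 9)
  expect_identical(banditTrace(e1), banditTrace(e2))
  expect_identical(e1@weightTrace, e2@weightTrace)
  p1 <- predictEnsemble(e1, ds)
  p2 <- predictEnsemble(e2, ds)
  expect_identical(p1$score, p2$score)
})

test_that("shared weights stay a distribution through every iteration", {
  ds <- simulateMultiView(n = 40, C = 3, q = c(4, 4), s = c(2, 1),
                          m = c(0.25, 0.25), seed = 13)
  ens <- fitIrboost(ds, T = 12, spec = learnerSpec("tree"), seed = 4)
  expect_true(all(abs(rowSums(ens@weightTrace) - 1) < 1e-12))
  expect_true(all(ens@weightTrace >= 0))
  expect_true(all(abs(rowSums(ens@probTrace) - 1) < 1e-12))
  expect_true(all(abs(banditTrace(ens)$edge) <= 1 + 1e-12))
})

test_that("ensemble prediction combines probability vectors by vote weight", {
  ds <- tinyIncompleteDataset()
  # hand-built ensemble: one constant hypothesis per view
  h1 <- new("WeakHypothesis", viewId = "v1", model = NULL, method = "tree",
            nClasses = 2L, featureIds = c("f1", "f2"), constant = 1L)
  h2 <- new("WeakHypothesis", viewId = "v2", model = NULL, method = "tree",
            nClasses = 2L, featureIds = c("g1", "g2", "g3"), constant = 2L)
  mkRound <- function(t, h, alpha)
    new("WeakRound", t = t, viewId = h@viewId, hypothesis = h,
        edge = 0.5, alpha = alpha)
  ens <- new("Ensemble",
             rounds = list(mkRound(1L, h1, 1), mkRound(2L, h2, 3)),
             type = "irboost", nClasses = 2L, encoding = ds@encoding,
             viewIds = c("v1", "v2"),
             winnerCounts = c(v1 = 1L, v2 = 1L), T = 2L,
             sigma = 0.15, gamma = 0.3,
             trace = data.frame(), probTrace = matrix(0, 0, 2),
             weightTrace = matrix(0, 0, 4))
  pr <- predictEnsemble(ens, ds)
  # 'a','c' see only view 1 (class 1); 'd' only view 2 (class 2);
  # 'b' sees both, and alpha 3 > 1 tips it to class 2
  expect_equal(unname(pr$code[c("a", "b", "c", "d")]), c(1L, 2L, 1L, 2L))
  expect_equal(unname(pr$score["b", ]), c(0.25, 0.75))
  # scores renormalized to sum 1 per sample
  expect_equal(unname(rowSums(pr$score)), rep(1, 4))
  # equal-alpha tie goes to the smallest class index
  ensTie <- ens
  ensTie@rounds[[2]]@alpha <- 1
  expect_equal(unname(predictEnsemble(ensTie, ds)$code[["b"]]), 1L)
})

test_that("a sample absent from a view is untouched by that view's rounds", {
  ds <- tinyIncompleteDataset()
  h2 <- new("WeakHypothesis", viewId = "v2", model = NULL, method = "tree",
            nClasses = 2L, featureIds = c("g1", "g2", "g3"), constant = 2L)
  ens <- new("Ensemble",
             rounds = list(new("WeakRound", t = 1L, viewId = "v2",
                               hypothesis = h2, edge = 0.5, alpha = 1)),
             type = "irboost", nClasses = 2L, encoding = ds@encoding,
             viewIds = c("v1", "v2"),
             winnerCounts = c(v1 = 0L, v2 = 1L), T = 1L,
             sigma = 0.15, gamma = 0.3,
             trace = data.frame(), probTrace = matrix(0, 0, 2),
             weightTrace = matrix(0, 0, 4))
  # 'a' and 'c' are absent from v2, the only voting view -> unpredictable
  expect_error(predictEnsemble(ens, ds), "unpredictable.*a.*c")
})

test_that("the binary predecessor matches hand properties", {
  ds <- completeBinaryDataset(n = 50, K = 2, seed = 31)
  expect_error(fitRboostBinary(tinyIncompleteDataset(), T = 2),
               "incomplete")
  ds3 <- simulateMultiView(n = 30, C = 3, q = c(3, 3), s = c(2, 2),
                           m = c(0, 0), seed = 1)
  expect_error(fitRboostBinary(ds3, T = 2), "binary-only")
  ens <- fitRboostBinary(ds, T = 10, spec = learnerSpec("tree"), seed = 2)
  pr <- predictEnsemble(ens, ds)
  expect_null(pr$score)                # labels only, no confidence
  # a separable single view drives training error to zero quickly
  sep <- simulateMultiView(n = 40, C = 2, q = 2, s = 8, m = 0, seed = 3)
  es <- fitRboostBinary(sep, T = 10, spec = learnerSpec("tree"), seed = 1)
  prs <- predictEnsemble(es, sep)
  expect_equal(mean(prs$code[allSamples(sep)] != sampleLabels(sep)), 0)
})

test_that("flipping all binary labels leaves the accuracy unchanged", {
  ds <- completeBinaryDataset(n = 40, K = 2, seed = 17)
  flipped <- assembleDataset(
    views(ds),
    stats::setNames(c("2", "1")[sampleLabels(ds)], allSamples(ds)))
  e1 <- fitRboostBinary(ds, T = 8, spec = learnerSpec("tree"), seed = 6)
  e2 <- fitRboostBinary(flipped, T = 8, spec = learnerSpec("tree"),
                        seed = 6)
  a1 <- mean(predictEnsemble(e1, ds)$code[allSamples(ds)] ==
               sampleLabels(ds))
  a2 <- mean(predictEnsemble(e2, flipped)$code[allSamples(flipped)] ==
               sampleLabels(flipped))
  expect_equal(a1, a2)
})

test_that("winner frequency tracks view informativeness (stump learner)", {
  shares <- vapply(1:10, function(i) {
    ds <- simulateMultiView(n = 150, C = 2, q = c(8, 8), s = c(2.5, 0),
                            m = c(0, 0), seed = 400 + i)
    ens <- fitIrboost(ds, T = 30, spec = learnerSpec("tree", maxdepth = 1),
                      seed = i)
    winnerCounts(ens)[["view1"]] / nRounds(ens)
  }, numeric(1))
  expect_gt(mean(shares), 0.5)
})
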