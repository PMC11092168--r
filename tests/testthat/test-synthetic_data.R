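test_that("the generator covers every sample and is seed-deterministic", {
  ds <- simulateMultiView(n = 60, C = 3, q = c(5, 4), s = c(2, 1),
                          m = c(0.4, 0.4), seed = 7)
  mask <- membershipMask(ds)
  expect_equal(ncol(mask), 60L)
  expect_true(all(colSums(mask) >= 1L))   # no orphan samples
  expect_true(any(!mask))                 # missingness actually happened
  expect_equal(length(allSamples(ds)), 60L)
  ds2 <- simulateMultiView(n = 60, C = 3, q = c(5, 4), s = c(2, 1),
                           m = c(0.4, 0.4), seed = 7)
  expect_identical(featureMatrix(getView(ds, "view1")),
                   featureMatrix(getView(ds2, "view1")))
  expect_identical(sampleLabels(ds), sampleLabels(ds2))
  ds3 <- simulateMultiView(n = 60, C = 3, q = c(5, 4), s = c(2, 1),
                           m = c(0.4, 0.4), seed = 8)
  expect_false(identical(featureMatrix(getView(ds, "view1")),
                         featureMatrix(getView(ds3, "view1"))))
})

test_that("class draws follow the requested balance within 3 SE", {
  ds <- simulateMultiView(n = 3000, C = 2, q = c(2, 2), s = c(0, 0),
                          m = c(0, 0), balance = c(0.7, 0.3), seed = 3)
  f1 <- mean(sampleLabels(ds) == 1L)
  expect_lt(abs(f1 - 0.7), 3 * sqrt(0.7 * 0.3 / 3000))
})

test_that("the ground-truth record reconstructs the dataset exactly", {
  ds <- simulateMultiView(n = 50, C = 2, q = c(3, 3), s = c(2, 2),
                          m = c(0.3, 0.3), seed = 11)
  truth <- ds@metadata$truth
  ds2 <- applyMasks(truth)
  expect_identical(featureMatrix(getView(ds2, "view1")),
                   featureMatrix(getView(ds, "view1")))
  expect_identical(featureMatrix(getView(ds2, "view2")),
                   featureMatrix(getView(ds, "view2")))
  expect_identical(membershipMask(ds2), membershipMask(ds))
  # full matrices cover all n samples; masks select the present rows
  expect_equal(nrow(truth$fullMatrices[[1]]), 50L)
  expect_equal(sum(truth$mask[, 1]),
               nrow(featureMatrix(getView(ds, "view1"))))
})

test_that("the count model emits nonnegative integers", {
  ds <- simulateMultiView(n = 40, C = 2, q = c(6, 6), s = c(2, 0),
                          m = c(0, 0), countModel = TRUE, seed = 5)
  m <- featureMatrix(getView(ds, "view1"))
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
})

test_that("complementary mode shifts only class j in view j", {
  ds <- simulateMultiView(n = 30, C = 3, q = c(4, 4), s = c(3, 3),
                          m = c(0, 0), complementary = TRUE, seed = 2)
  mu <- ds@metadata$truth$means
  expect_equal(mu[[1]][1, 1], 3)
  expect_equal(mu[[1]][2:3, ], matrix(0, 2, 4))
  expect_equal(mu[[2]][2, 1], 3)
  expect_error(simulateMultiView(n = 20, C = 4, q = c(3, 3), s = c(2, 2),
                                 complementary = TRUE, seed = 1),
               "C <= K \\+ 1")
})

test_that("the prescribed two-view membership structure is exact", {
  ds <- makeIncompleteTwoView(198, 4, 56, seed = 3)
  mask <- membershipMask(ds)
  expect_equal(unname(rowSums(mask)), c(254, 60))   # |N_1|, |N_2|
  expect_equal(ncol(mask), 258L)                    # |N|
  expect_equal(sum(mask["view1", ] & mask["view2", ]), 56L)
  # edge cases: fully overlapping (complete) and fully disjoint
  comp <- makeIncompleteTwoView(0, 0, 20, seed = 1)
  expect_true(all(membershipMask(comp)))
  disj <- makeIncompleteTwoView(10, 10, 0, seed = 1)
  expect_false(any(membershipMask(disj)["view1", ] &
                     membershipMask(disj)["view2", ]))
})

test_that("an informative view beats a noise view by a wide margin", {
  ds <- simulateMultiView(n = 300, C = 2, q = c(8, 8), s = c(3, 0),
                          m = c(0, 0), seed = 21)
  plan <- makeFolds(ds, k = 5, seed = 1)
  accOf <- function(v)
    evaluateMethod(ds, plan, "rf-sv", view = v,
                   spec = learnerSpec("rf", 30), seed = 2)$pooled[["accuracy"]]
  a1 <- accOf("view1"); a2 <- accOf("view2")
  expect_gt(a1 - a2, 20)
  # and the informative view does not beat its analytic ceiling by much
  expect_lt(a1, 100 * bayesAccuracy(3) + 5)
})

test_that("the analytic accuracy ceiling has its closed form", {
  expect_equal(bayesAccuracy(0), 0.5)
  expect_equal(bayesAccuracy(2.5), pnorm(1.25))
  expect_gt(bayesAccuracy(4), bayesAccuracy(2))
})
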