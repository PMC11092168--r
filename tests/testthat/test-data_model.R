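test_that("view tables parse from TSV/CSV in either orientation", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2",
               "a\t1\t4", "b\t2\t5", "c\t3\t6"), tf)
  v <- readViewTable(tf, viewId = "v1")
  expect_s4_class(v, "ViewTable")
  expect_equal(dim(v), c(3L, 2L))
  expect_equal(sampleIds(v), c("a", "b", "c"))
  expect_equal(featureMatrix(v)["b", "f2"], 5)

  # transposed file with features as rows yields the identical table
  tt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ta\tb\tc",
               "f1\t1\t2\t3", "f2\t4\t5\t6"), tt)
  vt <- readViewTable(tt, viewId = "v1", orientation = "features_as_rows")
  expect_identical(featureMatrix(vt), featureMatrix(v))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f2", "a,1,4", "b,2,5", "c,3,6"), csv)
  expect_identical(featureMatrix(readViewTable(csv, dialect = "csv")),
                   featureMatrix(v))
})

test_that("parse errors name the offending cell and duplicate ids fail", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tf1", "a\t1", "b\tNOPE"), bad)
  expect_error(readViewTable(bad), "NOPE.*row 'b'.*column 'f1'")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tf1", "a\t1", "a\t2"), dup)
  expect_error(readViewTable(dup), "duplicate sample identifier")
})

test_that("in-row missing values are rejected, never imputed", {
  m <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("a", "b"), c("f", "g")))
  expect_error(ViewTable("v", m), "non-finite")
})

test_that("read/write round-trips a view table", {
  v <- countTable()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeViewTable(v, tf)
  v2 <- readViewTable(tf, viewId = "otu")
  expect_equal(featureMatrix(v2), featureMatrix(v), tolerance = 1e-9)
  # and with real-valued entries
  set.seed(1)
  vr <- ViewTable("r", matrix(rnorm(12), 3,
                              dimnames = list(c("x", "y", "z"),
                                              paste0("f", 1:4))))
  writeViewTable(vr, tf)
  expect_equal(featureMatrix(readViewTable(tf, viewId = "r")),
               featureMatrix(vr), tolerance = 1e-9)
})

test_that("BIOM tables are accepted and converted on read", {
  m <- matrix(c(1, 0, 3, 2, 5, 0), nrow = 2,
              dimnames = list(c("otu1", "otu2"), c("a", "b", "c")))
  b <- biomformat::make_biom(m)
  tf <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, tf)
  v <- readViewTable(tf, viewId = "bm", dialect = "biom")
  expect_equal(sort(sampleIds(v)), c("a", "b", "c"))
  # column-major fill: otu1 column is (1, 3, 5) over samples (a, b, c)
  expect_equal(featureMatrix(v)["b", "otu1"], 3)
  expect_equal(featureMatrix(v)["c", "otu1"], 5)
})

test_that("assembly computes the union and membership masks", {
  ds <- tinyIncompleteDataset()
  expect_equal(allSamples(ds), c("a", "b", "c", "d"))
  mask <- membershipMask(ds)
  expect_equal(unname(mask["v1", ]), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(mask["v2", ]), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(rowSums(mask), c(v1 = 3, v2 = 2))  # |N_j| ones per mask
  # labels encoded 1..C with round-trip to external labels
  expect_equal(sort(unique(sampleLabels(ds))), c(1L, 2L))
  expect_equal(unname(sampleLabels(ds, external = TRUE)),
               c("ctrl", "case", "ctrl", "case"))
})

test_that("degenerate assemblies behave: single view, disjoint views", {
  v1 <- ViewTable("only", matrix(1:4, 2, dimnames = list(c("a", "b"),
                                                         c("f1", "f2"))))
  ds1 <- assembleDataset(list(v1), c(a = "x", b = "y"))
  expect_equal(allSamples(ds1), c("a", "b"))
  va <- ViewTable("va", matrix(1, 1, 1, dimnames = list("a", "f")))
  vb <- ViewTable("vb", matrix(2, 1, 1, dimnames = list("b", "f")))
  ds2 <- assembleDataset(list(va, vb), c(a = "x", b = "y"))
  expect_equal(length(allSamples(ds2)), 2L)
  expect_false(any(membershipMask(ds2)["va", ] &
                   membershipMask(ds2)["vb", ]))
})

test_that("assembly rejects unlabeled samples and empty views", {
  v1 <- ViewTable("v", matrix(1:4, 2, dimnames = list(c("a", "b"), c("f", "g"))))
  expect_error(assembleDataset(list(v1), c(a = "x")), "unlabeled.*b")
})

test_that("restriction is idempotent and reproduces paired-cohort settings", {
  ds <- tinyIncompleteDataset()
  expect_equal(allSamples(restrictToSamples(ds, allSamples(ds))),
               allSamples(ds))
  # keep = N_1: the second view restricted to samples also in view 1
  n1 <- sampleIds(getView(ds, "v1"))
  r1 <- restrictToSamples(ds, n1)
  expect_equal(allSamples(r1), n1)
  expect_equal(sampleIds(getView(r1, "v2")), "b")
  # keep = N_1 intersect N_2: complete-view subset
  r3 <- restrictToSamples(ds, intersect(n1, sampleIds(getView(ds, "v2"))))
  expect_true(all(membershipMask(r3)))
  # idempotence
  r1b <- restrictToSamples(r1, n1)
  expect_identical(membershipMask(r1b), membershipMask(r1))
  # views that become empty are retained (K unchanged) and flagged
  expect_message(r4 <- restrictToSamples(ds, c("a", "c")),
                 "empty after restriction")
  expect_equal(nViews(r4), 2L)
  expect_equal(nrow(featureMatrix(getView(r4, "v2"))), 0L)
  expect_error(restrictToSamples(ds, "zz"), "no samples")
})

test_that("label encoding round-trips and reserves code 0", {
  enc <- encodeLabels(c("b", "a", "c", "a"))
  expect_equal(decode(enc, encode(enc, c("c", "a", "b"))),
               c("c", "a", "b"))
  expect_true(is.na(decode(enc, 0L)))
  expect_error(encode(enc, "zz"), "unknown class label")
})

test_that("dataset writer and manifest reader round-trip", {
  ds <- tinyIncompleteDataset()
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  ds2 <- readDataset(file.path(dir, "manifest.json"))
  expect_equal(allSamples(ds2), allSamples(ds))
  expect_equal(sampleLabels(ds2, external = TRUE),
               sampleLabels(ds, external = TRUE))
  expect_equal(featureMatrix(getView(ds2, "v2")),
               featureMatrix(getView(ds, "v2")), tolerance = 1e-9)
  expect_error(readManifest(withr::local_tempfile(lines = "{}",
                                                  fileext = ".json")),
               "'views'")
})
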