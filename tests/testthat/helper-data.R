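# Shared in-code fixtures: tiny hand-checkable datasets.

# Two views over {a,b,c} and {b,d}: the canonical incomplete layout.
tinyIncompleteDataset <- function() {
  v1 <- ViewTable("v1", matrix(
    c(1, 2, 3, 4, 5, 6), nrow = 3,
    dimnames = list(c("a", "b", "c"), c("f1", "f2"))))
  v2 <- ViewTable("v2", matrix(
    c(7, 8, 9, 10, 11, 12), nrow = 2,
    dimnames = list(c("b", "d"), c("g1", "g2", "g3"))))
  assembleDataset(list(v1, v2),
                  c(a = "ctrl", b = "case", c = "ctrl", d = "case"))
}

# A complete two-class dataset with separable structure, labels 1/2.
completeBinaryDataset <- function(n = 40, K = 2, q = 3, seed = 1) {
  simulateMultiView(n = n, C = 2, q = rep(q, K), s = rep(2.5, K),
                    m = rep(0, K), seed = seed)
}

# A small OTU-like count table for filter tests.
countTable <- function() {
  m <- matrix(c(
    0, 3, 0, 0, 9,   # otuA present in 2/5
    1, 1, 1, 1, 1,   # otuB present in 5/5
    0, 0, 0, 0, 4,   # otuC present in 1/5
    2, 0, 5, 0, 0),  # otuD present in 2/5
    nrow = 5,
    dimnames = list(paste0("s", 1:5), c("otuA", "otuB", "otuC", "otuD")))
  ViewTable("otu", m)
}
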