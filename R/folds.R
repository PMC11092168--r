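#' Build a leakage-free cross-validation fold plan
#'
#' Assigns every sample of N to exactly one of `k` folds. Because a sample
#' may appear in several views, an independent per-view split would let the
#' same individual sit in the training set through one view and in the test
#' set through another; a single global assignment rules that out. Subject
#' to that, the assignment is chosen so that the split induced within every
#' view is near-equal-sized (fold sizes differing by at most 1) and
#' class-stratified: samples are grouped by (view-membership pattern,
#' class), shuffled within groups, and dealt greedily to the fold that
#' currently carries the fewest samples of the relevant views, followed by
#' a repair pass that moves samples between extreme folds until every
#' view's spread is at most 1 (or no admissible move remains).
#'
#' @param ds a [MultiViewDataset-class].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @export
makeFolds <- function(ds, k = 10L, seed = 1L) {
  stopifnot(is(ds, "MultiViewDataset"))
  k <- as.integer(k)
  n <- allSamples(ds)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > length(n)) stop("more folds than samples")
  y <- sampleLabels(ds)
  if (any(table(y) < k))
    warning("some class has fewer than k samples; stratification relaxed")
  set.seed(as.integer(seed))
  mask <- t(membershipMask(ds))            # samples x views
  K <- ncol(mask)
  pattern <- apply(mask, 1L, paste, collapse = "")
  counts <- matrix(0L, K, k)               # per-view per-fold sizes
  clsCounts <- matrix(0L, max(y), k)
  tot <- integer(k)
  assign <- stats::setNames(integer(length(n)), n)
  groups <- split(n, list(pattern, y[n]), drop = TRUE)
  groups <- groups[order(-lengths(groups))]
  for (g in groups) {
    g <- sample(g)
    for (id in g) {
      vs <- which(mask[id, ])
      cost <- colSums(counts[vs, , drop = FALSE])
      best <- which(cost == min(cost))
      if (length(best) > 1L) {
        cc <- clsCounts[y[[id]], best]
        best <- best[cc == min(cc)]
        if (length(best) > 1L) {
          tt <- tot[best]
          best <- best[tt == min(tt)][1L]
        } else best <- best[1L]
      }
      assign[id] <- best
      counts[vs, best] <- counts[vs, best] + 1L
      clsCounts[y[[id]], best] <- clsCounts[y[[id]], best] + 1L
      tot[best] <- tot[best] + 1L
    }
  }
  # repair pass: equalize each view's induced fold sizes
  spread <- function(v) max(counts[v, ]) - min(counts[v, ])
  for (pass in seq_len(50L)) {
    moved <- FALSE
    for (v in seq_len(K)) {
      while (spread(v) > 1L) {
        hi <- which.max(counts[v, ]); lo <- which.min(counts[v, ])
        cand <- names(assign)[assign == hi & mask[, v]]
        # prefer a candidate whose move does not worsen any other view
        ok <- vapply(cand, function(id) {
          vs <- setdiff(which(mask[id, ]), v)
          all(counts[vs, hi] >= counts[vs, lo])
        }, logical(1))
        pick <- if (any(ok)) cand[ok][1L] else cand[1L]
        if (!length(pick) || is.na(pick)) break
        vs <- which(mask[pick, ])
        counts[vs, hi] <- counts[vs, hi] - 1L
        counts[vs, lo] <- counts[vs, lo] + 1L
        clsCounts[y[[pick]], hi] <- clsCounts[y[[pick]], hi] - 1L
        clsCounts[y[[pick]], lo] <- clsCounts[y[[pick]], lo] + 1L
        tot[hi] <- tot[hi] - 1L; tot[lo] <- tot[lo] + 1L
        assign[pick] <- lo
        moved <- TRUE
      }
    }
    if (!moved) break
    if (all(vapply(seq_len(K), spread, integer(1)) <= 1L)) break
  }
  new("FoldPlan", assignment = assign, k = k, seed = as.integer(seed))
}

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d samples in %d folds (seed %d)\n",
              length(object@assignment), object@k, object@seed))
  print(table(object@assignment))
})

#' Train/test sample ids of one fold
#'
#' @param plan a [FoldPlan-class].
#' @param fold fold index in 1..k.
#' @return list with `train` and `test` character vectors.
#' @export
foldSplit <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"), fold >= 1L, fold <= plan@k)
  a <- plan@assignment
  list(train = names(a)[a != fold], test = names(a)[a == fold])
}

#' Audit a fold plan for leakage and balance
#'
#' Checks that every sample has exactly one fold (so it can never be in
#' train and test simultaneously in any view) and reports, per view, the
#' induced fold sizes and their spread.
#'
#' @param ds the [MultiViewDataset-class] the plan was built for.
#' @param plan a [FoldPlan-class].
#' @return data.frame with one row per view: `view`, `n`, `minFold`,
#'   `maxFold`, `spread`.
#' @export
auditFolds <- function(ds, plan) {
  a <- plan@assignment
  stopifnot(setequal(names(a), allSamples(ds)))
  out <- lapply(views(ds), function(v) {
    f <- a[sampleIds(v)]
    sz <- tabulate(f, plan@k)
    data.frame(view = viewId(v), n = length(f), minFold = min(sz),
               maxFold = max(sz), spread = max(sz) - min(sz))
  })
  do.call(rbind, out)
}
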