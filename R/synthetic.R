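#' Simulate a multi-view, multi-class dataset with incomplete views
#'
#' Generates K views of the same n samples. Class labels are drawn from
#' `balance`; each view's present samples are drawn from class-conditional
#' spherical Gaussians (noise SD 1) whose class means are placed so that
#' every pair of class means is `s[j]` noise-SDs apart; `s[j] = 0` yields a
#' label-independent pure-noise view. Per-view missingness is sampled
#' independently at rate `m[j]`, under the constraint that every sample
#' remains present in at least one view (violators are reassigned to one
#' uniformly chosen view). Deterministic under `seed`.
#'
#' Two variants: `complementary = TRUE` makes view j informative only about
#' class j versus the rest (its features separate class j from all others,
#' requiring `C <= K + 1`), so no single view can solve the task but the
#' views jointly can — the structural situation in which multi-view
#' learning is guaranteed an advantage. `countModel = TRUE` emits
#' negative-binomial counts (size 2, class-dependent means) instead of
#' Gaussians, for sparse OTU-table-like fixtures.
#'
#' The ground-truth record (class means, the pre-mask full matrices, the
#' missingness masks and the generator arguments) is stored in the result's
#' `metadata$truth`, sufficient e.g. to recompute the Bayes-optimal
#' accuracy of a view analytically (see [bayesAccuracy()]).
#'
#' @param n number of samples.
#' @param C number of classes (labels 1..C).
#' @param q integer vector of per-view feature counts.
#' @param s numeric vector of per-view signal strengths (class-mean
#'   separation in noise-SD units), >= 0.
#' @param m numeric vector of per-view missingness fractions in [0, 1).
#' @param balance class-probability vector (default balanced).
#' @param complementary one-vs-rest complementary views (see above).
#' @param countModel negative-binomial counts instead of Gaussians.
#' @param seed integer seed.
#' @return a [MultiViewDataset-class] with `metadata$truth`.
#' @examples
#' ds <- simulateMultiView(n = 100, C = 2, q = c(5, 5), s = c(2.5, 0),
#'                         m = c(0.3, 0.3), seed = 42)
#' ds
#' @export
simulateMultiView <- function(n, C = 2L, q = c(10L, 10L), s = c(2, 2),
                              m = rep(0, length(q)),
                              balance = rep(1 / C, C),
                              complementary = FALSE, countModel = FALSE,
                              seed = 1L) {
  K <- length(q)
  stopifnot(length(s) == K, length(m) == K, n >= 2L, C >= 2L,
            all(s >= 0), all(m >= 0), all(m < 1),
            abs(sum(balance) - 1) < 1e-8)
  if (complementary && C > K + 1L)
    stop("complementary mode needs C <= K + 1")
  if (!complementary && !countModel && any(q < C & s > 0))
    stop("each informative Gaussian view needs q >= C features")
  set.seed(as.integer(seed))
  ids <- sprintf("s%03d", seq_len(n))
  y <- sample.int(C, n, replace = TRUE, prob = balance)
  names(y) <- ids
  viewsFull <- vector("list", K)
  means <- vector("list", K)
  for (j in seq_len(K)) {
    mu <- matrix(0, C, q[j])
    if (s[j] > 0) {
      if (complementary) {
        # view j separates class j from the rest along its first feature
        mu[j, 1L] <- s[j]
      } else {
        # simplex-like placement: pairwise mean distance = s[j]
        mu[cbind(seq_len(C), seq_len(C))] <- s[j] / sqrt(2)
      }
    }
    if (countModel) {
      base <- 5
      lam <- base * exp(mu[y, , drop = FALSE] / 2)
      x <- matrix(stats::rnbinom(n * q[j], size = 2, mu = as.vector(lam)),
                  n, q[j])
    } else {
      x <- mu[y, , drop = FALSE] +
        matrix(stats::rnorm(n * q[j]), n, q[j])
    }
    dimnames(x) <- list(ids, sprintf("v%d_f%d", j, seq_len(q[j])))
    viewsFull[[j]] <- x
    means[[j]] <- mu
  }
  # per-view missingness, with full coverage guaranteed
  mask <- matrix(TRUE, n, K, dimnames = list(ids, NULL))
  for (j in seq_len(K))
    if (m[j] > 0) mask[, j] <- stats::runif(n) >= m[j]
  orphan <- which(rowSums(mask) == 0L)
  for (i in orphan) mask[i, sample.int(K, 1L)] <- TRUE
  views <- lapply(seq_len(K), function(j)
    ViewTable(paste0("view", j),
              viewsFull[[j]][mask[, j], , drop = FALSE]))
  truth <- list(n = n, C = C, q = q, s = s, m = m, balance = balance,
                complementary = complementary, countModel = countModel,
                seed = seed, labels = y, means = means,
                fullMatrices = viewsFull, mask = mask)
  assembleDataset(views, y, metadata = list(truth = truth))
}

#' Rebuild a simulated dataset from (possibly perturbed) full matrices
#'
#' Applies the stored missingness masks of a simulated dataset's
#' ground-truth record to a set of full matrices, reproducing the
#' `MultiViewDataset`. Used to audit incompleteness locality: perturbing a
#' full matrix only at masked (absent) rows yields a bit-identical dataset,
#' so no downstream quantity can change.
#'
#' @param truth the `metadata$truth` record of [simulateMultiView()].
#' @param fullMatrices list of full matrices (default: the stored ones).
#' @return a [MultiViewDataset-class].
#' @export
applyMasks <- function(truth, fullMatrices = truth$fullMatrices) {
  views <- lapply(seq_along(fullMatrices), function(j)
    ViewTable(paste0("view", j),
              fullMatrices[[j]][truth$mask[, j], , drop = FALSE]))
  assembleDataset(views, truth$labels, metadata = list(truth = truth))
}

#' Two-view dataset with a prescribed membership structure
#'
#' Builds a two-view dataset in which `nOnly1` samples appear only in the
#' first view, `nOnly2` only in the second, and `nOverlap` in both — the
#' membership structure of paired 16S/shotgun cohorts, where a large
#' amplicon view overlaps a much smaller whole-genome view, at arbitrary
#' scale. Features are drawn as in [simulateMultiView()].
#'
#' @param nOnly1,nOnly2,nOverlap nonnegative sample counts per membership
#'   cell (at least one sample overall; each view non-empty).
#' @param C,q,s,balance,seed as in [simulateMultiView()].
#' @return a [MultiViewDataset-class] with
#'   `|N_1| = nOnly1 + nOverlap`, `|N_2| = nOnly2 + nOverlap`,
#'   `|N| = nOnly1 + nOnly2 + nOverlap`.
#' @examples
#' ds <- makeIncompleteTwoView(198, 4, 56, seed = 3)
#' rowSums(membershipMask(ds))
#' @export
makeIncompleteTwoView <- function(nOnly1, nOnly2, nOverlap, C = 2L,
                                  q = c(10L, 10L), s = c(2, 2),
                                  balance = rep(1 / C, C), seed = 1L) {
  stopifnot(nOnly1 >= 0, nOnly2 >= 0, nOverlap >= 0, length(q) == 2L,
            length(s) == 2L)
  n <- nOnly1 + nOnly2 + nOverlap
  if (n < 2L) stop("at least two samples are required")
  if (nOnly1 + nOverlap == 0L || nOnly2 + nOverlap == 0L)
    stop("each view must contain at least one sample")
  ds <- simulateMultiView(n = n, C = C, q = q, s = s, m = c(0, 0),
                          balance = balance, seed = seed)
  ids <- allSamples(ds)
  in1 <- c(rep(TRUE, nOnly1), rep(FALSE, nOnly2), rep(TRUE, nOverlap))
  in2 <- c(rep(FALSE, nOnly1), rep(TRUE, nOnly2), rep(TRUE, nOverlap))
  truth <- ds@metadata$truth
  truth$mask <- cbind(in1, in2)
  rownames(truth$mask) <- ids
  truth$m <- c(mean(!in1), mean(!in2))
  applyMasks(truth)
}

#' Bayes-optimal accuracy of a Gaussian view
#'
#' For the two-class spherical-Gaussian generator with class-mean separation
#' `s` (in noise-SD units) and balanced classes, the Bayes error is
#' \eqn{\Phi(-s/2)}, so the optimal accuracy is \eqn{\Phi(s/2)}. Used to
#' calibrate simulation-based checks: no classifier on that view can
#' exceed this in expectation.
#'
#' @param s class-mean separation in noise-SD units.
#' @return the Bayes-optimal accuracy.
#' @export
bayesAccuracy <- function(s) stats::pnorm(s / 2)
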