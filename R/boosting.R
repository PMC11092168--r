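#' Agreement indicator between two labels
#'
#' Multi-class generalization of the binary product \eqn{y h \in \{-1,+1\}}:
#' returns 1 when the labels agree and 0 otherwise. Because real classes are
#' positive integers and the artificial label 0 marks "sample absent from
#' the view", a real label never agrees with an artificial prediction.
#'
#' @param a,b labels (vectorized).
#' @return integer 0/1 vector.
#' @export
agreementIndicator <- function(a, b) as.integer(a == b)

#' Modified prediction of a hypothesis over the full sample set
#'
#' For samples present in the hypothesis' view, the base model's label
#' (`modifiedPredict`) or probability vector (`modifiedProba`); for absent
#' samples, the artificial label 0, respectively the zero vector. The zero
#' probability vector contributes nothing to the weighted combination at
#' prediction time, and the artificial label can never match a true class,
#' so absent samples contribute neither to the edge nor to the weight
#' update.
#'
#' @param h a [WeakHypothesis-class].
#' @param view the [ViewTable-class] the samples live in (only its present
#'   rows are used).
#' @param samples character vector of sample ids (the full set N).
#' @return `modifiedPredict`: named integer vector over `samples` with 0 for
#'   absent ones; `modifiedProba`: a `length(samples) x C` matrix with zero
#'   rows for absent samples.
#' @export
modifiedPredict <- function(h, view, samples) {
  out <- stats::setNames(rep(0L, length(samples)), samples)
  present <- intersect(samples, sampleIds(view))
  if (length(present))
    out[present] <- predictLabel(h, featureMatrix(view)[present, ,
                                                        drop = FALSE])
  out
}

#' @rdname modifiedPredict
#' @export
modifiedProba <- function(h, view, samples) {
  out <- matrix(0, length(samples), h@nClasses,
                dimnames = list(samples, seq_len(h@nClasses)))
  present <- intersect(samples, sampleIds(view))
  if (length(present))
    out[present, ] <- predictProb(h, featureMatrix(view)[present, ,
                                                         drop = FALSE])
  out
}

#' Weighted multi-class edge of a hypothesis
#'
#' The edge is \eqn{2 \sum_{i \in N_j} w_i (I[y_i = \hat h(x_i)] - 1/2)},
#' the weighted multi-class generalization of \eqn{\sum_i w_i y_i h(x_i)}:
#' a correctly classified present sample contributes \eqn{+w_i}, a
#' misclassified one \eqn{-w_i}, and a sample absent from the view (whose
#' modified prediction is the artificial label 0) contributes exactly 0 —
#' it is excluded from the sum rather than counted as a mistake.
#'
#' @param weights named shared weights over all of N (summing to 1).
#' @param predicted named modified predictions over N (0 = absent).
#' @param labels named true class codes over N.
#' @return the edge, in \eqn{[-\sum_{i \in N_j} w_i, \sum_{i \in N_j} w_i]
#'   \subseteq [-1, 1]}.
#' @export
computeEdge <- function(weights, predicted, labels) {
  ids <- names(predicted)[predicted != 0L]
  if (!length(ids)) return(0)
  agree <- agreementIndicator(labels[ids], predicted[ids])
  sum(weights[ids] * (2 * agree - 1))
}

#' Vote weight from an edge
#'
#' The usual boosting half-log-odds \eqn{\alpha = \frac12
#' \log\frac{1+e}{1-e}} with the edge clipped into
#' \eqn{[-1+\epsilon, 1+... -\epsilon]} so a perfect (or perfectly wrong)
#' round yields a large finite weight. The sign of the edge is preserved
#' here; the fit loops assign combination weight 0 to rounds with
#' non-positive edge (see [fitIrboost()]).
#'
#' @param edge edge in [-1, 1].
#' @param clip clipping margin (default 1e-10).
#' @return the (signed) vote weight.
#' @export
computeAlpha <- function(edge, clip = 1e-10) {
  e <- min(max(edge, -1 + clip), 1 - clip)
  0.5 * log((1 + e) / (1 - e))
}

#' Update the shared instance weights after a round
#'
#' Present samples are reweighted by \eqn{e^{-\alpha(2 I - 1)}} (down if
#' classified correctly, up otherwise); samples absent from the winning view
#' keep their weight (multiplier \eqn{e^0 = 1}) and change only through the
#' final renormalization over all of N.
#'
#' @param weights named shared weights over N, summing to 1.
#' @param alpha vote weight of the round.
#' @param predicted named modified predictions over N (0 = absent).
#' @param labels named true class codes over N.
#' @return updated weights, renormalized to sum 1.
#' @export
updateWeights <- function(weights, alpha, predicted, labels) {
  ids <- names(predicted)[predicted != 0L]
  if (length(ids) && alpha != 0) {
    agree <- agreementIndicator(labels[ids], predicted[ids])
    weights[ids] <- weights[ids] * exp(-alpha * (2 * agree - 1))
  }
  s <- sum(weights)
  if (!is.finite(s) || s <= 0)
    stop("shared weights degenerated; cannot renormalize")
  weights / s
}

# Internal shared skeleton of one boosting run. edgeFun(h, viewTable)
# returns list(edge, predicted) where predicted follows the modified
# convention (0/-absent handled by the caller's arithmetic).
.boostLoop <- function(ds, T, spec, sigma, gamma, seed, type) {
  set.seed(seed)
  n <- allSamples(ds)
  y <- sampleLabels(ds)
  C <- nClasses(ds)
  K <- nViews(ds)
  vnames <- viewNames(ds)
  w <- stats::setNames(rep(1 / length(n), length(n)), n)
  bandit <- initBandit(K, sigma, gamma)
  rounds <- vector("list", T)
  trace <- data.frame(t = seq_len(T), view = NA_integer_,
                      viewId = NA_character_, edge = NA_real_,
                      reward = NA_real_, pSelect = NA_real_)
  probTrace <- matrix(NA_real_, T, K, dimnames = list(NULL, vnames))
  weightTrace <- matrix(NA_real_, T, length(n), dimnames = list(NULL, n))
  pm1 <- type == "rboost"  # +/-1 arithmetic for the binary predecessor
  if (pm1) ypm <- stats::setNames(ifelse(y == 2L, 1, -1), n)
  for (t in seq_len(T)) {
    # documented draw order: (1) bandit arm, (2) weak-learner seed
    j <- selectView(bandit)
    lseed <- sample.int(.Machine$integer.max, 1L)
    v <- ds@views[[j]]
    present <- sampleIds(v)
    pj <- bandit@prob[j]
    h <- NULL; edge <- 0; predicted <- NULL
    if (length(present) >= 1L) {
      wv <- w[present]
      h <- tryCatch(
        fitWeakLearner(featureMatrix(v), y[present], wv, C, viewId(v),
                       spec, lseed),
        error = function(e) {
          warning("round ", t, ": base learner failed on view '",
                  viewId(v), "' (", conditionMessage(e),
                  "); round skipped with alpha = 0", call. = FALSE)
          NULL
        })
    }
    if (!is.null(h)) {
      if (pm1) {
        hl <- predictLabel(h, featureMatrix(v))  # codes 1/2 on N_j = N
        hpm <- ifelse(hl == 2L, 1, -1)
        edge <- sum(w[present] * ypm[present] * hpm[present])
        predicted <- stats::setNames(rep(0L, length(n)), n)
        predicted[present] <- hl
      } else {
        predicted <- modifiedPredict(h, v, n)
        edge <- computeEdge(w, predicted, y)
      }
    } else {
      h <- new("WeakHypothesis", viewId = viewId(v), model = NULL,
               method = spec$method, nClasses = as.integer(C),
               featureIds = featureIds(v), constant = 0L)
    }
    reward <- edge
    trace$view[t] <- j; trace$viewId[t] <- vnames[j]
    trace$edge[t] <- edge; trace$reward[t] <- reward
    trace$pSelect[t] <- pj
    bandit <- updateBandit(bandit, j, reward)
    probTrace[t, ] <- bandit@prob
    alpha <- if (edge > 0) computeAlpha(edge) else 0
    if (!is.null(predicted)) {
      if (pm1) {
        upd <- w
        if (alpha != 0)
          upd[present] <- upd[present] *
            exp(-alpha * ypm[present] *
                  ifelse(predicted[present] == 2L, 1, -1))
        w <- upd / sum(upd)
      } else {
        w <- updateWeights(w, alpha, predicted, y)
      }
    }
    weightTrace[t, ] <- w
    rounds[[t]] <- new("WeakRound", t = t, viewId = vnames[j],
                       hypothesis = h, edge = edge, alpha = alpha)
  }
  wc <- table(factor(trace$viewId, levels = vnames))
  new("Ensemble", rounds = rounds, type = type, nClasses = as.integer(C),
      encoding = ds@encoding, viewIds = vnames,
      winnerCounts = stats::setNames(as.integer(wc), vnames),
      T = as.integer(T), sigma = sigma, gamma = gamma, trace = trace,
      probTrace = probTrace, weightTrace = weightTrace)
}

#' Fit the multi-class incomplete-view boosted ensemble
#'
#' The main training loop. Starting from uniform shared weights over the
#' full sample set N and a uniform bandit over the K views, each iteration
#' (i) samples a winning view from the bandit, (ii) fits the base learner on
#' that view's present samples with the shared weights restricted and
#' renormalized, (iii) computes the weighted multi-class edge over the
#' present samples (absent samples contribute nothing), (iv) feeds the edge,
#' importance-weighted by the selection probability, back to the bandit,
#' (v) converts a positive edge into a vote weight \eqn{\alpha} and updates
#' the shared weights (rounds with edge <= 0 are recorded with \eqn{\alpha
#' = 0}: they penalize the view through the bandit but are excluded from the
#' combined classifier, since a multi-class hypothesis cannot be inverted
#' the way a binary one can). The run is deterministic under `seed`; the
#' RNG is consumed in a fixed order (bandit draw, then weak-learner seed).
#'
#' The number of times each view wins (`winnerCounts`) indicates its
#' relevance — useful when views correspond to competing preprocessing
#' pipelines.
#'
#' @param ds a [MultiViewDataset-class].
#' @param T number of boosting iterations (default 50).
#' @param spec base [learnerSpec()] (default random forest with 50 trees).
#' @param sigma,gamma bandit parameters (defaults 0.15 and 0.3).
#' @param seed integer seed.
#' @return an [Ensemble-class].
#' @examples
#' ds <- simulateMultiView(n = 60, C = 2, q = c(4, 4), s = c(2, 0),
#'                         m = c(0.2, 0.2), seed = 7)
#' ens <- fitIrboost(ds, T = 5, spec = learnerSpec("tree"), seed = 1)
#' winnerCounts(ens)
#' @export
fitIrboost <- function(ds, T = 50L, spec = learnerSpec("rf", 50),
                       sigma = 0.15, gamma = 0.3, seed = 1L) {
  stopifnot(is(ds, "MultiViewDataset"), T >= 1L)
  .boostLoop(ds, as.integer(T), spec, sigma, gamma, as.integer(seed),
             "irboost")
}

#' Fit the binary complete-view predecessor algorithm
#'
#' Same bandit-driven shared-weight loop, but in the original binary
#' \eqn{\pm 1} arithmetic: the edge is \eqn{\sum_i w_i y_i h(x_i)} and the
#' final classifier is the sign of the weighted vote (no class probability
#' vector, hence no AUC at evaluation time). It requires exactly two
#' classes and complete views; pair it with [meanImputeUnion()] to run it
#' on incomplete data. On complete binary data it reproduces
#' [fitIrboost()] exactly (same seed, classes mapped to \{1, 2\}), since
#' \eqn{\sum_i w_i y_i h_i = 2\sum_i w_i(I[y_i = h_i] - 1/2)}.
#'
#' @inheritParams fitIrboost
#' @return an [Ensemble-class] of type `"rboost"`.
#' @export
fitRboostBinary <- function(ds, T = 50L, spec = learnerSpec("rf", 50),
                            sigma = 0.15, gamma = 0.3, seed = 1L) {
  stopifnot(is(ds, "MultiViewDataset"), T >= 1L)
  if (nClasses(ds) != 2L)
    stop("this algorithm is binary-only (found ", nClasses(ds),
         " classes); use fitIrboost() for multi-class tasks")
  mask <- membershipMask(ds)
  if (!all(mask))
    stop("this algorithm cannot work with incomplete views; impute first ",
         "(meanImputeUnion) or use fitIrboost()")
  .boostLoop(ds, as.integer(T), spec, sigma, gamma, as.integer(seed),
             "rboost")
}

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble (%s): %d round(s), %d class(es), %d view(s)\n",
              object@type, object@T, object@nClasses,
              length(object@viewIds)))
  cat("  winner counts:\n")
  for (v in names(object@winnerCounts))
    cat(sprintf("    %s: %d (%.0f%%)\n", v, object@winnerCounts[[v]],
                100 * object@winnerCounts[[v]] / object@T))
})

#' @rdname Ensemble-accessors
#' @param x an [Ensemble-class].
#' @export
setMethod("winnerCounts", "Ensemble", function(x) x@winnerCounts)

#' @rdname Ensemble-accessors
#' @export
setMethod("banditTrace", "Ensemble", function(x) x@trace)

#' @rdname Ensemble-accessors
#' @export
setMethod("nRounds", "Ensemble", function(x) x@T)

#' Predict with a fitted ensemble
#'
#' For the multi-class model, the combined score is
#' \eqn{F(x) = \sum_t \alpha_t \hat v^{j_t}(x)} where \eqn{\hat v} is the
#' modified class probability vector (the zero vector for views the sample
#' is absent from, which therefore contribute nothing); the label is
#' \eqn{\arg\max_c F_c} with ties broken toward the smallest class index,
#' and the reported score vector is F normalized to sum 1 (usable for AUC).
#' For the binary predecessor, the label is the sign of
#' \eqn{\sum_t \alpha_t h_t(x)} (ties toward the first class) and no score
#' vector is returned. A sample absent from every view used by a positive-
#' weight round is unpredictable and raises an error.
#'
#' @param ens an [Ensemble-class].
#' @param newdata a [MultiViewDataset-class] or a named list of
#'   [ViewTable-class] objects covering (a subset of) the training views.
#' @return list with `label` (named external labels), `code` (internal
#'   codes) and `score` (samples x C normalized score matrix, or NULL for
#'   the binary predecessor).
#' @export
predictEnsemble <- function(ens, newdata) {
  viewsList <- if (is(newdata, "MultiViewDataset")) views(newdata)
  else newdata
  vmap <- stats::setNames(viewsList,
                          vapply(viewsList, viewId, character(1)))
  samples <- unique(unlist(lapply(viewsList, sampleIds)))
  C <- ens@nClasses
  if (ens@type == "rboost") {
    Fv <- stats::setNames(rep(0, length(samples)), samples)
    any_vote <- stats::setNames(rep(FALSE, length(samples)), samples)
    for (r in ens@rounds) {
      if (r@alpha <= 0) next
      v <- vmap[[r@viewId]]
      if (is.null(v)) next
      present <- intersect(samples, sampleIds(v))
      if (!length(present)) next
      hl <- predictLabel(r@hypothesis,
                         featureMatrix(v)[present, , drop = FALSE])
      Fv[present] <- Fv[present] + r@alpha * ifelse(hl == 2L, 1, -1)
      any_vote[present] <- TRUE
    }
    if (!all(any_vote))
      stop("unpredictable instance(s): ",
           paste(samples[!any_vote], collapse = ", "))
    code <- ifelse(Fv > 0, 2L, 1L)  # tie toward the smallest class index
    return(list(label = stats::setNames(decode(ens@encoding, code),
                                        samples),
                code = stats::setNames(as.integer(code), samples),
                score = NULL))
  }
  Fm <- matrix(0, length(samples), C,
               dimnames = list(samples, seq_len(C)))
  for (r in ens@rounds) {
    if (r@alpha <= 0) next
    v <- vmap[[r@viewId]]
    if (is.null(v)) next
    Fm <- Fm + r@alpha * modifiedProba(r@hypothesis, v, samples)
  }
  tot <- rowSums(Fm)
  if (any(tot <= 0))
    stop("unpredictable instance(s) (absent from every voting view): ",
         paste(samples[tot <= 0], collapse = ", "))
  score <- Fm / tot
  code <- max.col(score, ties.method = "first")
  list(label = stats::setNames(decode(ens@encoding, code), samples),
       code = stats::setNames(as.integer(code), samples),
       score = score)
}
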