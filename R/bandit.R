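#' Initialize the adversarial bandit over views
#'
#' Creates a [BanditState-class] with uniform selection probabilities and
#' zero cumulative rewards. The forecaster follows the exponentially
#' weighted average construction of the EXP3.P family: after each reward
#' the probabilities become
#' \deqn{p_j = (1-\gamma)\,\frac{e^{\sigma R_j}}{\sum_k e^{\sigma R_k}}
#'       + \frac{\gamma}{K},}
#' where \eqn{R_j} is the cumulative importance-weighted reward of arm j.
#' The uniform mixing term keeps every \eqn{p_j \ge \gamma/K}, so the
#' importance weights are bounded and no view is ever starved.
#'
#' @param K number of arms (views), >= 1.
#' @param sigma learning rate, > 0 (default 0.15).
#' @param gamma exploration rate in (0, 1) (default 0.3).
#' @return a [BanditState-class].
#' @export
initBandit <- function(K, sigma = 0.15, gamma = 0.3) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be >= 1")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)")
  new("BanditState", K = K, prob = rep(1 / K, K), reward = rep(0, K),
      sigma = sigma, gamma = gamma)
}

setMethod("show", "BanditState", function(object) {
  cat(sprintf("BanditState: K=%d, sigma=%g, gamma=%g\n",
              object@K, object@sigma, object@gamma))
  cat("  p:", paste(sprintf("%.4f", object@prob), collapse = " "), "\n")
})

#' Sample an arm from the bandit's probability vector
#'
#' Draws one arm from the categorical distribution `p`, consuming one draw
#' from R's global RNG stream; under a fixed seed and call sequence the
#' selections are reproducible.
#'
#' @param state a [BanditState-class].
#' @return integer arm index in 1..K.
#' @export
selectView <- function(state) {
  stopifnot(is(state, "BanditState"))
  if (state@K == 1L) return(1L)
  sample.int(state@K, 1L, prob = state@prob)
}

#' Importance-weight a raw reward
#'
#' The reward observed for the selected arm is divided by the probability of
#' having selected it, which favours rarely chosen views (a view selected
#' with low probability gets its reward amplified, promoting diversity).
#' Since \eqn{p_j \ge \gamma/K}, the result is bounded by
#' \eqn{|reward| K/\gamma}.
#'
#' @param reward raw reward (here, the boosting edge of the winning view).
#' @param pj probability with which the arm was selected; must be > 0.
#' @return `reward / pj`.
#' @export
importanceWeightedReward <- function(reward, pj) {
  if (pj <= 0) stop("selection probability must be positive")
  reward / pj
}

#' Update the bandit after observing a reward
#'
#' Adds the importance-weighted reward to arm `j`'s cumulative estimate and
#' recomputes the probability vector via the exponentially weighted average
#' forecaster (see [initBandit()]). The softmax is computed after
#' subtracting \eqn{\max_k \sigma R_k} (log-sum-exp stabilization), which is
#' required because importance-weighted rewards grow without bound in the
#' number of iterations; the resulting probabilities are invariant to adding
#' any constant to all cumulative rewards.
#'
#' @param state a [BanditState-class].
#' @param j arm that was selected.
#' @param reward raw reward observed for arm `j` (importance weighting is
#'   applied internally using the current `p[j]`).
#' @return the updated [BanditState-class].
#' @export
updateBandit <- function(state, j, reward) {
  stopifnot(is(state, "BanditState"))
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > state@K) stop("invalid arm index")
  R <- state@reward
  R[j] <- R[j] + importanceWeightedReward(reward, state@prob[j])
  state@reward <- R
  state@prob <- ewaProbabilities(R, state@sigma, state@gamma)
  validObject(state)
  state
}

#' @rdname updateBandit
#' @param R cumulative reward vector.
#' @param sigma,gamma forecaster parameters.
#' @export
ewaProbabilities <- function(R, sigma, gamma) {
  z <- sigma * R
  z <- z - max(z)
  e <- exp(z)
  if (!all(is.finite(e))) stop("numeric overflow in forecaster update")
  (1 - gamma) * e / sum(e) + gamma / length(R)
}

#' Replay a bandit trace offline
#'
#' Recomputes the sequence of post-update probability vectors from a trace
#' of (selected view, raw reward, selection probability) rows, as logged by
#' [fitIrboost()]. Useful to audit a stored run: the replayed vectors match
#' the fitted model's `probTrace` to numerical precision.
#'
#' @param trace data.frame with columns `view` (arm index) and `reward`
#'   (raw reward), in iteration order.
#' @param K,sigma,gamma bandit configuration of the original run.
#' @return matrix of post-update probability vectors, one row per iteration.
#' @export
replayBanditTrace <- function(trace, K, sigma = 0.15, gamma = 0.3) {
  state <- initBandit(K, sigma, gamma)
  out <- matrix(NA_real_, nrow(trace), K)
  for (t in seq_len(nrow(trace))) {
    state <- updateBandit(state, trace$view[t], trace$reward[t])
    out[t, ] <- state@prob
  }
  out
}
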