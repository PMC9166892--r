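#' Rank-order probabilities when faking
#'
#' When a person fakes a block, the probability of selecting rank order
#' \eqn{r} is a softmax over block-level rank-order parameters:
#' \deqn{P(X_k = r \mid F = 1) = \exp(\beta_{kr}) / \sum_u \exp(\beta_{ku}).}
#' The probabilities vary by block but not by person. Computation is
#' stabilized by subtracting the row maximum before exponentiation, so the
#' result is invariant to adding a constant to all entries of a block.
#'
#' @param beta numeric vector of length `R` (one block) or a blocks x R
#'   matrix of rank-order parameters.
#' @return Probability vector (or matrix of row-wise probability vectors).
#' @examples
#' softmax_rank_probs(c(0, log(2), 0, 0, 0, 0)) # c(1/7, 2/7, 1/7, ...)
#' @export
softmax_rank_probs <- function(beta) {
  if (is.matrix(beta)) {
    if (any(!is.finite(beta))) stop("'beta' must be finite", call. = FALSE)
    e <- exp(beta - apply(beta, 1L, max))
    return(e / rowSums(e))
  }
  if (any(!is.finite(beta))) stop("'beta' must be finite", call. = FALSE)
  e <- exp(beta - max(beta))
  e / sum(e)
}

#' Derived block fakability
#'
#' Fakability is not a free parameter: it is the standard-normal quantile of
#' the sum of squared deviations of a block's faking rank-order
#' probabilities from their mean \eqn{1/R},
#' \deqn{\alpha_k = \Phi^{-1}\!\Big(\sum_r \big(P_{kr} - 1/R\big)^2\Big).}
#' Concentrated probabilities (one clearly preferable order) give high
#' fakability; a uniform profile gives a sum of squares of 0, whose quantile
#' is \eqn{-\infty} — the argument is therefore clamped below at `floor`
#' (default `1e-10`, i.e. \eqn{\alpha \approx -6.36}) to keep the model's
#' likelihood finite near uniform softmax outputs.
#'
#' @param probs probability vector of length `R`, or a blocks x R matrix of
#'   probability rows (each summing to 1).
#' @param floor lower clamp on the sum-of-squares argument.
#' @param tol tolerance for the sum-to-one check.
#' @return Fakability value(s) \eqn{\alpha}.
#' @examples
#' block_fakability(c(1, 0, 0, 0, 0, 0)) # qnorm(5/6) ~ 0.967
#' @export
block_fakability <- function(probs, floor = 1e-10, tol = 1e-6) {
  if (!is.matrix(probs)) probs <- matrix(probs, 1L)
  if (any(abs(rowSums(probs) - 1) > tol)) {
    stop("rank-order probabilities must sum to 1 per block", call. = FALSE)
  }
  R <- ncol(probs)
  ss <- rowSums((probs - 1 / R)^2)
  drop(qnorm(pmax(ss, floor)))
}

#' Probability of faking a block
#'
#' Probit model combining the person's faking trait and the block's derived
#' fakability: \eqn{P(F_{jk} = 1) = \Phi(\theta_j + \alpha_k)}. Vector
#' arguments are combined elementwise if of equal length, otherwise as the
#' outer sum (persons x blocks).
#'
#' @param theta faking trait value(s) \eqn{\theta_j}.
#' @param alpha block fakability value(s) \eqn{\alpha_k}.
#' @return Faking probabilities; a persons x blocks matrix when both
#'   arguments have length > 1 and different lengths.
#' @export
faking_probability <- function(theta, alpha) {
  if (length(theta) > 1L && length(alpha) > 1L &&
      length(theta) != length(alpha)) {
    return(pnorm(outer(theta, alpha, `+`)))
  }
  pnorm(theta + alpha)
}

#' Mixture response probability for one person-block
#'
#' The Faking Mixture model's response probability: a convex combination of
#' the faking softmax profile and the fixed honest profile,
#' \deqn{P(X_{jk} = r \mid \theta_j) = \Phi(\theta_j + \alpha_k)\,
#'   \mathrm{softmax}(\beta_k)_r + \big(1 - \Phi(\theta_j +
#'   \alpha_k)\big)\, P(X_{jk} = r \mid F = 0),}
#' with \eqn{\alpha_k} derived from \eqn{\beta_k} via [block_fakability()].
#'
#' @param theta scalar faking trait \eqn{\theta_j}.
#' @param beta_k length-`R` rank-order parameter vector for the block.
#' @param honest_k length-`R` honest probability vector (sums to 1).
#' @return Length-`R` probability vector.
#' @export
mixture_probability <- function(theta, beta_k, honest_k) {
  if (abs(sum(honest_k) - 1) > 1e-6) {
    stop("'honest_k' must sum to 1", call. = FALSE)
  }
  p_fake <- softmax_rank_probs(beta_k)
  pf <- faking_probability(theta, block_fakability(p_fake))
  pf * p_fake + (1 - pf) * honest_k
}

#' Log-likelihood of the Faking Mixture model
#'
#' Sum over persons and blocks of the log mixture probability of the
#' observed rank order. Used directly for diagnostics and as the reference
#' implementation against which the compiled sampler's log target is
#' validated.
#'
#' @param responses persons x blocks integer matrix of canonical order
#'   indices in `1:R`.
#' @param beta blocks x R matrix of rank-order parameters (first column 0
#'   under the identification constraint; any constant shift per row gives
#'   the same likelihood).
#' @param theta length-persons faking trait vector.
#' @param honest persons x blocks x R honest probability array.
#' @return Scalar log-likelihood.
#' @export
faking_mixture_loglik <- function(responses, beta, theta, honest) {
  responses <- as.matrix(responses)
  N <- nrow(responses); K <- ncol(responses); R <- dim(honest)[3L]
  stopifnot(dim(honest)[1L] == N, dim(honest)[2L] == K,
            nrow(beta) == K, ncol(beta) == R, length(theta) == N)
  bad <- which(responses < 1L | responses > R | responses != round(responses),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("response index out of 1..%d for person %d, block %d", R,
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  p_fake <- softmax_rank_probs(beta)
  alpha <- block_fakability(p_fake)
  ll <- 0
  for (j in seq_len(N)) {
    pf <- pnorm(theta[j] + alpha)
    for (k in seq_len(K)) {
      r <- responses[j, k]
      ll <- ll + log(pf[k] * p_fake[k, r] + (1 - pf[k]) * honest[j, k, r])
    }
  }
  ll
}
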