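#' Prior configuration for the Faking Mixture model
#'
#' The model's hierarchical priors: free rank-order parameters
#' \eqn{\beta \sim N(0, SD(\beta))}, faking traits
#' \eqn{\theta \sim N(M(\theta), SD(\theta))}, with hyperpriors
#' \eqn{M(\theta) \sim N(1, 2)}, \eqn{Var(\theta) \sim
#' \mathrm{InvGamma}(1.5, 1)} and \eqn{Var(\beta) \sim} truncated
#' \eqn{N(5, 10)} on \eqn{(0, 15)}. The second argument of each normal is a
#' standard deviation. Supplying `fix_var_theta` and/or `fix_var_beta`
#' replaces the corresponding hyperprior by a fixed value — the setting used
#' for empirical data, where `fix_var_theta = 0.25` and `fix_var_beta = 4`
#' leave only \eqn{M(\theta)} with a hyperprior.
#'
#' @param hyper_mean_theta length-2 numeric: mean and SD of the normal
#'   hyperprior on \eqn{M(\theta)}.
#' @param hyper_var_theta length-2 numeric: shape and rate of the
#'   inverse-gamma hyperprior on \eqn{Var(\theta)}.
#' @param hyper_var_beta length-4 numeric: mean, SD, lower, upper of the
#'   truncated-normal hyperprior on \eqn{Var(\beta)}.
#' @param fix_var_theta,fix_var_beta optional positive reals fixing the
#'   corresponding variance.
#' @return Object of class `"fm_priors"`.
#' @export
fm_priors <- function(hyper_mean_theta = c(1, 2),
                      hyper_var_theta = c(1.5, 1),
                      hyper_var_beta = c(5, 10, 0, 15),
                      fix_var_theta = NULL, fix_var_beta = NULL) {
  stopifnot(length(hyper_mean_theta) == 2L, hyper_mean_theta[2L] > 0,
            length(hyper_var_theta) == 2L, all(hyper_var_theta > 0),
            length(hyper_var_beta) == 4L, hyper_var_beta[2L] > 0,
            hyper_var_beta[3L] < hyper_var_beta[4L])
  if (!is.null(fix_var_theta)) stopifnot(fix_var_theta > 0)
  if (!is.null(fix_var_beta)) stopifnot(fix_var_beta > 0)
  structure(list(hyper_mean_theta = as.numeric(hyper_mean_theta),
                 hyper_var_theta = as.numeric(hyper_var_theta),
                 hyper_var_beta = as.numeric(hyper_var_beta),
                 fix_var_theta = fix_var_theta,
                 fix_var_beta = fix_var_beta),
            class = "fm_priors")
}

prior_vector <- function(priors) {
  c(priors$hyper_mean_theta, priors$hyper_var_theta, priors$hyper_var_beta)
}

#' Sampler configuration
#'
#' Markov chain Monte Carlo settings. The `"simulation"` preset mirrors the
#' recovery-study settings (3 chains of 3500 iterations, 750 warmup); the
#' `"empirical"` preset uses 6 chains of 5000 iterations with 2500 warmup
#' (pair it with fixed variances in [fm_priors()]). Explicit arguments
#' override the preset.
#'
#' @param chains number of chains.
#' @param iter total iterations per chain.
#' @param warmup iterations discarded (and used for proposal adaptation).
#' @param thin post-warmup thinning interval.
#' @param target_accept target acceptance rate of the adaptive
#'   random-walk proposals.
#' @param adapt_batch warmup batch size between proposal-scale updates.
#' @param preset `"simulation"` or `"empirical"`.
#' @return Object of class `"fm_control"`.
#' @export
fm_control <- function(chains = NULL, iter = NULL, warmup = NULL, thin = 1L,
                       target_accept = 0.44, adapt_batch = 50L,
                       preset = c("simulation", "empirical")) {
  preset <- match.arg(preset)
  def <- if (preset == "simulation") c(3L, 3500L, 750L) else
    c(6L, 5000L, 2500L)
  out <- list(chains = chains %||% def[1L], iter = iter %||% def[2L],
              warmup = warmup %||% def[3L], thin = as.integer(thin),
              target_accept = target_accept,
              adapt_batch = as.integer(adapt_batch), preset = preset)
  if (out$warmup >= out$iter) {
    stop("'warmup' must be smaller than 'iter'", call. = FALSE)
  }
  structure(out, class = "fm_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Faking Mixture model
#'
#' Estimates the Faking Mixture model from high-stakes rank-order responses,
#' with the honest-response probabilities fixed (two-step procedure: the
#' honest component is computed from a low-stakes administration, e.g. via
#' [honest_probabilities()], and enters as data). Sampling is by adaptive
#' Metropolis-within-Gibbs over the free rank-order parameters
#' \eqn{\beta_{kr}} (\eqn{\beta_{k1} = 0} fixed for identification) and
#' faking traits \eqn{\theta_j}, with conjugate Gibbs draws for
#' \eqn{M(\theta)} and \eqn{Var(\theta)} and a Jacobian-corrected log-scale
#' random-walk step for \eqn{Var(\beta)}; the discrete faking indicator is
#' marginalized analytically.
#'
#' Derived quantities — block fakabilities \eqn{\alpha_k} and faking
#' rank-order probabilities — are recomputed per posterior draw (never from
#' summarized parameters).
#'
#' @param responses persons x blocks integer matrix of canonical order
#'   indices (see [rank_orders()]), or values coercible via
#'   [parse_rank_order()].
#' @param honest persons x blocks x R array of honest-response
#'   probabilities.
#' @param priors an [fm_priors()] object.
#' @param control an [fm_control()] object.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param verbose print per-chain progress.
#' @return Object of class `"faking_mixture"` with components `draws` (list
#'   of per-chain draw matrices for `beta`, `theta`, `mtheta`, `vtheta`,
#'   `vbeta`, `lp`, `alpha`, `pfake`), `dims`, `priors`, `control`,
#'   `runtime`. Methods: [print()], [summary()], [coef()], [predict()],
#'   [plot()], plus [fm_convergence()].
#' @export
faking_mixture <- function(responses, honest, priors = fm_priors(),
                           control = fm_control(), seed = 1L,
                           verbose = FALSE) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  N <- nrow(responses); K <- ncol(responses)
  if (length(dim(honest)) != 3L || dim(honest)[1L] != N ||
      dim(honest)[2L] != K) {
    stop("'honest' must be a persons x blocks x R array matching ",
         "'responses'", call. = FALSE)
  }
  R <- dim(honest)[3L]
  check_honest_array(honest)
  bad <- which(responses < 1L | responses > R, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("response index out of 1..%d for person %d, block %d", R,
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  fit <- fm_fit_engine(responses, honest, group = rep(1L, N),
                       bmap = matrix(seq_len(K), 1L), R = R,
                       priors = priors, control = control, seed = seed,
                       verbose = verbose)
  fit$dims$block_map <- seq_len(K)
  fit
}

check_honest_array <- function(honest, tol = 1e-6) {
  if (any(honest < -tol | honest > 1 + tol)) {
    stop("honest probabilities must lie in [0, 1]", call. = FALSE)
  }
  sums <- apply(honest, c(1L, 2L), sum)
  if (any(abs(sums - 1) > 1e-3)) {
    stop("honest probabilities must sum to 1 per person-block ",
         "(use honest_probabilities(), which rescales)", call. = FALSE)
  }
  invisible(TRUE)
}

# Shared engine for single-group and multigroup fits.
fm_fit_engine <- function(responses, honest, group, bmap, R, priors, control,
                          seed, verbose) {
  N <- nrow(responses); K <- ncol(responses)
  M <- max(bmap)
  fix_vt <- !is.null(priors$fix_var_theta)
  fix_vb <- !is.null(priors$fix_var_beta)
  pv <- prior_vector(priors)
  t0 <- Sys.time()
  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(seed + ch - 1L)
    # overdispersed starts: beta near 0, theta near a hyper-mean draw
    beta_init <- cbind(0, matrix(rnorm(M * (R - 1L), 0, 0.5), M))
    mtheta_init <- rnorm(1L, priors$hyper_mean_theta[1L], 0.5)
    vtheta_init <- if (fix_vt) priors$fix_var_theta else
      1 / stats::qgamma(0.5, pv[3L], pv[4L])   # prior median
    vbeta_init <- if (fix_vb) priors$fix_var_beta else
      max(min(pv[5L], pv[8L] * 0.9), pv[7L] + 0.5)
    theta_init <- rnorm(N, mtheta_init, 0.5)
    if (verbose) {
      message(sprintf("chain %d/%d: %d iterations (%d warmup)", ch,
                      control$chains, control$iter, control$warmup))
    }
    chains[[ch]] <- fm_run_chain(
      responses, as.numeric(honest), as.integer(group), bmap, R, pv,
      fix_vt, priors$fix_var_theta %||% 0, fix_vb,
      priors$fix_var_beta %||% 0, control$iter, control$warmup,
      control$thin, beta_init, theta_init, mtheta_init, vtheta_init,
      vbeta_init, 1e-10, control$target_accept, control$adapt_batch)
  }
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  free_names <- as.vector(t(outer(seq_len(M), 2:R,
                                  function(m, r) sprintf("beta[%d,%d]", m, r))))
  draws <- lapply(chains, function(cc) {
    colnames(cc$beta) <- free_names
    colnames(cc$theta) <- sprintf("theta[%d]", seq_len(N))
    cc
  })
  # derived quantities per draw
  for (ch in seq_along(draws)) {
    d <- derived_draws(draws[[ch]]$beta, M, R)
    draws[[ch]]$alpha <- d$alpha
    draws[[ch]]$pfake <- d$pfake
  }
  structure(list(draws = draws,
                 dims = list(n_persons = N, n_blocks = K, n_orders = R,
                             n_beta_blocks = M, group = group, bmap = bmap),
                 priors = priors, control = control, seed = seed,
                 runtime = runtime),
            class = "faking_mixture")
}

# alpha and softmax probabilities per stored draw, from free-beta draws
derived_draws <- function(beta_draws, M, R) {
  S <- nrow(beta_draws)
  alpha <- matrix(NA_real_, S, M,
                  dimnames = list(NULL, sprintf("alpha[%d]", seq_len(M))))
  pfake <- array(NA_real_, c(S, M, R))
  for (m in seq_len(M)) {
    b <- cbind(0, beta_draws[, (m - 1L) * (R - 1L) + seq_len(R - 1L),
                             drop = FALSE])
    p <- softmax_rank_probs(b)
    pfake[, m, ] <- p
    alpha[, m] <- block_fakability(p)
  }
  list(alpha = alpha, pfake = pfake)
}

# stack a named component across chains: iterations x chains x parameters
stack_draws <- function(fit, what) {
  x <- lapply(fit$draws, `[[`, what)
  if (is.null(dim(x[[1L]]))) x <- lapply(x, as.matrix)
  if (length(dim(x[[1L]])) == 3L) {
    x <- lapply(x, function(a) matrix(a, nrow(a)))
  }
  arr <- array(NA_real_, c(nrow(x[[1L]]), length(x), ncol(x[[1L]])))
  for (ch in seq_along(x)) arr[, ch, ] <- x[[ch]]
  dimnames(arr) <- list(NULL, NULL, colnames(x[[1L]]))
  arr
}

# pooled draw matrix (all chains), iterations*chains x parameters
pooled_draws <- function(fit, what) {
  arr <- stack_draws(fit, what)
  out <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3L])
  colnames(out) <- dimnames(arr)[[3L]]
  out
}

posterior_table <- function(draws, probs = c(.025, .5, .975)) {
  qs <- t(apply(draws, 2L, quantile, probs = probs, names = FALSE))
  data.frame(parameter = colnames(draws), median = qs[, 2L],
             lower = qs[, 1L], upper = qs[, 3L], row.names = NULL)
}

#' @export
print.faking_mixture <- function(x, ...) {
  d <- x$dims
  cat("Faking Mixture model fit\n")
  cat(sprintf("  %d persons, %d blocks (%d rank orders), %d beta blocks\n",
              d$n_persons, d$n_blocks, d$n_orders, d$n_beta_blocks))
  cat(sprintf("  %d chain(s) x %d iterations (%d warmup), %.1f s\n",
              x$control$chains, x$control$iter, x$control$warmup,
              x$runtime))
  hyp <- summary(x)$hyperparameters
  cat("  hyperparameters (posterior median [95% interval]):\n")
  for (i in seq_len(nrow(hyp))) {
    cat(sprintf("    %-10s %6.2f [%6.2f; %6.2f]%s\n", hyp$parameter[i],
                hyp$median[i], hyp$lower[i], hyp$upper[i],
                if (isTRUE(hyp$fixed[i])) " (fixed)" else ""))
  }
  invisible(x)
}

#' Posterior summaries of a Faking Mixture fit
#'
#' Per-parameter posterior medians with 95% central intervals, and the
#' block-level fakability table: for every block, the median and interval of
#' \eqn{\alpha_k} and the percentage of persons \emph{predicted to fake} —
#' those whose posterior-median faking probability
#' \eqn{\Phi(\theta_j + \alpha_k)} exceeds .5.
#'
#' @param object a `"faking_mixture"` fit.
#' @param ... unused.
#' @return List with data frames `hyperparameters`, `blocks` (block,
#'   median, lower, upper, pct_predicted_to_fake), `beta`, `theta`, and
#'   `rank_order_probs` (posterior-median faking rank-order probabilities,
#'   blocks x R).
#' @export
summary.faking_mixture <- function(object, ...) {
  hyp_draws <- cbind(`M(theta)` = as.vector(pooled_draws(object, "mtheta")),
                     `Var(theta)` = as.vector(pooled_draws(object, "vtheta")),
                     `Var(beta)` = as.vector(pooled_draws(object, "vbeta")))
  hyp <- posterior_table(hyp_draws)
  hyp$fixed <- c(FALSE, !is.null(object$priors$fix_var_theta),
                 !is.null(object$priors$fix_var_beta))
  alpha <- pooled_draws(object, "alpha")
  blocks <- posterior_table(alpha)
  names(blocks)[1L] <- "block"
  blocks$block <- seq_len(ncol(alpha))
  # predicted-to-fake: share of persons with posterior-median faking
  # probability > .5, pooled over the person-block cells using each beta
  # block (for a single-group fit, simply per questionnaire block)
  pf <- predict(object, type = "faking_probability")
  grp <- object$dims$group; bmap <- object$dims$bmap
  hits <- cnt <- numeric(ncol(alpha))
  for (g in unique(grp)) {
    jj <- grp == g
    for (k in seq_len(ncol(pf))) {
      m <- bmap[g, k]
      hits[m] <- hits[m] + sum(pf[jj, k] > .5)
      cnt[m] <- cnt[m] + sum(jj)
    }
  }
  blocks$pct_predicted_to_fake <- 100 * hits / cnt
  pfake <- stack_draws(object, "pfake")
  R <- object$dims$n_orders
  M <- object$dims$n_beta_blocks
  pm <- matrix(apply(pfake, 3L, median), M, R)
  dimnames(pm) <- list(sprintf("block_%d", seq_len(M)),
                       sprintf("order_%d", seq_len(R)))
  list(hyperparameters = hyp,
       blocks = blocks[order(blocks$median), ],
       beta = posterior_table(pooled_draws(object, "beta")),
       theta = posterior_table(pooled_draws(object, "theta")),
       rank_order_probs = pm)
}

#' @export
coef.faking_mixture <- function(object, ...) {
  s <- summary(object)
  list(beta = setNames(s$beta$median, s$beta$parameter),
       theta = setNames(s$theta$median, s$theta$parameter),
       alpha = setNames(sort_by_block(s$blocks)$median,
                        sprintf("alpha[%d]", sort_by_block(s$blocks)$block)),
       hyper = setNames(s$hyperparameters$median,
                        s$hyperparameters$parameter))
}

sort_by_block <- function(blocks) blocks[order(blocks$block), ]

#' Posterior predictions from a Faking Mixture fit
#'
#' @param object a `"faking_mixture"` fit.
#' @param type `"faking_probability"` returns the persons x blocks matrix of
#'   posterior-median \eqn{\Phi(\theta_j + \alpha_k)} (computed per draw);
#'   `"response_probs"` returns the persons-independent posterior-median
#'   faking rank-order probabilities (blocks x R).
#' @param ... unused.
#' @export
predict.faking_mixture <- function(object,
                                   type = c("faking_probability",
                                            "response_probs"), ...) {
  type <- match.arg(type)
  if (type == "response_probs") return(summary(object)$rank_order_probs)
  theta <- pooled_draws(object, "theta")             # S x N
  alpha <- pooled_draws(object, "alpha")             # S x M
  grp <- object$dims$group
  bmap <- object$dims$bmap
  N <- object$dims$n_persons; K <- object$dims$n_blocks
  out <- matrix(NA_real_, N, K)
  for (k in seq_len(K)) {
    for (g in unique(grp)) {
      jj <- which(grp == g)
      pf <- pnorm(theta[, jj, drop = FALSE] + alpha[, bmap[g, k]])
      out[jj, k] <- apply(pf, 2L, median)
    }
  }
  colnames(out) <- sprintf("block_%d", seq_len(K))
  out
}

#' Plot method for Faking Mixture fits
#'
#' `type = "fakability"` draws the block fakability estimates with 95%
#' intervals, ordered by median; `type = "trace"` draws traceplots of the
#' hyperparameters by chain.
#'
#' @param x a `"faking_mixture"` fit.
#' @param type plot type.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.faking_mixture <- function(x, type = c("fakability", "trace"), ...) {
  type <- match.arg(type)
  if (type == "fakability") {
    b <- summary(x)$blocks
    idx <- seq_len(nrow(b))
    plot(b$median, idx, xlim = range(b$lower, b$upper),
         xlab = expression(alpha[k]), ylab = "", yaxt = "n",
         pch = 19, ...)
    segments(b$lower, idx, b$upper, idx)
    axis(2, at = idx, labels = paste("block", b$block), las = 1)
    abline(v = 0, lty = 3)
  } else {
    op <- par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
    on.exit(par(op))
    for (w in c("mtheta", "vtheta", "vbeta")) {
      arr <- stack_draws(x, w)[, , 1L]
      matplot(arr, type = "l", lty = 1, ylab = w, xlab = "", ...)
    }
  }
  invisible(x)
}
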