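# Shared fixture builders; everything is generated in code at test time.

# tiny questionnaire with fixed, hand-picked parameters (2 triplet blocks)
toy_items <- function() {
  data.frame(
    item_id = 1:6,
    block_id = rep(1:2, each = 3L),
    trait = c(1L, 2L, 3L, 2L, 3L, 1L),
    intercept = c(0.5, -0.2, 0.1, 0.8, 0.0, -0.5),
    loading = c(0.8, -0.7, 0.9, 0.66, 0.75, -0.85),
    error_variance = 1 - c(0.8, -0.7, 0.9, 0.66, 0.75, -0.85)^2
  )
}

# uniform honest-probability array (valid for any persons/blocks)
uniform_honest <- function(n_persons, n_blocks, R = 6L) {
  array(1 / R, dim = c(n_persons, n_blocks, R))
}

# a quick simulated study at small scale, honest probabilities included
small_sim <- function(seed = 42L, n_persons = 60L, n_blocks = 4L,
                      condition = list(fakability = "high", theta_mean = 1,
                                       theta_var = 0.5)) {
  simulate_fc_study(condition, n_persons = n_persons, n_blocks = n_blocks,
                    block_size = 3L, n_traits = 5L, seed = seed)
}

# quick sampler settings for smoke-level fits
quick_control <- function(chains = 2L, iter = 500L, warmup = 150L) {
  fm_control(chains = chains, iter = iter, warmup = warmup)
}

# R-side log posterior mirroring the sampler's target, used as oracle
r_log_posterior <- function(responses, honest, beta, theta, mtheta, vtheta,
                            vbeta, priors = fm_priors()) {
  ll <- faking_mixture_loglik(responses, beta, theta, honest)
  lp <- sum(dnorm(as.vector(beta[, -1L]), 0, sqrt(vbeta), log = TRUE)) +
    sum(dnorm(theta, mtheta, sqrt(vtheta), log = TRUE)) +
    dnorm(mtheta, priors$hyper_mean_theta[1L], priors$hyper_mean_theta[2L],
          log = TRUE)
  if (is.null(priors$fix_var_theta)) {
    a <- priors$hyper_var_theta[1L]; b <- priors$hyper_var_theta[2L]
    lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(vtheta) - b / vtheta
  }
  if (is.null(priors$fix_var_beta)) {
    h <- priors$hyper_var_beta
    z <- pnorm(h[4L], h[1L], h[2L]) - pnorm(h[3L], h[1L], h[2L])
    lp <- lp + dnorm(vbeta, h[1L], h[2L], log = TRUE) - log(z)
  }
  ll + lp
}

cpp_log_posterior <- function(responses, honest, beta, theta, mtheta, vtheta,
                              vbeta, priors = fm_priors()) {
  ns <- asNamespace("fakemix")
  ns$fm_log_posterior_cpp(
    responses, as.numeric(honest), rep(1L, nrow(responses)),
    matrix(seq_len(ncol(responses)), 1L), dim(honest)[3L], beta, theta,
    mtheta, vtheta, vbeta,
    c(priors$hyper_mean_theta, priors$hyper_var_theta, priors$hyper_var_beta),
    !is.null(priors$fix_var_theta), !is.null(priors$fix_var_beta), 1e-10)
}
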