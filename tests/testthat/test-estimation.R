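test_that("the sampler's log target equals likelihood plus priors", {
  set.seed(40)
  N <- 7L; K <- 3L; R <- 6L
  honest <- array(NA_real_, c(N, K, R))
  for (j in 1:N) for (k in 1:K) {
    w <- runif(R); honest[j, k, ] <- w / sum(w)
  }
  responses <- matrix(sample.int(R, N * K, TRUE), N, K)
  storage.mode(responses) <- "integer"
  for (i in 1:5) {
    beta <- cbind(0, matrix(rnorm(K * (R - 1L), 0, 1.5), K))
    theta <- rnorm(N, 1, 0.8)
    mtheta <- rnorm(1L); vtheta <- runif(1L, 0.1, 2)
    vbeta <- runif(1L, 0.5, 10)
    expect_equal(
      cpp_log_posterior(responses, honest, beta, theta, mtheta, vtheta,
                        vbeta),
      r_log_posterior(responses, honest, beta, theta, mtheta, vtheta,
                      vbeta),
      tolerance = 1e-8)
    # fixed-variance configuration drops the corresponding hyperprior terms
    pf <- fm_priors(fix_var_theta = vtheta, fix_var_beta = vbeta)
    expect_equal(
      cpp_log_posterior(responses, honest, beta, theta, mtheta, vtheta,
                        vbeta, priors = pf),
      r_log_posterior(responses, honest, beta, theta, mtheta, vtheta,
                      vbeta, priors = pf),
      tolerance = 1e-8)
  }
})

test_that("a short fit returns a coherent posterior object", {
  sim <- small_sim(seed = 50L)
  fit <- faking_mixture(sim$responses, sim$honest_probs,
                        control = quick_control(), seed = 50L)
  expect_s3_class(fit, "faking_mixture")
  expect_equal(fit$dims$n_persons, 60L)
  expect_equal(fit$dims$n_blocks, 4L)
  s <- summary(fit)
  expect_named(s, c("hyperparameters", "blocks", "beta", "theta",
                    "rank_order_probs"))
  expect_equal(nrow(s$blocks), 4L)
  expect_true(all(c("block", "median", "lower", "upper",
                    "pct_predicted_to_fake") %in% names(s$blocks)))
  expect_true(all(s$blocks$lower <= s$blocks$median &
                    s$blocks$median <= s$blocks$upper))
  expect_true(all(s$rank_order_probs >= 0 & s$rank_order_probs <= 1))
  # entrywise medians need not sum exactly to one, but should be close
  expect_true(all(abs(rowSums(s$rank_order_probs) - 1) < 0.1))
  co <- coef(fit)
  expect_length(co$theta, 60L)
  expect_length(co$alpha, 4L)
  pf <- predict(fit, type = "faking_probability")
  expect_equal(dim(pf), c(60L, 4L))
  expect_true(all(pf >= 0 & pf <= 1))
})

test_that("derived fakability draws are alpha of per-draw probabilities", {
  sim <- small_sim(seed = 51L, n_persons = 30L, n_blocks = 2L)
  fit <- faking_mixture(sim$responses, sim$honest_probs,
                        control = quick_control(chains = 1L, iter = 300L,
                                                warmup = 100L), seed = 51L)
  bd <- fit$draws[[1L]]$beta
  R <- 6L
  for (m in 1:2) {
    b <- cbind(0, bd[, (m - 1L) * (R - 1L) + 1:5])
    expect_equal(fit$draws[[1L]]$alpha[, m],
                 block_fakability(softmax_rank_probs(b)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("fixing the variances removes their posterior variation", {
  sim <- small_sim(seed = 52L, n_persons = 40L, n_blocks = 3L)
  fit <- faking_mixture(sim$responses, sim$honest_probs,
                        priors = fm_priors(fix_var_theta = 0.25,
                                           fix_var_beta = 4),
                        control = quick_control(chains = 1L, iter = 300L,
                                                warmup = 100L), seed = 52L)
  expect_true(all(fit$draws[[1L]]$vtheta == 0.25))
  expect_true(all(fit$draws[[1L]]$vbeta == 4))
  expect_gt(sd(fit$draws[[1L]]$mtheta), 0)  # only M(theta) keeps a hyperprior
})

test_that("data without faking drive the faking probabilities low", {
  set.seed(53)
  sim <- small_sim(seed = 53L, n_persons = 80L, n_blocks = 4L,
                   condition = list(fakability = "low", theta_mean = 0,
                                    theta_var = 0.2))
  # use the honest responses as the high-stakes data: nobody fakes
  fit <- faking_mixture(sim$honest, sim$honest_probs,
                        control = quick_control(chains = 1L, iter = 600L,
                                                warmup = 200L), seed = 53L)
  pf <- predict(fit, type = "faking_probability")
  expect_lt(mean(pf), 0.35)
  mdraws <- unlist(lapply(fit$draws, `[[`, "mtheta"))
  expect_lt(median(mdraws), 0.5)
})

test_that("input validation names the offending cells", {
  sim <- small_sim(seed = 54L, n_persons = 10L, n_blocks = 2L)
  bad <- sim$responses; bad[3L, 2L] <- 9L
  expect_error(faking_mixture(bad, sim$honest_probs), "person 3, block 2")
  expect_error(faking_mixture(sim$responses, sim$honest_probs * 0.5),
               "sum to 1")
  expect_error(faking_mixture(sim$responses[, 1L, drop = FALSE],
                              sim$honest_probs), "persons x blocks")
})

test_that("convergence diagnostics flag divergent chains and pass stable
          ones", {
  # synthetic fit skeleton: two chains of pure noise around the same value
  make_fake_fit <- function(shift = 0) {
    set.seed(60)
    S <- 400L
    mk <- function(offset) {
      list(beta = matrix(rnorm(S * 2L, offset), S,
                         dimnames = list(NULL, c("beta[1,2]", "beta[1,3]"))),
           theta = matrix(rnorm(S, offset), S,
                          dimnames = list(NULL, "theta[1]")),
           mtheta = rnorm(S, offset), vtheta = abs(rnorm(S, 1 + offset)),
           vbeta = abs(rnorm(S, 4)))
    }
    structure(list(draws = list(mk(0), mk(shift)),
                   priors = fm_priors(),
                   control = fm_control(chains = 2L, iter = 500L,
                                        warmup = 100L),
                   dims = list()),
              class = "faking_mixture")
  }
  good <- fm_convergence(make_fake_fit(0))
  expect_true(good$pass)
  expect_true(all(good$table$rhat < 1.01))
  bad <- fm_convergence(make_fake_fit(3))
  expect_false(bad$pass)
  expect_true("theta[1]" %in% bad$failed)
  expect_true(any(grepl("beta", bad$failed)))
  # identical chains: scale reduction ~ 1
  f <- make_fake_fit(0)
  f$draws[[2L]] <- f$draws[[1L]]
  expect_true(fm_convergence(f)$pass)
})

test_that("posterior summaries handle degenerate draws", {
  co <- asNamespace("fakemix")$posterior_table(
    matrix(2, 50L, 1L, dimnames = list(NULL, "x")))
  expect_equal(co$median, 2)
  expect_equal(co$lower, 2)
  expect_equal(co$upper, 2)
})
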