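test_that("default trait correlations hold the published pattern", {
  m <- big_five_correlations()
  expect_equal(m["N", "E"], -0.36)
  expect_equal(m["N", "O"], -0.17)
  expect_equal(m["N", "C"], -0.43)
  expect_equal(m["E", "O"], 0.43)
  expect_equal(m["A", "C"], 0.43)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(eigen(m, only.values = TRUE)$values > 0))
})

test_that("content traits reproduce the target correlations", {
  tr <- draw_content_traits(1e5, seed = 2)
  expect_equal(dim(tr), c(1e5L, 5L))
  expect_lt(max(abs(cor(tr) - big_five_correlations())), 0.02)
  expect_lt(max(abs(colMeans(tr))), 0.02)
  tr0 <- draw_content_traits(2e4, corr = diag(3), seed = 3)
  off <- cor(tr0)[lower.tri(diag(3))]
  expect_lt(max(abs(off)), 0.03)
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(draw_content_traits(10, corr = bad), "positive definite")
})

test_that("item parameters respect ranges, keying and identifiability", {
  items <- draw_item_parameters(20L, seed = 4)
  expect_equal(nrow(items), 60L)
  expect_true(all(abs(items$loading) >= .65 & abs(items$loading) <= .95))
  expect_true(all(items$intercept > -1 & items$intercept < 1))
  expect_equal(items$error_variance, 1 - items$loading^2)
  per_block <- split(items, items$block_id)
  for (bl in per_block) {
    expect_equal(sum(bl$loading < 0), 1L)       # one reversed item
    expect_equal(anyDuplicated(bl$trait), 0L)   # distinct traits
  }
  # proportional/equal loading patterns are flagged as dependent
  dep <- asNamespace("fakemix")$block_loadings_dependent
  expect_true(dep(c(0.8, 0.8, 0.7)))
  expect_true(dep(c(0.9, 0.81, 0.729)))  # ratios both 1/0.9
  expect_false(dep(c(0.95, 0.8, 0.66)))
  expect_error(draw_item_parameters(2L, block_size = 6L, n_traits = 5L),
               "invalid design")
})

test_that("honest responses rank mean utilities when errors vanish", {
  items <- toy_items()
  items$intercept <- c(2, 1, 0, 0, 1, 2)
  items$loading <- rep(0, 6)
  items$error_variance <- rep(1e-12, 6)
  resp <- simulate_honest_responses(items, matrix(0, 5L, 3L), seed = 1)
  expect_true(all(resp[, 1L] == 1L))   # means (2,1,0) -> order 1-2-3
  expect_true(all(resp[, 2L] == 6L))   # means (0,1,2) -> order 3-2-1
})

test_that("honest response frequencies match analytic probabilities", {
  items <- toy_items()[1:3, ]
  items$loading <- 0; items$error_variance <- c(1, 0.5, 0.8)
  items$intercept <- c(0.3, 0, -0.2)
  n <- 2e4
  resp <- simulate_honest_responses(items, matrix(0, n, 3L), seed = 9)
  freq <- tabulate(resp[, 1L], 6L) / n
  for (r in 1:6) {
    p <- honest_rank_probability(items$intercept, items$error_variance, r)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[r] - p), 3 * se + 1e-4)
  }
})

test_that("faking parameter draws respect the condition's distributions", {
  fp_low <- draw_faking_parameters(list(fakability = "low", theta_mean = 0,
                                        theta_var = 0.2),
                                   n_blocks = 4000L, R = 6L,
                                   n_persons = 4000L, seed = 12)
  expect_true(all(abs(fp_low$beta) < 2))
  expect_lt(abs(mean(fp_low$theta)), 0.05)
  expect_lt(abs(var(fp_low$theta) - 0.2), 0.02)
  fp_high <- draw_faking_parameters(list(fakability = "high", theta_mean = 2,
                                         theta_var = 1),
                                    n_blocks = 4000L, R = 6L,
                                    n_persons = 4000L, seed = 13)
  expect_true(all(abs(fp_high$beta) < 4))
  expect_gt(max(abs(fp_high$beta)), 2)  # actually uses the wider range
  expect_lt(abs(mean(fp_high$theta) - 2), 0.06)
  # fakability operationalization: 90% of per-block max softmax
  # probabilities in about [.3,.6] (low) and [.4,.9] (high)
  mx_low <- apply(softmax_rank_probs(fp_low$beta), 1L, max)
  mx_high <- apply(softmax_rank_probs(fp_high$beta), 1L, max)
  expect_lt(abs(mean(mx_low >= .3 & mx_low <= .6) - 0.9), 0.1)
  expect_lt(abs(mean(mx_high >= .4 & mx_high <= .9) - 0.9), 0.1)
})

test_that("faking overlay reduces to the pure processes at extreme traits", {
  set.seed(21)
  K <- 3L; N <- 1500L
  honest <- matrix(sample.int(6L, N * K, TRUE), N, K)
  beta <- rbind(c(0, 3, 0, 0, 0, 0), c(0, 0, 2, 1, 0, 0), rep(0, 6))
  none <- simulate_faking_responses(honest, beta, rep(-40, N), seed = 1)
  expect_identical(none$responses, honest)
  expect_false(any(none$faked))
  all_fake <- simulate_faking_responses(honest, beta, rep(40, N), seed = 2)
  expect_true(all(all_fake$faked))
  p_fake <- softmax_rank_probs(beta)
  for (k in 1:2) {
    freq <- tabulate(all_fake$responses[, k], 6L) / N
    se <- sqrt(p_fake[k, ] * (1 - p_fake[k, ]) / N)
    expect_true(all(abs(freq - p_fake[k, ]) < 3 * se + 0.01))
  }
})

test_that("realized faked fractions track the probit probabilities", {
  set.seed(22)
  N <- 4000L; K <- 2L
  honest <- matrix(1L, N, K)
  beta <- rbind(c(0, 2, 1, 0, -1, 0), c(0, 0.5, 0, 0.5, 0, 0.5))
  theta <- rnorm(N, 0.5, 0.5)
  out <- simulate_faking_responses(honest, beta, theta, seed = 3)
  alpha <- block_fakability(softmax_rank_probs(beta))
  for (k in 1:K) {
    expected <- mean(pnorm(theta + alpha[k]))
    expect_lt(abs(mean(out$faked[, k]) - expected), 0.025)
  }
})

test_that("the condition grid crosses 2 x 3 x 3 levels exactly once", {
  g <- condition_grid()
  expect_equal(nrow(g), 18L)
  expect_equal(anyDuplicated(g[-1L]), 0L)
  expect_true(any(g$fakability == "low" & g$theta_mean == 0 &
                    g$theta_var == 0.2))
  expect_true(any(g$fakability == "high" & g$theta_mean == 2 &
                    g$theta_var == 1))
  expect_setequal(unique(g$theta_mean), c(0, 1, 2))
  expect_setequal(unique(g$theta_var), c(0.2, 0.5, 1))
})

test_that("a fixed seed reproduces a study bit for bit", {
  s1 <- simulate_fc_study(5L, n_persons = 20L, n_blocks = 3L,
                          honest_probs = FALSE, seed = 77)
  s2 <- simulate_fc_study(5L, n_persons = 20L, n_blocks = 3L,
                          honest_probs = FALSE, seed = 77)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$items, s2$items)
  # generated honest data fed back reproduce their generating probabilities
  # (single-block frequency check at a larger n)
  expect_s3_class(s1, "fm_simulation")
})

test_that("faked choices are unrelated to content traits when everyone fakes", {
  set.seed(30)
  sim <- simulate_fc_study(list(fakability = "high", theta_mean = 40,
                                theta_var = 0.01),
                           n_persons = 2000L, n_blocks = 2L,
                           honest_probs = FALSE, seed = 31)
  expect_true(all(sim$faked))
  for (k in 1:2) {
    cors <- abs(cor(sim$traits, sim$responses[, k]))
    expect_lt(max(cors), 0.08)
  }
})
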