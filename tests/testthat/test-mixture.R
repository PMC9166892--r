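test_that("softmax rank probabilities are correct and shift-invariant", {
  expect_equal(softmax_rank_probs(rep(0, 6)), rep(1 / 6, 6))
  expect_equal(softmax_rank_probs(c(0, log(2), 0, 0, 0, 0)),
               c(1, 2, 1, 1, 1, 1) / 7)
  b <- c(0.3, -1, 2, 0.5, 0, 1.2)
  expect_equal(softmax_rank_probs(b), softmax_rank_probs(b + 17))
  # matrix form is row-wise
  m <- rbind(rep(0, 6), c(0, log(2), 0, 0, 0, 0))
  expect_equal(softmax_rank_probs(m)[2L, ], c(1, 2, 1, 1, 1, 1) / 7)
  # large entries do not overflow
  expect_equal(sum(softmax_rank_probs(c(1000, 0, 0, 0, 0, 0))), 1)
  expect_error(softmax_rank_probs(c(0, NA, 1)), "finite")
})

test_that("block fakability follows the squared-deviation quantile", {
  # uniform profile: sum of squares 0, clamped at the floor
  expect_equal(block_fakability(rep(1 / 6, 6)), qnorm(1e-10))
  # fully degenerate profile: 5/6 -> qnorm(5/6)
  expect_equal(block_fakability(c(1, 0, 0, 0, 0, 0)), qnorm(5 / 6))
  expect_equal(qnorm(5 / 6), 0.9674, tolerance = 1e-4)
  expect_error(block_fakability(c(0.5, 0.2, 0.1)), "sum to 1")
  # matrix input gives one alpha per row; identical rows -> equal alphas
  p <- softmax_rank_probs(rbind(c(0, 1, 2, 0, 1, 0), c(0, 1, 2, 0, 1, 0)))
  a <- block_fakability(p)
  expect_equal(a[1L], a[2L])
})

test_that("sum of squared deviations is bounded by (R-1)/R on the simplex", {
  # brute-force grid over small simplices
  for (R in c(3L, 4L)) {
    grid <- seq(0, 1, by = 0.1)
    pts <- expand.grid(rep(list(grid), R - 1L))
    pts <- pts[rowSums(pts) <= 1 + 1e-12, , drop = FALSE]
    pts <- cbind(pts, 1 - rowSums(pts))
    ss <- rowSums((pts - 1 / R)^2)
    expect_lte(max(ss), (R - 1) / R + 1e-12)
  }
  # degenerate vertex attains the bound
  expect_equal(sum((c(1, rep(0, 5)) - 1 / 6)^2), 5 / 6)
})

test_that("sharpening a two-point softmax pattern never lowers alpha", {
  set.seed(11)
  for (i in 1:20) {
    b <- rep(0, 6)
    b[sample(2:6, 1L)] <- runif(1L, 0.1, 3)   # two-point pattern
    for (c_scale in c(1.5, 3)) {
      a1 <- block_fakability(softmax_rank_probs(b))
      a2 <- block_fakability(softmax_rank_probs(b * c_scale))
      expect_gte(a2, a1 - 1e-12)
    }
  }
})

test_that("faking probability is the probit of trait plus fakability", {
  expect_equal(faking_probability(0, 0), 0.5)
  expect_equal(faking_probability(-50, 0), 0)
  expect_equal(faking_probability(50, 0), 1)
  m <- faking_probability(c(-1, 0, 1), c(0.5, -0.5))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[2L, 1L], pnorm(0.5))
})

test_that("mixture probabilities are convex combinations summing to one", {
  honest <- c(0.4, 0.1, 0.2, 0.1, 0.1, 0.1)
  beta <- c(0, 2, -1, 0.5, 0, 1)
  p_fake <- softmax_rank_probs(beta)
  # extreme faking traits recover the pure components
  expect_equal(mixture_probability(50, beta, honest), p_fake)
  expect_equal(mixture_probability(-50, beta, honest), honest)
  p <- mixture_probability(0.3, beta, honest)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= pmin(honest, p_fake) - 1e-12 &
                    p <= pmax(honest, p_fake) + 1e-12))
  expect_error(mixture_probability(0, beta, honest * 2), "sum to 1")
})

test_that("log-likelihood matches exhaustive summation on a toy set", {
  set.seed(5)
  N <- 3L; K <- 2L; R <- 6L
  honest <- array(NA_real_, c(N, K, R))
  for (j in 1:N) for (k in 1:K) {
    w <- runif(R); honest[j, k, ] <- w / sum(w)
  }
  beta <- cbind(0, matrix(rnorm(K * (R - 1L)), K))
  theta <- c(-0.5, 0.2, 1.3)
  responses <- matrix(sample.int(R, N * K, TRUE), N, K)
  # independent oracle: enumerate person-block terms via mixture_probability
  oracle <- 0
  for (j in 1:N) for (k in 1:K) {
    p <- mixture_probability(theta[j], beta[k, ], honest[j, k, ])
    oracle <- oracle + log(p[responses[j, k]])
  }
  expect_equal(faking_mixture_loglik(responses, beta, theta, honest), oracle,
               tolerance = 1e-12)
  # person relabelling leaves the sum unchanged
  perm <- c(3L, 1L, 2L)
  expect_equal(
    faking_mixture_loglik(responses[perm, ], beta, theta[perm],
                          honest[perm, , , drop = FALSE]),
    oracle, tolerance = 1e-12)
  expect_error(
    faking_mixture_loglik(matrix(7L, 1L, 1L), beta[1L, , drop = FALSE],
                          0, honest[1L, 1L, , drop = FALSE]),
    "person 1, block 1")
})

test_that("a vanishing faking probability reduces to the honest likelihood", {
  honest <- array(1 / 6, c(1L, 1L, 6L))
  beta <- matrix(c(0, 1, 2, 0, 1, 0), 1L)
  ll <- faking_mixture_loglik(matrix(4L, 1L, 1L), beta, theta = -40,
                              honest = honest)
  expect_equal(ll, log(1 / 6), tolerance = 1e-9)
})
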