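test_that("family metrics match hand computation on a 5-value fixture", {
  fam <- asNamespace("fakemix")$one_family_metrics
  true <- c(1, 2, 3, 4, 5)
  bias <- c(0.1, -0.1, 0.2, 0, -0.2)
  # degenerate draws: every interval is the point estimate itself
  draws <- matrix(rep(true + bias, each = 10L), 10L)
  m <- fam("toy", true, draws)
  expect_equal(m$coverage, 0.2)              # only the zero-bias entry
  expect_equal(m$mean_bias, mean(bias))
  expect_equal(m$sd_bias, sd(bias))
  expect_equal(m$correlation, cor(true, true + bias))
  expect_equal(m$n, 5L)
  # estimates identical to the truth
  m0 <- fam("toy", true, matrix(rep(true, each = 10L), 10L))
  expect_equal(m0$coverage, 1)
  expect_equal(m0$mean_bias, 0)
  expect_equal(m0$correlation, 1)
  # unbounded intervals always cover
  wide <- rbind(matrix(-1e6, 2L, 5L), matrix(rep(true, each = 96L), 96L),
                matrix(1e6, 2L, 5L))
  expect_equal(fam("toy", true, wide)$coverage, 1)
})

test_that("recovery metrics align families between truth and fit", {
  sim <- small_sim(seed = 80L, n_persons = 40L, n_blocks = 3L)
  fit <- faking_mixture(sim$responses, sim$honest_probs,
                        control = quick_control(chains = 1L, iter = 400L,
                                                warmup = 150L), seed = 80L)
  met <- recovery_metrics(sim, fit)
  expect_setequal(met$family, c("theta", "beta", "M(theta)", "Var(theta)",
                                "Var(beta)", "alpha", "pfake"))
  expect_equal(met$n[met$family == "beta"], 3L * 5L)
  expect_equal(met$n[met$family == "pfake"], 3L * 6L)
  expect_true(all(met$coverage >= 0 & met$coverage <= 1))
  expect_true(all(is.na(met$correlation) |
                    abs(met$correlation) <= 1 + 1e-12))
  # misalignment is reported with the family name
  bad <- sim; bad$theta <- bad$theta[-1L]
  expect_error(recovery_metrics(bad, fit), "theta")
})

test_that("variance decomposition matches a brute-force sums-of-squares
          oracle", {
  set.seed(81)
  grid <- condition_grid()
  reps <- 3L
  df <- grid[rep(seq_len(18L), each = reps), ]
  df$value <- rnorm(nrow(df))
  ve <- variance_explained(df)
  expect_equal(sum(ve$pct), 100, tolerance = 1e-8)

  # independent oracle: balanced-design SS from cell and marginal means
  g <- mean(df$value)
  ss_total <- sum((df$value - g)^2)
  mean_by <- function(...) {
    tapply(df$value, lapply(list(...), function(f) df[[f]]), mean)
  }
  eff1 <- function(f) {
    m <- mean_by(f)
    sum(table(df[[f]]) * (m - g)^2)
  }
  ss1 <- c(eff1("fakability"), eff1("theta_mean"), eff1("theta_var"))
  eff2 <- function(f1, f2) {
    cell <- mean_by(f1, f2)
    m1 <- mean_by(f1); m2 <- mean_by(f2)
    dev <- sweep(sweep(cell, 1L, m1), 2L, m2) + g
    sum(table(df[[f1]], df[[f2]]) * dev^2)
  }
  ss2 <- c(eff2("fakability", "theta_mean"), eff2("fakability", "theta_var"),
           eff2("theta_mean", "theta_var"))
  cell3 <- mean_by("fakability", "theta_mean", "theta_var")
  ss_cells <- sum(table(df$fakability, df$theta_mean, df$theta_var) *
                    (cell3 - g)^2)
  ss3 <- ss_cells - sum(ss1) - sum(ss2)
  ss_res <- ss_total - ss_cells
  oracle <- 100 * c(ss1, ss2, ss3, ss_res) / ss_total
  expect_equal(ve$pct, oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate metrics decompose as expected", {
  grid <- condition_grid()
  df <- grid[rep(seq_len(18L), each = 2L), ]
  df$value <- 0.5
  ve <- variance_explained(df)
  expect_equal(ve$pct[ve$term == "residual"], 100)
  df$value <- ifelse(df$fakability == "high", 1, 0)
  ve2 <- variance_explained(df)
  expect_equal(ve2$pct[ve2$term == "fakability"], 100, tolerance = 1e-8)
  drop_cell <- !(df$fakability == "low" & df$theta_mean == 0 &
                   df$theta_var == 0.2)
  expect_error(variance_explained(df[drop_cell, ]), "short cells")
})

test_that("a reduced recovery run emits a well-formed, reproducible report", {
  ctl <- quick_control(chains = 1L, iter = 250L, warmup = 100L)
  run <- function() {
    run_recovery_study(conditions = c(1L, 14L), n_reps = 2L,
                       n_persons = 25L, n_blocks = 2L, control = ctl,
                       seed = 99L)
  }
  rep1 <- run()
  expect_s3_class(rep1, "fm_recovery_report")
  expect_equal(length(unique(rep1$metrics$seed)), 4L)
  expect_true(all(c("family", "coverage", "correlation", "mean_bias",
                    "sd_bias", "fakability", "replication") %in%
                    names(rep1$metrics)))
  expect_null(rep1$variance_explained)  # grid incomplete on purpose
  expect_true(is.null(rep1$failures))
  # regeneration from the same seed is bit-identical
  rep2 <- run()
  expect_identical(rep1$metrics, rep2$metrics)
})
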