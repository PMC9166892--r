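#' Parameter-recovery metrics for one fitted replication
#'
#' Compares posterior summaries against the generating values, separately
#' per parameter family: faking traits `theta`, free rank-order parameters
#' `beta` (true values mapped to the identified scale
#' \eqn{\beta_{kr} - \beta_{k1}}, matching the model's \eqn{\beta_{k1} = 0}
#' constraint), hyperparameters `M(theta)`, `Var(theta)`, `Var(beta)` (true
#' value: the empirical variance of the identified free betas), and the
#' derived `alpha` and faking rank-order probabilities `pfake`.
#'
#' Metrics per family: coverage of the 95% posterior intervals, correlation
#' between true values and posterior medians, mean bias (median minus
#' true), and the SD of the bias across the family's parameters (scalar
#' families report `NA` for correlation and SD).
#'
#' @param truth an `"fm_simulation"` object, or a list with fields `beta`
#'   (blocks x R), `theta`, `alpha`, and `condition` (with `theta_mean`,
#'   `theta_var`).
#' @param fit the `"faking_mixture"` fit of the replication.
#' @return Data frame with one row per family: `family`, `coverage`,
#'   `correlation`, `mean_bias`, `sd_bias`, `n`.
#' @export
recovery_metrics <- function(truth, fit) {
  R <- fit$dims$n_orders
  M <- fit$dims$n_beta_blocks
  if (nrow(truth$beta) != M || ncol(truth$beta) != R) {
    stop("misaligned family 'beta': truth is ", nrow(truth$beta), "x",
         ncol(truth$beta), ", fit expects ", M, "x", R, call. = FALSE)
  }
  if (length(truth$theta) != fit$dims$n_persons) {
    stop("misaligned family 'theta': ", length(truth$theta), " true values ",
         "vs ", fit$dims$n_persons, " persons", call. = FALSE)
  }
  beta_free <- truth$beta[, -1L, drop = FALSE] - truth$beta[, 1L]
  true_vals <- list(
    theta = as.numeric(truth$theta),
    beta = as.vector(t(beta_free)),
    `M(theta)` = truth$condition$theta_mean,
    `Var(theta)` = truth$condition$theta_var,
    `Var(beta)` = var(as.vector(beta_free)),
    alpha = as.numeric(truth$alpha),
    pfake = as.vector(softmax_rank_probs(truth$beta))
  )
  draw_mats <- list(
    theta = pooled_draws(fit, "theta"),
    beta = pooled_draws(fit, "beta"),
    `M(theta)` = pooled_draws(fit, "mtheta"),
    `Var(theta)` = pooled_draws(fit, "vtheta"),
    `Var(beta)` = pooled_draws(fit, "vbeta"),
    alpha = pooled_draws(fit, "alpha"),
    pfake = pooled_draws(fit, "pfake")
  )
  rows <- lapply(names(true_vals), function(nm) {
    one_family_metrics(nm, true_vals[[nm]], draw_mats[[nm]])
  })
  do.call(rbind, rows)
}

one_family_metrics <- function(name, true, draws) {
  med <- apply(draws, 2L, median)
  lo <- apply(draws, 2L, quantile, probs = .025, names = FALSE)
  hi <- apply(draws, 2L, quantile, probs = .975, names = FALSE)
  if (length(true) != length(med)) {
    stop("misaligned family '", name, "'", call. = FALSE)
  }
  bias <- med - true
  data.frame(
    family = name,
    coverage = mean(true >= lo & true <= hi),
    correlation = if (length(true) > 1L && sd(true) > 0 && sd(med) > 0)
      cor(true, med) else NA_real_,
    mean_bias = mean(bias),
    sd_bias = if (length(true) > 1L) sd(bias) else NA_real_,
    n = length(true))
}

#' Variance explained by the simulation design factors
#'
#' Descriptive sums-of-squares decomposition of a replication-level
#' recovery metric over the full-factorial three-factor design (fakability
#' x faking trait mean x faking trait variance), with all two- and
#' three-way interactions and a residual, each reported as a percentage of
#' the total sum of squares. No F-tests are computed: the decomposition is
#' descriptive and insensitive to variance heterogeneity across cells.
#'
#' @param data data frame with columns `fakability`, `theta_mean`,
#'   `theta_var` and the metric in `value` (one row per replication).
#' @param value name of the metric column.
#' @return Data frame with columns `term` and `pct` summing to 100.
#' @export
variance_explained <- function(data, value = "value") {
  need <- c("fakability", "theta_mean", "theta_var", value)
  if (!all(need %in% names(data))) {
    stop("'data' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- data[is.finite(data[[value]]), , drop = FALSE]
  cells <- table(data$fakability, data$theta_mean, data$theta_var)
  if (any(cells < 2L)) {
    idx <- which(cells < 2L, arr.ind = TRUE)
    miss <- apply(idx, 1L, function(i) {
      paste0("(", dimnames(cells)[[1L]][i[1L]], ", M=",
             dimnames(cells)[[2L]][i[2L]], ", Var=",
             dimnames(cells)[[3L]][i[3L]], ")")
    })
    stop("need >= 2 replications per condition; short cells: ",
         paste(utils::head(miss, 6L), collapse = " "), call. = FALSE)
  }
  df <- data.frame(F1 = factor(data$fakability),
                   F2 = factor(data$theta_mean),
                   F3 = factor(data$theta_var),
                   y = data[[value]])
  # descriptive SS only; aov's F-machinery may warn on perfect fits
  ss <- suppressWarnings(anova(aov(y ~ F1 * F2 * F3, data = df))[["Sum Sq"]])
  terms <- c("fakability", "theta_mean", "theta_var",
             "fakability:theta_mean", "fakability:theta_var",
             "theta_mean:theta_var", "fakability:theta_mean:theta_var",
             "residual")
  pct <- if (sum(ss) < .Machine$double.eps) {
    c(rep(0, length(terms) - 1L), 100)   # constant metric: all residual
  } else {
    100 * ss / sum(ss)
  }
  data.frame(term = terms, pct = pct)
}

#' Run a parameter-recovery simulation study
#'
#' For every condition and replication: simulate a study
#' ([simulate_fc_study()]), compute honest probabilities, fit the Faking
#' Mixture model, and compute [recovery_metrics()]. Aggregates per-condition
#' means and SDs of each metric and, when every condition of the full grid
#' has at least two successful replications, the [variance_explained()]
#' decomposition per family and metric. Individual fit failures are logged
#' and excluded, with the count reported.
#'
#' Replication seeds are derived deterministically from `seed`, so a report
#' can be regenerated exactly from its configuration.
#'
#' @param conditions rows of [condition_grid()] (or their indices) to run.
#' @param n_reps replications per condition.
#' @param n_persons,n_blocks,block_size,n_traits design scale per
#'   replication.
#' @param priors,control estimation settings; the default control here is a
#'   reduced budget (1 chain of 800 iterations, 200 warmup) suited to
#'   many-replication runs — pass `fm_control()` for the full settings.
#' @param seed master seed.
#' @param verbose print progress lines.
#' @return Object of class `"fm_recovery_report"`: list with `metrics`
#'   (long data frame), `condition_summary`, `variance_explained`,
#'   `failures`, `config`.
#' @export
run_recovery_study <- function(conditions = seq_len(18L), n_reps = 2L,
                               n_persons = 100L, n_blocks = 10L,
                               block_size = 3L, n_traits = 5L,
                               priors = fm_priors(),
                               control = fm_control(chains = 1L, iter = 800L,
                                                    warmup = 200L),
                               seed = 1L, verbose = FALSE) {
  grid <- condition_grid()
  if (is.numeric(conditions)) conditions <- grid[conditions, ]
  rows <- list(); failures <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    for (rep in seq_len(n_reps)) {
      rep_seed <- seed + 1000L * (i - 1L) + rep
      if (verbose) {
        message(sprintf("condition %s/M=%g/Var=%g, replication %d (seed %d)",
                        cond$fakability, cond$theta_mean, cond$theta_var,
                        rep, rep_seed))
      }
      res <- tryCatch({
        sim <- simulate_fc_study(cond, n_persons = n_persons,
                                 n_blocks = n_blocks,
                                 block_size = block_size,
                                 n_traits = n_traits, seed = rep_seed)
        fit <- faking_mixture(sim$responses, sim$honest_probs,
                              priors = priors, control = control,
                              seed = rep_seed)
        met <- recovery_metrics(sim, fit)
        met$fakability <- cond$fakability
        met$theta_mean <- cond$theta_mean
        met$theta_var <- cond$theta_var
        met$replication <- rep
        met$seed <- rep_seed
        met
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(fakability = cond$fakability,
                     theta_mean = cond$theta_mean,
                     theta_var = cond$theta_var, replication = rep,
                     seed = rep_seed, message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  if (is.null(metrics)) {
    stop("recovery study produced no successful replications", call. = FALSE)
  }

  agg <- stats::aggregate(
    metrics[c("coverage", "correlation", "mean_bias", "sd_bias")],
    by = metrics[c("fakability", "theta_mean", "theta_var", "family")],
    FUN = function(x) mean(x, na.rm = TRUE))
  agg <- agg[order(agg$family, agg$fakability, agg$theta_mean,
                   agg$theta_var), ]

  ve <- NULL
  full <- merge(grid, unique(metrics[c("fakability", "theta_mean",
                                       "theta_var")]))
  if (nrow(full) == nrow(grid)) {
    ve_rows <- list()
    for (fam in unique(metrics$family)) {
      for (met in c("coverage", "correlation", "mean_bias", "sd_bias")) {
        sub <- metrics[metrics$family == fam, ]
        sub$value <- sub[[met]]
        if (all(is.na(sub$value))) next
        tab <- tryCatch(variance_explained(sub), error = function(e) NULL)
        if (!is.null(tab)) {
          tab$family <- fam; tab$metric <- met
          ve_rows[[length(ve_rows) + 1L]] <- tab
        }
      }
    }
    if (length(ve_rows)) ve <- do.call(rbind, ve_rows)
  }
  structure(list(metrics = metrics, condition_summary = agg,
                 variance_explained = ve, failures = failures,
                 config = list(n_reps = n_reps, n_persons = n_persons,
                               n_blocks = n_blocks, block_size = block_size,
                               n_traits = n_traits, seed = seed,
                               control = control, priors = priors)),
            class = "fm_recovery_report")
}

#' @export
print.fm_recovery_report <- function(x, digits = 3L, ...) {
  cfg <- x$config
  cat("Parameter-recovery study\n")
  cat(sprintf("  scale: %d persons, %d blocks of %d; %d replications/condition\n",
              cfg$n_persons, cfg$n_blocks, cfg$block_size, cfg$n_reps))
  nf <- if (is.null(x$failures)) 0L else nrow(x$failures)
  cat(sprintf("  replications: %d ok, %d failed\n",
              length(unique(interaction(x$metrics$seed))), nf))
  cat("\nMean metrics across conditions, by family:\n")
  fam_mean <- stats::aggregate(
    x$metrics[c("coverage", "correlation", "mean_bias", "sd_bias")],
    by = x$metrics["family"], FUN = function(v) mean(v, na.rm = TRUE))
  print(format(fam_mean, digits = digits), row.names = FALSE)
  if (!is.null(x$variance_explained)) {
    cat("\nVariance explained (%) available for",
        length(unique(x$variance_explained$family)), "families;",
        "see $variance_explained\n")
  }
  invisible(x)
}
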