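#' Convergence diagnostics for a Faking Mixture fit
#'
#' Computes the split-chain potential scale reduction statistic
#' \eqn{\hat{R}} and the effective sample size for every sampled parameter
#' (free \eqn{\beta}, \eqn{\theta}, and the non-fixed hyperparameters). A
#' parameter fails when \eqn{\hat{R} \ge 1.01} (strict) or when its
#' effective sample size divided by the number of stored draws is
#' \eqn{\le .001}.
#'
#' @param fit a `"faking_mixture"` object.
#' @param rhat_max failure threshold for \eqn{\hat{R}} (strict inequality
#'   `rhat < rhat_max` passes).
#' @param ess_ratio_min failure threshold for ESS / draws (strict
#'   inequality `ratio > ess_ratio_min` passes).
#' @return Object of class `"fm_convergence"`: a list with `table`
#'   (parameter, rhat, ess, ess_ratio, pass), `pass` (overall flag) and
#'   `failed` (offending parameter names). With a single chain, split
#'   halves of that chain are used and a warning notes the limitation.
#' @export
fm_convergence <- function(fit, rhat_max = 1.01, ess_ratio_min = 0.001) {
  mats <- list(beta = stack_draws(fit, "beta"),
               theta = stack_draws(fit, "theta"),
               `M(theta)` = stack_draws(fit, "mtheta"))
  if (is.null(fit$priors$fix_var_theta)) {
    mats$`Var(theta)` <- stack_draws(fit, "vtheta")
  }
  if (is.null(fit$priors$fix_var_beta)) {
    mats$`Var(beta)` <- stack_draws(fit, "vbeta")
  }
  if (fit$control$chains < 2L) {
    warning("single chain: diagnostics use split halves of one chain only",
            call. = FALSE)
  }
  rows <- lapply(names(mats), function(nm) {
    arr <- mats[[nm]]
    pn <- dimnames(arr)[[3L]] %||% nm
    data.frame(parameter = pn,
               rhat = apply(arr, 3L, split_rhat),
               ess = apply(arr, 3L, ess_basic), row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  n_draws <- dim(mats[[1L]])[1L] * dim(mats[[1L]])[2L]
  tab$ess_ratio <- tab$ess / n_draws
  tab$pass <- tab$rhat < rhat_max & tab$ess_ratio > ess_ratio_min
  structure(list(table = tab, pass = all(tab$pass),
                 failed = tab$parameter[!tab$pass],
                 thresholds = c(rhat_max = rhat_max,
                                ess_ratio_min = ess_ratio_min)),
            class = "fm_convergence")
}

#' @export
print.fm_convergence <- function(x, ...) {
  cat("Convergence diagnostics:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  max rhat = %.4f, min ESS ratio = %.4f over %d parameters\n",
              max(x$table$rhat), min(x$table$ess_ratio), nrow(x$table)))
  if (!x$pass) {
    cat("  failing:", paste(utils::head(x$failed, 10L), collapse = ", "),
        if (length(x$failed) > 10L) "...", "\n")
  }
  invisible(x)
}

# split each chain in half, then the usual between/within variance ratio
split_rhat <- function(draws) {
  draws <- as.matrix(draws)              # iterations x chains
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)  # constant draws
  sqrt((n - 1) / n + B / (n * W))
}

# effective sample size from chain-averaged autocorrelations, truncated at
# the first negative paired sum (initial monotone sequence estimator)
ess_basic <- function(draws, max_lag = NULL) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  max_lag <- max_lag %||% min(n - 2L, 500L)
  acs <- sapply(seq_len(m), function(ch) {
    x <- draws[, ch] - mean(draws[, ch])
    v <- sum(x^2) / n
    if (v < .Machine$double.eps) return(rep(0, max_lag + 1L))
    vapply(0:max_lag, function(l) {
      sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / n / v
    }, numeric(1L))
  })
  rho <- rowMeans(acs)
  if (all(rho == 0)) return(n * m)       # constant chains
  s <- 0; l <- 1L
  while (l + 1L <= max_lag) {
    pair <- rho[l + 1L] + rho[l + 2L]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    l <- l + 2L
  }
  max(1, n * m / (1 + 2 * s))
}
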