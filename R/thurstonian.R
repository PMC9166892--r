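#' Mean utilities under the Thurstonian model
#'
#' Each item's latent utility for a person is a linear function of one
#' content trait: `intercept + loading * trait`, plus a normal error with
#' variance `error_variance` that is *not* added here — errors enter either
#' through the covariance of the orthant integral
#' ([honest_rank_probability()]) or as explicit draws in the simulator
#' ([simulate_honest_responses()]).
#'
#' @param items item-parameter table as returned by [draw_item_parameters()]
#'   or [read_item_params()]: a data frame with columns `item_id`,
#'   `block_id`, `trait`, `intercept`, `loading`, `error_variance`.
#' @param traits numeric matrix of content trait scores, persons x traits.
#' @return Numeric matrix, persons x items, of mean utilities.
#' @export
utility_means <- function(items, traits) {
  items <- check_items(items)
  traits <- as.matrix(traits)
  if (any(items$trait < 1L | items$trait > ncol(traits))) {
    stop("configuration error: item 'trait' index outside 1..", ncol(traits),
         call. = FALSE)
  }
  mu <- matrix(items$intercept, nrow(traits), nrow(items), byrow = TRUE)
  mu + traits[, items$trait, drop = FALSE] *
    matrix(items$loading, nrow(traits), nrow(items), byrow = TRUE)
}

check_items <- function(items) {
  need <- c("item_id", "block_id", "trait", "intercept", "loading",
            "error_variance")
  if (!is.data.frame(items) || !all(need %in% names(items))) {
    stop("'items' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(items$error_variance <= 0)) {
    stop("item error variances must be strictly positive", call. = FALSE)
  }
  sizes <- table(items$block_id)
  if (length(unique(sizes)) != 1L) {
    stop("invalid block design: all blocks must have the same size",
         call. = FALSE)
  }
  items
}

#' Probability of one rank order under honest responding
#'
#' Under Thurstone's law of comparative judgment, a person ranks the items of
#' a block by the magnitudes of their latent utilities
#' \eqn{t_i = m_i + \epsilon_i}, \eqn{\epsilon_i \sim N(0, \psi_i^2)}
#' independently. The probability of a given rank order is the probability
#' that all successive differences of the utilities, sorted by that order,
#' are positive: a \eqn{(B-1)}-dimensional positive-orthant probability of a
#' multivariate normal with mean \eqn{A m_{(r)}} and covariance
#' \eqn{A \,\mathrm{diag}(\psi^2_{(r)})\, A^\top}, where \eqn{A} is
#' [comparison_matrix()].
#'
#' The orthant integral is evaluated with deterministic routines from
#' \pkg{mvtnorm} (exact univariate normal for `B = 2`, TVPACK for
#' `B` in 3:4, Miwa otherwise), with an absolute accuracy target of `1e-6`.
#' If the deterministic routine fails, a quasi-Monte-Carlo estimate
#' (Genz–Bretz) is returned with a warning; its error bound is attached as
#' attribute `"error"`.
#'
#' @param mean_utilities numeric vector of length `B`: mean utility of each
#'   item of the block (in item-label order).
#' @param error_variances numeric vector of length `B` of positive error
#'   variances.
#' @param order integer permutation of `1:B`, items in descending
#'   preference, or a canonical order index.
#' @return The rank-order probability, a scalar in `[0, 1]`.
#' @examples
#' # exchangeable items: every order of a triplet has probability 1/6
#' honest_rank_probability(c(0, 0, 0), c(1, 1, 1), c(1, 2, 3))
#' @export
honest_rank_probability <- function(mean_utilities, error_variances, order) {
  B <- length(mean_utilities)
  if (length(error_variances) != B) {
    stop("'mean_utilities' and 'error_variances' must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(error_variances)) || any(error_variances <= 0)) {
    stop("error variances must be finite and strictly positive",
         call. = FALSE)
  }
  if (length(order) == 1L) {
    order <- unclass(rank_orders(B))[as.integer(order), ]
  }
  if (!setequal(order, seq_len(B))) {
    stop("'order' is not a permutation of 1..", B, call. = FALSE)
  }
  m <- mean_utilities[order]
  v <- error_variances[order]
  A <- comparison_matrix(B)
  md <- drop(A %*% m)
  Sd <- A %*% diag(v, B) %*% t(A)
  orthant_upper(md, Sd)
}

# P(Z > 0) for Z ~ N(md, Sd); deterministic algorithms with QMC fallback.
orthant_upper <- function(md, Sd, abseps = 1e-6) {
  d <- length(md)
  if (d == 1L) return(unname(pnorm(md[1L] / sqrt(Sd[1L, 1L]))))
  alg <- if (d <= 3L) mvtnorm::TVPACK(abseps) else mvtnorm::Miwa(steps = 128L)
  p <- tryCatch(
    mvtnorm::pmvnorm(lower = rep(0, d), upper = rep(Inf, d), mean = md,
                     sigma = Sd, algorithm = alg),
    error = function(e) NULL)
  if (is.null(p) || is.na(p[1L])) {
    p <- tryCatch(
      mvtnorm::pmvnorm(lower = rep(0, d), upper = rep(Inf, d), mean = md,
                       sigma = Sd,
                       algorithm = mvtnorm::GenzBretz(abseps = abseps)),
      error = function(e) stop("numerical error in orthant integration: ",
                               conditionMessage(e), call. = FALSE))
    warning("deterministic orthant integration failed; quasi-Monte-Carlo ",
            "estimate used (error bound ", signif(attr(p, "error"), 3), ")",
            call. = FALSE)
    return(structure(min(max(p[1L], 0), 1), error = attr(p, "error")))
  }
  min(max(p[1L], 0), 1)
}

#' Honest rank-order probability table
#'
#' Computes, for every person and block, the probability of each of the
#' `R = B!` rank orders under honest responding. Per person-block, the `R`
#' probabilities are rescaled to sum exactly to 1 (divided by their sum),
#' absorbing numerical integration error; if any pre-rescaling sum deviates
#' from 1 by more than `warn_tol`, the offending cells are reported in a
#' warning.
#'
#' @inheritParams utility_means
#' @param warn_tol tolerance on the pre-rescaling per-cell probability sum.
#' @param rescale logical; divide by the per-cell sum (default `TRUE`).
#' @return Numeric array, persons x blocks x R, with per-cell sums equal to
#'   1 after rescaling. Block order follows the sorted unique `block_id`.
#' @export
honest_probabilities <- function(items, traits, rescale = TRUE,
                                 warn_tol = 1e-3) {
  items <- check_items(items)
  traits <- as.matrix(traits)
  mu <- utility_means(items, traits)
  blocks <- sort(unique(items$block_id))
  B <- sum(items$block_id == blocks[1L])
  R <- factorial(B)
  perms <- unclass(rank_orders(B))
  A <- comparison_matrix(B)
  N <- nrow(traits)
  out <- array(NA_real_, dim = c(N, length(blocks), R),
               dimnames = list(NULL, paste0("block_", blocks),
                               apply(perms, 1L, paste, collapse = "-")))
  bad <- character(0L)
  for (k in seq_along(blocks)) {
    cols <- which(items$block_id == blocks[k])
    v <- items$error_variance[cols]
    # covariance of the difference vector is person-invariant per order
    covs <- lapply(seq_len(R), function(r) {
      A %*% diag(v[perms[r, ]], B) %*% t(A)
    })
    for (j in seq_len(N)) {
      m <- mu[j, cols]
      p <- vapply(seq_len(R), function(r) {
        orthant_upper(drop(A %*% m[perms[r, ]]), covs[[r]])
      }, numeric(1L))
      s <- sum(p)
      if (abs(s - 1) > warn_tol) {
        bad <- c(bad, sprintf("person %d / block %s (sum %.6f)", j,
                              blocks[k], s))
      }
      out[j, k, ] <- if (rescale) p / s else p
    }
  }
  if (length(bad)) {
    warning("pre-rescaling probability sums deviate from 1 beyond ",
            warn_tol, " for: ", paste(utils::head(bad, 5L), collapse = "; "),
            if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
            call. = FALSE)
  }
  out
}
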