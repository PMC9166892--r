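#' Big Five trait correlations used by the default generator
#'
#' Meta-analytic correlations between neuroticism (N), extraversion (E),
#' openness (O), agreeableness (A) and conscientiousness (C) used as the
#' default content-trait correlation matrix of the simulator.
#'
#' @return A 5 x 5 correlation matrix with dimnames `N, E, O, A, C`.
#' @export
big_five_correlations <- function() {
  tr <- c("N", "E", "O", "A", "C")
  m <- diag(5)
  dimnames(m) <- list(tr, tr)
  m["N", "E"] <- -.36; m["N", "O"] <- -.17; m["N", "A"] <- -.36
  m["N", "C"] <- -.43
  m["E", "O"] <- .43; m["E", "A"] <- .26; m["E", "C"] <- .29
  m["O", "A"] <- .21; m["O", "C"] <- .20
  m["A", "C"] <- .43
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Draw correlated content traits
#'
#' Samples latent content traits from a multivariate normal with mean 0,
#' unit variances and the given correlation matrix.
#'
#' @param n_persons number of persons.
#' @param corr trait correlation matrix (unit diagonal, positive definite);
#'   defaults to [big_five_correlations()].
#' @param seed optional integer seed for reproducibility.
#' @return `n_persons` x `ncol(corr)` matrix of trait scores.
#' @export
draw_content_traits <- function(n_persons, corr = big_five_correlations(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  corr <- as.matrix(corr)
  if (!isSymmetric(unname(corr)) || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("configuration error: 'corr' must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("configuration error: 'corr' is not positive definite",
         call. = FALSE)
  }
  MASS::mvrnorm(n_persons, mu = rep(0, ncol(corr)), Sigma = corr)
}

#' Draw item parameters for a forced-choice questionnaire
#'
#' Generates a questionnaire of `n_blocks` blocks of `block_size` items
#' each, with standardized utilities: intercepts uniform on (-1, 1), loading
#' magnitudes uniform on (.65, .95), and error variances
#' \eqn{\psi^2 = 1 - \lambda^2}. Traits are assigned cyclically so that
#' items within a block measure distinct traits. Loading signs follow the
#' keying plan: by default one item per block is negatively keyed, so two of
#' the three pairwise comparisons in a triplet are between differently keyed
#' items. A block proposal is rejected and redrawn when its loadings are
#' linearly dependent — any two within-block loading ratios equal within
#' `dep_tol`, or two loadings equal in magnitude within `dep_tol` — since
#' such blocks do not identify normative trait levels.
#'
#' @param n_blocks number of blocks.
#' @param block_size items per block (must not exceed `n_traits`).
#' @param n_traits number of content traits.
#' @param n_negative number of negatively keyed items per block.
#' @param dep_tol tolerance of the linear-dependency rejection rule.
#' @param max_tries cap on redraws per block before erroring.
#' @param seed optional integer seed.
#' @return Item-parameter data frame with columns `item_id`, `block_id`,
#'   `trait`, `intercept`, `loading`, `error_variance`.
#' @export
draw_item_parameters <- function(n_blocks, block_size = 3L, n_traits = 5L,
                                 n_negative = 1L, dep_tol = 1e-3,
                                 max_tries = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block_size <- check_block_size(block_size)
  if (block_size > n_traits) {
    stop("invalid design: 'block_size' exceeds 'n_traits' (items within a ",
         "block must measure distinct traits)", call. = FALSE)
  }
  rows <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    traits <- ((k - 1L) * block_size + seq_len(block_size) - 1L) %%
      n_traits + 1L
    signs <- rep(1, block_size)
    if (n_negative > 0L) {
      signs[sample.int(block_size, n_negative)] <- -1
    }
    for (try in seq_len(max_tries)) {
      lam <- runif(block_size, .65, .95)
      if (!block_loadings_dependent(lam, dep_tol)) break
      if (try == max_tries) {
        stop("design error: could not draw linearly independent loadings ",
             "for block ", k, " in ", max_tries, " tries; consider a ",
             "different keying plan", call. = FALSE)
      }
    }
    lam <- lam * signs
    rows[[k]] <- data.frame(
      item_id = (k - 1L) * block_size + seq_len(block_size),
      block_id = k,
      trait = traits,
      intercept = runif(block_size, -1, 1),
      loading = lam,
      error_variance = 1 - lam^2
    )
  }
  do.call(rbind, rows)
}

# Reject blocks whose loading magnitudes have (near-)equal entries or
# duplicated pairwise ratios: such patterns are linearly dependent in the
# sense relevant for identification of normative traits.
block_loadings_dependent <- function(lam, tol = 1e-3) {
  a <- abs(lam)
  pairs <- utils::combn(length(a), 2L)
  ratios <- a[pairs[1L, ]] / a[pairs[2L, ]]
  if (any(abs(ratios - 1) < tol)) return(TRUE)
  if (length(ratios) > 1L &&
      any(abs(outer(ratios, ratios, `-`))[lower.tri(diag(length(ratios)))] <
          tol)) {
    return(TRUE)
  }
  FALSE
}

#' Simulate honest rank-order responses
#'
#' Adds independent normal errors (variance `error_variance`) to each
#' item's mean utility and ranks items within each block by decreasing
#' realized utility. Exact utility ties (possible only at degenerate
#' parameter values) are broken by stable item order.
#'
#' @inheritParams utility_means
#' @param seed optional integer seed.
#' @return Persons x blocks integer matrix of canonical order indices.
#' @export
simulate_honest_responses <- function(items, traits, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  items <- check_items(items)
  traits <- as.matrix(traits)
  mu <- utility_means(items, traits)
  util <- mu + matrix(rnorm(length(mu), sd = rep(sqrt(items$error_variance),
                                                 each = nrow(mu))),
                      nrow(mu))
  blocks <- sort(unique(items$block_id))
  out <- matrix(NA_integer_, nrow(traits), length(blocks))
  for (k in seq_along(blocks)) {
    cols <- which(items$block_id == blocks[k])
    ord <- apply(util[, cols, drop = FALSE], 1L, function(u) {
      rank_order_index(order(-u))    # order() breaks ties by position
    })
    out[, k] <- ord
  }
  colnames(out) <- paste0("block_", blocks)
  out
}

#' The crossed simulation design
#'
#' The generator's study design crosses three factors: block fakability
#' (`low`: rank-order parameters uniform on (-2, 2); `high`: uniform on
#' (-4, 4)), faking trait mean (0, 1, 2) and faking trait variance (0.2,
#' 0.5, 1), giving 18 conditions. Conditions are ordered with fakability
#' varying slowest, then the mean, then the variance.
#'
#' @return Data frame with columns `condition`, `fakability`, `theta_mean`,
#'   `theta_var` (18 rows).
#' @export
condition_grid <- function() {
  g <- expand.grid(theta_var = c(0.2, 0.5, 1), theta_mean = c(0, 1, 2),
                   fakability = c("low", "high"),
                   stringsAsFactors = FALSE)[, 3:1]
  data.frame(condition = seq_len(nrow(g)), g, row.names = NULL)
}

as_condition <- function(condition) {
  if (is.numeric(condition) && length(condition) == 1L) {
    grid <- condition_grid()
    if (condition < 1 || condition > nrow(grid)) {
      stop("condition index out of 1..", nrow(grid), call. = FALSE)
    }
    return(grid[condition, ])
  }
  condition <- as.list(condition)
  need <- c("fakability", "theta_mean", "theta_var")
  if (!all(need %in% names(condition))) {
    stop("a condition needs fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!condition$fakability %in% c("low", "high")) {
    stop("'fakability' must be \"low\" or \"high\"", call. = FALSE)
  }
  if (condition$theta_var <= 0) stop("'theta_var' must be > 0", call. = FALSE)
  on_design <- condition$theta_mean %in% c(0, 1, 2) &&
    condition$theta_var %in% c(0.2, 0.5, 1)
  if (!on_design) {
    message("note: condition (", condition$fakability, ", M=",
            condition$theta_mean, ", Var=", condition$theta_var,
            ") is off the standard design grid")
  }
  data.frame(condition = NA_integer_, fakability = condition$fakability,
             theta_mean = condition$theta_mean,
             theta_var = condition$theta_var)
}

#' Draw faking-process parameters for a simulation condition
#'
#' Rank-order parameters are drawn uniformly — on (-2, 2) under low
#' fakability, (-4, 4) under high — for all `R` entries of each block (the
#' identification constraint \eqn{\beta_{k1} = 0} is an estimation device;
#' by shift invariance of the softmax it does not affect the generated
#' probabilities). Faking traits are drawn from a normal with the
#' condition's mean and variance, independent of the content traits.
#'
#' @param condition a row of [condition_grid()], its index, or a list with
#'   fields `fakability`, `theta_mean`, `theta_var`.
#' @param n_blocks,n_persons design dimensions.
#' @param R number of rank orders per block.
#' @param seed optional integer seed.
#' @return List with `beta` (blocks x R), `theta` (length `n_persons`),
#'   `alpha` (derived fakabilities) and the resolved `condition`.
#' @export
draw_faking_parameters <- function(condition, n_blocks, R = 6L, n_persons,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- as_condition(condition)
  lim <- if (cond$fakability == "high") 4 else 2
  beta <- matrix(runif(n_blocks * R, -lim, lim), n_blocks, R)
  theta <- rnorm(n_persons, cond$theta_mean, sqrt(cond$theta_var))
  list(beta = beta, theta = theta,
       alpha = block_fakability(softmax_rank_probs(beta)),
       condition = cond)
}

#' Overlay faking on honest responses
#'
#' For every person-block, a faking indicator is drawn with probability
#' \eqn{\Phi(\theta_j + \alpha_k)}; where it fires, the honest rank order is
#' replaced by a draw from the block's softmax rank-order distribution.
#'
#' @param honest_responses persons x blocks matrix of canonical order
#'   indices ([simulate_honest_responses()]).
#' @param beta blocks x R rank-order parameter matrix.
#' @param theta length-persons faking trait vector.
#' @param seed optional integer seed.
#' @return List with `responses` (persons x blocks order indices) and
#'   `faked` (logical matrix of faking indicators).
#' @export
simulate_faking_responses <- function(honest_responses, beta, theta,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  honest_responses <- as.matrix(honest_responses)
  N <- nrow(honest_responses); K <- ncol(honest_responses)
  stopifnot(nrow(beta) == K, length(theta) == N)
  p_fake <- softmax_rank_probs(beta)
  alpha <- block_fakability(p_fake)
  pf <- faking_probability(theta, alpha)         # N x K
  faked <- matrix(rbinom(N * K, 1L, pf) == 1L, N, K)
  responses <- honest_responses
  for (k in seq_len(K)) {
    n_fake <- sum(faked[, k])
    if (n_fake > 0L) {
      responses[faked[, k], k] <- sample.int(ncol(beta), n_fake,
                                             replace = TRUE,
                                             prob = p_fake[k, ])
    }
  }
  dimnames(responses) <- dimnames(honest_responses)
  list(responses = responses, faked = faked)
}

#' Simulate a complete forced-choice faking study
#'
#' Runs the full generating recipe for one condition: correlated content
#' traits, item parameters with mixed keying, honest responses by utility
#' ranking, faking-process parameters for the condition, and high-stakes
#' responses from the mixture process. Optionally computes the honest
#' rank-order probability array needed for estimation.
#'
#' Defaults mirror the generator's study scale: 500 persons, 20 triplet
#' blocks, 5 traits.
#'
#' @inheritParams draw_faking_parameters
#' @param n_persons,n_blocks,block_size,n_traits design dimensions.
#' @param corr content-trait correlation matrix.
#' @param honest_probs logical; also compute [honest_probabilities()]
#'   (the costly step; skip when only responses are needed).
#' @param seed integer seed governing the whole replication.
#' @return Object of class `"fm_simulation"`: a list with `items`, `traits`,
#'   `honest` (responses), `responses` (high-stakes), `faked`, `beta`,
#'   `theta`, `alpha`, `condition`, and `honest_probs` (array or `NULL`).
#' @examples
#' sim <- simulate_fc_study(list(fakability = "low", theta_mean = 1,
#'                               theta_var = 0.5),
#'                          n_persons = 30, n_blocks = 4,
#'                          honest_probs = FALSE, seed = 1)
#' @export
simulate_fc_study <- function(condition, n_persons = 500L, n_blocks = 20L,
                              block_size = 3L, n_traits = 5L,
                              corr = big_five_correlations(),
                              honest_probs = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond <- as_condition(condition)
  R <- factorial(block_size)
  traits <- draw_content_traits(n_persons, corr)
  items <- draw_item_parameters(n_blocks, block_size, n_traits)
  honest <- simulate_honest_responses(items, traits)
  fp <- draw_faking_parameters(cond, n_blocks, R, n_persons)
  hs <- simulate_faking_responses(honest, fp$beta, fp$theta)
  hp <- if (honest_probs) honest_probabilities(items, traits) else NULL
  structure(list(items = items, traits = traits, honest = honest,
                 responses = hs$responses, faked = hs$faked,
                 beta = fp$beta, theta = fp$theta, alpha = fp$alpha,
                 condition = cond, honest_probs = hp, seed = seed,
                 n_persons = n_persons, n_blocks = n_blocks,
                 block_size = block_size),
            class = "fm_simulation")
}

#' @export
print.fm_simulation <- function(x, ...) {
  cat("Simulated forced-choice faking study\n")
  cat(sprintf("  %d persons, %d blocks of %d items (%d rank orders)\n",
              x$n_persons, x$n_blocks, x$block_size,
              factorial(x$block_size)))
  cat(sprintf("  condition: fakability %s, M(theta) = %g, Var(theta) = %g\n",
              x$condition$fakability, x$condition$theta_mean,
              x$condition$theta_var))
  cat(sprintf("  faked cells: %.1f%%\n", 100 * mean(x$faked)))
  invisible(x)
}
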