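#' Enumerate the rank orders of a forced-choice block
#'
#' A block of `block_size` items admits `factorial(block_size)` rank orders.
#' A rank order is written as a permutation of the item labels in descending
#' preference: the first label is the item ranked highest. For `block_size =
#' 3` the canonical (lexicographic) enumeration is 1-2-3, 1-3-2, 2-1-3,
#' 2-3-1, 3-1-2, 3-2-1, so e.g. index 5 ("3-1-2") means item 3 is ranked
#' first.
#'
#' @param block_size number of items per block, an integer >= 2.
#' @return An integer matrix with `factorial(block_size)` rows (one rank
#'   order each, in lexicographic order) and `block_size` columns, of class
#'   `"fm_rank_orders"`.
#' @examples
#' rank_orders(3)
#' @export
rank_orders <- function(block_size) {
  block_size <- check_block_size(block_size)
  perms <- permutations_lex(block_size)
  structure(perms, class = "fm_rank_orders", block_size = block_size)
}

#' @export
print.fm_rank_orders <- function(x, ...) {
  cat(nrow(x), "rank orders of a block of", attr(x, "block_size"),
      "items (first label = ranked highest):\n")
  cat(paste0("  [", seq_len(nrow(x)), "] ",
             apply(unclass(x), 1L, paste, collapse = "-")), sep = "\n")
  invisible(x)
}

# All permutations of 1..n in lexicographic order, rows of a matrix.
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

check_block_size <- function(block_size) {
  if (length(block_size) != 1L || !is.finite(block_size) || block_size < 2 ||
      block_size != round(block_size)) {
    stop("invalid block design: 'block_size' must be a single integer >= 2",
         call. = FALSE)
  }
  as.integer(block_size)
}

#' Canonical index of a rank order
#'
#' Maps a permutation (item labels in descending preference) to its position
#' in the lexicographic enumeration of [rank_orders()], using the factorial
#' number system; the identity permutation has index 1.
#'
#' @param perm integer vector, a permutation of `1:length(perm)`, or a matrix
#'   with one permutation per row.
#' @return Integer index (or vector of indices) in `1:factorial(B)`.
#' @examples
#' rank_order_index(c(3, 1, 2)) # 5
#' @export
rank_order_index <- function(perm) {
  if (is.matrix(perm)) return(apply(perm, 1L, rank_order_index))
  B <- length(perm)
  if (!setequal(perm, seq_len(B))) {
    stop("'perm' is not a permutation of 1..", B, call. = FALSE)
  }
  idx <- 0L
  remaining <- seq_len(B)
  for (pos in seq_len(B - 1L)) {
    smaller <- match(perm[pos], sort(remaining)) - 1L
    idx <- idx + smaller * factorial(B - pos)
    remaining <- setdiff(remaining, perm[pos])
  }
  as.integer(idx + 1L)
}

#' Parse and format rank-order tokens
#'
#' Response files may store a cell either as a canonical order index
#' (`"5"`) or as a hyphen- or en-dash-separated permutation (`"3-1-2"`).
#' `parse_rank_order()` normalizes either dialect to the canonical
#' lexicographic index; `format_rank_order()` is its inverse.
#'
#' @param token character scalar or vector of tokens.
#' @param block_size block size the tokens refer to.
#' @return `parse_rank_order()`: integer index vector; `format_rank_order()`:
#'   character vector of hyphenated permutations.
#' @examples
#' parse_rank_order("3-1-2", 3) # 5
#' format_rank_order(5, 3)      # "3-1-2"
#' @export
parse_rank_order <- function(token, block_size) {
  block_size <- check_block_size(block_size)
  R <- factorial(block_size)
  vapply(as.character(token), function(tok) {
    tok <- gsub("–|—", "-", trimws(tok))
    if (grepl("-", tok, fixed = TRUE)) {
      parts <- suppressWarnings(as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]]))
      if (anyNA(parts) || length(parts) != block_size ||
          !setequal(parts, seq_len(block_size))) {
        stop("cannot parse rank-order token '", tok,
             "': not a permutation of 1..", block_size, call. = FALSE)
      }
      rank_order_index(parts)
    } else {
      idx <- suppressWarnings(as.integer(tok))
      if (is.na(idx) || idx < 1L || idx > R) {
        stop("cannot parse rank-order token '", tok,
             "': not an order index in 1..", R, call. = FALSE)
      }
      idx
    }
  }, integer(1L), USE.NAMES = FALSE)
}

#' @rdname parse_rank_order
#' @param index canonical order index (vector allowed).
#' @export
format_rank_order <- function(index, block_size) {
  block_size <- check_block_size(block_size)
  perms <- rank_orders(block_size)
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > nrow(perms))) {
    stop("order index out of 1..", nrow(perms), call. = FALSE)
  }
  apply(perms[index, , drop = FALSE], 1L, paste, collapse = "-")
}

#' Pairwise comparison matrix for ordered utilities
#'
#' The banded contrast matrix that maps a vector of utilities, sorted by a
#' rank order, to successive differences: row \eqn{b} has 1 in column
#' \eqn{b} and -1 in column \eqn{b + 1}. A rank order is observed exactly
#' when all differences of the sorted utilities are positive.
#'
#' @inheritParams rank_orders
#' @return A `(block_size - 1) x block_size` numeric matrix.
#' @examples
#' comparison_matrix(3)
#' @export
comparison_matrix <- function(block_size) {
  block_size <- check_block_size(block_size)
  A <- matrix(0, block_size - 1L, block_size)
  for (b in seq_len(block_size - 1L)) {
    A[b, b] <- 1
    A[b, b + 1L] <- -1
  }
  A
}
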