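#' Read and write rank-order response files
#'
#' Responses are stored as comma-separated text with a header: a
#' `person_id` column followed by one column per block. Cells hold either
#' the canonical order index (`dialect = "index"`) or a hyphenated
#' permutation such as `"3-1-2"` (`dialect = "rank"`); the reader accepts
#' both dialects (en dashes are normalized to hyphens) and returns
#' canonical indices.
#'
#' @param responses persons x blocks matrix of canonical order indices.
#' @param path file path.
#' @param block_size block size of the questionnaire.
#' @param dialect cell format to write.
#' @return `read_responses()`: an integer matrix with `person_id` row
#'   names; `write_responses()`: the path, invisibly.
#' @export
write_responses <- function(responses, path, block_size,
                            dialect = c("index", "rank")) {
  dialect <- match.arg(dialect)
  responses <- as.matrix(responses)
  K <- ncol(responses)
  cells <- if (dialect == "index") responses else
    matrix(format_rank_order(responses, block_size), nrow(responses))
  df <- data.frame(person_id = rownames(responses) %||%
                     seq_len(nrow(responses)), cells)
  names(df) <- c("person_id", paste0("block_", seq_len(K)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, block_size) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1L] != "person_id") {
    stop("response file must start with a 'person_id' column",
         call. = FALSE)
  }
  out <- vapply(seq_len(ncol(df) - 1L), function(k) {
    tryCatch(parse_rank_order(df[[k + 1L]], block_size),
             error = function(e) {
               stop("column '", names(df)[k + 1L], "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }, integer(nrow(df)))
  out <- matrix(out, nrow(df))
  dimnames(out) <- list(df$person_id, names(df)[-1L])
  out
}

#' Read and write item-parameter tables
#'
#' Comma-separated text with columns `item_id`, `block_id`, `trait`,
#' `intercept`, `loading`, `error_variance`.
#'
#' @param items item-parameter data frame ([draw_item_parameters()]).
#' @param path file path.
#' @export
write_item_params <- function(items, path) {
  write.csv(check_items(items), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_params
#' @export
read_item_params <- function(path) {
  check_items(read.csv(path))
}

#' Read and write honest probability arrays
#'
#' Long-format comma-separated text with columns `person_id`, `block_id`,
#' `order_index`, `prob`; one row per person-block-order.
#'
#' @param honest persons x blocks x R probability array
#'   ([honest_probabilities()]).
#' @param path file path.
#' @export
write_honest_probs <- function(honest, path) {
  d <- dim(honest)
  df <- data.frame(person_id = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                   block_id = rep(rep(seq_len(d[2L]), each = d[1L]),
                                  times = d[3L]),
                   order_index = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
                   prob = as.vector(honest))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_honest_probs
#' @export
read_honest_probs <- function(path) {
  df <- read.csv(path)
  need <- c("person_id", "block_id", "order_index", "prob")
  if (!all(need %in% names(df))) {
    stop("honest-probability file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  persons <- sort(unique(df$person_id))
  blocks <- sort(unique(df$block_id))
  orders <- sort(unique(df$order_index))
  arr <- array(NA_real_, c(length(persons), length(blocks), length(orders)))
  arr[cbind(match(df$person_id, persons), match(df$block_id, blocks),
            match(df$order_index, orders))] <- df$prob
  if (anyNA(arr)) {
    stop("honest-probability file is not a complete person x block x order ",
         "grid", call. = FALSE)
  }
  arr
}

#' Read and write run configuration files
#'
#' YAML key-value files holding design, condition, prior and sampler
#' settings plus the mandatory seed, as used by the command-line interface.
#'
#' @param path file path.
#' @param config named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
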