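#' Train an order-k finite-context model on a reference sequence
#'
#' Builds the exact context -> next-symbol count table of an order-`k`
#' Markov (finite-context) model from a reference sequence. Each of the
#' `length(y) - k` positions with a full k-symbol context contributes one
#' counting event. The model is static: it is never updated while profiling
#' a target, so every code length is conditioned exclusively on the
#' reference.
#'
#' @param y a [dna_seq()] or character scalar over ACGT (the reference).
#' @param k context order, an integer in `[1, 28]`. Orders up to 12 are
#'   stored densely, larger orders in a hashed sparse table; counts are
#'   value-identical either way.
#' @param alpha additive smoothing parameter of the probability estimator
#'   (default 0.001, which makes the estimator behave close to maximum
#'   likelihood while keeping all probabilities strictly positive).
#' @return An object of class `fcm_model`.
#' @export
fcm_train <- function(y, k, alpha = 0.001) {
  if (is.character(y)) y <- dna_seq(y)
  stopifnot(inherits(y, "dna_seq"))
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 28) {
    abort("context order k must be an integer in the range [1,28]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("alpha must be a positive number")
  }
  ints <- seq_to_ints(y$symbols)
  structure(
    list(
      ptr = .cpp_fcm_train(ints, as.integer(k)),
      k = as.integer(k),
      alpha = alpha,
      reference_name = y$name,
      reference_length = y$length
    ),
    class = "fcm_model"
  )
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf(
    "<fcm_model> order k = %d, alpha = %g, trained on '%s' (%s bp, %s counting events)\n",
    x$k, x$alpha, x$reference_name,
    format(x$reference_length, big.mark = ","),
    format(fcm_total_events(x), big.mark = ",")
  ))
  invisible(x)
}

#' Total number of counting events in a model
#'
#' Equals `length(reference) - k` for any reference long enough to contain
#' at least one full context.
#'
#' @param model an [fcm_train()] model.
#' @return A numeric count.
#' @export
fcm_total_events <- function(model) {
  stopifnot(inherits(model, "fcm_model"))
  .cpp_fcm_total_events(model$ptr)
}

#' Estimated next-symbol probability
#'
#' Applies the additive-smoothing estimator
#' `P(s | c) = (N(s|c) + alpha) / (N(c) + 4 alpha)` where `N(s|c)` is the
#' number of times symbol `s` followed context `c` in the reference and
#' `N(c)` the total number of events for that context. For an unseen
#' context the four probabilities are all 1/4.
#'
#' @param model an [fcm_train()] model.
#' @param context character scalar of exactly `k` symbols over ACGT.
#' @param symbol one or more of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param alpha optional override of the model's smoothing parameter.
#' @return Numeric vector of probabilities in `(0, 1)`, one per symbol.
#' @export
fcm_probability <- function(model, context, symbol, alpha = model$alpha) {
  stopifnot(inherits(model, "fcm_model"))
  if (!is.character(context) || length(context) != 1L ||
      nchar(context) != model$k) {
    abort(sprintf("context must be a string of exactly k = %d symbols", model$k))
  }
  ctx <- seq_to_ints(context)
  vapply(symbol, function(s) {
    stopifnot(s %in% .ALPHABET)
    q <- .cpp_fcm_query(model$ptr, ctx, match(s, .ALPHABET) - 1L)
    (q[1] + alpha) / (q[2] + 4 * alpha)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Code length of a symbol in bits
#'
#' The number of bits required to represent `symbol` after `context` under
#' the model: `-log2 P(symbol | context)`. Low values mean the symbol is
#' well predicted from information present in the reference.
#'
#' @inheritParams fcm_probability
#' @return Numeric vector of non-negative code lengths in bits.
#' @export
fcm_code_length <- function(model, context, symbol, alpha = model$alpha) {
  -log2(fcm_probability(model, context, symbol, alpha = alpha))
}

#' Extract the non-zero counts of a model
#'
#' Returns every context/symbol pair observed in the reference with its
#' count, ordered by context then symbol. Intended for inspection and
#' testing at small `k`; at large orders the table can be huge.
#'
#' @param model an [fcm_train()] model.
#' @return A tibble with columns `context`, `symbol`, `count`.
#' @export
fcm_counts <- function(model) {
  stopifnot(inherits(model, "fcm_model"))
  df <- .cpp_fcm_counts(model$ptr)
  k <- model$k
  ctx <- vapply(df$context_code, function(code) {
    syms <- integer(k)
    for (j in k:1) {
      syms[j] <- code %% 4
      code <- code %/% 4
    }
    paste(.ALPHABET[syms + 1L], collapse = "")
  }, character(1))
  tibble(context = ctx,
         symbol = .ALPHABET[df$symbol_code + 1L],
         count = df$count)
}
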