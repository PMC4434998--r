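# Independent brute-force oracles, kept deliberately naive: they enumerate
# substrings directly and never touch the package's counting code.

# all (context, next symbol) counts of order k by direct substring scan
oracle_counts <- function(s, k) {
  n <- nchar(s)
  if (n < k + 1) {
    return(tibble::tibble(context = character(), symbol = character(),
                          count = integer()))
  }
  i <- (k + 1):n
  ctx <- substring(s, i - k, i - 1)
  sym <- substring(s, i, i)
  tab <- table(paste(ctx, sym))
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  out <- tibble::tibble(
    context = vapply(parts, `[`, "", 1),
    symbol = vapply(parts, `[`, "", 2),
    count = as.integer(tab)
  )
  out[order(out$context, out$symbol), ]
}

# estimator probability straight from oracle counts
oracle_probability <- function(s, k, context, symbol, alpha = 0.001) {
  oc <- oracle_counts(s, k)
  rows <- oc[oc$context == context, ]
  cnt <- if (symbol %in% rows$symbol) rows$count[rows$symbol == symbol] else 0L
  (cnt + alpha) / (sum(rows$count) + 4 * alpha)
}

# every DNA string of a given length, in lexicographic order
all_dna_strings <- function(len) {
  if (len == 0) return("")
  grid <- do.call(expand.grid,
                  rep(list(c("A", "C", "G", "T")), len))[, len:1, drop = FALSE]
  do.call(paste0, grid)
}

random_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# length of the intersection of two half-open intervals
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  max(0, min(a_end, b_end) - max(a_start, b_start))
}

reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- interval_overlap(a_start, a_end, b_start, b_end)
  min(ov / (a_end - a_start), ov / (b_end - b_start))
}
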