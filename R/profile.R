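#' Conditional information profile of a target sequence
#'
#' Computes, for every position `i` of the target, the number of bits needed
#' to encode the symbol at `i` given its `k` preceding symbols, using the
#' next-symbol statistics of a model trained exclusively on a reference.
#' Regions where the profile is low share information with the reference;
#' regions near the 2-bit ceiling (the entropy of a uniform 4-letter
#' alphabet) share none. The first `k` positions have no full context and
#' are assigned the uniform fallback of 2 bits.
#'
#' @param model an [fcm_train()] model of the reference (direct strand) or
#'   of its reverse complement (inverted strand).
#' @param x target [dna_seq()] or character scalar over ACGT.
#' @param orientation label recorded in the profile metadata, `"direct"` or
#'   `"inverted"`, describing which strand of the reference the model was
#'   trained on.
#' @return An `information_profile`: numeric vector of bits (one per target
#'   position) with metadata attributes.
#' @export
information_profile <- function(model, x, orientation = c("direct", "inverted")) {
  stopifnot(inherits(model, "fcm_model"))
  orientation <- match.arg(orientation)
  if (is.character(x)) x <- dna_seq(x)
  stopifnot(inherits(x, "dna_seq"))
  vals <- .cpp_fcm_profile(model$ptr, seq_to_ints(x$symbols), model$alpha)
  new_information_profile(vals,
                          target_name = x$name,
                          reference_name = model$reference_name,
                          k = model$k, alpha = model$alpha,
                          orientation = orientation,
                          window = 1L)
}

new_information_profile <- function(values, target_name, reference_name,
                                    k, alpha, orientation, window) {
  structure(values,
            target_name = target_name,
            reference_name = reference_name,
            k = k, alpha = alpha,
            orientation = orientation,
            window = as.integer(window),
            class = "information_profile")
}

#' @export
print.information_profile <- function(x, ...) {
  cat(sprintf(
    "<information_profile> %s | %s (%s), k = %d, alpha = %g, window = %d\n",
    attr(x, "target_name"), attr(x, "reference_name"), attr(x, "orientation"),
    attr(x, "k"), attr(x, "alpha"), attr(x, "window")
  ))
  cat(sprintf("  length %s, mean %.4f bits\n",
              format(length(x), big.mark = ","), mean(x)))
  invisible(x)
}

#' @export
tidy.information_profile <- function(x, ...) {
  tibble(position = seq_along(unclass(x)) - 1L, bits = as.numeric(x))
}

#' @export
autoplot.information_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", attr(object, "target_name")),
      y = "information (bits/symbol)",
      title = sprintf("%s given %s (%s strand)", attr(object, "target_name"),
                      attr(object, "reference_name"), attr(object, "orientation"))
    ) +
    ggplot2::ylim(0, NA)
}

#' Smooth a profile with a centred moving average
#'
#' Each position is replaced by the mean of the values inside a centred
#' window, truncated at the sequence boundaries (so the output has the same
#' length as the input and constant profiles are fixed points). For even
#' window lengths the window extends one position further to the right.
#'
#' @param profile an [information_profile()] (or bare numeric vector).
#' @param window window length in positions (`>= 1`); 1 is the identity.
#' @return A smoothed profile of the same class and length.
#' @export
smooth_profile <- function(profile, window) {
  if (length(window) != 1L || is.na(window) || window < 1) {
    abort("window must be a single integer >= 1")
  }
  window <- as.integer(window)
  vals <- as.numeric(profile)
  n <- length(vals)
  if (window == 1L || n == 0L) {
    sm <- vals
  } else {
    left <- (window - 1L) %/% 2L
    right <- window - 1L - left
    cs <- c(0, cumsum(vals))
    lo <- pmax(seq_len(n) - left, 1L)
    hi <- pmin(seq_len(n) + right, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (inherits(profile, "information_profile")) {
    new_information_profile(sm,
                            target_name = attr(profile, "target_name"),
                            reference_name = attr(profile, "reference_name"),
                            k = attr(profile, "k"), alpha = attr(profile, "alpha"),
                            orientation = attr(profile, "orientation"),
                            window = window)
  } else {
    sm
  }
}

#' Segmentation parameters
#'
#' Bundles the four knobs of the region-finding step.
#'
#' @param threshold threshold T in bits, within `[0, 2]` (the 2-bit alphabet
#'   ceiling). Positions with smoothed information strictly below T are
#'   low-information; a smaller T suits closely related sequences, a larger
#'   T more distant ones. Default 1.5.
#' @param window smoothing window in positions (default 1000).
#' @param min_block minimum reported region length in positions (default
#'   20000, i.e. matched regions smaller than 20 kb are discarded).
#' @param merge_gap maximum gap between below-threshold runs that is bridged
#'   before length filtering (default 0: pure thresholding).
#' @return A `seg_params` list.
#' @export
seg_params <- function(threshold = 1.5, window = 1000L, min_block = 20000L,
                       merge_gap = 0L) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 2) {
    abort("threshold must be a number in [0, 2] bits")
  }
  if (window < 1) abort("window must be >= 1")
  if (min_block < 1) abort("min_block must be >= 1")
  if (merge_gap < 0) abort("merge_gap must be >= 0")
  structure(list(threshold = threshold, window = as.integer(window),
                 min_block = as.integer(min_block),
                 merge_gap = as.integer(merge_gap)),
            class = "seg_params")
}

#' Segment a smoothed profile into low-information regions
#'
#' Finds maximal runs of positions whose smoothed information is strictly
#' below the threshold, optionally merges runs separated by gaps of at most
#' `merge_gap` positions, and drops runs shorter than `min_block`.
#'
#' @param smoothed a smoothed [information_profile()] (or numeric vector).
#' @param params a [seg_params()] object.
#' @return A tibble of regions with 0-based half-open `start`, `end` and the
#'   mean smoothed information `mean_bits` inside each region, sorted and
#'   non-overlapping.
#' @export
segment_profile <- function(smoothed, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  vals <- as.numeric(smoothed)
  n <- length(vals)
  empty <- tibble(start = integer(), end = integer(), mean_bits = numeric())
  if (n == 0L) return(empty)
  low <- vals < params$threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty)
  if (params$merge_gap > 0L && nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)]
    grp <- cumsum(c(0L, as.integer(gap > params$merge_gap)))
    runs <- runs |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      dplyr::select("start", "end")
  }
  runs <- runs[runs$end - runs$start >= params$min_block, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)
  cs <- c(0, cumsum(vals))
  tibble(
    start = as.integer(runs$start),
    end = as.integer(runs$end),
    mean_bits = (cs[runs$end + 1L] - cs[runs$start + 1L]) / (runs$end - runs$start)
  )
}

#' Write a profile as two-column TSV
#'
#' @param profile an [information_profile()].
#' @param path output path; columns are 0-based `position` and `bits`.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(tidy(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a profile as fixed-step wiggle text
#'
#' Emits a `fixedStep` track (1-based start, step 1) suitable for genome
#' browsers.
#'
#' @param profile an [information_profile()].
#' @param path output path.
#' @param chrom chromosome name for the track (defaults to the target name).
#' @export
write_profile_wig <- function(profile, path, chrom = attr(profile, "target_name")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
  writeLines(formatC(as.numeric(profile), format = "g", digits = 6), con)
  invisible(path)
}
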