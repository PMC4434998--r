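#' Find target regions that share information with a reference
#'
#' First stage of the pipeline: the target is profiled twice, once against
#' a model of the reference and once against a model of its reverse
#' complement, each profile is smoothed, and below-threshold runs are
#' segmented. The direct list marks candidate direct homologies, the
#' inverted list candidate inversions.
#'
#' @param y reference [dna_seq()] (preprocessed to ACGT).
#' @param x target [dna_seq()] (preprocessed to ACGT).
#' @param k context order of the model.
#' @param params a [seg_params()] object.
#' @param alpha estimator smoothing parameter.
#' @return A list with elements `direct` and `inverted` (region tibbles)
#'   and `profiles` (the two smoothed [information_profile()]s).
#' @export
find_target_regions <- function(y, x, k, params = seg_params(), alpha = 0.001) {
  stopifnot(inherits(y, "dna_seq"), inherits(x, "dna_seq"),
            inherits(params, "seg_params"))
  prof_d <- smooth_profile(
    information_profile(fcm_train(y, k, alpha), x, orientation = "direct"),
    params$window
  )
  prof_i <- smooth_profile(
    information_profile(fcm_train(reverse_complement(y), k, alpha), x,
                        orientation = "inverted"),
    params$window
  )
  list(
    direct = segment_profile(prof_d, params),
    inverted = segment_profile(prof_i, params),
    profiles = list(direct = prof_d, inverted = prof_i)
  )
}

#' Resolve direct/inverted conflicts on the target
#'
#' Combines the two orientation-specific region lists into one strand-aware
#' segmentation of the target. A position claimed by exactly one orientation
#' keeps it. A position claimed by both is assigned, run by run, to the
#' orientation with the smaller mean smoothed information over the disputed
#' run (the better-explained strand). A position claimed by neither is left
#' unmarked: high information under both models means the region shares no
#' information with the reference (unique or originally unsequenced DNA).
#' Regions are re-filtered by `min_block` after resolution.
#'
#' @param direct,inverted region tibbles from [find_target_regions()].
#' @param profile_direct,profile_inverted the matching smoothed profiles.
#' @param params a [seg_params()] object.
#' @return A tibble of non-overlapping regions with `start`, `end`,
#'   `orientation`, `mean_bits`, sorted by `start`.
#' @export
resolve_overlaps <- function(direct, inverted, profile_direct, profile_inverted,
                             params = seg_params()) {
  n <- length(profile_direct)
  stopifnot(length(profile_inverted) == n)
  mask_d <- .regions_to_mask(direct, n)
  mask_i <- .regions_to_mask(inverted, n)
  both <- mask_d & mask_i
  if (any(both)) {
    vd <- as.numeric(profile_direct)
    vi <- as.numeric(profile_inverted)
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (j in which(r$values)) {
      idx <- (starts[j] + 1L):ends[j]
      if (mean(vd[idx]) <= mean(vi[idx])) {
        mask_i[idx] <- FALSE
      } else {
        mask_d[idx] <- FALSE
      }
    }
  }
  out <- bind_rows(
    .mask_to_regions(mask_d, profile_direct, "direct", params$min_block),
    .mask_to_regions(mask_i, profile_inverted, "inverted", params$min_block)
  )
  arrange(out, .data$start)
}

.regions_to_mask <- function(regions, n) {
  mask <- logical(n)
  if (nrow(regions)) {
    for (j in seq_len(nrow(regions))) {
      mask[(regions$start[j] + 1L):regions$end[j]] <- TRUE
    }
  }
  mask
}

.mask_to_regions <- function(mask, profile, orientation, min_block) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & (r$lengths >= min_block)
  if (!any(keep)) {
    return(tibble(start = integer(), end = integer(),
                  orientation = character(), mean_bits = numeric()))
  }
  vals <- as.numeric(profile)
  cs <- c(0, cumsum(vals))
  s <- starts[keep]; e <- ends[keep]
  tibble(start = as.integer(s), end = as.integer(e),
         orientation = orientation,
         mean_bits = (cs[e + 1L] - cs[s + 1L]) / (e - s))
}

#' Localise a target region on the reference
#'
#' Second stage (role inversion): the target region itself is taken as the
#' training sequence — reverse-complemented first if the region is an
#' inversion — and the full reference is profiled against it. Low-information
#' runs of the reference are the regions associated with the target region.
#' Several reference regions may be returned (duplications); an empty result
#' means the association did not survive the threshold in this direction.
#'
#' @param region one-row tibble (or list) with `start`, `end`,
#'   `orientation` on the target.
#' @param x target [dna_seq()].
#' @param y reference [dna_seq()].
#' @param k context order.
#' @param params a [seg_params()] object.
#' @param alpha estimator smoothing parameter.
#' @return A tibble of reference regions (`start`, `end`, `mean_bits`).
#' @export
locate_in_reference <- function(region, x, y, k, params = seg_params(),
                                alpha = 0.001) {
  stopifnot(inherits(x, "dna_seq"), inherits(y, "dna_seq"))
  sub <- substr(x$symbols, region$start + 1L, region$end)
  if (identical(region$orientation, "inverted")) {
    sub <- reverse_complement(sub)
  }
  model <- fcm_train(dna_seq(sub, name = sprintf("%s:%d-%d", x$name,
                                                 region$start, region$end)),
                     k, alpha)
  prof <- smooth_profile(information_profile(model, y), params$window)
  segment_profile(prof, params)
}

#' Build the full rearrangement map between two sequences
#'
#' Runs the complete procedure: (1) preprocess both sequences (random
#' uniform fill of non-ACGT symbols, seeded), (2) profile the target against
#' direct and reverse-complement reference models and segment low-information
#' regions, (3) resolve orientation conflicts and leave doubly-high regions
#' unmarked, (4) localise every surviving target region back onto the
#' reference by swapping roles, (5) assign one HSV hue per pair, equally
#' spaced, in target order. Pairs whose localisation comes back empty are
#' dropped with a warning (threshold effects are not perfectly symmetric
#' between the two passes).
#'
#' @param y reference [dna_seq()] (raw or preprocessed).
#' @param x target [dna_seq()] (raw or preprocessed).
#' @param k context order (default 14, suited to sequences of about 1 Mb
#'   and above).
#' @param params a [seg_params()] object.
#' @param alpha estimator smoothing parameter (default 0.001).
#' @param seed seed for the non-ACGT randomisation (default 1).
#' @return A `rearrangement_map` object; see [tidy.rearrangement_map()],
#'   [glance.rearrangement_map()], [render_svg()].
#' @export
build_map <- function(y, x, k = 14L, params = seg_params(), alpha = 0.001,
                      seed = 1L) {
  stopifnot(inherits(y, "dna_seq"), inherits(x, "dna_seq"))
  y <- replace_non_acgt(y, seed = seed)
  x <- replace_non_acgt(x, seed = seed)
  found <- find_target_regions(y, x, k, params, alpha)
  resolved <- resolve_overlaps(found$direct, found$inverted,
                               found$profiles$direct, found$profiles$inverted,
                               params)
  refs <- vector("list", nrow(resolved))
  keep <- logical(nrow(resolved))
  for (j in seq_len(nrow(resolved))) {
    r <- locate_in_reference(resolved[j, ], x, y, k, params, alpha)
    if (nrow(r) == 0L) {
      warn(sprintf(
        "target region [%d,%d) (%s) could not be localised on the reference; pair dropped",
        resolved$start[j], resolved$end[j], resolved$orientation[j]
      ))
    } else {
      refs[[j]] <- r
      keep[j] <- TRUE
    }
  }
  pairs <- resolved[keep, , drop = FALSE]
  pairs <- tibble(
    pair_id = seq_len(nrow(pairs)),
    target_start = pairs$start,
    target_end = pairs$end,
    orientation = pairs$orientation,
    mean_bits = pairs$mean_bits,
    hue = assign_hues(nrow(pairs)),
    ref = refs[keep]
  )
  structure(
    list(
      reference_name = y$name, target_name = x$name,
      reference_length = y$length, target_length = x$length,
      pairs = pairs,
      params = list(k = as.integer(k), alpha = alpha,
                    threshold = params$threshold, window = params$window,
                    min_block = params$min_block, merge_gap = params$merge_gap,
                    seed = as.integer(seed))
    ),
    class = "rearrangement_map"
  )
}

#' @export
print.rearrangement_map <- function(x, ...) {
  cat(sprintf("<rearrangement_map> %s (reference, %s bp) vs %s (target, %s bp)\n",
              x$reference_name, format(x$reference_length, big.mark = ","),
              x$target_name, format(x$target_length, big.mark = ",")))
  p <- x$params
  cat(sprintf("  k = %d, alpha = %g, T = %g, window = %d, min_block = %d, merge_gap = %d, seed = %d\n",
              p$k, p$alpha, p$threshold, p$window, p$min_block, p$merge_gap, p$seed))
  cat(sprintf("  %d pair(s): %d direct, %d inverted; target coverage %.1f%%\n",
              nrow(x$pairs), sum(x$pairs$orientation == "direct"),
              sum(x$pairs$orientation == "inverted"),
              100 * region_coverage(x$pairs, x$target_length,
                                    start_col = "target_start",
                                    end_col = "target_end")))
  invisible(x)
}

#' Tidy a rearrangement map into one row per target/reference link
#'
#' @param x a [build_map()] result.
#' @param ... unused.
#' @return A tibble with one row per (target region, reference region)
#'   association.
#' @export
tidy.rearrangement_map <- function(x, ...) {
  if (nrow(x$pairs) == 0L) {
    return(tibble(pair_id = integer(), target_start = integer(),
                  target_end = integer(), orientation = character(),
                  target_mean_bits = numeric(), ref_start = integer(),
                  ref_end = integer(), ref_mean_bits = numeric(),
                  hue = numeric()))
  }
  x$pairs |>
    dplyr::rename(target_mean_bits = "mean_bits") |>
    mutate(ref = purrr::map(.data$ref, ~ dplyr::rename(.x, ref_start = "start",
                                                       ref_end = "end",
                                                       ref_mean_bits = "mean_bits"))) |>
    tidyr::unnest("ref") |>
    dplyr::select("pair_id", "target_start", "target_end", "orientation",
                  "target_mean_bits", "ref_start", "ref_end", "ref_mean_bits",
                  "hue")
}

#' One-row summary of a rearrangement map
#'
#' @param x a [build_map()] result.
#' @param ... unused.
#' @return A one-row tibble with pair counts, coverages and parameters.
#' @export
glance.rearrangement_map <- function(x, ...) {
  td <- tidy(x)
  ref_regions <- if (nrow(td)) {
    tibble(start = td$ref_start, end = td$ref_end)
  } else {
    tibble(start = integer(), end = integer())
  }
  tibble(
    n_pairs = nrow(x$pairs),
    n_direct = sum(x$pairs$orientation == "direct"),
    n_inverted = sum(x$pairs$orientation == "inverted"),
    target_coverage = region_coverage(x$pairs, x$target_length,
                                      start_col = "target_start",
                                      end_col = "target_end"),
    reference_coverage = region_coverage(ref_regions, x$reference_length),
    k = x$params$k, alpha = x$params$alpha, threshold = x$params$threshold,
    window = x$params$window, min_block = x$params$min_block,
    merge_gap = x$params$merge_gap, seed = x$params$seed
  )
}

#' Fraction of a sequence covered by a set of regions
#'
#' @param regions tibble with start/end columns (0-based half-open).
#' @param seq_length total sequence length.
#' @param start_col,end_col column names holding the interval bounds.
#' @return Covered fraction in `[0, 1]` (overlaps counted once).
#' @export
region_coverage <- function(regions, seq_length, start_col = "start",
                            end_col = "end") {
  if (nrow(regions) == 0L || seq_length == 0) return(0)
  iv <- tibble(start = regions[[start_col]], end = regions[[end_col]])
  merged <- merge_intervals(iv)
  sum(merged$end - merged$start) / seq_length
}

#' Merge overlapping or touching intervals
#'
#' @param intervals tibble with 0-based half-open `start`, `end`.
#' @return Sorted tibble of disjoint intervals covering the same positions.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(tibble(start = integer(), end = integer()))
  iv <- arrange(intervals, .data$start)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  ss <- c(); ee <- c()
  for (j in seq_len(nrow(iv))[-1]) {
    if (iv$start[j] <= out_e) {
      out_e <- max(out_e, iv$end[j])
    } else {
      ss <- c(ss, out_s); ee <- c(ee, out_e)
      out_s <- iv$start[j]; out_e <- iv$end[j]
    }
  }
  tibble(start = c(ss, out_s), end = c(ee, out_e))
}
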