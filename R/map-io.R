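#' Write a rearrangement map as JSON
#'
#' The JSON document embeds sequence names, lengths, every region pair and
#' the full parameter record (k, alpha, threshold, window, min_block,
#' merge_gap, seed) — it is the unit of reproducibility for a run. The same
#' map always serialises to the same bytes.
#'
#' @param map a [build_map()] result.
#' @param path output path.
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "rearrangement_map"))
  doc <- list(
    format = "fcmap-map",
    version = 1L,
    reference = list(name = map$reference_name, length = map$reference_length),
    target = list(name = map$target_name, length = map$target_length),
    params = map$params,
    pairs = purrr::pmap(map$pairs, function(pair_id, target_start, target_end,
                                            orientation, mean_bits, hue, ref) {
      list(pair_id = pair_id,
           target = list(start = target_start, end = target_end,
                         mean_bits = mean_bits),
           orientation = orientation,
           hue = hue,
           reference_regions = purrr::pmap(ref, function(start, end, mean_bits) {
             list(start = start, end = end, mean_bits = mean_bits)
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rearrangement map from JSON
#'
#' @param path a file written by [write_map_json()].
#' @return A `rearrangement_map`.
#' @export
read_map_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "fcmap-map")) {
    abort(sprintf("%s is not an fcmap map JSON document", path))
  }
  pairs <- purrr::map(doc$pairs, function(p) {
    tibble(
      pair_id = as.integer(p$pair_id),
      target_start = as.integer(p$target$start),
      target_end = as.integer(p$target$end),
      orientation = p$orientation,
      mean_bits = as.numeric(p$target$mean_bits),
      hue = as.numeric(p$hue),
      ref = list(purrr::map_dfr(p$reference_regions, function(r) {
        tibble(start = as.integer(r$start), end = as.integer(r$end),
               mean_bits = as.numeric(r$mean_bits))
      }))
    )
  })
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(pair_id = integer(), target_start = integer(),
           target_end = integer(), orientation = character(),
           mean_bits = numeric(), hue = numeric(), ref = list())
  structure(
    list(
      reference_name = doc$reference$name,
      target_name = doc$target$name,
      reference_length = as.integer(doc$reference$length),
      target_length = as.integer(doc$target$length),
      pairs = pairs,
      params = list(k = as.integer(doc$params$k),
                    alpha = as.numeric(doc$params$alpha),
                    threshold = as.numeric(doc$params$threshold),
                    window = as.integer(doc$params$window),
                    min_block = as.integer(doc$params$min_block),
                    merge_gap = as.integer(doc$params$merge_gap),
                    seed = as.integer(doc$params$seed))
    ),
    class = "rearrangement_map"
  )
}

#' Write a rearrangement map as BED-like TSV, one file per side
#'
#' Emits `<prefix>.target.bed` and `<prefix>.reference.bed`, six columns
#' each: chrom, 0-based half-open start/end, pair id, mean information in
#' bits (full precision), and strand (`+` direct, `-` inverted).
#'
#' @param map a [build_map()] result.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_map_bed <- function(map, prefix) {
  stopifnot(inherits(map, "rearrangement_map"))
  td <- tidy(map)
  strand <- function(o) ifelse(o == "inverted", "-", "+")
  tgt <- map$pairs
  tgt_df <- data.frame(
    chrom = rep(map$target_name, nrow(tgt)),
    start = tgt$target_start, end = tgt$target_end,
    name = sprintf("pair_%d", tgt$pair_id),
    mean_bits = format(tgt$mean_bits, digits = 17, scientific = FALSE,
                       trim = TRUE),
    strand = strand(tgt$orientation)
  )
  ref_df <- data.frame(
    chrom = rep(map$reference_name, nrow(td)),
    start = td$ref_start, end = td$ref_end,
    name = sprintf("pair_%d", td$pair_id),
    mean_bits = format(td$ref_mean_bits, digits = 17, scientific = FALSE,
                       trim = TRUE),
    strand = strand(td$orientation)
  )
  paths <- paste0(prefix, c(".target.bed", ".reference.bed"))
  utils::write.table(tgt_df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ref_df, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
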