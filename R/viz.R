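#' Equally spaced HSV hues for block colouring
#'
#' Block colours vary only in hue; saturation and value are fixed by the
#' style. Hues are spread uniformly over the colour circle in target order:
#' `hue_i = i * 360 / n`.
#'
#' @param n_pairs number of pairs (`>= 0`).
#' @return Numeric vector of hue angles in degrees, all distinct.
#' @export
assign_hues <- function(n_pairs) {
  stopifnot(n_pairs >= 0)
  if (n_pairs == 0L) return(numeric())
  (seq_len(n_pairs) - 1) * 360 / n_pairs
}

#' Ideogram rendering style
#'
#' @param width,height image size in pixels.
#' @param bar_width chromosome bar width in pixels.
#' @param margin outer margin in pixels.
#' @param saturation,value fixed HSV saturation and value components in
#'   `(0, 1]`; only the hue varies between blocks.
#' @param scale base pairs per pixel; `NULL` (default) fits the longer
#'   sequence into the drawable height.
#' @return An `ideogram_style` list.
#' @export
ideogram_style <- function(width = 720L, height = 640L, bar_width = 56L,
                           margin = 48L, saturation = 0.65, value = 0.95,
                           scale = NULL) {
  stopifnot(saturation > 0, saturation <= 1, value > 0, value <= 1,
            is.null(scale) || scale > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 bar_width = as.integer(bar_width), margin = as.integer(margin),
                 saturation = saturation, value = value, scale = scale),
            class = "ideogram_style")
}

.svg_num <- function(x) formatC(x, format = "f", digits = 2, drop0trailing = TRUE)

#' Render a rearrangement map as an SVG ideogram
#'
#' Draws the reference (left) and target (right) as two vertical bars at a
#' common base-pairs-per-pixel scale. Each region pair is filled with its
#' hue on both bars; inverted pairs additionally carry a diagonal-hatch
#' overlay so orientation does not rely on colour alone. Unmarked stretches
#' stay uncoloured. Output is deterministic: the same map and style always
#' produce byte-identical SVG.
#'
#' @param map a [build_map()] (or [read_map_json()]) result.
#' @param path output path for the SVG file, or `NULL` to only return the
#'   document text.
#' @param style an [ideogram_style()].
#' @return The SVG document as a character scalar (invisibly when `path`
#'   is given).
#' @export
render_svg <- function(map, path = NULL, style = ideogram_style()) {
  stopifnot(inherits(map, "rearrangement_map"),
            inherits(style, "ideogram_style"))
  drawable <- style$height - 2L * style$margin
  scale <- if (is.null(style$scale)) {
    max(map$reference_length, map$target_length, 1) / drawable
  } else {
    style$scale
  }
  x_ref <- style$margin
  x_tgt <- style$width - style$margin - style$bar_width
  y0 <- style$margin
  px <- function(bp) bp / scale

  rect <- function(x, y, w, h, fill, extra = "") {
    sprintf('  <rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
            .svg_num(x), .svg_num(y), .svg_num(w), .svg_num(h), fill, extra)
  }
  hue_fill <- function(hue) {
    grDevices::hsv(hue / 360, style$saturation, style$value)
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            style$width, style$height),
    '  <defs>',
    '    <pattern id="inv-hatch" width="6" height="6" patternTransform="rotate(45)" patternUnits="userSpaceOnUse">',
    '      <rect width="6" height="6" fill="none"/>',
    '      <line x1="0" y1="0" x2="0" y2="6" stroke="#000000" stroke-opacity="0.45" stroke-width="1.6"/>',
    '    </pattern>',
    '  </defs>',
    sprintf('  <text x="%s" y="%s" font-family="sans-serif" font-size="13">%s</text>',
            .svg_num(x_ref), .svg_num(y0 - 10), map$reference_name),
    sprintf('  <text x="%s" y="%s" font-family="sans-serif" font-size="13" text-anchor="end">%s</text>',
            .svg_num(x_tgt + style$bar_width), .svg_num(y0 - 10), map$target_name),
    rect(x_ref, y0, style$bar_width, px(map$reference_length), "#e6e6e6",
         ' stroke="#555555" stroke-width="1"'),
    rect(x_tgt, y0, style$bar_width, px(map$target_length), "#e6e6e6",
         ' stroke="#555555" stroke-width="1"')
  )

  td <- tidy(map)
  if (nrow(map$pairs) > 0) {
    for (j in seq_len(nrow(map$pairs))) {
      p <- map$pairs[j, ]
      fill <- hue_fill(p$hue)
      inv <- identical(p$orientation, "inverted")
      y_t <- y0 + px(p$target_start)
      h_t <- px(p$target_end - p$target_start)
      lines <- c(lines, rect(x_tgt, y_t, style$bar_width, h_t, fill))
      if (inv) {
        lines <- c(lines, rect(x_tgt, y_t, style$bar_width, h_t,
                               "url(#inv-hatch)"))
      }
      links <- td[td$pair_id == p$pair_id, , drop = FALSE]
      for (i in seq_len(nrow(links))) {
        y_r <- y0 + px(links$ref_start[i])
        h_r <- px(links$ref_end[i] - links$ref_start[i])
        lines <- c(lines, rect(x_ref, y_r, style$bar_width, h_r, fill))
        if (inv) {
          lines <- c(lines, rect(x_ref, y_r, style$bar_width, h_r,
                                 "url(#inv-hatch)"))
        }
        # ribbon connecting the two blocks
        lines <- c(lines, sprintf(
          '  <path d="M %s %s L %s %s L %s %s L %s %s Z" fill="%s" fill-opacity="0.25"/>',
          .svg_num(x_ref + style$bar_width), .svg_num(y_r),
          .svg_num(x_tgt), .svg_num(if (inv) y_t + h_t else y_t),
          .svg_num(x_tgt), .svg_num(if (inv) y_t else y_t + h_t),
          .svg_num(x_ref + style$bar_width), .svg_num(y_r + h_r),
          fill
        ))
      }
    }
  }
  lines <- c(lines, "</svg>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "\n", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Plot a rearrangement map with ggplot2
#'
#' A ggplot rendition of the ideogram: two horizontal bars with same-hue
#' blocks and connecting ribbons; inverted pairs are outlined.
#'
#' @param object a [build_map()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rearrangement_map <- function(object, ...) {
  td <- tidy(object)
  bars <- tibble(
    side = factor(c("reference", "target"), levels = c("target", "reference")),
    len = c(object$reference_length, object$target_length)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bars,
      ggplot2::aes(xmin = 0, xmax = .data$len,
                   ymin = as.integer(.data$side) - 0.12,
                   ymax = as.integer(.data$side) + 0.12),
      fill = "grey90", colour = "grey40"
    )
  if (nrow(td) > 0) {
    blocks <- bind_rows(
      tibble(y = 2, start = td$ref_start, end = td$ref_end,
             hue = td$hue, orientation = td$orientation),
      tibble(y = 1, start = td$target_start, end = td$target_end,
             hue = td$hue, orientation = td$orientation)
    )
    blocks$fill <- grDevices::hsv(blocks$hue / 360, 0.65, 0.95)
    ribbons <- tibble(
      x = c(rbind(td$ref_start, td$ref_end, td$target_end, td$target_start)),
      y = rep(c(2, 2, 1, 1) - c(0.12, 0.12, -0.12, -0.12), nrow(td)),
      grp = rep(seq_len(nrow(td)), each = 4),
      fill = rep(grDevices::hsv(td$hue / 360, 0.65, 0.95), each = 4)
    )
    p <- p +
      ggplot2::geom_polygon(data = ribbons,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$grp),
                            fill = ribbons$fill[!duplicated(ribbons$grp)][ribbons$grp],
                            alpha = 0.25) +
      ggplot2::geom_rect(
        data = blocks,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = .data$y - 0.12, ymax = .data$y + 0.12,
                     linetype = .data$orientation),
        fill = blocks$fill, colour = "grey20", linewidth = 0.3
      ) +
      ggplot2::scale_linetype_manual(values = c(direct = "blank",
                                                inverted = "solid"),
                                     drop = FALSE)
  }
  p +
    ggplot2::scale_y_continuous(breaks = c(1, 2),
                                labels = c(object$target_name,
                                           object$reference_name)) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
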