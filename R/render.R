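#' Render a computational karyogram as SVG
#'
#' Draws each contig or scaffold as a colored vertical rectangle whose rows
#' are the majority-rule pixels of its binned call track, grouped by
#' assigned chromosome in placement order.  Sequences shorter than
#' `min_draw_bp` (default 1 Mbp) are filtered out and not drawn — the
#' filter affects rendering only, never classification or placement.  The
#' output is a pure function of its inputs: rendering the same tracks,
#' placements and options twice produces byte-identical SVG.
#'
#' @param tracks Named list of `feature_call_track` objects.
#' @param placements Placement tibble from [place_contigs()]; computed from
#'   `tracks` when omitted.
#' @param pixel_bp Bases per pixel row (default 250000).
#' @param min_draw_bp Minimum sequence length drawn (default 1e6; 0 disables
#'   the filter).
#' @param px_per_pixel Device pixels per pixel row (default 2).
#' @param col_width Rectangle width in device pixels (default 18).
#' @return The SVG document as a single character scalar (class
#'   `karyomer_svg`); write it with [write_svg()].
#' @export
render_karyogram <- function(tracks, placements = NULL, pixel_bp = 250000,
                             min_draw_bp = 1e6, px_per_pixel = 2,
                             col_width = 18) {
  if (is.null(placements)) placements <- place_contigs(tracks)
  drawn <- placements |> filter(.data$length >= min_draw_bp) |>
    arrange(.data$order_rank)
  feats <- tracks[[1]]$features
  if (nrow(drawn) == 0) {
    warn("no sequences pass the draw filter; rendering an empty canvas")
  }

  gap <- 8
  label_h <- 14
  x <- gap
  rects <- character()
  labels <- character()
  max_h <- 0
  for (i in seq_len(nrow(drawn))) {
    tr <- tracks[[drawn$contig[i]]]
    px <- bin_majority(tr, pixel_bp)
    colors <- px$color
    if (identical(drawn$orientation[i], "-")) colors <- rev(colors)
    h <- length(colors) * px_per_pixel
    max_h <- max(max_h, h)
    # merge runs of identical color into single rects for compactness
    r <- rle(colors)
    y <- label_h + 4
    for (j in seq_along(r$lengths)) {
      hh <- r$lengths[j] * px_per_pixel
      rects <- c(rects, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="none"/>',
        x, y, col_width, hh, r$values[j]))
      y <- y + hh
    }
    rects <- c(rects, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="#555555" stroke-width="0.5"/>',
      x, label_h + 4, col_width, h))
    lab <- if (is.na(drawn$chromosome[i])) drawn$contig[i] else drawn$chromosome[i]
    labels <- c(labels, sprintf(
      '<text x="%d" y="%d" font-size="9" font-family="sans-serif" text-anchor="middle">%s</text>',
      x + col_width %/% 2, label_h, lab))
    x <- x + col_width + gap
  }

  # legend: one swatch per feature class plus ambiguous/novel
  legend_entries <- rbind(
    data.frame(label = "telomere", color = COLOR_TELOMERE),
    data.frame(label = "centromere", color = COLOR_CENTROMERE),
    data.frame(label = "ambiguous", color = COLOR_AMBIGUOUS),
    data.frame(label = "novel/gap", color = COLOR_BLANK)
  )
  ly <- label_h + 4 + max_h + 20
  legend <- character()
  lx <- gap
  for (i in seq_len(nrow(legend_entries))) {
    legend <- c(legend, sprintf(
      '<rect x="%d" y="%d" width="10" height="10" fill="%s" stroke="#555555" stroke-width="0.5"/>',
      lx, ly, legend_entries$color[i]),
      sprintf('<text x="%d" y="%d" font-size="9" font-family="sans-serif">%s</text>',
              lx + 14, ly + 9, legend_entries$label[i]))
    lx <- lx + 100
  }

  width <- max(x, lx) + gap
  height <- ly + 24
  svg <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n',
            width, height, width, height),
    '<rect width="100%" height="100%" fill="#FFFFFF"/>\n',
    paste(c(rects, labels, legend), collapse = "\n"),
    "\n</svg>\n"
  )
  structure(svg, class = "karyomer_svg")
}

#' @export
print.karyomer_svg <- function(x, ...) {
  cat(sprintf("<karyomer_svg> %d bytes; write with write_svg()\n", nchar(x)))
  invisible(x)
}

#' Write an SVG document to a file
#'
#' @param svg A `karyomer_svg` (from [render_karyogram()]).
#' @param path Output path.
#' @export
write_svg <- function(svg, path) {
  writeLines(unclass(svg), path, sep = "")
  invisible(path)
}
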