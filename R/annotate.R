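#' Annotate a sequence against a k-mer feature database
#'
#' Classifies every k-mer window of a contig or scaffold by database lookup,
#' producing a feature call track: per position one of a feature id,
#' `AMBIGUOUS` (k-mer present in several features), `NOVEL` (absent from the
#' database), or `GAP` (window contains a non-ACGT character).  Strand votes
#' (query orientation versus stored reference orientation) are accumulated
#' per feature for unambiguous calls whose stored strand is not mixed.
#'
#' @param db A `feature_db`.
#' @param seq A single sequence: `DNAString`, character scalar, or a
#'   one-element `DNAStringSet`.
#' @param name Contig name recorded in the track (defaults to the sequence
#'   name when available).
#' @return A `feature_call_track` object.  Sequences shorter than k yield an
#'   empty track.
#' @export
annotate_sequence <- function(db, seq, name = NULL) {
  stopifnot(inherits(db, "feature_db"))
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1) {
      abort("`seq` must be a single sequence; use annotate_assembly() for sets",
            class = "karyomer_parameter_error")
    }
    name <- name %||% names(seq)
    seq <- as.character(seq[[1]])
  } else if (methods::is(seq, "DNAString")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("`seq` must be one non-empty sequence", class = "karyomer_input_error")
  }
  res <- .kmer_db_query(db$key_hi, db$key_lo, db$payload, db$strand, seq, db$k)
  votes <- strand_votes(res$calls, res$orient, db$features)
  structure(
    list(contig = name %||% "contig", length = nchar(seq), k = db$k,
         calls = res$calls, orient = res$orient,
         features = db$features, strand_votes = votes),
    class = "feature_call_track"
  )
}

strand_votes <- function(calls, orient, features) {
  keep <- !is.na(orient)
  feats <- calls[keep]
  ori <- orient[keep]
  tibble(
    feature_id = features$feature_id,
    match = map_int(features$feature_id, \(f) sum(ori == 1L & feats == f)),
    mismatch = map_int(features$feature_id, \(f) sum(ori == 0L & feats == f))
  )
}

#' Annotate every sequence of an assembly
#'
#' @param db A `feature_db`.
#' @param assembly A `DNAStringSet`, named character vector, or FASTA path.
#' @return A named list of `feature_call_track` objects.
#' @export
annotate_assembly <- function(db, assembly) {
  seqs <- as_dna_set(assembly)
  tracks <- lapply(seq_along(seqs), function(i) {
    annotate_sequence(db, as.character(seqs[[i]]), name = names(seqs)[i])
  })
  setNames(tracks, names(seqs))
}

#' @export
print.feature_call_track <- function(x, ...) {
  cat(sprintf("<feature_call_track> %s: %d bp, %d calls (k=%d)\n",
              x$contig, x$length, length(x$calls), x$k))
  invisible(x)
}

# Human-readable label for a call code.
call_label <- function(code, features) {
  lab <- character(length(code))
  lab[code == CALL_GAP] <- "GAP"
  lab[code == CALL_NOVEL] <- "NOVEL"
  lab[code == CALL_AMBIG] <- "AMBIGUOUS"
  pos <- code >= 0
  lab[pos] <- features$name[match(code[pos], features$feature_id)]
  lab
}

#' @export
tidy.feature_call_track <- function(x, ...) {
  tibble(
    contig = x$contig,
    position = seq_along(x$calls) - 1L,
    call = call_label(x$calls, x$features),
    strand_match = if_else(is.na(x$orient), NA, x$orient == 1L)
  )
}

#' Bin a call track into majority-rule pixels
#'
#' Divides the contig into consecutive windows of `pixel_bp` bases; each
#' pixel takes the modal call among the k-mer calls starting inside its
#' window, mapped to colors: telomere blue, centromere orange, arms their
#' chromosome color (p light, q dark), ambiguous gray, novel and gap white.
#' Exact count ties are resolved by precedence telomere > centromere > arm
#' (lowest feature id) > ambiguous > novel > gap, so binning is
#' deterministic.  The final partial pixel is computed over the calls
#' actually present; a trailing pixel with no call windows is white.
#'
#' @param track A `feature_call_track`.
#' @param pixel_bp Bases per pixel (default 250000); must be at least k.
#' @return A `pixel_track`: a tibble with columns `pixel`, `start_bp`,
#'   `end_bp`, `label`, `color`, `n_calls`, carrying the contig name and
#'   pixel size as attributes.
#' @export
bin_majority <- function(track, pixel_bp = 250000) {
  stopifnot(inherits(track, "feature_call_track"))
  pixel_bp <- stopifnot_scalar_int(pixel_bp, "pixel_bp")
  if (pixel_bp < track$k) {
    abort("`pixel_bp` must be at least k", class = "karyomer_parameter_error")
  }
  n_pix <- ceiling(track$length / pixel_bp)
  calls <- track$calls
  bin <- if (length(calls) > 0) (seq_along(calls) - 1L) %/% pixel_bp else integer()
  labels <- integer(n_pix)
  n_calls <- integer(n_pix)
  for (j in seq_len(n_pix)) {
    in_bin <- calls[bin == (j - 1L)]
    n_calls[j] <- length(in_bin)
    labels[j] <- majority_call(in_bin)
  }
  out <- tibble(
    pixel = seq_len(n_pix),
    start_bp = (seq_len(n_pix) - 1L) * pixel_bp,
    end_bp = pmin(seq_len(n_pix) * pixel_bp, track$length),
    label = call_label(labels, track$features),
    color = call_color(labels, track$features),
    n_calls = n_calls
  )
  structure(out, class = c("pixel_track", class(out)),
            contig = track$contig, pixel_bp = pixel_bp,
            contig_length = track$length)
}

# Modal call with the deterministic precedence tie-break.  Empty windows
# (e.g. a trailing pixel shorter than k) fall back to GAP (drawn white).
majority_call <- function(calls) {
  if (length(calls) == 0) return(CALL_GAP)
  tab <- table(calls)
  codes <- as.integer(names(tab))
  counts <- as.integer(tab)
  # precedence: feature ids in increasing order (TEL=0 first), then
  # AMBIGUOUS, NOVEL, GAP
  prec <- ifelse(codes >= 0, codes,
                 ifelse(codes == CALL_AMBIG, 1e9,
                        ifelse(codes == CALL_NOVEL, 1e9 + 1, 1e9 + 2)))
  codes[order(-counts, prec)][1]
}

call_color <- function(code, features) {
  col <- character(length(code))
  col[code %in% c(CALL_GAP, CALL_NOVEL)] <- COLOR_BLANK
  col[code == CALL_AMBIG] <- COLOR_AMBIGUOUS
  pos <- code >= 0
  col[pos] <- features$color[match(code[pos], features$feature_id)]
  col
}

#' @export
autoplot.pixel_track <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = 0, xmax = 1,
                                   ymin = .data$start_bp, ymax = .data$end_bp)) +
    ggplot2::geom_rect(fill = df$color, color = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = attr(object, "contig"), y = "position (bp)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
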