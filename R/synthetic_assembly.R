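# Truth-labeled derived assemblies: apply structural events to reference
# chromosomes so every structural-completeness category is instantiated
# with a known truth label.

#' Assembly-derivation events
#'
#' Constructors for the events accepted by [derive_assembly()].  Each event
#' applies to one reference chromosome and carries the truth
#' structural-completeness label of the contig it produces.
#'
#' * `ev_identity(chrom)` — the whole chromosome (truth: complete
#'   chromosome).
#' * `ev_drop_telomere(chrom, end)` — remove one telomere array (`end`
#'   `"left"` or `"right"`; truth: complete arm).
#' * `ev_extract(chrom, start, end, truth)` — extract a 0-based half-open
#'   slice with an explicit truth label (partial arm, centromere, marker,
#'   ...).
#' * `ev_revcomp(chrom)` — the reverse complement of the whole chromosome
#'   (truth: complete chromosome, orientation `-`).
#' * `ev_split(chrom, pos)` — split the chromosome at `pos` into two
#'   contigs; truth labels are derived from which annotated features each
#'   side retains.
#' * `ev_fuse(chrom_a, chrom_b)` — concatenate two whole chromosomes
#'   (truth: complete chromosome by termini, a fusion artifact).
#'
#' @param chrom,chrom_a,chrom_b Reference chromosome name(s).
#' @param end `"left"` or `"right"`.
#' @param start,end_pos 0-based half-open slice coordinates.
#' @param pos Split position.
#' @param truth Truth category for `ev_extract`.
#' @name assembly_events
NULL

#' @rdname assembly_events
#' @export
ev_identity <- function(chrom) list(type = "identity", chrom = chrom)

#' @rdname assembly_events
#' @export
ev_drop_telomere <- function(chrom, end = c("right", "left")) {
  list(type = "drop_telomere", chrom = chrom, end = match.arg(end))
}

#' @rdname assembly_events
#' @export
ev_extract <- function(chrom, start, end_pos, truth) {
  list(type = "extract", chrom = chrom, start = start, end = end_pos,
       truth = truth)
}

#' @rdname assembly_events
#' @export
ev_revcomp <- function(chrom) list(type = "revcomp", chrom = chrom)

#' @rdname assembly_events
#' @export
ev_split <- function(chrom, pos) list(type = "split", chrom = chrom, pos = pos)

#' @rdname assembly_events
#' @export
ev_fuse <- function(chrom_a, chrom_b) {
  list(type = "fuse", chrom_a = chrom_a, chrom_b = chrom_b)
}

chrom_intervals <- function(reference, chrom) {
  reference$annotation |> filter(.data$seqname == chrom)
}

# Truth label for a slice [start, end) of a chromosome, derived from which
# annotated features the slice touches — the same definitions the
# classifier implements, but computed from the generator's event log, not
# from k-mer calls.
slice_truth <- function(reference, chrom, start, end) {
  ann <- chrom_intervals(reference, chrom)
  touches <- function(kl, arm = NULL) {
    rows <- ann$klass == kl
    if (!is.null(arm)) rows <- rows & ann$arm == arm
    any(ann$start[rows] < end & ann$end[rows] > start)
  }
  overlap_bp <- function(kl) {
    rows <- which(ann$klass == kl)
    sum(pmax(0, pmin(ann$end[rows], end) - pmax(ann$start[rows], start)))
  }
  L <- end - start
  tel_left <- any(ann$klass == "TEL" & ann$start <= start & ann$end > start)
  tel_right <- any(ann$klass == "TEL" & ann$start < end & ann$end >= end)
  cen_left <- any(ann$klass == "CEN" & ann$start <= start & ann$end > start)
  cen_right <- any(ann$klass == "CEN" & ann$start < end & ann$end >= end)
  cen_frac <- overlap_bp("CEN") / L
  if (tel_left && tel_right) return("complete_chromosome")
  if ((tel_left || tel_right) &&
      (cen_left || cen_right ||
       (touches("ARM", "p") && touches("ARM", "q") && cen_frac > 0))) {
    return("complete_arm")
  }
  if (cen_frac >= 0.9) return("centromere")
  if (cen_left || cen_right || tel_left || tel_right) return("partial_arm")
  "marker"
}

#' Derive a truth-labeled assembly from a toy reference
#'
#' Applies structural events (see [assembly_events]) to the reference
#' chromosomes, producing contigs whose structural-completeness truth
#' labels are known by construction.
#'
#' @param reference Output of [make_reference()].
#' @param events List of events.
#' @return A list with `contigs` (a `DNAStringSet`) and `truth` (a tibble
#'   `contig`, `chromosome`, `truth`, `orientation`).
#' @export
derive_assembly <- function(reference, events) {
  seqs <- reference$sequences
  out_seq <- character()
  out_truth <- list()
  push <- function(name, seq, chrom, truth, orientation = "+") {
    out_seq[[name]] <<- seq
    out_truth[[name]] <<- tibble(contig = name, chromosome = chrom,
                                 truth = truth, orientation = orientation)
  }
  for (ev in events) {
    if (ev$type == "fuse") {
      if (!all(c(ev$chrom_a, ev$chrom_b) %in% names(seqs))) {
        abort("fuse event references unknown chromosome",
              class = "karyomer_event_error")
      }
      nm <- paste0(ev$chrom_a, "_", ev$chrom_b, "_fusion")
      push(nm, paste0(as.character(seqs[[ev$chrom_a]]),
                      as.character(seqs[[ev$chrom_b]])),
           ev$chrom_a, "complete_chromosome")
      next
    }
    if (!ev$chrom %in% names(seqs)) {
      abort(sprintf("event references unknown chromosome '%s'", ev$chrom),
            class = "karyomer_event_error")
    }
    s <- as.character(seqs[[ev$chrom]])
    L <- nchar(s)
    switch(
      ev$type,
      identity = push(ev$chrom, s, ev$chrom, "complete_chromosome"),
      revcomp = push(paste0(ev$chrom, "_rc"), revcomp_chr(s), ev$chrom,
                     "complete_chromosome", orientation = "-"),
      drop_telomere = {
        ann <- chrom_intervals(reference, ev$chrom)
        tel <- ann[ann$klass == "TEL", ]
        if (ev$end == "right") {
          cut <- min(tel$start[tel$start > 0])
          push(paste0(ev$chrom, "_no_tel_r"), substr(s, 1, cut), ev$chrom,
               "complete_arm")
        } else {
          cut <- min(tel$end[tel$start == 0])
          push(paste0(ev$chrom, "_no_tel_l"), substr(s, cut + 1, L), ev$chrom,
               "complete_arm")
        }
      },
      extract = {
        if (ev$start < 0 || ev$end > L || ev$start >= ev$end) {
          abort(sprintf("extract [%d,%d) out of range for %s (%d bp)",
                        ev$start, ev$end, ev$chrom, L),
                class = "karyomer_event_error")
        }
        truth <- ev$truth %||% slice_truth(reference, ev$chrom, ev$start, ev$end)
        push(sprintf("%s_%d_%d", ev$chrom, ev$start, ev$end),
             substr(s, ev$start + 1, ev$end), ev$chrom, truth)
      },
      split = {
        if (ev$pos <= 0 || ev$pos >= L) {
          abort("split position out of range", class = "karyomer_event_error")
        }
        push(paste0(ev$chrom, "_splitL"), substr(s, 1, ev$pos), ev$chrom,
             slice_truth(reference, ev$chrom, 0, ev$pos))
        push(paste0(ev$chrom, "_splitR"), substr(s, ev$pos + 1, L), ev$chrom,
             slice_truth(reference, ev$chrom, ev$pos, L))
      },
      abort(sprintf("unknown event type '%s'", ev$type),
            class = "karyomer_event_error")
    )
  }
  list(contigs = Biostrings::DNAStringSet(out_seq),
       truth = bind_rows(out_truth))
}

#' Preset truth-labeled assembly suite
#'
#' A standard "one of each" suite instantiating all five
#' structural-completeness categories from a toy reference: a full
#' chromosome, a chromosome missing one telomere, a pure centromere
#' fragment, a telomere-anchored partial arm, and a mid-arm marker
#' fragment.
#'
#' @param reference Output of [make_reference()]; needs at least 5
#'   chromosomes.
#' @return As [derive_assembly()].
#' @export
preset_assembly_suite <- function(reference) {
  chroms <- names(reference$sequences)
  stopifnot(length(chroms) >= 5)
  iv <- function(chrom) chrom_intervals(reference, chrom)
  c3 <- iv(chroms[3]); cen3 <- c3[c3$klass == "CEN", ]
  c4 <- iv(chroms[4]); tel4 <- c4[c4$klass == "TEL" & c4$start == 0, ]
  p4 <- c4[c4$klass == "ARM" & c4$arm == "p", ]
  c5 <- iv(chroms[5]); q5 <- c5[c5$klass == "ARM" & c5$arm == "q", ]
  events <- list(
    ev_identity(chroms[1]),
    ev_drop_telomere(chroms[2], "right"),
    # interior of the centromere array, trimmed so flanks are centromeric
    ev_extract(chroms[3], cen3$start + 500, cen3$end - 500, "centromere"),
    # telomere plus the proximal half of the p arm: one telomeric flank
    ev_extract(chroms[4], 0, p4$start + floor((p4$end - p4$start) / 2),
               "partial_arm"),
    # mid-q fragment with no telomeric or centromeric flank
    ev_extract(chroms[5], q5$start + 1000,
               q5$start + 1000 + floor((q5$end - q5$start) / 2), "marker")
  )
  derive_assembly(reference, events)
}
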