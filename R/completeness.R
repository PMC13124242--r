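#' Thresholds for the structural-completeness classifier
#'
#' Terminal windows are `min(terminal_bp, terminal_frac * L)` bases at each
#' end of a contig of length L.  A terminus is telomeric when at least
#' `tel_frac` of the non-gap calls in its terminal window are telomere
#' calls; a flank is centromeric analogously with `cen_frac`.  A contig
#' "contains" a centromere when it carries at least `cen_min_bp` of
#' centromere calls, and is "entirely centromeric" when the centromere
#' fraction of its non-gap calls reaches `cen_pure_frac`.  Arm-specificity
#' reuses the karyogram assignment with threshold `arm_min_fraction`.
#'
#' @param terminal_bp,terminal_frac Terminal window size cap (bp) and
#'   fraction of contig length (defaults 10 kbp and 5%).
#' @param tel_frac,cen_frac Telomeric / centromeric flank call fractions
#'   (defaults 0.5).
#' @param cen_pure_frac Centromere-call fraction above which a contig is
#'   entirely centromeric (default 0.9).
#' @param cen_min_bp Minimum centromere evidence in bases (default 50 kbp).
#' @param arm_min_fraction Assignment threshold (default 0.5).
#' @return A named list of thresholds.
#' @export
completeness_params <- function(terminal_bp = 10000, terminal_frac = 0.05,
                                tel_frac = 0.5, cen_frac = 0.5,
                                cen_pure_frac = 0.9, cen_min_bp = 50000,
                                arm_min_fraction = 0.5) {
  list(terminal_bp = terminal_bp, terminal_frac = terminal_frac,
       tel_frac = tel_frac, cen_frac = cen_frac,
       cen_pure_frac = cen_pure_frac, cen_min_bp = cen_min_bp,
       arm_min_fraction = arm_min_fraction)
}

COMPLETENESS_CATEGORIES <- c("complete_chromosome", "complete_arm",
                             "centromere", "partial_arm", "marker")

#' Classify a contig into one of five structural-completeness categories
#'
#' Applies a first-match decision cascade over a contig's feature call
#' track:
#' 1. *complete chromosome* — both termini telomeric (a fully
#'    telomere-to-telomere sequence);
#' 2. *complete arm* — exactly one terminus telomeric and either the
#'    opposite flank is centromeric, or the contig spans p–centromere–q
#'    and is missing only a single telomere;
#' 3. *centromere* — essentially all non-gap calls are centromeric;
#' 4. *partial arm* — arm-specific with exactly one flank telomeric or
#'    centromeric;
#' 5. *marker* — arm-specific with neither flank telomeric nor centromeric.
#'
#' Gap (N-run) calls are neutral: they are excluded from every fraction
#' denominator, so scaffold gaps do not break a classification.  An empty
#' track is reported as category `"undefined"` rather than silently
#' dropped.
#'
#' @param track A `feature_call_track`.
#' @param params Thresholds from [completeness_params()].
#' @return A one-row tibble: `contig`, `category`, plus the evidence used
#'   (`tel_start`, `tel_end`, `cen_start`, `cen_end`,
#'   `centromere_fraction`, `centromere_bp`, `chromosome`,
#'   `assignment_fraction`, `has_p`, `has_q`).
#' @export
classify_contig <- function(track, params = completeness_params()) {
  stopifnot(inherits(track, "feature_call_track"))
  feats <- track$features
  tel_id <- feats$feature_id[feats$klass == "TEL"]
  cen_id <- feats$feature_id[feats$klass == "CEN"]
  calls <- track$calls
  non_gap <- calls[calls != CALL_GAP]

  assignment <- assign_contig(track, params$arm_min_fraction)
  if (length(calls) == 0 || length(non_gap) == 0) {
    return(mutate(assignment, category = "undefined",
                  tel_start = NA, tel_end = NA, cen_start = NA, cen_end = NA,
                  centromere_fraction = NA_real_, centromere_bp = 0,
                  has_p = NA, has_q = NA) |>
             select("contig", "category", dplyr::everything()))
  }

  w <- max(track$k, min(params$terminal_bp,
                        round(params$terminal_frac * track$length)))
  n <- length(calls)
  head_calls <- calls[seq_len(min(n, max(1, w - track$k + 1)))]
  tail_calls <- calls[seq.int(max(1, n - max(1, w - track$k + 1) + 1), n)]
  frac_of <- function(window, id) {
    ng <- window[window != CALL_GAP]
    if (length(ng) == 0) return(0)
    sum(ng %in% id) / length(ng)
  }
  tel_start <- frac_of(head_calls, tel_id) >= params$tel_frac
  tel_end <- frac_of(tail_calls, tel_id) >= params$tel_frac
  cen_start <- frac_of(head_calls, cen_id) >= params$cen_frac
  cen_end <- frac_of(tail_calls, cen_id) >= params$cen_frac

  cen_bp <- sum(calls %in% cen_id)
  cen_fraction <- cen_bp / length(non_gap)
  has_cen <- cen_bp >= params$cen_min_bp

  chrom <- assignment$chromosome
  if (!is.na(chrom)) {
    p_id <- feats$feature_id[feats$klass == "ARM" & feats$chromosome == chrom & feats$arm == "p"]
    q_id <- feats$feature_id[feats$klass == "ARM" & feats$chromosome == chrom & feats$arm == "q"]
    has_p <- any(calls %in% p_id)
    has_q <- any(calls %in% q_id)
  } else {
    has_p <- FALSE
    has_q <- FALSE
  }
  arm_specific <- !is.na(chrom)

  n_tel_termini <- tel_start + tel_end
  category <- if (n_tel_termini == 2) {
    "complete_chromosome"
  } else if (n_tel_termini == 1 &&
             ((tel_start && cen_end) || (tel_end && cen_start) ||
              (has_cen && has_p && has_q))) {
    "complete_arm"
  } else if (cen_fraction >= params$cen_pure_frac) {
    "centromere"
  } else if (arm_specific &&
             sum(tel_start, tel_end, cen_start, cen_end) >= 1) {
    "partial_arm"
  } else {
    "marker"
  }

  mutate(assignment,
         category = category,
         tel_start = tel_start, tel_end = tel_end,
         cen_start = cen_start, cen_end = cen_end,
         centromere_fraction = cen_fraction, centromere_bp = cen_bp,
         has_p = has_p, has_q = has_q) |>
    select("contig", "category", dplyr::everything())
}

#' Classify every contig of an annotated assembly
#'
#' @param tracks A list of `feature_call_track` objects.
#' @param params Thresholds from [completeness_params()].
#' @return A tibble with one classification row per contig.
#' @export
classify_assembly <- function(tracks, params = completeness_params()) {
  bind_rows(lapply(tracks, classify_contig, params = params))
}
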