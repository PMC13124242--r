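#' Assign a contig to a chromosome
#'
#' A contig is assigned to the chromosome whose p- plus q-arm k-mer calls
#' dominate its track.  Telomere and centromere calls are uninformative
#' here (those features are global), as are ambiguous, novel and gap calls.
#' The assignment fraction is the winning chromosome's arm-call count over
#' all informative (arm) calls; a contig is unplaced when it has no
#' informative calls or the fraction falls below `min_fraction`.
#'
#' @param track A `feature_call_track`.
#' @param min_fraction Minimum winning fraction to accept (default 0.5).
#' @return A one-row tibble: `contig`, `chromosome` (NA when unplaced),
#'   `assignment_fraction`, `informative_n`.
#' @export
assign_contig <- function(track, min_fraction = 0.5) {
  stopifnot(inherits(track, "feature_call_track"))
  feats <- track$features
  arm_ids <- feats$feature_id[feats$klass == "ARM"]
  arm_calls <- track$calls[track$calls %in% arm_ids]
  informative_n <- length(arm_calls)
  if (informative_n == 0) {
    return(tibble(contig = track$contig, chromosome = NA_character_,
                  assignment_fraction = NA_real_, informative_n = 0L))
  }
  chrom_of <- setNames(feats$chromosome, as.character(feats$feature_id))
  chrom_counts <- tapply(rep(1L, informative_n),
                         chrom_of[as.character(arm_calls)], sum)
  # deterministic argmax: ties go to the chromosome first seen in the table
  chrom_order <- unique(feats$chromosome[feats$klass == "ARM"])
  chrom_counts <- chrom_counts[order(-chrom_counts,
                                     match(names(chrom_counts), chrom_order))]
  frac <- unname(chrom_counts[1]) / informative_n
  tibble(
    contig = track$contig,
    chromosome = if (frac >= min_fraction) names(chrom_counts)[1] else NA_character_,
    assignment_fraction = frac,
    informative_n = informative_n
  )
}

#' Orient a contig relative to the reference
#'
#' Orientation is `"+"` when strand-vote matches are at least as many as
#' mismatches among the contig's arm calls for its assigned chromosome.
#' When the strand votes tie (including the all-zero case), the expected
#' p -> centromere -> q feature progression breaks the tie: if the mean
#' position of q-arm calls precedes the mean position of p-arm calls the
#' contig is reversed.  Any remaining tie defaults to `"+"`.
#'
#' @param track A `feature_call_track`.
#' @param chromosome Chromosome to orient against; defaults to the
#'   [assign_contig()] winner.
#' @return `"+"` or `"-"`.
#' @export
orient_contig <- function(track, chromosome = NULL) {
  stopifnot(inherits(track, "feature_call_track"))
  feats <- track$features
  if (is.null(chromosome)) {
    chromosome <- assign_contig(track)$chromosome
  }
  ids <- if (!is.na(chromosome) && length(chromosome) == 1) {
    feats$feature_id[feats$klass == "ARM" & feats$chromosome == chromosome]
  } else {
    feats$feature_id[feats$klass == "ARM"]
  }
  votes <- track$strand_votes |> filter(.data$feature_id %in% ids)
  m <- sum(votes$match)
  x <- sum(votes$mismatch)
  if (m > x) return("+")
  if (x > m) return("-")
  # order concordance: p calls should precede q calls on the forward strand
  p_ids <- feats$feature_id[feats$feature_id %in% ids & feats$arm == "p"]
  q_ids <- feats$feature_id[feats$feature_id %in% ids & feats$arm == "q"]
  p_pos <- which(track$calls %in% p_ids)
  q_pos <- which(track$calls %in% q_ids)
  if (length(p_pos) > 0 && length(q_pos) > 0 && mean(q_pos) < mean(p_pos)) {
    return("-")
  }
  "+"
}

# Mean expected-rank of a contig's calls along the idealized chromosome
# progression: telomere-adjacent-p 0, p arm 1, centromere 2, q arm 3,
# telomere-adjacent-q 4.  Telomere calls take rank 0 or 4 by whether they
# fall in the first or second half of the (oriented) track.  Used as the
# within-chromosome sort key.
track_mean_rank <- function(track, chromosome, orientation = "+") {
  feats <- track$features
  p_ids <- feats$feature_id[feats$klass == "ARM" & feats$chromosome == chromosome & feats$arm == "p"]
  q_ids <- feats$feature_id[feats$klass == "ARM" & feats$chromosome == chromosome & feats$arm == "q"]
  tel_id <- feats$feature_id[feats$klass == "TEL"]
  cen_id <- feats$feature_id[feats$klass == "CEN"]
  calls <- track$calls
  pos <- seq_along(calls)
  if (orientation == "-") pos <- rev(pos)
  rank <- rep(NA_real_, length(calls))
  rank[calls %in% p_ids] <- 1
  rank[calls %in% cen_id] <- 2
  rank[calls %in% q_ids] <- 3
  tel <- calls %in% tel_id
  rank[tel] <- ifelse(pos[tel] <= length(calls) / 2, 0, 4)
  if (all(is.na(rank))) return(NA_real_)
  mean(rank, na.rm = TRUE)
}

#' Place all contigs of an assembly
#'
#' Runs chromosome assignment, orientation, and ordering over a set of call
#' tracks.  The layout sort key is (chromosome index, mean expected rank of
#' calls along the p -> centromere -> q progression, decreasing length);
#' unplaced contigs come last, by decreasing length.
#'
#' @param tracks A list of `feature_call_track` objects (see
#'   [annotate_assembly()]).
#' @param min_fraction Assignment threshold passed to [assign_contig()].
#' @return A tibble of placements with columns `contig`, `chromosome`,
#'   `orientation`, `assignment_fraction`, `informative_n`, `length`,
#'   `mean_rank`, and `order_rank`.
#' @export
place_contigs <- function(tracks, min_fraction = 0.5) {
  stopifnot(length(tracks) > 0)
  feats <- tracks[[1]]$features
  chrom_order <- unique(feats$chromosome[feats$klass == "ARM"])
  rows <- map(tracks, function(tr) {
    a <- assign_contig(tr, min_fraction)
    ori <- if (is.na(a$chromosome)) "+" else orient_contig(tr, a$chromosome)
    mr <- if (is.na(a$chromosome)) NA_real_ else track_mean_rank(tr, a$chromosome, ori)
    mutate(a, orientation = ori, length = tr$length, mean_rank = mr)
  })
  out <- bind_rows(rows) |>
    mutate(chrom_idx = match(.data$chromosome, chrom_order)) |>
    arrange(is.na(.data$chromosome), .data$chrom_idx,
            .data$mean_rank, desc(.data$length)) |>
    mutate(order_rank = row_number()) |>
    select("contig", "chromosome", "orientation", "assignment_fraction",
           "informative_n", "length", "mean_rank", "order_rank")
  out
}
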