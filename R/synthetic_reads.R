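# Paired-end read simulation from a toy diploid, plus a scoring model that
# stands in for a short-read aligner at known truth loci: per mate and
# haplotype AS = match * n_match - mismatch * n_mismatch, computed by
# direct comparison against the haplotype sequence at the read's true
# locus (substitution-only variant model, so coordinates coincide across
# haplotypes).

#' Simulate paired-end reads from a toy diploid
#'
#' Pairs are sampled uniformly from a uniformly chosen haplotype; mate 1 is
#' the forward strand at the fragment start, mate 2 the reverse complement
#' at the fragment end.  Sequencing errors are injected per base at
#' `error_rate`.  Optional decoy pairs of pure random sequence (matching no
#' genome locus) exercise the not-properly-mapped path.
#'
#' @param diploid A `diploid_truth` from [make_diploid()].
#' @param n_pairs Number of genomic read pairs.
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Fragment size distribution (defaults 300,
#'   30).
#' @param error_rate Per-base sequencing error probability (default 0).
#' @param seed Integer seed.
#' @param n_decoy Number of random decoy pairs appended (default 0).
#' @param chroms Restrict sampling to these chromosomes (default all).
#' @return A tibble with one row per pair: `qname`, `hap` (1, 2, or NA for
#'   decoys), `chrom`, `start1`, `start2` (0-based mate loci), `seq1`,
#'   `seq2` (mate 2 reverse-complemented, as read).
#' @export
simulate_pairs <- function(diploid, n_pairs, read_len = 100,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0, seed = 1, n_decoy = 0,
                           chroms = NULL) {
  stopifnot(inherits(diploid, "diploid_truth"))
  chroms <- chroms %||% names(diploid$hap1)
  lens <- setNames(Biostrings::width(diploid$hap1), names(diploid$hap1))[chroms]
  if (read_len > insert_mean || any(insert_mean > lens)) {
    abort("need read_len <= insert_mean <= chromosome length",
          class = "karyomer_parameter_error")
  }
  withr::with_seed(seed, {
    hap <- sample(1:2, n_pairs, replace = TRUE)
    chrom <- sample(chroms, n_pairs, replace = TRUE,
                    prob = lens / sum(lens))
    insert <- pmax(read_len, round(stats::rnorm(n_pairs, insert_mean, insert_sd)))
    insert <- pmin(insert, lens[chrom])
    start1 <- vapply(seq_len(n_pairs), function(i) {
      sample.int(lens[[chrom[i]]] - insert[i] + 1L, 1) - 1L
    }, integer(1))
    start2 <- start1 + insert - read_len
    seq1 <- character(n_pairs)
    seq2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      src <- if (hap[i] == 1) diploid$hap1 else diploid$hap2
      s <- as.character(src[[chrom[i]]])
      r1 <- substr(s, start1[i] + 1, start1[i] + read_len)
      r2 <- revcomp_chr(substr(s, start2[i] + 1, start2[i] + read_len))
      if (error_rate > 0) {
        r1 <- mutate_dna(r1, error_rate)
        r2 <- mutate_dna(r2, error_rate)
      }
      seq1[i] <- r1
      seq2[i] <- r2
    }
    genomic <- tibble(
      qname = sprintf("pair%05d", seq_len(n_pairs)),
      hap = hap, chrom = chrom,
      start1 = as.integer(start1), start2 = as.integer(start2),
      seq1 = seq1, seq2 = seq2
    )
    if (n_decoy > 0) {
      decoys <- tibble(
        qname = sprintf("decoy%05d", seq_len(n_decoy)),
        hap = NA_integer_, chrom = NA_character_,
        start1 = NA_integer_, start2 = NA_integer_,
        seq1 = vapply(seq_len(n_decoy), function(i) random_dna(read_len),
                      character(1)),
        seq2 = vapply(seq_len(n_decoy), function(i) random_dna(read_len),
                      character(1))
      )
      genomic <- bind_rows(genomic, decoys)
    }
    genomic
  })
}

#' Score simulated pairs against both haplotypes
#'
#' Emulates the per-haplotype alignment step: each mate is scored against
#' each haplotype at its true locus with `AS = match * n_match - mismatch *
#' n_mismatch` (defaults 1 and 4, the common short-read scoring scale).  A
#' pair is properly paired on a haplotype when both mates score at least
#' `proper_floor`; decoy pairs are unaligned everywhere.
#'
#' @param pairs Output of [simulate_pairs()].
#' @param diploid The `diploid_truth` the pairs were simulated from.
#' @param match,mismatch Scoring constants (defaults 1, 4).
#' @param proper_floor Minimum per-mate AS for a proper pair; default half
#'   the perfect score.
#' @return A `pair_summary` tibble (as [summarize_pairs()] produces),
#'   with additional per-mate score columns `as1_m1`, `as1_m2`, `as2_m1`,
#'   `as2_m2` retained for SAM export.
#' @export
score_pairs <- function(pairs, diploid, match = 1, mismatch = 4,
                        proper_floor = NULL) {
  read_len <- nchar(pairs$seq1[which(!is.na(pairs$chrom))[1]])
  proper_floor <- proper_floor %||% (match * read_len / 2)
  n <- nrow(pairs)
  score_mate <- function(hap_seqs, seq, chrom, start, revcomp) {
    if (is.na(chrom)) return(NA_integer_)
    ref <- substr(as.character(hap_seqs[[chrom]]), start + 1,
                  start + nchar(seq))
    q <- if (revcomp) revcomp_chr(seq) else seq
    .score_alignment(q, ref, as.integer(match), as.integer(mismatch))
  }
  as1_m1 <- integer(n); as1_m2 <- integer(n)
  as2_m1 <- integer(n); as2_m2 <- integer(n)
  for (i in seq_len(n)) {
    as1_m1[i] <- score_mate(diploid$hap1, pairs$seq1[i], pairs$chrom[i],
                            pairs$start1[i], FALSE)
    as1_m2[i] <- score_mate(diploid$hap1, pairs$seq2[i], pairs$chrom[i],
                            pairs$start2[i], TRUE)
    as2_m1[i] <- score_mate(diploid$hap2, pairs$seq1[i], pairs$chrom[i],
                            pairs$start1[i], FALSE)
    as2_m2[i] <- score_mate(diploid$hap2, pairs$seq2[i], pairs$chrom[i],
                            pairs$start2[i], TRUE)
  }
  aligned1 <- !is.na(as1_m1)
  tibble(
    qname = pairs$qname,
    proper1 = aligned1 & as1_m1 >= proper_floor & as1_m2 >= proper_floor,
    proper2 = aligned1 & as2_m1 >= proper_floor & as2_m2 >= proper_floor,
    as1 = if_else(aligned1, as1_m1 + as1_m2, NA_integer_),
    as2 = if_else(aligned1, as2_m1 + as2_m2, NA_integer_),
    ref1_1 = pairs$chrom, ref1_2 = pairs$chrom,
    ref2_1 = pairs$chrom, ref2_2 = pairs$chrom,
    as1_m1 = as1_m1, as1_m2 = as1_m2, as2_m1 = as2_m1, as2_m2 = as2_m2,
    start1 = pairs$start1, start2 = pairs$start2,
    seq1 = pairs$seq1, seq2 = pairs$seq2
  ) |>
    mutate(proper1 = tidyr::replace_na(.data$proper1, FALSE),
           proper2 = tidyr::replace_na(.data$proper2, FALSE))
}

sam_header <- function(ref_lens, ref_prefix = "") {
  c("@HD\tVN:1.6\tGO:query",
    sprintf("@SQ\tSN:%s%s\tLN:%d", ref_prefix, names(ref_lens), ref_lens))
}

sam_record <- function(qname, flag, rname, pos0, mapq, seq, as = NA) {
  if (is.na(rname)) {
    sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t*", qname, flag, seq)
  } else {
    base <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t0\t%s\t*",
                    qname, flag, rname, pos0 + 1L, mapq, nchar(seq), 1L, seq)
    if (is.na(as)) base else paste0(base, sprintf("\tAS:i:%d", as))
  }
}

#' Write scored pairs as minimally valid SAM
#'
#' Emits name-grouped SAM so the phasing readers can be exercised
#' end-to-end without an external aligner.  In per-haplotype mode the
#' chosen haplotype's scores and loci are written against that haplotype's
#' references; in combined mode both haplotypes' references appear with
#' `hap1_`/`hap2_` prefixes and each pair is placed on its better-scoring
#' haplotype with MAPQ 60 (or MAPQ 0 on haplotype 1 when the scores tie,
#' mirroring an aligner's arbitrary placement of ambiguous pairs).
#'
#' @param scores Output of [score_pairs()].
#' @param diploid The source `diploid_truth` (for reference lengths).
#' @param path Output SAM path.
#' @param mode `"hap1"`, `"hap2"`, or `"combined"`.
#' @export
write_sam <- function(scores, diploid, path,
                      mode = c("hap1", "hap2", "combined")) {
  mode <- match.arg(mode)
  ref_lens <- setNames(Biostrings::width(diploid$hap1), names(diploid$hap1))
  lines <- if (mode == "combined") {
    c(sam_header(ref_lens, "hap1_"), sam_header(ref_lens, "hap2_")[-1],
      combined_records(scores))
  } else {
    c(sam_header(ref_lens), haplotype_records(scores, mode))
  }
  writeLines(lines, path)
  invisible(path)
}

haplotype_records <- function(scores, mode) {
  h <- if (mode == "hap1") 1L else 2L
  unlist(lapply(seq_len(nrow(scores)), function(i) {
    r <- scores[i, ]
    if (is.na(r$ref1_1)) {
      # decoy: unmapped pair
      return(c(sam_record(r$qname, 77L, NA, NA, 0L, r$seq1),
               sam_record(r$qname, 141L, NA, NA, 0L, r$seq2)))
    }
    proper <- if (h == 1L) r$proper1 else r$proper2
    as_m1 <- if (h == 1L) r$as1_m1 else r$as2_m1
    as_m2 <- if (h == 1L) r$as1_m2 else r$as2_m2
    f1 <- 0x1 + 0x20 + 0x40 + if (proper) 0x2 else 0
    f2 <- 0x1 + 0x10 + 0x80 + if (proper) 0x2 else 0
    c(sam_record(r$qname, f1, r$ref1_1, r$start1, 60L, r$seq1, as_m1),
      sam_record(r$qname, f2, r$ref1_2, r$start2, 60L,
                 revcomp_chr(r$seq2), as_m2))
  }))
}

combined_records <- function(scores) {
  unlist(lapply(seq_len(nrow(scores)), function(i) {
    r <- scores[i, ]
    if (is.na(r$ref1_1)) {
      return(c(sam_record(r$qname, 77L, NA, NA, 0L, r$seq1),
               sam_record(r$qname, 141L, NA, NA, 0L, r$seq2)))
    }
    tie <- r$as1 == r$as2
    best <- if (tie || r$as1 > r$as2) 1L else 2L
    mapq <- if (tie) 0L else 60L
    rname <- paste0("hap", best, "_", r$ref1_1)
    as_m1 <- if (best == 1L) r$as1_m1 else r$as2_m1
    as_m2 <- if (best == 1L) r$as1_m2 else r$as2_m2
    proper <- if (best == 1L) r$proper1 else r$proper2
    f1 <- 0x1 + 0x20 + 0x40 + if (proper) 0x2 else 0
    f2 <- 0x1 + 0x10 + 0x80 + if (proper) 0x2 else 0
    c(sam_record(r$qname, f1, rname, r$start1, mapq, r$seq1, as_m1),
      sam_record(r$qname, f2, rname, r$start2, mapq,
                 revcomp_chr(r$seq2), as_m2))
  }))
}
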