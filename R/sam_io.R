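# SAM ingestion via Rsamtools (SAM -> BAM -> scanBam), returning a flat
# per-record tibble the phasing module collates by read name.

#' Read paired-end alignment records from a SAM or BAM file
#'
#' @param path A SAM (text) or BAM file.
#' @return A tibble with one row per primary alignment record: `qname`,
#'   `mate` (1 or 2), `rname`, `mapq`, `mapped`, `proper`, `as`
#'   (alignment score from the AS tag; NA when absent).
#' @export
read_sam_pairs <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "mapq"),
      tag = "AS"
    )
  )[[1]]
  flag <- res$flag
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  tibble(
    qname = res$qname,
    mate = if_else(bitwAnd(flag, 0x40) != 0, 1L,
                   if_else(bitwAnd(flag, 0x80) != 0, 2L, NA_integer_)),
    rname = as.character(res$rname),
    mapq = as.integer(res$mapq),
    mapped = bitwAnd(flag, 0x4) == 0,
    proper = bitwAnd(flag, 0x2) != 0,
    as = if (is.null(res$tag$AS)) NA_integer_ else as.integer(res$tag$AS)
  )[primary, ]
}

# Collate one haplotype's records into per-pair rows.  Records whose AS tag
# is missing on a mapped mate are treated as unaligned (logged); read names
# with only one mate present are warned about and treated as unaligned on
# this haplotype.
collate_haplotype <- function(records, hap_label) {
  records <- records |> filter(!is.na(.data$mate))
  wide <- records |>
    mutate(aligned = .data$mapped & !is.na(.data$as)) |>
    select("qname", "mate", "rname", "proper", "aligned", "as") |>
    tidyr::pivot_wider(names_from = "mate",
                       values_from = c("rname", "proper", "aligned", "as"))
  need <- c("rname_1", "rname_2", "proper_1", "proper_2",
            "aligned_1", "aligned_2", "as_1", "as_2")
  missing_cols <- setdiff(need, names(wide))
  for (m in missing_cols) wide[[m]] <- if (grepl("^rname", m)) NA_character_ else NA
  unpaired <- is.na(wide$aligned_1) | is.na(wide$aligned_2)
  if (any(unpaired)) {
    warn(sprintf("%d read name(s) unpaired in %s stream; treated as unaligned there",
                 sum(unpaired), hap_label))
  }
  missing_as <- sum(records$mapped & is.na(records$as))
  if (missing_as > 0) {
    inform(sprintf("%d mapped record(s) in %s stream lack an AS tag; treated as unaligned",
                   missing_as, hap_label))
  }
  ok <- !unpaired &
    tidyr::replace_na(wide$aligned_1, FALSE) &
    tidyr::replace_na(wide$aligned_2, FALSE)
  tibble(
    qname = wide$qname,
    proper = ok &
      tidyr::replace_na(wide$proper_1, FALSE) &
      tidyr::replace_na(wide$proper_2, FALSE),
    as_sum = if_else(ok, wide$as_1 + wide$as_2, NA_integer_),
    ref_1 = wide$rname_1,
    ref_2 = wide$rname_2
  )
}

#' Summarize read pairs aligned separately to each haplotype
#'
#' Joins the per-haplotype alignments of each read pair into one summary
#' row: per haplotype the proper-pair status, the summed alignment score
#' (AS tag of mate 1 plus mate 2; defined only when both mates have primary
#' alignments with scores), and the reference names hit.
#'
#' @param hap1,hap2 SAM/BAM paths or record tibbles from
#'   [read_sam_pairs()], one per haplotype.
#' @return A `pair_summary` tibble: `qname`, `proper1`, `proper2`, `as1`,
#'   `as2`, `ref1_1`, `ref1_2`, `ref2_1`, `ref2_2`.
#' @export
summarize_pairs <- function(hap1, hap2) {
  if (is.character(hap1)) hap1 <- read_sam_pairs(hap1)
  if (is.character(hap2)) hap2 <- read_sam_pairs(hap2)
  h1 <- collate_haplotype(hap1, "hap1") |>
    rename(proper1 = "proper", as1 = "as_sum",
           ref1_1 = "ref_1", ref1_2 = "ref_2")
  h2 <- collate_haplotype(hap2, "hap2") |>
    rename(proper2 = "proper", as2 = "as_sum",
           ref2_1 = "ref_1", ref2_2 = "ref_2")
  out <- dplyr::full_join(h1, h2, by = "qname") |>
    mutate(proper1 = tidyr::replace_na(.data$proper1, FALSE),
           proper2 = tidyr::replace_na(.data$proper2, FALSE))
  out
}
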