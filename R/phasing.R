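PHASE_GROUPS <- c("not_properly_mapped", "sex_chromosome",
                  "hap1", "hap2", "homozygous")

#' Phase read pairs by summed alignment score
#'
#' Assigns every read pair to exactly one of five mutually exclusive
#' groups, evaluated in order:
#' 1. `not_properly_mapped` — not properly mapped as a pair to either
#'    haplotype (aligner proper-pair flag);
#' 2. `sex_chromosome` — any mate's reference on either haplotype is a sex
#'    chromosome (`sex_refs`), regardless of scores;
#' 3. `hap1` / `hap2` — properly mapped to only one haplotype: assigned to
#'    that haplotype;
#' 4. `homozygous` — properly mapped to both with equal summed alignment
#'    score;
#' 5. otherwise the haplotype with the higher summed alignment score.
#'
#' @param summaries A `pair_summary` tibble from [summarize_pairs()].
#' @param sex_refs Reference names treated as sex chromosomes (default
#'   `c("chrX", "chrY")`); matched against every available alignment.
#' @return The input with a `group` factor column (five levels).
#' @export
phase_pairs_as <- function(summaries, sex_refs = c("chrX", "chrY")) {
  refs <- cbind(summaries$ref1_1, summaries$ref1_2,
                summaries$ref2_1, summaries$ref2_2)
  on_sex <- apply(refs, 1, function(r) any(r %in% sex_refs))
  group <- case_when(
    !summaries$proper1 & !summaries$proper2 ~ "not_properly_mapped",
    on_sex ~ "sex_chromosome",
    summaries$proper1 & !summaries$proper2 ~ "hap1",
    !summaries$proper1 & summaries$proper2 ~ "hap2",
    summaries$as1 == summaries$as2 ~ "homozygous",
    summaries$as1 > summaries$as2 ~ "hap1",
    TRUE ~ "hap2"
  )
  mutate(summaries, group = factor(group, levels = PHASE_GROUPS))
}

#' Phase read pairs by mapping quality on the combined diploid assembly
#'
#' A read pair aligned to the concatenation of both haplotypes is phased to
#' haplotype h when both mates map to h's references with mapping quality
#' at or above `threshold`; anything else (low MAPQ, unmapped mates, mates
#' split across haplotypes) is conservatively unphased.
#'
#' @param records A SAM/BAM path or record tibble from [read_sam_pairs()]
#'   for the combined diploid assembly.
#' @param threshold Minimum MAPQ (default 10).
#' @param hap_patterns Named character vector of regular expressions that
#'   attribute a reference name to a haplotype (default `hap1_`/`hap2_`
#'   prefixes).
#' @return A tibble: `qname`, `group` in `{hap1, hap2, unphased}`.
#' @export
phase_pairs_mapq <- function(records, threshold = 10,
                             hap_patterns = c(hap1 = "^hap1_", hap2 = "^hap2_")) {
  if (is.character(records)) records <- read_sam_pairs(records)
  recs <- records |> filter(!is.na(.data$mate))
  mapped_refs <- unique(recs$rname[recs$mapped & !is.na(recs$rname)])
  hap_of_ref <- function(r) {
    hit <- which(vapply(hap_patterns, grepl, logical(1), x = r))
    if (length(hit) != 1) {
      abort(sprintf("reference '%s' cannot be attributed to a haplotype", r),
            class = "karyomer_input_error")
    }
    names(hap_patterns)[hit]
  }
  ref_hap <- setNames(vapply(mapped_refs, hap_of_ref, character(1)), mapped_refs)
  recs |>
    mutate(hap = if_else(.data$mapped, unname(ref_hap[.data$rname]), NA_character_),
           confident = .data$mapped & .data$mapq >= threshold) |>
    group_by(.data$qname) |>
    summarise(
      group = if (sum(!is.na(.data$mate)) >= 2 && all(.data$confident) &&
                  dplyr::n_distinct(.data$hap) == 1 &&
                  length(unique(.data$mate)) == 2) unique(.data$hap)
              else "unphased",
      .groups = "drop"
    ) |>
    mutate(group = factor(.data$group, levels = c("hap1", "hap2", "unphased")))
}

#' Tabulate phase groups and the phased fraction
#'
#' @param phased Output of [phase_pairs_as()].
#' @return A tibble with one row per group (all five levels, zero counts
#'   kept): `group`, `n`, `fraction`; the phased fraction
#'   (`(hap1 + hap2) / total`) is attached as attribute
#'   `"phased_fraction"` and returned by [phased_fraction()].
#' @export
phase_summary <- function(phased) {
  counts <- phased |>
    count(.data$group, .drop = FALSE) |>
    mutate(fraction = .data$n / sum(.data$n))
  structure(counts, phased_fraction = phased_fraction(phased))
}

#' @rdname phase_summary
#' @export
phased_fraction <- function(phased) {
  sum(phased$group %in% c("hap1", "hap2")) / nrow(phased)
}

#' Compare concordant and discordant alignment-score distributions
#'
#' For every pair phased to a haplotype by [phase_pairs_as()] with summed
#' alignment scores available on both haplotypes, the concordant sample
#' takes the score on the assigned haplotype and the discordant sample the
#' score on the other.  Each sample gets a two-parameter exponential fit
#' (location = sample minimum, scale = mean minus minimum, the closed-form
#' maximum-likelihood estimates) and the two samples are compared with a
#' two-sample Kolmogorov-Smirnov test (asymptotic p-value with effective
#' sample size n1*n2/(n1+n2)).
#'
#' @param phased Output of [phase_pairs_as()] (must retain `as1`, `as2`).
#' @return An `as_comparison` object with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
compare_as_distributions <- function(phased) {
  decided <- phased |>
    filter(.data$group %in% c("hap1", "hap2"),
           !is.na(.data$as1), !is.na(.data$as2))
  if (nrow(decided) < 2) {
    abort("need at least 2 haplotype-assigned pairs with scores on both haplotypes",
          class = "karyomer_diagnostic_error")
  }
  concordant <- if_else(decided$group == "hap1", decided$as1, decided$as2)
  discordant <- if_else(decided$group == "hap1", decided$as2, decided$as1)
  ks <- suppressWarnings(ks.test(concordant, discordant, exact = FALSE))
  structure(
    list(
      concordant = as.numeric(concordant),
      discordant = as.numeric(discordant),
      median_concordant = median(concordant),
      median_discordant = median(discordant),
      fit_concordant = fit_exponential(concordant),
      fit_discordant = fit_exponential(discordant),
      ks_D = unname(ks$statistic),
      ks_p = unname(ks$p.value),
      n = nrow(decided)
    ),
    class = "as_comparison"
  )
}

# Two-parameter exponential MLE: location at the sample minimum, scale as
# the mean exceedance over it.
fit_exponential <- function(x) {
  c(location = min(x), scale = mean(x) - min(x))
}

#' @export
print.as_comparison <- function(x, ...) {
  cat(sprintf(
    "<as_comparison> n = %d pairs\n  median concordant = %g, discordant = %g\n  KS D = %.4f, p = %.3g\n",
    x$n, x$median_concordant, x$median_discordant, x$ks_D, x$ks_p))
  invisible(x)
}

#' @export
tidy.as_comparison <- function(x, ...) {
  bind_rows(
    tibble(sample = "concordant", as_sum = x$concordant),
    tibble(sample = "discordant", as_sum = x$discordant)
  )
}

#' @export
glance.as_comparison <- function(x, ...) {
  tibble(
    n = x$n,
    median_concordant = x$median_concordant,
    median_discordant = x$median_discordant,
    exp_location_concordant = x$fit_concordant[["location"]],
    exp_scale_concordant = x$fit_concordant[["scale"]],
    exp_location_discordant = x$fit_discordant[["location"]],
    exp_scale_discordant = x$fit_discordant[["scale"]],
    ks_D = x$ks_D,
    ks_p = x$ks_p
  )
}

#' @export
autoplot.as_comparison <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$as_sum, fill = .data$sample)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "summed alignment score", y = "read pairs",
                  subtitle = sprintf("KS D = %.3f, p = %.3g",
                                     object$ks_D, object$ks_p)) +
    ggplot2::theme_minimal()
}
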