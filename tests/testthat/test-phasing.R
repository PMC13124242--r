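# Hand-written SAM fixtures: name-grouped, minimal header, AS tags.
sam_lines <- function(records, refs = c(chrA = 10000L)) {
  c("@HD\tVN:1.6\tGO:query",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs),
    records)
}

rec <- function(qname, flag, rname, pos, mapq, as = NULL) {
  base <- sprintf("%s\t%d\t%s\t%d\t%d\t10M\t=\t%d\t0\tACGTACGTAC\t*",
                  qname, flag, rname, pos, mapq, pos)
  if (is.null(as)) base else paste0(base, sprintf("\tAS:i:%d", as))
}

write_fixture_sam <- function(records, refs = c(chrA = 10000L)) {
  f <- withr::local_tempfile(fileext = ".sam", .local_envir = parent.frame())
  writeLines(sam_lines(records, refs), f)
  f
}

test_that("pair summaries add per-mate alignment scores per haplotype", {
  h1 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60, 151),
                            rec("p1", 147, "chrA", 300, 60, 151)))
  h2 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60, 151),
                            rec("p1", 147, "chrA", 300, 60, 140)))
  s <- summarize_pairs(h1, h2)
  expect_identical(nrow(s), 1L)
  expect_identical(s$as1, 302L)
  expect_identical(s$as2, 291L)
  expect_true(s$proper1 && s$proper2)
})

test_that("a pair absent from one haplotype is unaligned there", {
  h1 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60, 100),
                            rec("p1", 147, "chrA", 300, 60, 100),
                            rec("p2", 99, "chrA", 500, 60, 90),
                            rec("p2", 147, "chrA", 700, 60, 90)))
  h2 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60, 100),
                            rec("p1", 147, "chrA", 300, 60, 100)))
  s <- summarize_pairs(h1, h2)
  p2 <- s[s$qname == "p2", ]
  expect_false(p2$proper2)
  expect_true(is.na(p2$as2))
})

test_that("a mapped record without an AS tag is treated as unaligned", {
  h1 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60),
                            rec("p1", 147, "chrA", 300, 60, 100)))
  h2 <- write_fixture_sam(c(rec("p1", 99, "chrA", 100, 60, 100),
                            rec("p1", 147, "chrA", 300, 60, 100)))
  s <- suppressMessages(summarize_pairs(h1, h2))
  expect_false(s$proper1)
  expect_true(is.na(s$as1))
  expect_true(s$proper2)
})

# Directly constructed pair summaries for the assignment rules.
mk_summary <- function(proper1, proper2, as1, as2, ref = "chr1") {
  tibble::tibble(qname = "p", proper1 = proper1, proper2 = proper2,
                 as1 = as1, as2 = as2,
                 ref1_1 = ref, ref1_2 = ref, ref2_1 = ref, ref2_2 = ref)
}

test_that("the five-group assignment rules fire in order", {
  expect_identical(
    as.character(phase_pairs_as(mk_summary(TRUE, TRUE, 302L, 291L))$group),
    "hap1")
  expect_identical(
    as.character(phase_pairs_as(mk_summary(TRUE, TRUE, 300L, 300L))$group),
    "homozygous")
  expect_identical(
    as.character(phase_pairs_as(mk_summary(FALSE, TRUE, 200L, 180L))$group),
    "hap2")
  expect_identical(
    as.character(phase_pairs_as(mk_summary(FALSE, FALSE, NA_integer_,
                                           NA_integer_))$group),
    "not_properly_mapped")
  # sex chromosome wins over scores whenever any mate touches chrX/chrY
  expect_identical(
    as.character(phase_pairs_as(mk_summary(TRUE, TRUE, 302L, 291L,
                                           ref = "chrX"))$group),
    "sex_chromosome")
})

test_that("MAPQ phasing requires both mates confidently on one haplotype", {
  recs <- function(qname, rnames, mapqs) {
    tibble::tibble(qname = qname, mate = 1:2, rname = rnames,
                   mapq = mapqs, mapped = TRUE, proper = TRUE,
                   as = 100L)
  }
  both60 <- phase_pairs_mapq(recs("p", c("hap1_chr1", "hap1_chr1"), c(60L, 60L)))
  expect_identical(as.character(both60$group), "hap1")
  low <- phase_pairs_mapq(recs("p", c("hap1_chr1", "hap1_chr1"), c(0L, 60L)))
  expect_identical(as.character(low$group), "unphased")
  split <- phase_pairs_mapq(recs("p", c("hap1_chr1", "hap2_chr1"), c(60L, 60L)))
  expect_identical(as.character(split$group), "unphased")
  expect_error(phase_pairs_mapq(recs("p", c("weird_ref", "weird_ref"),
                                     c(60L, 60L))),
               class = "karyomer_input_error")
})

test_that("KS statistic matches the explicit ECDF enumeration oracle", {
  # frozen toy case: ECDF gap 0.25 at the tails
  toy <- tibble::tibble(
    qname = paste0("p", 1:4), proper1 = TRUE, proper2 = TRUE,
    as1 = c(1L, 2L, 3L, 4L), as2 = c(2L, 3L, 4L, 5L),
    ref1_1 = "c", ref1_2 = "c", ref2_1 = "c", ref2_2 = "c",
    group = factor("hap1", levels = levels(phase_pairs_as(
      mk_summary(TRUE, TRUE, 1L, 2L))$group))
  )
  cmp <- compare_as_distributions(toy)
  expect_equal(cmp$ks_D, 0.25)
  expect_equal(cmp$ks_D, oracle_ks_D(c(1, 2, 3, 4), c(2, 3, 4, 5)))

  # random samples up to 1000: library statistic equals the double loop
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(50:1000, 1)
    x <- sample.int(50, n, replace = TRUE)
    y <- sample.int(50, n, replace = TRUE) + sample(0:3, n, replace = TRUE)
    df <- tibble::tibble(
      qname = paste0("p", seq_len(n)), proper1 = TRUE, proper2 = TRUE,
      as1 = x, as2 = y, ref1_1 = "c", ref1_2 = "c", ref2_1 = "c",
      ref2_2 = "c",
      group = factor("hap1", levels = levels(toy$group)))
    cmp <- compare_as_distributions(df)
    expect_equal(cmp$ks_D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
})

test_that("identical concordant and discordant samples give D = 0, p = 1", {
  lv <- levels(phase_pairs_as(mk_summary(TRUE, TRUE, 1L, 2L))$group)
  df <- tibble::tibble(
    qname = c("a", "b"), proper1 = TRUE, proper2 = TRUE,
    as1 = c(5L, 7L), as2 = c(7L, 5L),
    ref1_1 = "c", ref1_2 = "c", ref2_1 = "c", ref2_2 = "c",
    group = factor(c("hap1", "hap1"), levels = lv))
  cmp <- compare_as_distributions(df)
  expect_identical(cmp$ks_D, 0)
  expect_equal(cmp$ks_p, 1)
  expect_identical(length(cmp$concordant), length(cmp$discordant))
})

test_that("the exponential fit uses the closed-form location/scale estimates", {
  x <- c(280, 290, 290, 300, 302)
  fit <- karyomer:::fit_exponential(x)
  expect_identical(fit[["location"]], 280)
  expect_equal(fit[["scale"]], mean(x) - 280)
})

test_that("per-pair concordant scores dominate discordant ones by construction", {
  ref <- make_reference(toy_genome_spec(seed = 31, n_chrom = 2,
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 2e-3, seed = 32)
  sc <- score_pairs(simulate_pairs(dip, 400, seed = 33), dip)
  ph <- phase_pairs_as(sc)
  cmp <- compare_as_distributions(ph)
  expect_true(all(cmp$concordant >= cmp$discordant))
  expect_gte(cmp$median_concordant, cmp$median_discordant)
})

test_that("groups are exhaustive, exclusive, and conserved in count", {
  ref <- make_reference(toy_genome_spec(seed = 41, n_chrom = 3,
                                        chrom_names = c("chr1", "chr2", "chrX"),
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 1e-3, seed = 42)
  sc <- score_pairs(simulate_pairs(dip, 300, seed = 43, n_decoy = 15), dip)
  ph <- phase_pairs_as(sc)
  expect_false(anyNA(ph$group))
  summ <- phase_summary(ph)
  expect_identical(sum(summ$n), nrow(sc))
  expect_identical(nrow(summ), 5L)
  # all five groups realized on this engineered input
  expect_true(all(summ$n > 0))
})

test_that("swapping the haplotype streams swaps hap1/hap2 and fixes the rest", {
  ref <- make_reference(toy_genome_spec(seed = 51, n_chrom = 2,
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 1e-3, seed = 52)
  sc <- score_pairs(simulate_pairs(dip, 300, seed = 53, n_decoy = 10), dip)
  swapped <- sc |>
    dplyr::rename(proper1 = proper2, proper2 = proper1, as1 = as2, as2 = as1,
                  ref1_1 = ref2_1, ref1_2 = ref2_2,
                  ref2_1 = ref1_1, ref2_2 = ref1_2)
  a <- phase_summary(phase_pairs_as(sc))
  b <- phase_summary(phase_pairs_as(swapped))
  expect_identical(a$n[a$group == "hap1"], b$n[b$group == "hap2"])
  expect_identical(a$n[a$group == "hap2"], b$n[b$group == "hap1"])
  expect_identical(a$n[a$group == "homozygous"], b$n[b$group == "homozygous"])
  expect_identical(a$n[a$group == "not_properly_mapped"],
                   b$n[b$group == "not_properly_mapped"])
})

test_that("with no heterozygosity every mapped pair is homozygous", {
  ref <- make_reference(toy_genome_spec(seed = 61, n_chrom = 2,
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 0, seed = 62)
  sc <- score_pairs(simulate_pairs(dip, 200, seed = 63), dip)
  ph <- phase_pairs_as(sc)
  mapped <- ph[ph$group != "not_properly_mapped", ]
  expect_true(all(mapped$group == "homozygous"))
  expect_identical(phased_fraction(ph), 0)
})

test_that("error-free pairs overlapping a het site recover the truth haplotype", {
  ref <- make_reference(toy_genome_spec(seed = 71, n_chrom = 2,
                                        arm_len = c(10000, 15000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 2e-3, seed = 72)
  pairs <- simulate_pairs(dip, 500, seed = 73, error_rate = 0)
  sc <- score_pairs(pairs, dip)
  ph <- phase_pairs_as(sc)
  read_len <- nchar(pairs$seq1[1])
  overlaps_het <- vapply(seq_len(nrow(pairs)), function(i) {
    v <- dip$variants[dip$variants$chrom == pairs$chrom[i], "pos", drop = TRUE]
    any((v >= pairs$start1[i] & v < pairs$start1[i] + read_len) |
        (v >= pairs$start2[i] & v < pairs$start2[i] + read_len))
  }, logical(1))
  decided <- overlaps_het & ph$group %in% c("hap1", "hap2")
  expect_gt(sum(decided), 20)
  expect_identical(as.character(ph$group[decided]),
                   paste0("hap", pairs$hap[decided]))
  # pairs overlapping a het with no errors are never called homozygous
  expect_true(all(ph$group[overlaps_het] %in% c("hap1", "hap2")))
})

test_that("phased fraction rises with heterozygosity (trend over seeds)", {
  ref <- make_reference(toy_genome_spec(seed = 81, n_chrom = 2,
                                        arm_len = c(6000, 9000),
                                        telomere_copies = 40,
                                        centromere_copies = 10))
  rates <- c(0, 1e-4, 1e-3, 1e-2)
  fracs <- sapply(seq_along(rates), function(i) {
    sapply(1:5, function(s) {
      dip <- make_diploid(ref, het_rate = rates[i], seed = 100 * i + s)
      ph <- phase_pairs_as(score_pairs(
        simulate_pairs(dip, 150, seed = 200 * i + s), dip))
      phased_fraction(ph)
    })
  })
  means <- colMeans(fracs)
  expect_true(all(diff(means) >= 0))
  expect_gt(means[4], means[1])
})

test_that("generated SAM round-trips through the summarizer unchanged", {
  ref <- make_reference(toy_genome_spec(seed = 91, n_chrom = 2,
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 1e-3, seed = 92)
  sc <- score_pairs(simulate_pairs(dip, 100, seed = 93, n_decoy = 5), dip)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(sc, dip, f1, "hap1")
  write_sam(sc, dip, f2, "hap2")
  s <- summarize_pairs(f1, f2)
  expect_identical(nrow(s), nrow(sc))
  m <- match(sc$qname, s$qname)
  expect_identical(s$as1[m], sc$as1)
  expect_identical(s$as2[m], sc$as2)
  expect_identical(s$proper1[m], sc$proper1)
  # and the phase groups agree end to end
  expect_identical(as.character(phase_pairs_as(s)$group[m]),
                   as.character(phase_pairs_as(sc)$group))
})

test_that("MAPQ phasing of the combined SAM separates het-informative pairs", {
  ref <- make_reference(toy_genome_spec(seed = 95, n_chrom = 2,
                                        arm_len = c(8000, 12000),
                                        telomere_copies = 60,
                                        centromere_copies = 20))
  dip <- make_diploid(ref, het_rate = 2e-3, seed = 96)
  sc <- score_pairs(simulate_pairs(dip, 200, seed = 97), dip)
  fc <- withr::local_tempfile(fileext = ".sam")
  write_sam(sc, dip, fc, "combined")
  mq <- phase_pairs_mapq(fc)
  ph <- phase_pairs_as(sc)
  m <- match(sc$qname, mq$qname)
  # AS-decided pairs carry MAPQ 60 on their haplotype; ties carry MAPQ 0
  expect_identical(as.character(mq$group[m][ph$group == "hap1"]),
                   rep("hap1", sum(ph$group == "hap1")))
  expect_true(all(mq$group[m][ph$group == "homozygous"] == "unphased"))
})
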