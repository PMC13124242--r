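test_that("a 24-chromosome annotated reference yields 50 features (48 arms)", {
  ref <- make_reference(toy_genome_spec(
    seed = 3, n_chrom = 24, arm_len = c(1200, 1800),
    telomere_copies = 30, centromere_copies = 6,
    chrom_names = c(paste0("chr", 1:22), "chrX", "chrY")
  ))
  db <- build_feature_db(ref$sequences, ref$annotation, k = 31)
  g <- glance(db)
  expect_identical(g$n_features, 50L)
  expect_identical(g$n_arm_features, 48L)
  expect_identical(sum(tidy(db)$klass == "TEL"), 1L)
  expect_identical(sum(tidy(db)$klass == "CEN"), 1L)
})

test_that("one annotated chromosome yields four features", {
  ref <- make_reference(toy_genome_spec(seed = 5, n_chrom = 1,
                                        arm_len = c(1000, 1500),
                                        telomere_copies = 20,
                                        centromere_copies = 4))
  db <- build_feature_db(ref$sequences, ref$annotation, k = 31)
  expect_identical(sort(tidy(db)$name), sort(c("TEL", "CEN", "chr1_p", "chr1_q")))
})

test_that("entries and ambiguity match brute-force enumeration", {
  ref <- small_ref()
  db <- small_db()
  oracle <- oracle_kmer_map(ref, k = 31)
  g <- glance(db)
  expect_identical(g$n_kmers, nrow(oracle))
  expect_identical(g$n_ambiguous, sum(oracle$n_features > 1L))

  # spot-check feature agreement on a deterministic sample of keys
  idx <- seq(1, nrow(oracle), length.out = 200)
  for (i in idx) {
    hit <- lookup_kmer(db, oracle$canon[i])
    expected <- if (oracle$n_features[i] > 1) "AMBIGUOUS" else oracle$feat[i]
    expect_identical(hit$call, expected)
  }
})

test_that("a segment shared between two arms makes its interior k-mers ambiguous", {
  ref <- make_reference(toy_genome_spec(
    seed = 17, n_chrom = 3, arm_len = c(2500, 4000),
    telomere_copies = 60, centromere_copies = 10,
    shared_dup = list(length = 300, from = "chr1_p", to = "chr2_q")
  ))
  db <- build_feature_db(ref$sequences, ref$annotation, k = 31)
  oracle <- oracle_kmer_map(ref, k = 31)
  n_amb_oracle <- sum(oracle$n_features > 1L)
  expect_gt(n_amb_oracle, 0L)
  expect_identical(glance(db)$n_ambiguous, n_amb_oracle)
  # interior k-mers of the duplicated segment are ambiguous in both copies
  p_start <- with(ref$annotation,
                  start[seqname == "chr1" & klass == "ARM" & arm == "p"])
  seg <- substr(as.character(ref$sequences[["chr1"]]),
                p_start + 101, p_start + 400)
  mid <- substr(seg, 100, 130)
  expect_identical(lookup_kmer(db, mid)$call, "AMBIGUOUS")
})

test_that("lookup handles orientation, alphabet and length rules", {
  ref <- small_ref()
  db <- small_db()
  q_iv <- ref$annotation |>
    dplyr::filter(seqname == "chr1", klass == "ARM", arm == "q")
  kmer <- substr(as.character(ref$sequences[["chr1"]]),
                 q_iv$start + 51, q_iv$start + 81)
  fwd <- lookup_kmer(db, kmer)
  expect_identical(fwd$call, "chr1_q")
  rev <- lookup_kmer(db, oracle_revcomp(kmer))
  expect_identical(rev$call, "chr1_q")
  expect_identical(rev$strand_match, !fwd$strand_match)
  expect_identical(lookup_kmer(db, paste0("N", substr(kmer, 2, 31)))$call,
                   "INVALID")
  expect_error(lookup_kmer(db, "ACGT"), class = "karyomer_parameter_error")
})

test_that("every k-mer of the source reference is found (zero novel calls)", {
  ref <- small_ref()
  db <- small_db()
  for (chrom in names(ref$sequences)) {
    tr <- annotate_sequence(db, ref$sequences[chrom])
    expect_identical(sum(tr$calls == -2L), 0L)  # no NOVEL
    expect_identical(sum(tr$calls == -3L), 0L)  # no GAP on ACGT-only input
  }
})

test_that("database serialization round-trips and is deterministic", {
  db <- small_db()
  f1 <- withr::local_tempfile(fileext = ".ksdb")
  f2 <- withr::local_tempfile(fileext = ".ksdb")
  write_feature_db(db, f1)
  back <- read_feature_db(f1)
  expect_identical(back$k, db$k)
  expect_equal(back$features, db$features)
  expect_identical(back$key_hi, db$key_hi)
  expect_identical(back$key_lo, db$key_lo)
  expect_identical(back$payload, db$payload)
  expect_identical(back$strand, db$strand)
  write_feature_db(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an entry-less database keeps its feature table through a round trip", {
  db <- small_db()
  empty <- db
  empty$key_hi <- integer(0)
  empty$key_lo <- integer(0)
  empty$payload <- integer(0)
  empty$strand <- integer(0)
  f <- withr::local_tempfile(fileext = ".ksdb")
  write_feature_db(empty, f)
  back <- read_feature_db(f)
  expect_equal(back$features, db$features)
  expect_identical(length(back$payload), 0L)
})

test_that("a tampered magic string is rejected as a format error", {
  db <- small_db()
  f <- withr::local_tempfile(fileext = ".ksdb")
  write_feature_db(db, f)
  raw <- readBin(f, "raw", file.size(f))
  raw[1] <- as.raw(88)
  writeBin(raw, f)
  expect_error(read_feature_db(f), class = "karyomer_format_error")
})

test_that("parameter and input validation reject bad databases", {
  ref <- small_ref()
  expect_error(build_feature_db(ref$sequences, ref$annotation, k = 32),
               class = "karyomer_parameter_error")
  expect_error(build_feature_db(ref$sequences, ref$annotation, k = 1),
               class = "karyomer_parameter_error")
  bad_ann <- ref$annotation
  bad_ann$end[1] <- 10^9
  expect_error(build_feature_db(ref$sequences, bad_ann, k = 31),
               class = "karyomer_annotation_error")
  expect_error(build_feature_db(Biostrings::DNAStringSet(), ref$annotation),
               class = "karyomer_input_error")
})

test_that("BED annotation I/O round-trips intervals and feature names", {
  ref <- small_ref()
  f <- withr::local_tempfile(fileext = ".bed")
  write_feature_bed(ref$annotation, f)
  back <- read_feature_bed(f)
  orig <- ref$annotation |> dplyr::arrange(seqname, start)
  back <- back |> dplyr::arrange(seqname, start)
  expect_equal(back, orig)
})
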