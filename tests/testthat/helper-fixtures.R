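# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles.  Oracles deliberately use different algorithms and
# data structures than the package internals (string hashing and direct
# counting instead of 2-bit packed binary search).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small 3-chromosome reference for k-mer level tests (fast to enumerate
# by brute force): ~10 kb chromosomes.
small_ref <- function() {
  cached("small_ref", make_reference(toy_genome_spec(
    seed = 101, n_chrom = 3, arm_len = c(2500, 4000),
    telomere_copies = 60, centromere_copies = 10
  )))
}

small_db <- function() {
  cached("small_db", {
    ref <- small_ref()
    suppressMessages(build_feature_db(ref$sequences, ref$annotation, k = 31))
  })
}

# Classifier-scale reference (defaults sized for the default thresholds).
preset_ref <- function(seed = 7) {
  cached(paste0("preset_ref_", seed),
         make_reference(toy_genome_spec(seed = seed, n_chrom = 5)))
}

preset_db <- function(seed = 7) {
  cached(paste0("preset_db_", seed), {
    ref <- preset_ref(seed)
    suppressMessages(build_feature_db(ref$sequences, ref$annotation, k = 31))
  })
}

# Reverse complement for oracle use (chartr + explicit reversal).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force (k-mer, feature) enumeration: per-window locus resolution by
# TEL > CEN > ARM precedence from per-base labels, canonicalization by
# string comparison, multi-feature keys flagged ambiguous.
oracle_kmer_map <- function(reference, k) {
  ann <- reference$annotation
  out <- list()
  for (chrom in names(reference$sequences)) {
    s <- as.character(reference$sequences[[chrom]])
    L <- nchar(s)
    base_name <- rep(NA_character_, L)
    base_prio <- integer(L)
    rows <- which(ann$seqname == chrom)
    prio_of <- c(TEL = 3L, CEN = 2L, ARM = 1L)
    for (j in rows[order(prio_of[ann$klass[rows]])]) {
      idx <- (ann$start[j] + 1L):ann$end[j]
      base_name[idx] <- if (ann$klass[j] == "ARM") {
        paste0(ann$chromosome[j], "_", ann$arm[j])
      } else ann$klass[j]
      base_prio[idx] <- prio_of[[ann$klass[j]]]
    }
    starts <- seq_len(L - k + 1)
    kmers <- substring(s, starts, starts + k - 1)
    # windowed "any base of priority p" via cumulative sums
    win_has <- function(ind) {
      cs <- cumsum(ind)
      (cs[starts + k - 1] - c(0, cs)[starts]) > 0
    }
    has_tel <- win_has(base_prio == 3L)
    has_cen <- win_has(base_prio == 2L)
    feat <- ifelse(has_tel, "TEL",
                   ifelse(has_cen, "CEN", base_name[starts]))
    keep <- !is.na(feat) & !grepl("[^ACGT]", kmers)
    rc <- oracle_revcomp(kmers[keep])
    canon <- pmin(kmers[keep], rc)
    out[[chrom]] <- data.frame(canon = canon, feat = feat[keep])
  }
  df <- do.call(rbind, out)
  df <- unique(df)
  agg <- tapply(df$feat, df$canon, function(f) length(unique(f)))
  data.frame(canon = names(agg), n_features = as.integer(agg),
             feat = tapply(df$feat, df$canon, function(f)
               if (length(unique(f)) == 1) unique(f) else NA_character_))
}

# Construct a bare feature_call_track (for placement/binning unit tests
# that need exact call patterns without sequence round trips).
fake_track <- function(calls, features, contig = "synthetic", k = 31,
                       bp = length(calls) + k - 1, orient = NULL) {
  if (is.null(orient)) orient <- rep(NA_integer_, length(calls))
  votes <- tibble::tibble(
    feature_id = features$feature_id,
    match = vapply(features$feature_id,
                   function(f) sum(orient == 1L & calls == f, na.rm = TRUE),
                   integer(1)),
    mismatch = vapply(features$feature_id,
                      function(f) sum(orient == 0L & calls == f, na.rm = TRUE),
                      integer(1))
  )
  structure(
    list(contig = contig, length = bp, k = k, calls = as.integer(calls),
         orient = orient, features = features, strand_votes = votes),
    class = "feature_call_track"
  )
}

# Brute-force two-sample KS statistic: double loop over the pooled points.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (p in pts) {
    fx <- sum(x <= p) / length(x)
    fy <- sum(y <= p) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Brute-force NG(x): test every candidate length directly.
oracle_ng <- function(lengths, G, x) {
  need <- x / 100 * G
  if (x == 0) return(as.numeric(max(lengths)))
  best <- NA_real_
  for (cand in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= cand]) >= need) { best <- cand; break }
  }
  as.numeric(if (is.na(best)) 0 else best)
}

CATEGORIES <- c("complete_chromosome", "complete_arm", "centromere",
                "partial_arm", "marker")
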