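#' Feature annotations for a reference genome
#'
#' A feature annotation is a tibble with one row per annotated interval and
#' columns `seqname`, `start`, `end` (0-based, half-open base coordinates),
#' `klass` (one of `"TEL"`, `"CEN"`, `"ARM"`), `chromosome` (empty unless
#' `klass == "ARM"`), and `arm` (`"p"` or `"q"` for arm intervals, otherwise
#' empty).  Telomere and centromere intervals describe single global
#' features; each annotated arm becomes its own chromosome-specific feature.
#'
#' @param path Path to a BED file.  Column 4 encodes the feature as `"TEL"`,
#'   `"CEN"`, or `"<chromosome>_<p|q>"` (for example `"chr1_p"`).
#' @return A feature annotation tibble.
#' @export
read_feature_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) {
    abort("BED annotation requires a name column (TEL, CEN, or <chrom>_<p|q>)",
          class = "karyomer_annotation_error")
  }
  tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    name = nm
  ) |>
    mutate(
      klass = case_when(
        .data$name == "TEL" ~ "TEL",
        .data$name == "CEN" ~ "CEN",
        grepl("_[pq]$", .data$name) ~ "ARM",
        TRUE ~ NA_character_
      ),
      chromosome = if_else(.data$klass == "ARM",
                           sub("_[pq]$", "", .data$name), ""),
      arm = if_else(.data$klass == "ARM",
                    sub("^.*_", "", .data$name), "")
    ) |>
    (\(d) {
      bad <- d$name[is.na(d$klass)]
      if (length(bad) > 0) {
        abort(sprintf("unrecognized BED feature name(s): %s",
                      paste(unique(bad), collapse = ", ")),
              class = "karyomer_annotation_error")
      }
      d
    })() |>
    select("seqname", "start", "end", "klass", "chromosome", "arm")
}

#' @rdname read_feature_bed
#' @param annotation A feature annotation tibble.
#' @export
write_feature_bed <- function(annotation, path) {
  nm <- ifelse(annotation$klass == "ARM",
               paste0(annotation$chromosome, "_", annotation$arm),
               annotation$klass)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqname,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    name = nm
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Build the dense feature table (ids 0..F-1) from an annotation.
# TEL and CEN are single global features; arms are per chromosome,
# ordered by first appearance in the annotation, p before q.
feature_table_from_annotation <- function(annotation) {
  arms <- annotation |>
    filter(.data$klass == "ARM") |>
    select("chromosome", "arm") |>
    unique()
  chrom_order <- unique(arms$chromosome)
  arms <- arms |>
    mutate(chrom_idx = match(.data$chromosome, chrom_order)) |>
    arrange(.data$chrom_idx, .data$arm)
  pal <- chromosome_palette(chrom_order)
  arm_colors <- ifelse(arms$arm == "p",
                       pal$p[arms$chrom_idx],
                       pal$q[arms$chrom_idx])
  tibble(
    feature_id = c(0L, 1L, seq_len(nrow(arms)) + 1L),
    name = c("TEL", "CEN", paste0(arms$chromosome, "_", arms$arm)),
    klass = c("TEL", "CEN", rep("ARM", nrow(arms))),
    chromosome = c("", "", arms$chromosome),
    arm = c("", "", arms$arm),
    color = c(COLOR_TELOMERE, COLOR_CENTROMERE, arm_colors)
  )
}

validate_annotation <- function(annotation, seq_lengths) {
  for (i in seq_len(nrow(annotation))) {
    s <- annotation$seqname[i]
    if (!s %in% names(seq_lengths)) {
      abort(sprintf("annotation interval %d references unknown sequence '%s'", i, s),
            class = "karyomer_annotation_error")
    }
    if (annotation$start[i] < 0 || annotation$start[i] >= annotation$end[i] ||
        annotation$end[i] > seq_lengths[[s]]) {
      abort(sprintf(
        "annotation interval %d (%s:%d-%d) out of bounds for sequence of length %d",
        i, s, annotation$start[i], annotation$end[i], seq_lengths[[s]]),
        class = "karyomer_annotation_error")
    }
  }
  invisible(annotation)
}

#' Build a k-mer feature database from an annotated reference
#'
#' Associates every k-mer of the annotated portions of a reference genome
#' with a genomic feature: the global telomere feature, the global
#' centromere feature, or one of the chromosome-specific arm features.
#' Keys are canonical (the lexicographic minimum of a k-mer and its reverse
#' complement) so that reverse-complemented query sequences are still
#' annotated, and each key carries a strand tag recording the orientation
#' of its reference occurrence(s) relative to the canonical form.
#'
#' A k-mer window overlapping annotation intervals of several classes at one
#' locus is resolved by precedence telomere > centromere > arm; a k-mer
#' sequence whose occurrences resolve to two or more distinct features is
#' stored as ambiguous.  Windows containing non-ACGT characters are skipped,
#' and k-mers from unannotated reference regions are excluded (they will
#' read back as novel), with a warning reporting the uncovered fraction.
#'
#' @param reference Reference sequences: a `DNAStringSet`, a named character
#'   vector, or a FASTA path (gzip accepted).
#' @param annotation A feature annotation tibble (see [read_feature_bed()]).
#' @param k Odd k-mer size between 3 and 31 (default 31, so a k-mer packs
#'   into a single 64-bit code).
#' @return A `feature_db` object.
#' @examples
#' ref <- make_reference(toy_genome_spec(seed = 1, n_chrom = 2,
#'                                       arm_len = c(2000, 3000)))
#' db <- build_feature_db(ref$sequences, ref$annotation, k = 21)
#' glance(db)
#' @export
build_feature_db <- function(reference, annotation, k = 31) {
  k <- stopifnot_scalar_int(k, "k")
  if (k < 3 || k > 31 || k %% 2 == 0) {
    abort("`k` must be an odd integer between 3 and 31",
          class = "karyomer_parameter_error")
  }
  seqs <- as_dna_set(reference)
  if (length(seqs) == 0) {
    abort("reference contains no sequences", class = "karyomer_input_error")
  }
  seq_lengths <- setNames(Biostrings::width(seqs), names(seqs))
  validate_annotation(annotation, seq_lengths)

  features <- feature_table_from_annotation(annotation)
  feat_id <- setNames(features$feature_id, features$name)
  ann_name <- ifelse(annotation$klass == "ARM",
                     paste0(annotation$chromosome, "_", annotation$arm),
                     annotation$klass)
  ann_feat <- unname(feat_id[ann_name])
  ann_prio <- c(TEL = 3L, CEN = 2L, ARM = 1L)[annotation$klass]

  base_feat <- vector("list", length(seqs))
  base_prio <- vector("list", length(seqs))
  covered <- 0
  for (i in seq_along(seqs)) {
    L <- seq_lengths[[i]]
    bf <- rep(-1L, L)
    bp <- integer(L)
    rows <- which(annotation$seqname == names(seqs)[i])
    # paint in increasing precedence so TEL overwrites CEN overwrites ARM
    for (j in rows[order(ann_prio[rows])]) {
      idx <- (annotation$start[j] + 1L):annotation$end[j]
      bf[idx] <- ann_feat[j]
      bp[idx] <- ann_prio[j]
    }
    covered <- covered + sum(bp > 0)
    base_feat[[i]] <- bf
    base_prio[[i]] <- bp
    if (length(rows) == 0) {
      warn(sprintf("reference sequence '%s' has no annotation; its k-mers will read as novel",
                   names(seqs)[i]))
    }
  }
  total_bp <- sum(seq_lengths)
  if (covered < total_bp) {
    inform(sprintf("%.1f%% of the reference is unannotated and excluded from the database",
                   100 * (1 - covered / total_bp)))
  }

  acc <- .kmer_db_accumulate(as.character(seqs), base_feat, base_prio, k)
  structure(
    list(k = k, features = features,
         key_hi = acc$key_hi, key_lo = acc$key_lo,
         payload = acc$payload, strand = acc$strand),
    class = "feature_db"
  )
}

#' @export
print.feature_db <- function(x, ...) {
  cat(sprintf("<feature_db> k=%d, %d features, %d canonical k-mers (%d ambiguous)\n",
              x$k, nrow(x$features), length(x$payload),
              sum(x$payload == CALL_AMBIG)))
  invisible(x)
}

#' @export
tidy.feature_db <- function(x, ...) x$features

#' @export
glance.feature_db <- function(x, ...) {
  tibble(
    k = x$k,
    n_features = nrow(x$features),
    n_arm_features = sum(x$features$klass == "ARM"),
    n_kmers = length(x$payload),
    n_ambiguous = sum(x$payload == CALL_AMBIG)
  )
}

#' Look up a single k-mer in a feature database
#'
#' @param db A `feature_db`.
#' @param kmer A string of length `db$k`.
#' @return A one-row tibble with columns `kmer`, `call` (feature name,
#'   `"AMBIGUOUS"`, `"NOVEL"`, or `"INVALID"`), `feature_id` (NA unless a
#'   feature call), and `strand_match` (TRUE if the queried orientation
#'   matches the stored reference orientation, NA when undefined, e.g. for
#'   mixed-strand keys).
#' @export
lookup_kmer <- function(db, kmer) {
  stopifnot(inherits(db, "feature_db"))
  if (!is.character(kmer) || length(kmer) != 1 || nchar(kmer) != db$k) {
    abort(sprintf("`kmer` must be a single string of length k = %d", db$k),
          class = "karyomer_parameter_error")
  }
  res <- .kmer_db_query(db$key_hi, db$key_lo, db$payload, db$strand, kmer, db$k)
  code <- res$calls[1]
  call <- if (code == CALL_GAP) "INVALID"
          else if (code == CALL_NOVEL) "NOVEL"
          else if (code == CALL_AMBIG) "AMBIGUOUS"
          else db$features$name[match(code, db$features$feature_id)]
  tibble(
    kmer = kmer,
    call = call,
    feature_id = if (code >= 0) code else NA_integer_,
    strand_match = if (is.na(res$orient[1])) NA else res$orient[1] == 1L
  )
}

DB_MAGIC <- "KARYOMERDB"
DB_VERSION <- 1L

#' Serialize a feature database
#'
#' The file layout is a magic string, a format version, k, the feature
#' table (JSON), and the sorted canonical key array with parallel payload
#' and strand arrays, all little-endian.  Serialization is deterministic:
#' writing the same database twice produces identical bytes.
#'
#' @param db A `feature_db`.
#' @param path Output path (conventionally `.ksdb`).
#' @export
write_feature_db <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DB_MAGIC), con)
  writeBin(DB_VERSION, con, size = 4, endian = "little")
  writeBin(db$k, con, size = 4, endian = "little")
  ft <- charToRaw(jsonlite::toJSON(db$features, digits = NA))
  writeBin(length(ft), con, size = 4, endian = "little")
  writeBin(ft, con)
  writeBin(length(db$payload), con, size = 4, endian = "little")
  writeBin(db$key_hi, con, size = 4, endian = "little")
  writeBin(db$key_lo, con, size = 4, endian = "little")
  writeBin(db$payload, con, size = 4, endian = "little")
  writeBin(db$strand, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_feature_db
#' @export
read_feature_db <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(DB_MAGIC)))
  if (!identical(magic, DB_MAGIC)) {
    abort("not a karyomer feature database (bad magic string)",
          class = "karyomer_format_error")
  }
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(version, DB_VERSION)) {
    abort(sprintf("unsupported feature database version %s", version),
          class = "karyomer_format_error")
  }
  k <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  ft_len <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  ft_raw <- readBin(con, "raw", n = ft_len)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(ft_raw) < ft_len || length(n) != 1 || length(k) != 1) {
    abort("truncated feature database file", class = "karyomer_io_error")
  }
  features <- as_tibble(jsonlite::fromJSON(rawToChar(ft_raw)))
  features$feature_id <- as.integer(features$feature_id)
  key_hi <- readBin(con, "integer", n = n, size = 4, endian = "little")
  key_lo <- readBin(con, "integer", n = n, size = 4, endian = "little")
  payload <- readBin(con, "integer", n = n, size = 4, endian = "little")
  strand <- readBin(con, "integer", n = n, size = 4, endian = "little")
  if (length(strand) < n) {
    abort("truncated feature database file", class = "karyomer_io_error")
  }
  structure(
    list(k = k, features = features, key_hi = key_hi, key_lo = key_lo,
         payload = payload, strand = strand),
    class = "feature_db"
  )
}
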