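#' Specification of a deterministic toy genome
#'
#' Describes a multi-chromosome toy reference with realistic structure:
#' telomeric repeat arrays at both termini (`CCCTAA` units at the start,
#' `TTAGGG` at the end), a satellite centromere array built from a single
#' monomer shared across chromosomes (mutated per copy so arrays are
#' non-identical yet belong to one global centromere feature), and
#' chromosome-unique random p and q arms.  Generation is a pure function of
#' the spec: identical specs produce identical sequences.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_chrom Number of chromosomes.
#' @param arm_len Length range (bp) from which each arm length is drawn.
#' @param telomere_unit Telomeric repeat unit (default `"TTAGGG"`).
#' @param telomere_copies Number of repeat units per telomere array.
#' @param centromere_monomer Satellite monomer; generated from the seed
#'   (171 bp, alpha-satellite-like length) when NULL.
#' @param centromere_copies Monomer copies per centromere array.
#' @param monomer_divergence Per-base substitution rate applied to each
#'   monomer copy (default 0.02).
#' @param shared_dup Optional segmental duplication shared between two
#'   arms: `list(length =, from = "chr1_p", to = "chr2_q")`; the segment is
#'   copied verbatim from the interior of one arm into the interior of the
#'   other.
#' @param acrocentric Chromosome names given degenerate (short) p arms.
#' @param acro_p_len p-arm length used for acrocentric chromosomes.
#' @param chrom_names Chromosome names (default `chr1..chrN`; pass names
#'   including `"chrX"`/`"chrY"` to emulate sex chromosomes).
#' @return A `toy_genome_spec` list.
#' @export
toy_genome_spec <- function(seed = 1, n_chrom = 3, arm_len = c(20000, 40000),
                            telomere_unit = "TTAGGG", telomere_copies = 700,
                            centromere_monomer = NULL, centromere_copies = 320,
                            monomer_divergence = 0.02, shared_dup = NULL,
                            acrocentric = character(), acro_p_len = 3000,
                            chrom_names = NULL) {
  structure(
    list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
         arm_len = arm_len, telomere_unit = telomere_unit,
         telomere_copies = as.integer(telomere_copies),
         centromere_monomer = centromere_monomer,
         centromere_copies = as.integer(centromere_copies),
         monomer_divergence = monomer_divergence, shared_dup = shared_dup,
         acrocentric = acrocentric, acro_p_len = as.integer(acro_p_len),
         chrom_names = chrom_names %||% paste0("chr", seq_len(n_chrom))),
    class = "toy_genome_spec"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Generate a toy reference genome with feature annotations
#'
#' @param spec A [toy_genome_spec()].
#' @param k Minimum arm length sanity check (arms must be at least k).
#' @return A list with `sequences` (a `DNAStringSet`), `annotation` (a
#'   feature annotation tibble, see [read_feature_bed()]), and `spec`.
#' @export
make_reference <- function(spec, k = 31) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  withr::with_seed(spec$seed, {
    monomer <- spec$centromere_monomer %||% random_dna(171)
    tel_end <- strrep(spec$telomere_unit, spec$telomere_copies)
    tel_start <- revcomp_chr(tel_end)
    tel_len <- nchar(tel_end)

    seqs <- character(spec$n_chrom)
    ann <- vector("list", spec$n_chrom)
    arms <- list() # keep arm sequences for shared_dup injection
    for (i in seq_len(spec$n_chrom)) {
      chrom <- spec$chrom_names[i]
      p_len <- if (chrom %in% spec$acrocentric) spec$acro_p_len
               else sample(spec$arm_len[1]:spec$arm_len[2], 1)
      q_len <- sample(spec$arm_len[1]:spec$arm_len[2], 1)
      if (min(p_len, q_len) < k) {
        abort(sprintf("arm of %d bp is shorter than k = %d; use longer arms",
                      min(p_len, q_len), k),
              class = "karyomer_generation_error")
      }
      p_arm <- random_dna(p_len)
      q_arm <- random_dna(q_len)
      cen <- paste(vapply(seq_len(spec$centromere_copies),
                          function(j) mutate_dna(monomer, spec$monomer_divergence),
                          character(1)), collapse = "")
      arms[[paste0(chrom, "_p")]] <- p_arm
      arms[[paste0(chrom, "_q")]] <- q_arm
      seqs[i] <- paste0(tel_start, p_arm, cen, q_arm, tel_end)
      cen_len <- nchar(cen)
      offs <- as.integer(cumsum(c(0, tel_len, p_len, cen_len, q_len)))
      ann[[i]] <- tibble(
        seqname = chrom,
        start = offs,
        end = c(offs[-1], offs[5] + as.integer(tel_len)),
        klass = c("TEL", "ARM", "CEN", "ARM", "TEL"),
        chromosome = c("", chrom, "", chrom, ""),
        arm = c("", "p", "", "q", "")
      )
    }
    names(seqs) <- spec$chrom_names
    annotation <- bind_rows(ann)

    if (!is.null(spec$shared_dup)) {
      sd <- spec$shared_dup
      src <- arms[[sd$from]]
      if (is.null(src) || nchar(src) < sd$length + 200) {
        abort("shared_dup source arm too short", class = "karyomer_generation_error")
      }
      seg <- substr(src, 101, 100 + sd$length)
      # splice the segment into the interior of the target arm, length-preserving
      tgt_chrom <- sub("_[pq]$", "", sd$to)
      tgt_arm <- sub("^.*_", "", sd$to)
      row <- which(annotation$chromosome == tgt_chrom & annotation$arm == tgt_arm)
      stopifnot(length(row) == 1)
      a0 <- annotation$start[row]
      insert_at <- a0 + 100
      s <- seqs[tgt_chrom]
      substr(s, insert_at + 1, insert_at + sd$length) <- seg
      seqs[tgt_chrom] <- s
    }

    list(sequences = Biostrings::DNAStringSet(seqs),
         annotation = annotation, spec = spec)
  })
}

#' Introduce heterozygous SNVs to form a diploid toy genome
#'
#' Haplotype 1 is the reference; haplotype 2 carries substitutions (no
#' indels) placed uniformly over the arm (non-telomere, non-centromere)
#' regions at the given per-base rate, all recorded in a truth table.
#'
#' @param reference Output of [make_reference()].
#' @param het_rate Per-base heterozygous substitution probability in
#'   `[0, 0.05]`.
#' @param seed Integer seed.
#' @return A `diploid_truth` list: `hap1`, `hap2` (DNAStringSets),
#'   `variants` (tibble `chrom`, `pos` 0-based, `ref`, `alt`), `het_rate`.
#' @export
make_diploid <- function(reference, het_rate, seed = 1) {
  if (het_rate < 0 || het_rate > 0.05) {
    abort("`het_rate` must be in [0, 0.05]", class = "karyomer_parameter_error")
  }
  withr::with_seed(seed, {
    hap1 <- reference$sequences
    hap2 <- as.character(hap1)
    ann <- reference$annotation
    vars <- list()
    for (chrom in names(hap2)) {
      eligible <- ann |> filter(.data$seqname == chrom, .data$klass == "ARM")
      pos <- unlist(lapply(seq_len(nrow(eligible)), function(i) {
        seq.int(eligible$start[i], eligible$end[i] - 1L)
      }))
      n_var <- rbinom(1, length(pos), het_rate)
      if (n_var == 0) next
      sites <- sort(sample(pos, n_var))
      s <- hap2[[chrom]]
      refb <- vapply(sites, function(p) substr(s, p + 1, p + 1), character(1))
      altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
      for (j in seq_along(sites)) {
        substr(s, sites[j] + 1, sites[j] + 1) <- altb[j]
      }
      hap2[[chrom]] <- s
      vars[[chrom]] <- tibble(chrom = chrom, pos = sites,
                              ref = unname(refb), alt = unname(altb))
    }
    variants <- if (length(vars) > 0) bind_rows(vars) else
      tibble(chrom = character(), pos = integer(),
             ref = character(), alt = character())
    structure(
      list(hap1 = hap1, hap2 = Biostrings::DNAStringSet(hap2),
           variants = variants, het_rate = het_rate, seed = seed),
      class = "diploid_truth"
    )
  })
}
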