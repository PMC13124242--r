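# Small internal helpers shared across modules.

# Reverse complement of a plain character scalar.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce sequences to a named DNAStringSet; accepts a DNAStringSet,
# a named character vector, or a path to a (optionally gzipped) FASTA file.
as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  abort("cannot interpret input as DNA sequences", class = "karyomer_input_error")
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer", name),
          class = "karyomer_parameter_error")
  }
  as.integer(x)
}

# Deterministic chromosome palette: q arm at full chroma/darker luminance,
# p arm lighter.  Pure arithmetic in HCL space, so byte-stable across runs.
chromosome_palette <- function(chroms) {
  n <- length(chroms)
  hues <- seq(15, 375, length.out = n + 1)[seq_len(n)]
  q <- grDevices::hcl(h = hues, c = 90, l = 55)
  p <- grDevices::hcl(h = hues, c = 55, l = 78)
  tibble(chromosome = chroms, p = p, q = q)
}

COLOR_TELOMERE <- "#1F77B4"  # blue
COLOR_CENTROMERE <- "#FF7F0E"  # orange
COLOR_AMBIGUOUS <- "#BEBEBE"  # gray
COLOR_BLANK <- "#FFFFFF"  # novel / gap
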