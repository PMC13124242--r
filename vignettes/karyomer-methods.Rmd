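---
title: "Methods: k-mer karyograms, completeness classification, and read-pair phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer karyograms, completeness classification, and read-pair phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyomer)
```

## The problem

Chromosome-level genome assemblies need structural validation: does each
scaffold correspond to a whole chromosome, is it oriented and placed
correctly, and where do telomeres and centromeres fall?  karyomer answers
these questions without alignment, by exact k-mer membership against a
feature database built from an annotated reference, and complements them
with assembly contiguity statistics and two simple haplotype-phasing
procedures for paired-end short reads mapped to a diploid assembly.

## The k-mer feature database

Every k-mer (default k = 31, capped at 31 so a k-mer packs into one 64-bit
2-bit code) of the annotated portions of a reference is associated with one
of F features: a single global telomere feature, a single global centromere
feature, and one feature per annotated chromosome arm.  For a human-like
reference with 24 chromosomes this gives 50 features (2 global + 48 arms).

Three decisions here were genuinely open and are this package's choices:

* **Canonicalization.** Keys are the lexicographic minimum of a k-mer and
  its reverse complement, so reverse-complemented contigs are still
  annotated.  Each key carries a strand tag (forward / reverse / mixed
  relative to the canonical form) recording how its reference occurrences
  were oriented; without this tag, orientation calls for single-arm contigs
  would be impossible.  Odd k guarantees no k-mer is its own reverse
  complement.
* **Boundary attribution.** A k-mer window overlapping annotation intervals
  of several classes at one locus is resolved by precedence telomere >
  centromere > arm.  A k-mer whose occurrences resolve to two or more
  distinct features is stored as ambiguous — this is exactly the "present
  in multiple features" case that renders gray in the karyogram.
* **Unannotated sequence** is excluded from the database (it reads back as
  novel), with a warning giving the uncovered fraction.

Membership is exact: the store is a sorted key array with parallel payload
arrays, binary-searched at query time.  Serialization (magic string,
version, k, feature table, arrays, all little-endian) is deterministic, so
rewriting a database is byte-identical.

## Karyograms

`annotate_sequence()` classifies every k-mer window of a contig as a
feature, ambiguous, novel (absent — a sequence difference relative to the
reference), or gap (window contains a non-ACGT base).  `bin_majority()`
collapses calls into pixels of 250 kbp (default) by majority rule; exact
ties — rare, but they happen on short final pixels — resolve by precedence
telomere > centromere > arm (lowest feature id) > ambiguous > novel > gap,
keeping rendering deterministic.  Colors: telomere blue, centromere
orange, arms a fixed 24-hue chromosome palette with p arms lighter than q
arms, ambiguous gray, novel/gap white.

Contig placement is three independent decisions:

* **Assignment**: the chromosome maximizing p + q arm call counts;
  telomere, centromere, ambiguous, novel and gap calls are uninformative
  (the first two are global features).  A contig is unplaced when the
  winning fraction of informative calls is below 0.5 (configurable).
* **Orientation**: strand-vote majority first; when votes tie (e.g. a
  contig of entirely mixed-strand k-mers), the expected p → centromere → q
  progression breaks the tie; any remainder defaults to `+`.
* **Ordering**: within a chromosome, contigs sort by the mean expected
  rank of their calls along the idealized progression (p-adjacent telomere
  0, p arm 1, centromere 2, q arm 3, q-adjacent telomere 4), then by
  decreasing length; unplaced contigs go last by decreasing length.

`render_karyogram()` draws one vertical rectangle per sequence, omitting
sequences under 1 Mbp (rendering filter only — classification and
placement always see every contig), and is a pure function of its inputs:
the same tracks and options give byte-identical SVG.

## Structural completeness

Each contig falls into exactly one of five categories by a first-match
cascade: **complete chromosome** (both termini telomeric), **complete
arm** (one terminus telomeric and either a centromeric opposite flank or a
p–centromere–q span missing only one telomere), **centromere** (≥ 90% of
non-gap calls centromeric), **partial arm** (arm-specific, exactly one
flank telomeric or centromeric), **marker** (arm-specific, no flanking
telomere or centromere).

The underlying definitions do not come with thresholds, so these defaults
are declared, configurable choices: a terminal window of min(10 kbp, 5% of
contig length); a terminus counts as telomeric (flank as centromeric) when
at least half its non-gap calls are such; centromere "presence" requires
at least 50 kbp of centromere calls; a fragment between the pure-centromere
threshold and a flanking arm classifies as partial arm rather than
centromere.  Gap calls from scaffold N-runs are neutral — excluded from
every denominator — so gaps never break a classification.

## Contiguity

NG(x) is the maximum length L such that sequences of length ≥ L jointly
cover at least x% of the expected genome size G; LG(x) is the number of
sequences used.  When the assembly total falls short of x% of G the value
is undefined and reported as 0 with a flag.  auN = ΣL²/ΣL is the exact
area under the Nx step curve and is independent of G.  These are
closed-form scans over the sorted lengths; the tests compare them against
brute-force candidate enumeration and step-function integration
(tolerance 1e-9).

## Read-pair phasing

Given paired-end reads aligned separately to each haplotype of a diploid
assembly, the summed alignment score (AS tag of mate 1 + mate 2) per
haplotype drives a five-group assignment, evaluated in order: not properly
mapped on either haplotype; sex chromosome (any mate on chrX/chrY in
either haplotype — checked against all available alignments, not only the
proper ones); properly mapped to only one haplotype → that haplotype;
equal summed scores → homozygous; otherwise the higher-scoring haplotype.
Only primary alignments contribute; a mapped record without an AS tag is
treated conservatively as unaligned.  The phased fraction is
(hap1 + hap2) / total.

The MAPQ-based alternative aligns pairs to the concatenated diploid
assembly and phases a pair only when both mates map to one haplotype's
references with MAPQ ≥ 10; everything else is unphased.  Haplotype
attribution of reference names uses a configurable prefix convention
(default `hap1_`/`hap2_`).

For validation, pairs assigned to a haplotype with scores on both
haplotypes contribute their assigned-haplotype score to a concordant
sample and their other-haplotype score to a discordant sample (pairs
properly mapped to only one haplotype have no discordant score and are
excluded).  Each sample gets a two-parameter exponential fit — location at
the sample minimum and scale = mean − minimum, the closed-form maximum
likelihood estimates — and the samples are compared with a two-sample
Kolmogorov–Smirnov test using the asymptotic Kolmogorov distribution at
effective sample size n1·n2/(n1+n2).

## The synthetic data generator

`make_reference()` emulates the structure the methods rely on: telomeric
repeat arrays at both termini (`CCCTAA` units entering the p side,
`TTAGGG` leaving the q side), chromosome-unique random arms, and a
centromeric satellite array built from one monomer shared across
chromosomes, each copy independently mutated at 2% so arrays diverge while
remaining a single global centromere feature.  Optional extras: shared
segmental duplications between two arms (the canonical source of
ambiguous k-mers), acrocentric chromosomes with degenerate p arms, and sex
chromosome names.  Default dimensions — arms of 20–40 kbp, ~4.2 kbp
telomere arrays, ~55 kbp centromere arrays — are scaled-down but keep the
proportions the classifier's default thresholds assume (telomeres larger
than half a terminal window; centromeres above the 50 kbp presence
threshold), which is what makes the truth-label agreement suite a fair
test of the classifier rather than of retuned thresholds.

`derive_assembly()` applies structural events (identity, telomere drops,
extractions, splits, reverse complement, fusions) whose truth
completeness labels follow from the annotation each slice retains;
`preset_assembly_suite()` instantiates all five categories.
`make_diploid()` places substitution-only heterozygous SNVs uniformly over
arm regions (indels would change alignment-score arithmetic and are out of
scope); `simulate_pairs()` samples pairs uniformly from a uniformly chosen
haplotype; `score_pairs()` scores each mate against both haplotypes at the
truth locus (match +1, mismatch −4, so one overlapped heterozygous site
shifts the summed score by exactly 5) and can emit minimally valid
name-grouped SAM so the SAM ingestion path is exercised end to end.
Everything is a pure function of (spec, seed).

What the generator does **not** emulate: realistic error profiles, indels
and structural variants beyond the five-category events, repeat families
other than the two satellite classes, mapping ambiguity from genome-wide
repeats, and GC/coverage biases.  Passing tests therefore demonstrate the
correctness of the algorithms under their stated assumptions, not
performance on real sequencing data.

## Problem sizes and numerics

The test and acceptance suites run at deliberately small scale: toy
genomes of 2–24 chromosomes (10 kbp–3.5 Mbp total), read sets of a few
hundred to 10,000 pairs, and 1,000-fold randomized oracle comparisons for
the contiguity statistics.  These sizes exercise every code path
(including the compiled k-mer core) while keeping the whole suite fast.
Degenerate inputs are defined, not errors: sequences shorter than k yield
empty tracks, an empty call track classifies as `undefined`, an
insufficient assembly flags NG50 as undefined, and identical
concordant/discordant samples give KS D = 0.
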