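#' NGx and LGx curves against an expected genome size
#'
#' `NG(x)` is the maximum sequence length L such that all sequences of
#' length L or longer together cover at least x% of the expected genome
#' size G; `LG(x)` is the number of sequences needed to reach that
#' threshold.  When the summed assembly length falls short of x% of G the
#' value is undefined and reported as 0 with `defined = FALSE`.
#'
#' @param lengths Positive sequence lengths (bp).
#' @param genome_size Expected genome size G in bp (> 0).
#' @param x Percentages at which to evaluate the curves (default 0:100).
#' @return A tibble with columns `x`, `ng`, `lg`, `defined`.
#' @examples
#' ngx_curve(c(50, 40, 30, 20), genome_size = 100, x = 50)
#' @export
ngx_curve <- function(lengths, genome_size, x = 0:100) {
  check_lengths(lengths)
  if (!is.numeric(genome_size) || length(genome_size) != 1 || genome_size <= 0) {
    abort("`genome_size` must be a single positive number",
          class = "karyomer_parameter_error")
  }
  lens <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(lens)
  need <- x / 100 * genome_size
  # index of the first sequence at which the cumulative sum reaches the
  # target (NG(0) is met by the largest sequence alone); csum is strictly
  # increasing so this is 1 + |{csum < need}|
  i <- findInterval(need, csum, left.open = TRUE) + 1L
  defined <- i <= length(csum) | x == 0
  i <- pmax(1L, i)
  tibble(
    x = as.numeric(x),
    ng = if_else(defined, lens[pmin(i, length(lens))], 0),
    lg = as.integer(if_else(defined, pmin(i, length(lens)), length(lens))),
    defined = defined
  )
}

check_lengths <- function(lengths) {
  if (length(lengths) == 0 || !is.numeric(lengths) || any(lengths <= 0) ||
      anyNA(lengths)) {
    abort("`lengths` must be a non-empty vector of positive sizes",
          class = "karyomer_parameter_error")
  }
  invisible(lengths)
}

#' @rdname ngx_curve
#' @export
ng50 <- function(lengths, genome_size) {
  ngx_curve(lengths, genome_size, x = 50)$ng
}

#' @rdname ngx_curve
#' @export
lg50 <- function(lengths, genome_size) {
  ngx_curve(lengths, genome_size, x = 50)$lg
}

#' Area under the Nx curve
#'
#' `auN = sum(L^2) / sum(L)`, the continuous area under the Nx
#' step curve.  Unlike NG50 it does not depend on an expected genome size.
#'
#' @param lengths Positive sequence lengths (bp).
#' @return auN in bp.
#' @examples
#' aun(c(50, 40, 30, 20))  # 5400 / 140
#' @export
aun <- function(lengths) {
  check_lengths(lengths)
  sum(as.numeric(lengths)^2) / sum(as.numeric(lengths))
}

#' Contiguity statistics for an assembly
#'
#' Bundles the NGx/LGx curves, NG50, LG50, auN, and total size of a set of
#' sequence lengths against an expected genome size.
#'
#' @param lengths Positive sequence lengths in bp, or a `DNAStringSet` /
#'   FASTA path whose widths are used.
#' @param genome_size Expected genome size G in bp.
#' @return A `contiguity_stats` object with [tidy()] (the curves),
#'   [glance()] (the scalar summaries), and [autoplot()] methods.
#' @export
contiguity_stats <- function(lengths, genome_size) {
  if (!is.numeric(lengths)) lengths <- Biostrings::width(as_dna_set(lengths))
  check_lengths(lengths)
  curve <- ngx_curve(lengths, genome_size)
  at50 <- curve[curve$x == 50, ]
  structure(
    list(lengths = sort(as.numeric(lengths), decreasing = TRUE),
         genome_size = genome_size,
         ng50 = at50$ng, lg50 = at50$lg,
         ng50_defined = at50$defined,
         aun = aun(lengths), total_bp = sum(as.numeric(lengths)),
         curve = curve),
    class = "contiguity_stats"
  )
}

#' @export
print.contiguity_stats <- function(x, ...) {
  cat(sprintf(
    "<contiguity_stats> %d sequences, %.0f bp total (G = %.0f)\n  NG50 = %.0f%s, LG50 = %d, auN = %.1f\n",
    length(x$lengths), x$total_bp, x$genome_size,
    x$ng50, if (x$ng50_defined) "" else " (undefined: total < 50% of G)",
    x$lg50, x$aun))
  invisible(x)
}

#' @export
tidy.contiguity_stats <- function(x, ...) x$curve

#' @export
glance.contiguity_stats <- function(x, ...) {
  tibble(n_seqs = length(x$lengths), total_bp = x$total_bp,
         genome_size = x$genome_size, ng50 = x$ng50, lg50 = x$lg50,
         ng50_defined = x$ng50_defined, aun = x$aun)
}

#' @export
autoplot.contiguity_stats <- function(object, ...) {
  df <- object$curve |> filter(.data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ng)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = 50, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "x (% of expected genome size)", y = "NG(x) (bp)",
                  subtitle = sprintf("NG50 = %.0f, LG50 = %d, auN = %.1f",
                                     object$ng50, object$lg50, object$aun)) +
    ggplot2::theme_minimal()
}
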