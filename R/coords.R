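#' TSS-relative coordinate arithmetic
#'
#' All promoter coordinates in this package live on a "no-zero" axis
#' anchored at the transcription start site (TSS): the TSS base is +1, the
#' base immediately upstream is -1, and there is no position 0. This is the
#' convention in which promoter elements are conventionally labelled
#' (-35, -12, -7, +1).
#'
#' `rel_to_abs()` maps a TSS-relative coordinate to an absolute 1-based
#' genome position, taking strand into account: on the minus strand the
#' upstream direction runs towards larger absolute coordinates.
#'
#' `count_gap()` counts the integer positions strictly between two axis
#' coordinates, skipping 0 -- the quantity used for spacer and
#' discriminator lengths.
#'
#' @param position 1-based absolute genome position of the TSS (+1 base).
#' @param strand `"+"` or `"-"`.
#' @param rel integer vector of TSS-relative coordinates (nonzero).
#' @return `rel_to_abs()`: integer vector of absolute positions.
#' @examples
#' rel_to_abs(100, "+", c(-2, -1, 1, 2))  # 98 99 100 101
#' rel_to_abs(100, "-", c(-2, -1, 1, 2))  # 102 101 100 99
#' count_gap(-30, -12)  # 17, the canonical sigma-70 spacer
#' count_gap(-7, 1)     # 6, the canonical discriminator
#' @export
rel_to_abs <- function(position, strand, rel) {
  stopifnot(length(strand) == 1L, strand %in% c("+", "-"))
  if (any(rel == 0L)) stop("TSS-relative coordinates have no position 0")
  step <- ifelse(rel > 0L, rel - 1L, rel)
  if (strand == "+") position + step else position - step
}

#' @rdname rel_to_abs
#' @param a,b axis coordinates with `a < b`, both nonzero.
#' @return `count_gap()`: number of nonzero integers strictly between
#'   `a` and `b`.
#' @export
count_gap <- function(a, b) {
  stopifnot(a != 0L, b != 0L)
  if (a >= b) stop("count_gap() requires a < b")
  n <- b - a - 1L
  if (a < 0L && b > 0L) n <- n - 1L  # the axis skips 0
  as.integer(n)
}

# number of integer axis positions in [from, to] (both nonzero)
axis_span_length <- function(from, to) {
  stopifnot(from != 0L, to != 0L, from <= to)
  n <- to - from + 1L
  if (from < 0L && to > 0L) n <- n - 1L
  as.integer(n)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors (alphabet A, C, G, T, N).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

DNA_BASES <- c("A", "C", "G", "T")
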