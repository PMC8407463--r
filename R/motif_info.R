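# Information-theoretic motif machinery: per-column information content
# with the small-sample correction e(n) = 3 / (2 ln2 n) bits, total
# alignment information Rsequence, logo height matrices, and a second,
# independent motif finder that maximizes alignment information by
# coordinate ascent with one site per window.

.e_n <- function(n) 3 / (2 * log(2) * n)

.shannon_bits <- function(f) {
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Corrected information content of one alignment column
#'
#' Computes `2 - H(counts/n) - e(n)` bits, where `H` is the Shannon
#' entropy of the observed base frequencies and `e(n) = 3 / (2 ln2 n)` is
#' the small-sample correction that zeroes the expected information of a
#' random column. The corrected value can be negative for near-uniform
#' small-n columns.
#'
#' @param counts integer 4-vector of base counts (A, C, G, T).
#' @param n number of aligned sequences; `sum(counts)` must equal `n`.
#' @return information content in bits (at most 2).
#' @export
column_information <- function(counts, n) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  if (n < 1L) stop("column_information: n must be >= 1")
  if (sum(counts) != n) stop("column counts must sum to n")
  2 - .shannon_bits(counts / n) - .e_n(n)
}

#' Information content of a site alignment
#'
#' @param sites character vector of equal-width A/C/G/T strings.
#' @return `alignment_info` object: `counts` (w x 4), `n`, `w`, `ic_col`
#'   (per-column corrected bits), `r_seq` (their sum), `e_n`.
#' @export
alignment_information <- function(sites) {
  if (!length(sites)) stop("alignment_information: no sites")
  w <- nchar(sites[1L])
  if (any(nchar(sites) != w)) stop("sites differ in width")
  X <- .encode_seqs(sites)
  n <- length(sites)
  counts <- t(apply(X, 2L, tabulate, nbins = 4L))
  if (w == 1L) counts <- matrix(tabulate(X, 4L), nrow = 1L)
  colnames(counts) <- DNA_BASES
  ic <- apply(counts, 1L, column_information, n = n)
  structure(list(counts = counts, n = n, w = w, ic_col = ic,
                 r_seq = sum(ic), e_n = .e_n(n)),
            class = "alignment_info")
}

#' @export
print.alignment_info <- function(x, ...) {
  cat("alignment_info: ", x$n, " sites, width ", x$w,
      ", Rsequence = ", round(x$r_seq, 3), " bits\n", sep = "")
  invisible(x)
}

# Rsequence straight from a counts matrix (internal fast path)
.r_seq_counts <- function(counts, n) {
  f <- counts / n
  h <- apply(f, 1L, .shannon_bits)
  sum(2 - h - .e_n(n))
}

#' Discover a motif by information-content maximization
#'
#' A one-occurrence-per-sequence aligner: every window contributes exactly
#' one w-mer site. From each common-offset initialization in turn (all
#' sites at offset o), coordinate ascent repeatedly re-places each
#' window's site at the offset maximizing the corrected total information
#' of the full alignment, sweeping until no site moves (or `max_sweeps`);
#' the best converged alignment across the starts is returned. Ties go to
#' the leftmost (most-upstream) offset; Rsequence never decreases across
#' sweeps within a start.
#'
#' @inheritParams zoops_em
#' @param max_sweeps maximum coordinate-ascent sweeps (default 100).
#' @return list: `alignment` ([alignment_information()] of the final
#'   sites), `offsets` (1-based per window), `occurrences` (data.frame
#'   `tss_id`, `rel_start`, `site_seq`), `model` (a `motif_model`-shaped
#'   frequency summary usable by [anchor_ta()]), `sweeps`, `converged`.
#' @export
info_maximize <- function(windows, w, max_sweeps = 100L) {
  win <- .as_window_df(windows)
  if (!nrow(win)) stop("info_maximize: no windows")
  short <- which(nchar(win$seq) < w)
  if (length(short)) {
    stop("window ", win$tss_id[short[1L]], " is shorter than motif width ", w)
  }
  n <- nrow(win)
  lens <- nchar(win$seq)
  n_off <- lens - w + 1L
  # site base indices per window per offset: list of (n_off x w) matrices
  enc <- lapply(seq_len(n), function(i) {
    X <- .encode_seqs(win$seq[i])
    t(vapply(seq_len(n_off[i]), function(o) X[1L, o:(o + w - 1L)],
             integer(w)))
  })

  count_of <- function(i, o) {
    m <- matrix(0L, nrow = w, ncol = 4L)
    m[cbind(seq_len(w), enc[[i]][o, ])] <- 1L
    m
  }

  ascend <- function(offsets) {
    counts <- Reduce(`+`, lapply(seq_len(n),
                                 function(i) count_of(i, offsets[i])))
    r_cur <- .r_seq_counts(counts, n)
    sweeps <- 0L; converged <- FALSE
    while (sweeps < max_sweeps) {
      sweeps <- sweeps + 1L
      moved <- FALSE
      for (i in seq_len(n)) {
        base_counts <- counts - count_of(i, offsets[i])
        cand_r <- vapply(seq_len(n_off[i]), function(o) {
          .r_seq_counts(base_counts + count_of(i, o), n)
        }, numeric(1))
        o_new <- which(cand_r >= max(cand_r) - 1e-12)[1L]  # leftmost argmax
        accept <- cand_r[o_new] > r_cur + 1e-12 ||
          (abs(cand_r[o_new] - r_cur) <= 1e-12 && o_new < offsets[i])
        if (accept && o_new != offsets[i]) {
          counts <- base_counts + count_of(i, o_new)
          offsets[i] <- o_new
          r_cur <- cand_r[o_new]
          moved <- TRUE
        }
      }
      if (!moved) { converged <- TRUE; break }
    }
    list(offsets = offsets, r = r_cur, sweeps = sweeps,
         converged = converged)
  }

  # multi-start: one ascent from every common-offset initialization
  best <- NULL
  for (o in seq_len(min(n_off))) {
    run <- ascend(rep(o, n))
    if (is.null(best) || run$r > best$r + 1e-12) best <- run
  }
  offsets <- best$offsets
  sweeps <- best$sweeps
  converged <- best$converged

  sites <- substring(win$seq, offsets, offsets + w - 1L)
  aln <- alignment_information(sites)
  occurrences <- data.frame(tss_id = win$tss_id,
                            rel_start = win$rel_start + offsets - 1L,
                            site_seq = sites, stringsAsFactors = FALSE)
  freq <- (aln$counts + 0.25) / (aln$n + 1)
  model <- structure(list(w = w, p = freq, lambda = 1,
                          background = estimate_background(win),
                          loglik = NA_real_, llr = NA_real_,
                          objective = aln$r_seq, n_sites = n,
                          n_windows = n),
                     class = "motif_model")
  list(alignment = aln, offsets = offsets, occurrences = occurrences,
       model = model, sweeps = sweeps, converged = converged)
}

#' Exhaustive information-maximal alignment (testing oracle)
#'
#' Enumerates every offset vector and returns the alignment with maximal
#' Rsequence (lexicographically first offset vector on ties). Refuses
#' search spaces above `10^6` combinations; intended as a brute-force
#' oracle for [info_maximize()] on tiny instances.
#'
#' @inheritParams info_maximize
#' @return list: `offsets`, `r_seq`, `alignment`.
#' @export
brute_force_align <- function(windows, w) {
  win <- .as_window_df(windows)
  n_off <- nchar(win$seq) - w + 1L
  if (any(n_off < 1L)) stop("window shorter than motif width ", w)
  if (prod(n_off) > 1e6) {
    stop("brute_force_align: search space exceeds 10^6 offset vectors")
  }
  grid <- expand.grid(lapply(n_off, seq_len), KEEP.OUT.ATTRS = FALSE)
  best_r <- -Inf; best_off <- NULL
  for (k in seq_len(nrow(grid))) {
    off <- as.integer(grid[k, ])
    sites <- substring(win$seq, off, off + w - 1L)
    r <- alignment_information(sites)$r_seq
    if (r > best_r + 1e-12) { best_r <- r; best_off <- off }
  }
  sites <- substring(win$seq, best_off, best_off + w - 1L)
  list(offsets = best_off, r_seq = best_r,
       alignment = alignment_information(sites))
}

#' Sequence-logo height matrix
#'
#' Letter heights in bits: height of base b in column j is the observed
#' frequency of b times the column's corrected information content,
#' floored at 0 (columns with negative corrected information draw no
#' letters).
#'
#' @param alignment an [alignment_information()] result.
#' @return `w x 4` numeric matrix of heights (columns A, C, G, T).
#' @export
logo_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_info"))
  f <- alignment$counts / alignment$n
  h <- f * alignment$ic_col
  h[h < 0] <- 0
  colnames(h) <- DNA_BASES
  h
}

#' Write a logo matrix as TSV
#'
#' @param alignment an [alignment_information()] result.
#' @param path output path; columns `position`, `A`, `C`, `G`, `T`
#'   (heights in bits).
#' @param rel_start optional TSS-relative coordinate of column 1, used to
#'   label positions; defaults to 1-based column indices.
#' @export
write_logo_tsv <- function(alignment, path, rel_start = NULL) {
  h <- logo_matrix(alignment)
  pos <- if (is.null(rel_start)) seq_len(nrow(h)) else {
    p <- rel_start + seq_len(nrow(h)) - 1L
    p[p >= 0 & rel_start < 0] <- p[p >= 0 & rel_start < 0] + 1L
    p
  }
  utils::write.table(data.frame(position = pos, h, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
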