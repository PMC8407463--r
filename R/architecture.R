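# Promoter architecture: register predicted -10 elements on their
# conserved TA dinucleotide (nominally -12/-11), read the base at -7,
# classify promoters (-7T vs -7A/C/G), locate -35 elements, and compute
# spacer / discriminator lengths and cross-method agreement.

#' TA anchor columns of a motif model
#'
#' Finds the adjacent column pair `(j, j+1)` maximizing
#' `p(T at j) + p(A at j+1)` (leftmost on ties) -- the model-level TA
#' dinucleotide that registers a -10 element on the TSS-relative axis.
#'
#' @param model a `motif_model`.
#' @return integer: 1-based column index of the anchor T.
#' @export
ta_anchor_column <- function(model) {
  p <- model$p
  w <- model$w
  if (w < 2L) stop("TA anchoring needs motif width >= 2")
  score <- p[seq_len(w - 1L), "T"] + p[seq_len(w - 1L) + 1L, "A"]
  which.max(score)  # which.max is leftmost on exact ties
}

#' Anchor occurrences on the TA dinucleotide and read the -7 base
#'
#' For each motif occurrence, the anchor T of the model's TA column pair
#' is mapped onto the TSS-relative axis (`ta_anchor`; nominally -12) and
#' the base five positions downstream (`ta_anchor + 5`; nominally -7) is
#' read from the occurrence's source window -- extending past the
#' occurrence into the window if needed. Occurrences whose -7 position
#' falls outside the window are dropped with a warning and reported in the
#' `"dropped"` attribute.
#'
#' @param model the `motif_model` the occurrences were called under.
#' @param occurrences occurrence data.frame ([call_occurrences()] or
#'   `info_maximize()$occurrences`).
#' @param windows the window data.frame the occurrences came from.
#' @return data.frame: `tss_id`, `rel_start`, `ta_anchor`, `minus7_base`,
#'   `minus7_class` (`"T"` or `"ACG"`); attribute `"dropped"` lists
#'   anchoring failures.
#' @export
anchor_ta <- function(model, occurrences, windows) {
  win <- .as_window_df(windows)
  j <- ta_anchor_column(model)
  m <- match(occurrences$tss_id, win$tss_id)
  if (anyNA(m)) stop("occurrences and windows are not aligned by tss_id")
  ta <- occurrences$rel_start + (j - 1L)          # all-upstream axis: no 0 skip
  minus7 <- ta + 5L
  wstart <- win$rel_start[m]
  wend <- win$rel_start[m] + nchar(win$seq[m]) - 1L
  ok <- minus7 < 0L & minus7 >= wstart & minus7 <= wend
  if (any(!ok)) {
    warning(sum(!ok), " occurrence(s) dropped: anchored -7 position ",
            "outside the window", call. = FALSE)
  }
  base7 <- substr(win$seq[m], minus7 - wstart + 1L, minus7 - wstart + 1L)
  out <- data.frame(tss_id = occurrences$tss_id,
                    rel_start = occurrences$rel_start,
                    ta_anchor = ta,
                    minus7_base = base7,
                    minus7_class = ifelse(base7 == "T", "T", "ACG"),
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    tss_id = occurrences$tss_id[!ok],
    reason = if (any(!ok)) "anchor_fail" else character())
  out
}

#' Call -10 promoter elements for a TSS set
#'
#' Convenience wrapper joining motif discovery output into per-TSS
#' promoter calls: anchors every called occurrence on the TA dinucleotide,
#' classifies the -7 base, and attaches the downstream gene id.
#'
#' @param fit result of [discover_motif()] (ZOOPS) or [info_maximize()].
#' @param windows the window data.frame the finder ran on.
#' @param tss TSS table (for `gene_id`).
#' @param threshold occurrence-posterior threshold for the ZOOPS finder
#'   (ignored for information-finder fits, which place one site per
#'   window).
#' @return promoter-call data.frame: `tss_id`, `gene_id`, `minus10_start`,
#'   `minus10_end`, `ta_anchor`, `minus7_base`, `minus7_class`; attribute
#'   `"dropped"` aggregates no-occurrence and anchoring drops.
#' @export
classify_promoters <- function(fit, windows, tss, threshold = 0.5) {
  occ <- if (!is.null(fit$assignments)) {
    call_occurrences(fit$model, fit$assignments, threshold)
  } else {
    fit$occurrences
  }
  win <- .as_window_df(windows)
  no_occ <- setdiff(win$tss_id, occ$tss_id)
  anchored <- anchor_ta(fit$model, occ, win)
  w <- fit$model$w
  m <- match(anchored$tss_id, tss$tss_id)
  calls <- data.frame(tss_id = anchored$tss_id,
                      gene_id = tss$gene_id[m],
                      minus10_start = anchored$rel_start,
                      minus10_end = anchored$rel_start + w - 1L,
                      ta_anchor = anchored$ta_anchor,
                      minus7_base = anchored$minus7_base,
                      minus7_class = anchored$minus7_class,
                      stringsAsFactors = FALSE)
  drops <- rbind(
    data.frame(tss_id = no_occ,
               reason = rep("no_occurrence", length(no_occ))),
    attr(anchored, "dropped"))
  attr(calls, "dropped") <- drops
  calls
}

#' Search for -35 elements upstream of called -10 elements
#'
#' Runs a motif finder over windows (default -40..-28) of exactly those
#' TSSs that already carry a -10 call -- the -35 search is conditioned on
#' a found -10. Returns per-TSS -35 occurrences.
#'
#' @param genome a [genome_set()].
#' @param tss TSS table.
#' @param calls promoter calls from [classify_promoters()].
#' @param rel_from,rel_to search window (default -40..-28).
#' @param finder `"zoops"` or `"info"`.
#' @param widths widths searched; default 6, the -35 element's hexamer
#'   width, so that the occurrence start coincides with the hexamer start
#'   that canonical spacer arithmetic assumes (see the package vignette).
#' @param threshold ZOOPS calling threshold.
#' @param n_seeds ZOOPS seeds per width.
#' @return data.frame `tss_id`, `minus35_start`, `minus35_end`,
#'   `site_seq`; plus attribute `"model"` (the fitted -35 motif).
#' @export
find_minus35 <- function(genome, tss, calls, rel_from = -40L, rel_to = -28L,
                         finder = c("zoops", "info"), widths = 6L,
                         threshold = 0.5, n_seeds = 50L) {
  finder <- match.arg(finder)
  sub <- tss[tss$tss_id %in% calls$tss_id, , drop = FALSE]
  win <- suppressWarnings(extract_windows(genome, sub, rel_from, rel_to))
  if (!nrow(win)) stop("no -35 search windows could be extracted")
  if (finder == "zoops") {
    fit <- discover_motif(win, widths = widths, n_seeds = n_seeds)
    occ <- call_occurrences(fit$model, fit$assignments, threshold)
    w <- fit$model$w
    model <- fit$model
  } else {
    fit <- info_maximize(win, w = widths[1L])
    occ <- fit$occurrences
    w <- widths[1L]
    model <- fit$model
  }
  out <- data.frame(tss_id = occ$tss_id,
                    minus35_start = occ$rel_start,
                    minus35_end = occ$rel_start + w - 1L,
                    site_seq = occ$site_seq, stringsAsFactors = FALSE)
  attr(out, "model") <- model
  out
}

#' Spacer and discriminator lengths of one promoter
#'
#' On the no-zero TSS-relative axis: the spacer is the number of positions
#' strictly between the -35 element's 3' end and the -10 element's 5'
#' start; the discriminator is the number of positions strictly between
#' the -10 element's 3' end and the TSS at +1. The canonical E. coli
#' promoter (-35 at -35..-30, -10 at -12..-7) has spacer 17 and
#' discriminator 6.
#'
#' @param minus10_span integer 2-vector `(start, end)` of the -10 element.
#' @param minus35_span optional `(start, end)` of the -35 element; when
#'   `NULL` only the discriminator is computed.
#' @return list `spacer` (NA without a -35) and `discriminator`.
#' @examples
#' element_distances(c(-12, -7), c(-35, -30))  # spacer 17, discriminator 6
#' @export
element_distances <- function(minus10_span, minus35_span = NULL) {
  stopifnot(length(minus10_span) == 2L, minus10_span[1] <= minus10_span[2],
            minus10_span[2] < 0L)
  disc <- count_gap(minus10_span[2], 1L)
  spacer <- NA_integer_
  if (!is.null(minus35_span)) {
    stopifnot(length(minus35_span) == 2L,
              minus35_span[1] <= minus35_span[2])
    if (minus35_span[2] >= minus10_span[1]) {
      stop("element spans overlap or are out of order")
    }
    spacer <- count_gap(minus35_span[2], minus10_span[1])
  }
  list(spacer = spacer, discriminator = disc)
}

#' Add spacer/discriminator columns to promoter calls
#'
#' In `"canonical"` mode (the default, used for all reported distance
#' statistics) the -10 element is taken as the canonical hexamer
#' `(ta_anchor, ta_anchor + 5)` and the -35 as the 6-base span from its
#' occurrence start; `"occurrence"` mode uses the full motif occurrence
#' spans instead.
#'
#' @param calls promoter calls ([classify_promoters()]).
#' @param minus35 optional -35 table ([find_minus35()]); merged by
#'   `tss_id`.
#' @param mode `"canonical"` or `"occurrence"`.
#' @return `calls` with columns `minus35_start`, `minus35_end`, `spacer`,
#'   `discriminator` added.
#' @export
add_distances <- function(calls, minus35 = NULL,
                          mode = c("canonical", "occurrence")) {
  mode <- match.arg(mode)
  if (!is.null(minus35)) {
    m <- match(calls$tss_id, minus35$tss_id)
    calls$minus35_start <- minus35$minus35_start[m]
    calls$minus35_end <- minus35$minus35_end[m]
  } else {
    calls$minus35_start <- NA_integer_
    calls$minus35_end <- NA_integer_
  }
  span10 <- if (mode == "canonical") {
    cbind(calls$ta_anchor, calls$ta_anchor + 5L)
  } else {
    cbind(calls$minus10_start, calls$minus10_end)
  }
  span35 <- if (mode == "canonical") {
    cbind(calls$minus35_start, calls$minus35_start + 5L)
  } else {
    cbind(calls$minus35_start, calls$minus35_end)
  }
  calls$spacer <- NA_integer_
  calls$discriminator <- NA_integer_
  for (i in seq_len(nrow(calls))) {
    s35 <- if (is.na(span35[i, 1L])) NULL else span35[i, ]
    ok <- !is.null(s35) && s35[2L] < span10[i, 1L]
    d <- element_distances(span10[i, ], if (ok) s35 else NULL)
    calls$spacer[i] <- d$spacer
    calls$discriminator[i] <- d$discriminator
  }
  calls
}

#' Summarise promoter architecture over a call set
#'
#' @param calls deduplicated promoter calls, optionally carrying
#'   `spacer` / `discriminator` columns ([add_distances()]).
#' @return `architecture_summary` list: `n_calls`, `minus7_fractions`
#'   (named A/C/G/T, summing to 1), `spacer_hist`, `discriminator_hist`
#'   (named count tables), `spacer_mode`, `discriminator_mode` (smallest
#'   length on tied counts).
#' @export
summarize_calls <- function(calls) {
  if (!nrow(calls)) stop("summarize_calls: empty call list")
  frac <- vapply(DNA_BASES, function(b) mean(calls$minus7_base == b),
                 numeric(1))
  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    tab <- table(x)
    lens <- as.integer(names(tab))
    min(lens[tab == max(tab)])  # smallest length wins ties
  }
  hist_of <- function(x) table(x[!is.na(x)])
  structure(list(
    n_calls = nrow(calls),
    minus7_fractions = frac,
    spacer_hist = hist_of(calls$spacer),
    discriminator_hist = hist_of(calls$discriminator),
    spacer_mode = mode_of(calls$spacer),
    discriminator_mode = mode_of(calls$discriminator)
  ), class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("architecture_summary over", x$n_calls, "promoter calls\n")
  cat("  -7 base fractions:",
      paste(sprintf("%s=%.3f", names(x$minus7_fractions),
                    x$minus7_fractions), collapse = " "), "\n")
  cat("  spacer mode:", x$spacer_mode,
      "bp | discriminator mode:", x$discriminator_mode, "bp\n")
  invisible(x)
}

#' Agreement between two promoter-calling methods
#'
#' Over TSSs called by both methods, the fraction whose anchored TA
#' coordinates agree (within `tolerance`; exact equality by default).
#' Symmetric in its arguments.
#'
#' @param calls_a,calls_b promoter-call data.frames keyed by `tss_id`.
#' @param tolerance maximum |anchor difference| counted as agreement
#'   (default 0).
#' @return agreement fraction in [0, 1].
#' @export
method_agreement <- function(calls_a, calls_b, tolerance = 0L) {
  common <- intersect(calls_a$tss_id, calls_b$tss_id)
  if (!length(common)) stop("method_agreement: no TSS called by both methods")
  a <- calls_a$ta_anchor[match(common, calls_a$tss_id)]
  b <- calls_b$ta_anchor[match(common, calls_b$tss_id)]
  mean(abs(a - b) <= tolerance)
}
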