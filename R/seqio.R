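#' Read a genome FASTA into a genome set
#'
#' Reads one or more replicons from a FASTA file, uppercases the sequence,
#' maps U to T, and validates the alphabet (A, C, G, T, N only). Replicon
#' ids are taken as the first whitespace-delimited word of each header.
#'
#' @param path path to a FASTA file.
#' @return a `genome_set`: named character vector of replicon sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA parse error: no records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate replicon id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- chartr("U", "T", toupper(as.character(seqs)))
  names(x) <- ids
  genome_set(x)
}

#' Construct a genome set from named sequences
#'
#' @param replicons named character vector, one uppercase A/C/G/T/N string
#'   per replicon; every replicon must be non-empty.
#' @return a `genome_set` object.
#' @export
genome_set <- function(replicons) {
  if (length(replicons) == 0L || is.null(names(replicons)) ||
      any(!nzchar(names(replicons)))) {
    stop("genome_set needs a non-empty named character vector")
  }
  if (any(!nzchar(replicons))) {
    stop("parse error: empty replicon sequence: ",
         paste(names(replicons)[!nzchar(replicons)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", replicons)
  if (any(bad)) {
    stop("parse error: illegal character(s) outside {A,C,G,T,N} in replicon ",
         paste(names(replicons)[bad], collapse = ", "))
  }
  structure(replicons, class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set with", length(x), "replicon(s):\n")
  for (id in names(x)) cat("  ", id, ": ", nchar(x[[id]]), " bp\n", sep = "")
  invisible(x)
}

#' Read a TSS table
#'
#' Reads a tab-separated table of experimentally mapped transcription start
#' sites. Required columns: `replicon`, `position` (1-based coordinate of
#' the +1 base), `strand` (`+`/`-`), `gene_id` (downstream gene, may be
#' empty), `condition`. An optional `tss_id` column is honoured; otherwise
#' stable ids `tss_000001, ...` are assigned in file order.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `tss_id`, `replicon`, `position`,
#'   `strand`, `gene_id`, `condition`, rows in file order.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("replicon", "position", "strand", "gene_id", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("TSS table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$position))
  num <- suppressWarnings(as.numeric(df$position))
  bad <- which(is.na(pos) | pos < 1L | is.na(num) | num != pos)
  if (length(bad)) {
    stop("TSS table row ", bad[1L], ": position '", df$position[bad[1L]],
         "' is not a positive integer")
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("TSS table row ", bad[1L], ": strand '", df$strand[bad[1L]],
         "' is not '+' or '-'")
  }
  gene <- df$gene_id
  gene[!nzchar(gene)] <- NA_character_
  data.frame(
    tss_id = if ("tss_id" %in% names(df)) df$tss_id else
      sprintf("tss_%06d", seq_len(nrow(df))),
    replicon = df$replicon,
    position = pos,
    strand = df$strand,
    gene_id = gene,
    condition = df$condition,
    stringsAsFactors = FALSE
  )
}

#' Extract a strand-aware TSS-relative window
#'
#' Returns the upstream subsequence spanning TSS-relative positions
#' `rel_from..rel_to` (both negative), read 5' to 3' on the transcribed
#' strand: position -1 is always the base immediately upstream of the TSS.
#' On the minus strand this is the reverse complement of the mirrored
#' absolute interval.
#'
#' Windows that would run past a replicon edge yield `NULL` (a skip
#' signal); the vectorised [extract_windows()] logs and counts such drops.
#'
#' @param genome a [genome_set()].
#' @param tss a single-row TSS data.frame (or list) with fields `tss_id`,
#'   `replicon`, `position`, `strand`.
#' @param rel_from,rel_to TSS-relative bounds, `rel_from < rel_to < 0`.
#' @return list with `tss_id`, `seq`, `rel_start`, `rel_end`, `has_n`,
#'   or `NULL` if the window falls outside the replicon.
#' @export
extract_window <- function(genome, tss, rel_from, rel_to) {
  stopifnot(inherits(genome, "genome_set"),
            rel_from < rel_to, rel_from != 0L, rel_to != 0L, rel_to < 0L)
  idx <- match(as.character(tss$replicon), names(genome))
  if (is.na(idx)) stop("unknown replicon: ", tss$replicon)
  chrom <- genome[[idx]]
  len <- nchar(chrom)
  pos <- as.integer(tss$position)
  if (pos < 1L || pos > len) stop("TSS position outside replicon: ", tss$tss_id)
  if (tss$strand == "+") {
    lo <- pos + rel_from
    hi <- pos + rel_to
    if (lo < 1L || hi > len) return(NULL)
    s <- substr(chrom, lo, hi)
  } else {
    lo <- pos - rel_to
    hi <- pos - rel_from
    if (lo < 1L || hi > len) return(NULL)
    s <- revcomp(substr(chrom, lo, hi))
  }
  list(tss_id = tss$tss_id, seq = s,
       rel_start = as.integer(rel_from), rel_end = as.integer(rel_to),
       has_n = grepl("N", s, fixed = TRUE))
}

#' Extract windows for a whole TSS table
#'
#' Vectorised form of [extract_window()]. Windows running off a replicon
#' edge and (by default) windows containing N are dropped with a warning;
#' the dropped records are attached as attribute `"dropped"`, a data.frame
#' of `tss_id` and `reason` (`"edge"` or `"contains_n"`).
#'
#' @inheritParams extract_window
#' @param tss TSS table as returned by [read_tss_table()].
#' @param drop_n drop windows containing N (default `TRUE`).
#' @return data.frame with columns `tss_id`, `seq`, `rel_start`,
#'   `rel_end`; attribute `"dropped"` records the discarded TSSs.
#' @export
extract_windows <- function(genome, tss, rel_from, rel_to, drop_n = TRUE) {
  rows <- vector("list", nrow(tss))
  dropped <- list()
  for (i in seq_len(nrow(tss))) {
    w <- extract_window(genome, tss[i, ], rel_from, rel_to)
    if (is.null(w)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(tss_id = tss$tss_id[i], reason = "edge")
    } else if (drop_n && w$has_n) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(tss_id = tss$tss_id[i], reason = "contains_n")
    } else {
      rows[[i]] <- data.frame(tss_id = w$tss_id, seq = w$seq,
                              rel_start = w$rel_start, rel_end = w$rel_end,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(tss_id = character(), seq = character(),
                      rel_start = integer(), rel_end = integer())
  }
  drop_df <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(tss_id = character(), reason = character())
  if (nrow(drop_df)) {
    warning(nrow(drop_df), " window(s) dropped (",
            paste(sprintf("%s: %d", names(table(drop_df$reason)),
                          as.integer(table(drop_df$reason))), collapse = ", "),
            ")", call. = FALSE)
  }
  attr(out, "dropped") <- drop_df
  out
}

#' Collapse duplicated windows from closely spaced TSSs
#'
#' Among windows that share an identical sequence, lie upstream of the same
#' gene, and whose TSS positions are pairwise within `max_spacing` bp, only
#' the first in genomic position order is kept; all other windows pass
#' through unchanged. Windows without a gene id are never collapsed. The
#' operation is idempotent.
#'
#' @param windows window data.frame from [extract_windows()].
#' @param tss TSS table aligned by `tss_id` (supplies `position`, `gene_id`).
#' @param max_spacing maximum pairwise TSS distance (bp) for a duplicate
#'   group; default 5.
#' @return the deduplicated window data.frame, original row order; dropped
#'   tss ids attached as attribute `"dropped"` with reason `"duplicate"`.
#' @export
dedup_windows <- function(windows, tss, max_spacing = 5L) {
  if (!nrow(windows)) return(windows)
  m <- match(windows$tss_id, tss$tss_id)
  if (anyNA(m)) stop("windows and TSS table are not aligned by tss_id")
  pos <- tss$position[m]
  gene <- tss$gene_id[m]
  key <- paste(windows$seq, gene, sep = "\r")
  keep <- rep(TRUE, nrow(windows))
  for (grp in split(seq_len(nrow(windows))[!is.na(gene)],
                    key[!is.na(gene)])) {
    if (length(grp) < 2L) next
    ord <- grp[order(pos[grp])]
    cluster_min <- pos[ord[1L]]
    for (j in ord[-1L]) {
      if (pos[j] - cluster_min <= max_spacing) {
        keep[j] <- FALSE  # pairwise-within-spacing duplicate of cluster head
      } else {
        cluster_min <- pos[j]
      }
    }
  }
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    tss_id = windows$tss_id[!keep],
    reason = if (any(!keep)) "duplicate" else character())
  out
}

#' Read gene annotations from GFF3
#'
#' Imports gene-type features and returns their identifier (`ID` falling
#' back to `locus_tag`) and coordinates; other GFF content is ignored.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with `gene_id`, `replicon`, `start`, `end`, `strand`.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- as.character(gr$ID)
  if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    lt <- as.character(gr$locus_tag)
    id[is.na(id)] <- lt[is.na(id)]
  }
  data.frame(gene_id = id,
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
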