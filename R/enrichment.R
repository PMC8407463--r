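# Gene-set statistics for -7 promoter classes: exact hypergeometric
# over-representation tests (essentiality at adjusted P <= 0.05,
# functional terms at adjusted P <= 0.1), Benjamini-Hochberg adjustment,
# supergroup binning, and grouped expression-trend comparison against
# size-matched randomized gene sets.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' without replacement from a universe of `N` of which `K` carry the term.
#' One-sided over-representation, the direction meant by "enrichment".
#'
#' @param k observed overlap (class genes carrying the term).
#' @param K universe genes carrying the term.
#' @param n class size.
#' @param N universe size.
#' @return upper-tail probability.
#' @examples
#' hypergeom_sf(5, 5, 5, 10)   # 1 / choose(10, 5)
#' hypergeom_sf(2, 3, 4, 10)   # 1/3
#' @export
hypergeom_sf <- function(k, K, n, N) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N,
            k >= 0, k <= min(K, n))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' a validated wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of terms in a gene class
#'
#' Tests each term carried by at least one universe gene for
#' over-representation in `class_genes`, adjusting across all terms tested
#' for this class by Benjamini-Hochberg.
#'
#' @param class_genes character vector, the focal gene class (must be a
#'   subset of the universe).
#' @param universe_genes character vector, the gene universe.
#' @param term_map data.frame with columns `gene_id`, `term_id` (extra
#'   columns ignored), or a named list of term -> gene-id vectors.
#' @param alpha significance threshold on the adjusted p (default 0.1,
#'   the conventional level for functional terms; use 0.05 for
#'   essentiality).
#' @param class_label label stored with each result row.
#' @return data.frame of `enrichment_result` rows: `class_label`,
#'   `term_id`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant`.
#' @export
test_class <- function(class_genes, universe_genes, term_map,
                       alpha = 0.1, class_label = NA_character_) {
  universe_genes <- unique(universe_genes)
  if (!length(universe_genes)) stop("test_class: empty universe")
  class_genes <- unique(class_genes)
  if (!all(class_genes %in% universe_genes)) {
    stop("test_class: class genes must be a subset of the universe")
  }
  sets <- if (is.data.frame(term_map)) {
    split(term_map$gene_id, term_map$term_id)
  } else {
    term_map
  }
  sets <- lapply(sets, function(g) intersect(unique(g), universe_genes))
  sets <- sets[vapply(sets, length, integer(1)) >= 1L]
  if (!length(sets)) {
    return(data.frame(class_label = character(), term_id = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  n <- length(class_genes); N <- length(universe_genes)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(g) length(intersect(g, class_genes)),
              integer(1))
  p_raw <- mapply(hypergeom_sf, k = k, K = K,
                  MoreArgs = list(n = n, N = N))
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(class_label = class_label, term_id = names(sets),
                    k = k, K = K, n = n, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_adj, out$p_raw, out$term_id), ]
}

#' Bin enrichment results into functional supergroups
#'
#' Annotates each result with its supergroup (unmapped terms get
#' `"unassigned"`). When `term_map` is supplied, per-supergroup gene
#' counts are aggregated as the *union* of member-term gene sets (shared
#' genes counted once), optionally also within `class_genes`.
#'
#' @param results data.frame from [test_class()].
#' @param supergroup_map data.frame with columns `term_id`, `supergroup`,
#'   or a named character vector term -> supergroup.
#' @param term_map optional term -> gene mapping (as in [test_class()])
#'   for gene-count aggregation.
#' @param class_genes optional focal class for within-class union counts.
#' @return `results` with a `supergroup` column; when `term_map` is given,
#'   attribute `"supergroups"` holds a data.frame of `supergroup`,
#'   `n_terms`, `n_genes` (universe union) and `n_genes_class`.
#' @export
bin_supergroups <- function(results, supergroup_map, term_map = NULL,
                            class_genes = NULL) {
  map <- if (is.data.frame(supergroup_map)) {
    stats::setNames(supergroup_map$supergroup, supergroup_map$term_id)
  } else {
    supergroup_map
  }
  sg <- unname(map[results$term_id])
  sg[is.na(sg)] <- "unassigned"
  results$supergroup <- sg
  if (!is.null(term_map)) {
    sets <- if (is.data.frame(term_map)) {
      split(term_map$gene_id, term_map$term_id)
    } else {
      term_map
    }
    agg <- lapply(split(results$term_id, results$supergroup), function(terms) {
      genes <- unique(unlist(sets[terms], use.names = FALSE))
      data.frame(n_terms = length(terms), n_genes = length(genes),
                 n_genes_class = if (is.null(class_genes)) NA_integer_ else
                   length(intersect(genes, class_genes)))
    })
    tab <- do.call(rbind, agg)
    tab <- cbind(data.frame(supergroup = rownames(tab)), tab)
    rownames(tab) <- NULL
    attr(results, "supergroups") <- tab
  }
  results
}

#' Compare expression trends of a gene set against randomized controls
#'
#' Computes the per-timepoint mean abundance of a focal gene set and of
#' `n_controls` size-matched gene sets drawn without replacement from the
#' complement of the focal set. Fully reproducible given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   timepoints in columns.
#' @param focal_genes character vector of focal gene ids (subset of
#'   `rownames(expr)`).
#' @param n_controls number of randomized control sets (default 1000).
#' @param seed integer RNG seed for the control draws.
#' @return `trend_result` list: `group_mean` (per-timepoint focal means),
#'   `control_means` (`n_controls x timepoints` matrix), `n_controls`,
#'   `seed`, `focal_size`.
#' @export
trend_compare <- function(expr, focal_genes, n_controls = 1000L, seed = 1L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  focal_genes <- unique(focal_genes)
  if (!length(focal_genes)) stop("trend_compare: empty focal set")
  if (!all(focal_genes %in% rownames(expr))) {
    stop("trend_compare: focal genes absent from the expression matrix")
  }
  complement <- setdiff(rownames(expr), focal_genes)
  if (length(complement) < length(focal_genes)) {
    stop("trend_compare: complement smaller than the focal set")
  }
  group_mean <- colMeans(expr[focal_genes, , drop = FALSE])
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  control_means <- t(vapply(seq_len(n_controls), function(i) {
    colMeans(expr[sample(complement, length(focal_genes)), , drop = FALSE])
  }, numeric(ncol(expr))))
  structure(list(group_mean = group_mean, control_means = control_means,
                 n_controls = n_controls, seed = seed,
                 focal_size = length(focal_genes)),
            class = "trend_result")
}
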