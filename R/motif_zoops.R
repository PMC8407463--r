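# ZOOPS (zero-or-one-occurrence-per-sequence) motif discovery by
# expectation-maximization over a two-component mixture: each window either
# carries one motif site at an unknown offset (uniform positional prior) or
# is pure background. Multi-start seeding from frequent w-mers; model
# selection across seeds and widths by a BIC-penalized log-likelihood ratio.

.as_window_df <- function(windows) {
  if (is.data.frame(windows)) {
    stopifnot(all(c("tss_id", "seq") %in% names(windows)))
    if (is.null(windows$rel_start)) windows$rel_start <- NA_integer_
    return(windows)
  }
  data.frame(
    tss_id = if (!is.null(names(windows))) names(windows) else
      sprintf("w%05d", seq_along(windows)),
    seq = as.character(windows),
    rel_start = rep(NA_integer_, length(windows)),
    stringsAsFactors = FALSE
  )
}

# integer-encode equal-length sequences into an n x L matrix (A=1..T=4)
.encode_seqs <- function(seqs) {
  L <- nchar(seqs[1L])
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("windows must contain only A, C, G, T")
  m
}

.validate_pwm <- function(p, w) {
  stopifnot(is.matrix(p), nrow(p) == w, ncol(p) == 4L,
            all(p > 0), all(abs(rowSums(p) - 1) < 1e-9))
}

#' Estimate an order-0 background model from windows
#'
#' Pools base counts over all windows, adds one pseudocount per base, and
#' normalises.
#'
#' @param windows character vector of A/C/G/T strings, or a window
#'   data.frame with a `seq` column.
#' @return named numeric vector of length 4 (A, C, G, T), class
#'   `background_model`; probabilities sum to 1.
#' @export
estimate_background <- function(windows) {
  seqs <- .as_window_df(windows)$seq
  if (length(seqs) == 0L) stop("estimate_background: no windows")
  counts <- vapply(DNA_BASES, function(b) {
    sum(nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE)))
  }, numeric(1))
  b <- (counts + 1) / sum(counts + 1)
  structure(b, class = "background_model")
}

#' Seed matrices from the most frequent w-mers
#'
#' Deterministic multi-start seeding: the `n_seeds` most frequent distinct
#' w-mers across all windows (ties broken lexicographically) are each
#' converted to a position probability matrix with probability `1 - 3 *
#' eps` on the matching base and `eps` elsewhere.
#'
#' @inheritParams estimate_background
#' @param w motif width.
#' @param n_seeds number of seeds requested; fewer are returned when there
#'   are fewer distinct w-mers.
#' @param eps off-consensus probability per seed column (default 0.05).
#' @return list of `w x 4` matrices, named by the seeding w-mer.
#' @export
seed_candidates <- function(windows, w, n_seeds = 50L, eps = 0.05) {
  stopifnot(n_seeds >= 1L, eps > 0, eps < 1 / 3)
  seqs <- .as_window_df(windows)$seq
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - w + 1L
    if (n < 1L) return(character())
    substring(s, seq_len(n), seq_len(n) + w - 1L)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) stop("no ", w, "-mers available for seeding")
  tab <- table(kmers)
  ord <- order(-as.integer(tab), names(tab))  # count desc, then lexicographic
  top <- names(tab)[ord][seq_len(min(n_seeds, length(tab)))]
  lapply(stats::setNames(top, top), function(kmer) {
    p <- matrix(eps, nrow = w, ncol = 4L, dimnames = list(NULL, DNA_BASES))
    p[cbind(seq_len(w), match(strsplit(kmer, "")[[1L]], DNA_BASES))] <-
      1 - 3 * eps
    p
  })
}

#' Fit the ZOOPS mixture model by expectation-maximization
#'
#' E-step: per window, posterior over the `L - w + 1` candidate offsets and
#' the no-site event, under a uniform positional prior, occurrence prior
#' `lambda`, motif columns `p` and background `b`. M-step: `p` from
#' posterior-weighted site counts plus Dirichlet pseudocounts, `lambda`
#' from the mean occurrence posterior. Iterates until the relative
#' change of the monitored objective drops below `tol` or `max_iter` is
#' reached. Because the M-step uses Dirichlet pseudocounts, the quantity
#' that provably never decreases is the penalized log-likelihood (data
#' log-likelihood plus the Dirichlet log-prior of the motif columns);
#' that is the monitored objective stored in `loglik_trace`. The plain
#' data log-likelihood of the converged model is reported as `loglik`
#' and drives model selection.
#'
#' @inheritParams estimate_background
#' @param w motif width; every window must be at least `w` long.
#' @param seed_pwm initial `w x 4` position probability matrix.
#' @param background optional [estimate_background()] result; estimated
#'   from `windows` when `NULL`.
#' @param lambda0 initial occurrence prior (default 0.5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @param pseudocount Dirichlet pseudocount per base in the M-step
#'   (default 0.25).
#' @return list with components `model` (a `motif_model`: `w`, `p`,
#'   `lambda`, `background`, `loglik`, `llr`, `objective`, `n_sites`,
#'   `loglik_trace`) and `assignments` (data.frame: `tss_id`, `seq`,
#'   `rel_start`, `map_offset`, `map_posterior`, `p_nosite`, plus a
#'   `posterior` list-column of per-window posteriors, offsets first and
#'   the no-site event last).
#' @export
zoops_em <- function(windows, w, seed_pwm, background = NULL,
                     lambda0 = 0.5, tol = 1e-6, max_iter = 200L,
                     pseudocount = 0.25) {
  win <- .as_window_df(windows)
  if (!nrow(win)) stop("zoops_em: no windows")
  short <- which(nchar(win$seq) < w)
  if (length(short)) {
    stop("window ", win$tss_id[short[1L]], " is shorter than motif width ", w)
  }
  .validate_pwm(seed_pwm, w)
  if (is.null(background)) background <- estimate_background(win)
  b <- as.numeric(background)
  n <- nrow(win)

  groups <- split(seq_len(n), nchar(win$seq))
  enc <- lapply(groups, function(idx) {
    X <- .encode_seqs(win$seq[idx])
    n_off <- ncol(X) - w + 1L
    # background log-likelihood of the full window, constant over EM
    B <- rowSums(matrix(log(b)[X], nrow = nrow(X)))
    # per-base one-hot slabs used for fast weighted counting
    onehot <- lapply(1:4, function(bb) X == bb)
    list(idx = idx, X = X, n_off = n_off, B = B, onehot = onehot)
  })

  p <- seed_pwm
  lambda <- lambda0
  ll_trace <- numeric(0)
  ll_prev <- -Inf

  for (iter in seq_len(max_iter)) {
    d <- log(p) - matrix(log(b), nrow = w, ncol = 4L, byrow = TRUE)
    ll <- 0
    z_list <- vector("list", length(enc))
    for (g in seq_along(enc)) {
      e <- enc[[g]]
      S <- matrix(0, nrow = nrow(e$X), ncol = e$n_off)
      for (j in seq_len(w)) {
        S <- S + matrix(d[j, ][e$X[, j:(j + e$n_off - 1L), drop = FALSE]],
                        nrow = nrow(e$X))
      }
      # log joint (up to the shared background term B): offsets then no-site
      lj <- cbind(S + log(lambda / e$n_off), log1p(-lambda))
      mx <- apply(lj, 1L, max)
      ez <- exp(lj - mx)
      norm <- rowSums(ez)
      z_list[[g]] <- ez / norm
      ll <- ll + sum(e$B + mx + log(norm))
    }
    ll_pen <- ll + pseudocount * sum(log(p))  # MAP-EM monotone objective
    ll_trace <- c(ll_trace, ll_pen)
    if (ll_pen < ll_prev - 1e-9) {
      warning("ZOOPS EM penalized log-likelihood decreased at iteration ",
              iter)
    }
    converged <- is.finite(ll_prev) &&
      abs(ll_pen - ll_prev) < tol * (abs(ll_prev) + 1e-12)
    ll_prev <- ll_pen
    if (converged && iter > 1L) break

    counts <- matrix(pseudocount, nrow = w, ncol = 4L,
                     dimnames = list(NULL, DNA_BASES))
    occ_sum <- 0
    for (g in seq_along(enc)) {
      e <- enc[[g]]
      z <- z_list[[g]][, seq_len(e$n_off), drop = FALSE]
      occ_sum <- occ_sum + sum(z)
      for (bb in 1:4) {
        oh <- e$onehot[[bb]]
        for (j in seq_len(w)) {
          counts[j, bb] <- counts[j, bb] +
            sum(z * oh[, j:(j + e$n_off - 1L), drop = FALSE])
        }
      }
    }
    lambda <- min(max(occ_sum / n, 1e-9), 1 - 1e-9)
    p <- counts / rowSums(counts)
  }

  # assemble per-window assignments in input order
  map_offset <- integer(n); map_post <- numeric(n); p_nosite <- numeric(n)
  posterior <- vector("list", n)
  for (g in seq_along(enc)) {
    e <- enc[[g]]
    z <- z_list[[g]]
    off <- max.col(z[, seq_len(e$n_off), drop = FALSE], ties.method = "first")
    map_offset[e$idx] <- off
    map_post[e$idx] <- z[cbind(seq_len(nrow(z)), off)]
    p_nosite[e$idx] <- z[, e$n_off + 1L]
    posterior[e$idx] <- lapply(seq_len(nrow(z)), function(i) z[i, ])
  }
  assignments <- data.frame(tss_id = win$tss_id, seq = win$seq,
                            rel_start = win$rel_start,
                            map_offset = map_offset,
                            map_posterior = map_post,
                            p_nosite = p_nosite,
                            stringsAsFactors = FALSE)
  assignments$posterior <- posterior

  llr <- ll - sum(vapply(enc, function(e) sum(e$B), numeric(1)))
  model <- structure(list(
    w = w, p = p, lambda = lambda, background = background,
    loglik = ll, llr = llr,
    objective = llr - 0.5 * (3 * w + 1) * log(n),
    n_sites = sum(map_post > 0.5),
    loglik_trace = ll_trace, n_windows = n
  ), class = "motif_model")
  list(model = model, assignments = assignments)
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$w, "| lambda", signif(x$lambda, 3),
      "| sites", x$n_sites, "/", x$n_windows,
      "| objective", signif(x$objective, 6), "\n")
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a motif model
#'
#' @param model a `motif_model` (or anything with a `p` matrix).
#' @return character scalar: per-column argmax base.
#' @export
motif_consensus <- function(model) {
  paste(DNA_BASES[apply(model$p, 1L, which.max)], collapse = "")
}

#' Select the best motif among fitted candidates
#'
#' Maximises the selection objective (BIC-penalized log-likelihood ratio
#' against the background-only model); ties are broken by more called
#' sites, then by smaller width.
#'
#' @param candidates list of `motif_model` objects (or of
#'   `list(model=, assignments=)` pairs as returned by [zoops_em()]).
#' @return the winning element of `candidates`.
#' @export
select_motif <- function(candidates) {
  if (!length(candidates)) stop("select_motif: empty candidate list")
  get_model <- function(x) if (inherits(x, "motif_model")) x else x$model
  best <- 1L
  for (i in seq_along(candidates)[-1L]) {
    a <- get_model(candidates[[i]]); bm <- get_model(candidates[[best]])
    better <- (a$objective > bm$objective) ||
      (a$objective == bm$objective && a$n_sites > bm$n_sites) ||
      (a$objective == bm$objective && a$n_sites == bm$n_sites && a$w < bm$w)
    if (better) best <- i
  }
  candidates[[best]]
}

#' Call motif occurrences from ZOOPS assignments
#'
#' One occurrence per window whose maximum-posterior offset carries
#' occurrence posterior above `threshold`. With `threshold = 0` every
#' window yields its maximum-posterior offset.
#'
#' @param model `motif_model` from [zoops_em()].
#' @param assignments matching `assignments` data.frame from [zoops_em()].
#' @param threshold occurrence-posterior calling threshold (default 0.5).
#' @return data.frame: `tss_id`, `rel_start` (TSS-relative coordinate of
#'   the site's first base), `site_seq`, `score` (site log-odds vs
#'   background), `posterior`.
#' @export
call_occurrences <- function(model, assignments, threshold = 0.5) {
  keep <- assignments$map_posterior > threshold
  a <- assignments[keep, , drop = FALSE]
  w <- model$w
  site <- substring(a$seq, a$map_offset, a$map_offset + w - 1L)
  d <- log(model$p) -
    matrix(log(as.numeric(model$background)), nrow = w, ncol = 4L,
           byrow = TRUE)
  score <- vapply(site, function(s) {
    sum(d[cbind(seq_len(w), match(strsplit(s, "")[[1L]], DNA_BASES))])
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(tss_id = a$tss_id,
             rel_start = a$rel_start + a$map_offset - 1L,
             site_seq = site, score = score,
             posterior = a$map_posterior,
             stringsAsFactors = FALSE)
}

#' Discover a motif with the ZOOPS finder
#'
#' Full multi-start search: for each width, seeds from the most frequent
#' w-mers are refined by [zoops_em()]; the best model across all seeds and
#' widths is chosen by [select_motif()].
#'
#' @inheritParams zoops_em
#' @param widths integer vector of widths to search (default `c(9, 10)`,
#'   the conventional search range for bacterial -10 elements).
#' @param n_seeds seeds per width (default 50).
#' @return list: `model`, `assignments`, `n_candidates`.
#' @export
discover_motif <- function(windows, widths = c(9L, 10L), n_seeds = 50L,
                           background = NULL, tol = 1e-6, max_iter = 200L) {
  win <- .as_window_df(windows)
  if (is.null(background)) background <- estimate_background(win)
  best <- NULL
  n_cand <- 0L
  for (w in widths) {
    seeds <- seed_candidates(win, w, n_seeds)
    for (s in seeds) {
      fit <- zoops_em(win, w, s, background = background,
                      tol = tol, max_iter = max_iter)
      n_cand <- n_cand + 1L
      best <- if (is.null(best)) fit else select_motif(list(best, fit))
    }
  }
  list(model = best$model, assignments = best$assignments,
       n_candidates = n_cand)
}
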