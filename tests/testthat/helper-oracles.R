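# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own computational paths.

BASES <- c("A", "C", "G", "T")

# hypergeometric upper tail by direct rational enumeration of the pmf
hyper_sf_enum <- function(k, K, n, N) {
  ks <- max(0L, n - (N - K)):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# BH step-up worked by hand
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# random A/C/G/T string
rand_seq <- function(len, prob = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

# windows of length L with a motif planted at a fixed 1-based offset in a
# fraction `prob` of them; returns character vector plus the planted flag
plant_windows <- function(n, L, motif, offset, prob = 1) {
  w <- nchar(motif)
  stopifnot(offset + w - 1L <= L)
  planted <- runif(n) < prob
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(BASES, L, replace = TRUE)
    if (planted[i]) {
      s[offset:(offset + w - 1L)] <- strsplit(motif, "")[[1L]]
    }
    paste(s, collapse = "")
  }, character(1))
  list(seqs = seqs, planted = planted)
}

# Rsequence of an alignment computed independently (direct formula)
r_seq_by_hand <- function(sites) {
  n <- length(sites)
  w <- nchar(sites[1L])
  m <- do.call(rbind, strsplit(sites, ""))
  sum(vapply(seq_len(w), function(j) {
    f <- table(factor(m[, j], levels = BASES)) / n
    f <- f[f > 0]
    2 + sum(f * log2(f)) - 3 / (2 * log(2) * n)
  }, numeric(1)))
}

# --- ZOOPS complete-data oracle ------------------------------------------
# Enumerates every site/no-site configuration over tiny window sets; for a
# configuration, parameters are the closed-form (pseudocounted) estimates
# and the score is the complete-data log-likelihood under those estimates.

zoops_complete_ll <- function(seqs, w, config, b, pc = 0.25) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  n_off <- nchar(seqs) - w + 1L
  k <- sum(config > 0L)
  lambda <- min(max(k / n, 1e-9), 1 - 1e-9)
  counts <- matrix(pc, nrow = w, ncol = 4L)
  for (i in seq_len(n)) {
    if (config[i] > 0L) {
      site <- chars[[i]][config[i]:(config[i] + w - 1L)]
      idx <- cbind(seq_len(w), match(site, BASES))
      counts[idx] <- counts[idx] + 1L
    }
  }
  p <- counts / rowSums(counts)
  ll <- 0
  for (i in seq_len(n)) {
    xi <- match(chars[[i]], BASES)
    if (config[i] > 0L) {
      site_pos <- config[i]:(config[i] + w - 1L)
      ll <- ll + log(lambda) - log(n_off[i]) +
        sum(log(p[cbind(seq_len(w), xi[site_pos])])) +
        sum(log(b[xi[-site_pos]]))
    } else {
      ll <- ll + log(1 - lambda) + sum(log(b[xi]))
    }
  }
  list(ll = ll, p = p, lambda = lambda)
}

zoops_oracle <- function(seqs, w, b, pc = 0.25) {
  n_off <- nchar(seqs) - w + 1L
  grid <- expand.grid(lapply(n_off, function(m) 0:m),
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    cfg <- as.integer(grid[r, ])
    res <- zoops_complete_ll(seqs, w, cfg, b, pc)
    if (is.null(best) || res$ll > best$ll + 1e-12) {
      best <- c(res, list(config = cfg))
    }
  }
  best
}

# count matching consensus columns after aligning two models on their TA
# anchor columns; non-overlapping planted columns count as mismatches
consensus_matches <- function(model, planted_consensus, planted_ta_col) {
  fitted <- strsplit(promarch::motif_consensus(model), "")[[1L]]
  planted <- strsplit(planted_consensus, "")[[1L]]
  shift <- promarch::ta_anchor_column(model) - planted_ta_col
  sum(vapply(seq_along(planted), function(j) {
    jf <- j + shift
    jf >= 1L && jf <= length(fitted) && fitted[jf] == planted[j]
  }, logical(1)))
}
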