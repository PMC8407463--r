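test_that("estimate_background pools counts with one pseudocount per base", {
  b <- estimate_background(c("AAAA", "TTTT"))
  expect_equal(as.numeric(b), c(5, 1, 1, 5) / 12)
  expect_equal(as.numeric(estimate_background("ACGT")), rep(2 / 8, 4))
  expect_error(estimate_background(character()), "no windows")
})

test_that("seed_candidates is deterministic with lexicographic ties", {
  win <- c("AATATAATGCAT", "GGTATAATGCAG", "CCTATAATGCAC")
  seeds <- seed_candidates(win, 9, n_seeds = 1)
  expect_identical(names(seeds), "TATAATGCA")
  expect_equal(max(seeds[[1]]), 0.85)
  expect_equal(min(seeds[[1]]), 0.05)
  # tie between equally frequent w-mers resolved lexicographically
  seeds2 <- seed_candidates(c("AAAC", "CAAA"), 3, n_seeds = 2)
  expect_identical(names(seeds2)[1], "AAA")
  # asking for more seeds than distinct w-mers returns all of them
  expect_length(seed_candidates("ACGTACGT", 4, n_seeds = 100), 4L)
})

test_that("zoops_em recovers a planted motif and its occurrence prior", {
  set.seed(101)
  pw <- plant_windows(200, 15, "TATAATGCA", offset = 4, prob = 0.9)
  seeds <- seed_candidates(pw$seqs, 9, n_seeds = 1)
  fit <- zoops_em(pw$seqs, 9, seeds[[1]])
  cons <- motif_consensus(fit$model)
  expect_gte(sum(strsplit(cons, "")[[1]] ==
                   strsplit("TATAATGCA", "")[[1]]), 8L)
  expect_lt(abs(fit$model$lambda - 0.9), 0.1)
  # planted windows called at the true offset
  occ_off <- fit$assignments$map_offset[pw$planted &
                                          fit$assignments$map_posterior > 0.5]
  expect_gte(mean(occ_off == 4), 0.85)
})

test_that("zoops_em fixed point: degenerate identical windows", {
  win <- rep("GGTATAATGCATT", 50)
  seeds <- seed_candidates(win, 9, n_seeds = 1)
  fit <- zoops_em(win, 9, seeds[[1]])
  expect_gt(fit$model$lambda, 0.95)
  expect_gt(min(apply(fit$model$p, 1, max)), 0.9)  # near-degenerate columns
})

test_that("zoops_em on pure background finds no strong motif", {
  set.seed(77)
  lams <- objs <- numeric(3)
  for (r in 1:3) {
    win <- vapply(1:100, function(i) rand_seq(15), character(1))
    fit <- discover_motif(win, widths = 9, n_seeds = 5)
    lams[r] <- fit$model$lambda
    p <- fit$model$p
    ic <- apply(p, 1, function(f) 2 + sum(f * log2(f)))
    objs[r] <- mean(ic)
  }
  expect_lt(mean(objs), 1)  # no column reaches 1 bit on average
})

test_that("EM posteriors normalize and the monitored objective ascends", {
  set.seed(5)
  pw <- plant_windows(60, 13, "TTGACA", offset = 3, prob = 0.7)
  for (s in seed_candidates(pw$seqs, 6, n_seeds = 5)) {
    fit <- zoops_em(pw$seqs, 6, s)
    sums <- vapply(fit$assignments$posterior, sum, numeric(1))
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(diff(fit$model$loglik_trace) >= -1e-9))
  }
})

test_that("zoops_em errors name a too-short window", {
  expect_error(zoops_em(c(x1 = "ACGTACGTACGT", x2 = "ACG"), 9,
                        seed_candidates("ACGTACGTACGT", 9, 1)[[1]]),
               "x2")
})

test_that("select_motif applies objective then site-count then width ties", {
  m <- function(obj, sites, w) {
    structure(list(objective = obj, n_sites = sites, w = w),
              class = "motif_model")
  }
  expect_identical(select_motif(list(m(10, 5, 9), m(20, 2, 10)))$objective, 20)
  expect_identical(select_motif(list(m(10, 80, 9), m(10, 150, 10)))$n_sites,
                   150)
  expect_identical(select_motif(list(m(10, 80, 10), m(10, 80, 9)))$w, 9)
  expect_identical(select_motif(list(m(1, 1, 9)))$objective, 1)
  expect_error(select_motif(list()), "empty")
})

test_that("select_motif prefers the planted-data fit over shuffled data", {
  set.seed(42)
  pw <- plant_windows(150, 15, "TATAATGCA", offset = 4, prob = 0.9)
  shuffled <- vapply(pw$seqs, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  fit_real <- zoops_em(pw$seqs, 9, seed_candidates(pw$seqs, 9, 1)[[1]])
  fit_shuf <- zoops_em(shuffled, 9, seed_candidates(shuffled, 9, 1)[[1]])
  sel <- select_motif(list(fit_shuf, fit_real))
  expect_identical(sel$model$loglik, fit_real$model$loglik)
})

test_that("call_occurrences respects the posterior threshold", {
  set.seed(9)
  pw <- plant_windows(80, 15, "TATAATGCA", offset = 4, prob = 0.5)
  fit <- zoops_em(pw$seqs, 9, seed_candidates(pw$seqs, 9, 1)[[1]])
  occ_all <- call_occurrences(fit$model, fit$assignments, threshold = 0)
  expect_equal(nrow(occ_all), 80L)  # limiting case: every MAP offset
  occ <- call_occurrences(fit$model, fit$assignments, threshold = 0.5)
  expect_lt(nrow(occ), 80L)
  # a window dominated by the no-site event is not called
  hi_null <- fit$assignments$p_nosite > 0.9
  expect_false(any(fit$assignments$tss_id[hi_null] %in% occ$tss_id))
})
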