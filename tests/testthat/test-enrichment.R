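test_that("hypergeom_sf matches closed forms and rational enumeration", {
  expect_equal(hypergeom_sf(0, 3, 4, 10), 1)
  expect_equal(hypergeom_sf(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_sf(2, 3, 4, 10), 1 / 3)
  set.seed(2)
  for (i in 1:300) {
    N <- sample(1:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(hypergeom_sf(k, K, n, N), hyper_sf_enum(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_sf(5, 3, 4, 10), "k <=")
})

test_that("the hypergeometric pmf sums to one on a parameter grid", {
  for (N in c(5, 17, 41, 60)) {
    for (K in unique(c(0, 1, N %/% 2, N))) {
      for (n in unique(c(0, 1, N %/% 3, N))) {
        ks <- max(0, n - (N - K)):min(K, n)
        pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
        expect_equal(sum(pmf), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("bh_adjust equals the step-up procedure worked by hand", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_by_hand(p))
    expect_true(all(adj >= p & adj <= 1))
    expect_identical(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("test_class runs one exact test per term with BH across terms", {
  universe <- sprintf("g%03d", 1:100)
  class10 <- universe[1:10]
  term_map <- data.frame(gene_id = universe[1:10], term_id = "X")
  res <- test_class(class10, universe, term_map, alpha = 0.1,
                    class_label = "-7T")
  expect_equal(res$k, 10L)
  expect_equal(res$K, 10L)
  expect_equal(res$p_raw, 1 / choose(100, 10))
  expect_true(res$significant)
  # a term absent from the class is not significant
  term_map2 <- rbind(term_map,
                     data.frame(gene_id = universe[90:95], term_id = "Y"))
  res2 <- test_class(class10, universe, term_map2)
  expect_equal(nrow(res2), 2L)
  expect_gt(res2$p_raw[res2$term_id == "Y"], 0.5)
  expect_false(res2$significant[res2$term_id == "Y"])
  expect_true(all(res2$p_adj >= res2$p_raw))
  expect_error(test_class(class10, character(), term_map), "empty universe")
  expect_error(test_class(c(class10, "zz"), universe, term_map), "subset")
})

test_that("supergroup binning uses union gene counts", {
  sets <- list(pepA = c("g1", "g2", "g3", "g4"),
               pepB = c("g2", "g3", "g4", "g5"),
               other = "g9")
  res <- data.frame(class_label = "-7T",
                    term_id = c("pepA", "pepB", "other", "novel"),
                    k = 1, K = 1, n = 1, N = 9,
                    p_raw = 0.5, p_adj = 0.5, significant = FALSE)
  sg <- data.frame(term_id = c("pepA", "pepB", "other"),
                   supergroup = c("Protein Degradation",
                                  "Protein Degradation", "Misc"))
  out <- bin_supergroups(res, sg, term_map = sets,
                         class_genes = c("g1", "g5"))
  expect_identical(out$supergroup,
                   c("Protein Degradation", "Protein Degradation",
                     "Misc", "unassigned"))
  tab <- attr(out, "supergroups")
  pd <- tab[tab$supergroup == "Protein Degradation", ]
  expect_identical(pd$n_genes, 5L)        # union, not 4 + 4
  expect_identical(pd$n_genes_class, 2L)
  expect_identical(pd$n_terms, 2L)
})

test_that("trend_compare separates a rising focal group from controls", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:120)
  tp <- 8
  expr <- matrix(rnorm(120 * tp, sd = 0.3), nrow = 120,
                 dimnames = list(genes, paste0("t", 1:tp)))
  focal <- genes[1:20]
  expr[focal, ] <- expr[focal, ] + matrix(rep(0.8 * (0:(tp - 1)),
                                              each = 20), nrow = 20)
  tr <- trend_compare(expr, focal, n_controls = 200, seed = 99)
  expect_true(all(diff(tr$group_mean) > 0))  # strictly increasing
  focal_slope <- coef(lm(tr$group_mean ~ seq_len(tp)))[2]
  ctrl_slopes <- apply(tr$control_means, 1, function(m) {
    coef(lm(m ~ seq_len(tp)))[2]
  })
  expect_gte(mean(abs(ctrl_slopes) < focal_slope / 2), 0.95)
  # bit-reproducible given the seed, without disturbing the caller's RNG
  before <- .Random.seed
  tr2 <- trend_compare(expr, focal, n_controls = 200, seed = 99)
  expect_identical(tr$control_means, tr2$control_means)
  expect_identical(before, .Random.seed)
  expect_error(trend_compare(expr, genes), "complement")
  expect_error(trend_compare(expr, character()), "empty focal")
})
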