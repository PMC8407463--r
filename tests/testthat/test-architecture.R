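# helper: motif model peaked on a consensus, with a designated strong TA
peaked_model <- function(consensus, ta_col, strong = 0.9) {
  p <- consensus_pwm(consensus, 0.8)
  p[ta_col, ] <- (1 - strong) / 3
  p[ta_col, "T"] <- strong
  p[ta_col + 1, ] <- (1 - strong) / 3
  p[ta_col + 1, "A"] <- strong
  structure(list(w = nchar(consensus), p = p), class = "motif_model")
}

test_that("ta_anchor_column picks the max T+A pair, leftmost on ties", {
  m <- peaked_model("GGTAGGGGG", ta_col = 3)
  expect_identical(ta_anchor_column(m), 3L)
  # two exactly equal TA pairs: leftmost wins
  p <- consensus_pwm("ATAGTAG", 0.8)
  m2 <- structure(list(w = 7L, p = p), class = "motif_model")
  expect_identical(ta_anchor_column(m2), 2L)
})

test_that("anchor_ta does the positional arithmetic on the source window", {
  # window -19..-5; occurrence of a 9-mer at -14; model TA at columns 2,3
  # => anchor at -13, -7 base read 5 positions downstream from the window
  win <- data.frame(tss_id = "t1", seq = "CCCCCGTATAATGGA",
                    rel_start = -19L, rel_end = -5L)
  occ <- data.frame(tss_id = "t1", rel_start = -14L,
                    site_seq = "GTATAATGG")
  m <- peaked_model("GTATAATGG", ta_col = 2)
  a <- anchor_ta(m, occ, win)
  expect_identical(a$ta_anchor, -13L)
  # -8 maps to window string index 12
  expect_identical(a$minus7_base, substr("CCCCCGTATAATGGA", 12, 12))
  expect_identical(a$minus7_base, "T")
  expect_identical(a$minus7_class, "T")
  # planted -7 base is read even when it lies outside the occurrence:
  # 6-mer occurrence TATAAT at -12, anchor T at -12, -7 is the final T
  win2 <- data.frame(tss_id = "t2", seq = "CCCCCCCTATAATCC",
                     rel_start = -19L, rel_end = -5L)
  occ2 <- data.frame(tss_id = "t2", rel_start = -12L, site_seq = "TATAAT")
  m2 <- peaked_model("TATAAT", ta_col = 1)
  a2 <- anchor_ta(m2, occ2, win2)
  expect_identical(a2$ta_anchor, -12L)
  expect_identical(a2$minus7_base, "T")
  expect_identical(a2$minus7_class, "T")
})

test_that("anchor_ta drops occurrences whose -7 leaves the window", {
  win <- data.frame(tss_id = "t1", seq = "GTATAATGG", rel_start = -9L,
                    rel_end = -1L)
  occ <- data.frame(tss_id = "t1", rel_start = -9L, site_seq = "GTATAATGG")
  m <- peaked_model("GTATAATGG", ta_col = 2)
  # anchor at -8, -7 base at -3: inside => kept
  expect_equal(nrow(suppressWarnings(anchor_ta(m, occ, win))), 1L)
  win$rel_start <- -12L; win$rel_end <- -4L; occ$rel_start <- -12L
  # anchor at -11, -7 position -6 still inside
  expect_equal(nrow(suppressWarnings(anchor_ta(m, occ, win))), 1L)
  win$rel_start <- -20L; win$rel_end <- -12L; occ$rel_start <- -20L
  # anchor at -19, -7 position -14 < window start? no: -14 inside -20..-12
  expect_equal(nrow(suppressWarnings(anchor_ta(m, occ, win))), 1L)
  win$seq <- "GGGGTATAA"; occ$site_seq <- "GGGGTATAA"
  m2 <- peaked_model("GGGGTATAA", ta_col = 5)
  win$rel_start <- -9L; win$rel_end <- -1L; occ$rel_start <- -9L
  # anchor at -5 => -7 position would be +1: dropped with a warning
  expect_warning(a <- anchor_ta(m2, occ, win), "dropped")
  expect_equal(nrow(a), 0L)
  expect_identical(attr(a, "dropped")$reason, "anchor_fail")
})

test_that("element_distances reproduces canonical promoter arithmetic", {
  d <- element_distances(c(-12, -7), c(-35, -30))
  expect_identical(d$spacer, 17L)
  expect_identical(d$discriminator, 6L)
  expect_identical(element_distances(c(-24, -19), c(-30, -25))$spacer, 0L)
  expect_identical(element_distances(c(-7, -2))$discriminator, 1L)
  expect_error(element_distances(c(-12, -7), c(-14, -9)), "overlap")
})

test_that("distances match the count-the-integers oracle over span pairs", {
  brute_open <- function(a, b) length(setdiff(seq(a, b), c(a, b, 0)))
  set.seed(17)
  for (i in 1:200) {
    e35 <- sample(-50:-20, 1)
    s35 <- e35 - 5L
    s10 <- sample((e35 + 1):-8, 1)
    e10 <- s10 + 5L
    if (e10 >= 0) next
    d <- element_distances(c(s10, e10), c(s35, e35))
    expect_identical(d$spacer, brute_open(e35, s10))
    expect_identical(d$discriminator, brute_open(e10, 1))
  }
})

test_that("summarize_calls counts -7 fractions and modal distances", {
  calls <- data.frame(tss_id = c("a", "b", "c"),
                      minus7_base = c("T", "T", "G"),
                      spacer = c(17L, 17L, 16L),
                      discriminator = c(6L, 7L, 6L))
  s <- summarize_calls(calls)
  expect_equal(unname(s$minus7_fractions), c(0, 0, 1 / 3, 2 / 3))
  expect_equal(sum(s$minus7_fractions), 1)
  expect_identical(s$spacer_mode, 17L)
  expect_identical(s$discriminator_mode, 6L)
  # smallest length wins a tied histogram
  calls$spacer <- c(16L, 18L, 16L); calls$spacer[2] <- 18L
  calls2 <- calls; calls2$spacer <- c(16L, 18L, 18L)
  calls2 <- rbind(calls2, within(calls2[1, ], spacer <- 16L))
  expect_identical(summarize_calls(calls2)$spacer_mode, 16L)
  expect_error(summarize_calls(calls[0, ]), "empty")
})

test_that("method_agreement is symmetric, bounded, and exact by default", {
  a <- data.frame(tss_id = c("x", "y", "z"), ta_anchor = c(-12L, -12L, -11L))
  b <- data.frame(tss_id = c("y", "z", "w"), ta_anchor = c(-12L, -12L, -12L))
  expect_equal(method_agreement(a, a), 1)
  expect_equal(method_agreement(a, b), 0.5)
  expect_equal(method_agreement(a, b), method_agreement(b, a))
  expect_equal(method_agreement(a, b, tolerance = 1L), 1)
  disjoint <- data.frame(tss_id = c("y", "z"), ta_anchor = c(-15L, -15L))
  expect_equal(method_agreement(a, disjoint), 0)
  expect_error(method_agreement(a, data.frame(tss_id = "q",
                                              ta_anchor = -12L)),
               "no TSS")
})

test_that("find_minus35 is conditioned on TSSs with a -10 call", {
  ds <- simulate_promoter_dataset(sim_config(n_tss = 150L, seed = 19L))
  win <- suppressWarnings(extract_windows(ds$genome, ds$tss, -19L, -5L))
  fit <- discover_motif(win, n_seeds = 20)
  calls <- suppressWarnings(classify_promoters(fit, win, ds$tss))
  m35 <- find_minus35(ds$genome, ds$tss, calls, finder = "zoops",
                      n_seeds = 20)
  expect_true(all(m35$tss_id %in% calls$tss_id))
  tr <- ds$truth$tss
  m <- match(m35$tss_id, tr$tss_id)
  planted <- !is.na(tr$minus35_rel_start[m])
  hits <- abs(m35$minus35_start[planted] -
                tr$minus35_rel_start[m][planted]) <= 1
  expect_gte(mean(hits), 0.85)
})
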