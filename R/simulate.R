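# Synthetic TSS-seq-like datasets with planted ground truth. The
# generator emulates the structure of genome-scale bacterial TSS maps:
# thousands of oriented TSSs, each with an upstream -10 element whose TA
# dinucleotide is registered at -12/-11 (given the sampled discriminator),
# a configurable base distribution at -7, an optional -35 element at a
# sampled spacer, downstream gene annotations, essentiality labels with a
# configurable class association, functional terms, and expression
# trajectories. The generator never calls the motif-inference code, so
# planted truth stays independent of what the pipeline infers.

#' Position probability matrix from a consensus string
#'
#' @param consensus A/C/G/T string.
#' @param match_prob probability of the consensus base per column; the
#'   remainder is spread evenly over the other three bases.
#' @return `w x 4` matrix with columns A, C, G, T.
#' @export
consensus_pwm <- function(consensus, match_prob = 0.85) {
  stopifnot(match_prob > 0.25, match_prob < 1)
  bases <- strsplit(toupper(consensus), "")[[1L]]
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) stop("consensus must be A/C/G/T only")
  p <- matrix((1 - match_prob) / 3, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  p[cbind(seq_along(bases), idx)] <- match_prob
  p
}

# TA column pair of a planting PWM (local on purpose: the generator must
# not depend on the inference-side anchoring code)
.pwm_ta_col <- function(pwm) {
  w <- nrow(pwm)
  which.max(pwm[seq_len(w - 1L), "T"] + pwm[seq_len(w - 1L) + 1L, "A"])
}

.normalized <- function(x) abs(sum(x) - 1) < 1e-9

# Default -10 planting PWM: 9 columns around the TATAAT consensus
# (2-base 5' flank, 1-base 3' flank), 85% consensus-base probability,
# except the internal T (hexamer position 3, the -10 base) at 65%. The
# weaker internal T mirrors real sigma-70 promoters, where the -12/-11
# TA is the overrepresented dinucleotide; with equal column strengths the
# two TA pairs of TATAAT would be exactly tied and TA anchoring ill-posed.
.default_minus10_pwm <- function() {
  p <- consensus_pwm("CGTATAATG", 0.85)
  p[5L, ] <- (1 - 0.65) / 3
  p[5L, "T"] <- 0.65
  p
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a -10 element drawn from a 9-column PWM around the TATAAT
#' consensus (85% consensus-base probability, 65% at the internal T so
#' that the -12/-11 TA dinucleotide is the overrepresented one, as in
#' real sigma-70 promoters) with its TA registered at -12/-11 for the
#' modal discriminator, a uniform base distribution at
#' -7 (the Alphaproteobacteria-like regime), a TTGACA-consensus -35 at a
#' spacer distribution with mode 17 bp, discriminator mode 6 bp, and an
#' odds ratio of 3 linking the -7A/C/G class to gene essentiality.
#'
#' @param ... overrides for any field (see the function body / vignette
#'   for the full list and units).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_tss = 2000L,
    tss_spacing = 120L,          # bp between consecutive TSS slots
    margin = 100L,               # bp of genome flanking the TSS array
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    minus10_pwm = .default_minus10_pwm(),
    minus10_prob = 0.9,          # probability a TSS carries a -10 element
    minus7_distribution = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    minus35_pwm = consensus_pwm("TTGACA", 0.85),
    minus35_prob = 0.8,          # P(-35 | -10 planted)
    spacer_distribution = c("15" = 0.10, "16" = 0.20, "17" = 0.40,
                            "18" = 0.20, "19" = 0.10),
    discriminator_distribution = c("5" = 0.2, "6" = 0.5, "7" = 0.2,
                                   "8" = 0.1),
    essentiality_odds_ratio = 3,   # -7A/C/G class vs -7T class
    essential_base_rate = 0.15,    # P(essential | -7T class)
    n_terms = 20L,
    terms_per_gene = 2,            # expected terms per gene
    enriched_term = "term01",      # term enriched in the -7T class
    term_odds_ratio = 3,
    timepoints = 8L,
    expr_baseline = 8,
    expr_slope = 0.5,              # per-timepoint rise of the focal group
    expr_noise_sd = 0.5,
    minus_strand_prob = 0.5,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(.normalized(cfg$background),
            .normalized(cfg$minus7_distribution),
            .normalized(cfg$spacer_distribution),
            .normalized(cfg$discriminator_distribution),
            all(as.integer(names(cfg$spacer_distribution)) >= 10L),
            all(as.integer(names(cfg$spacer_distribution)) <= 25L),
            nrow(cfg$minus10_pwm) >= 6L, nrow(cfg$minus10_pwm) <= 12L,
            cfg$tss_spacing >= 100L, cfg$margin >= 60L)
  structure(cfg, class = "sim_config")
}

#' Simulate a TSS dataset with planted promoter architecture
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, all outputs are also
#'   written as plain-text files (`genome.fa`, `tss.tsv`, `genes.gff3`,
#'   `terms.tsv`, `essential.tsv`, `expr.tsv`, `supergroups.tsv`,
#'   `truth_tss.tsv`, `truth_genes.tsv`). Byte-identical across runs with
#'   the same config.
#' @return list: `genome` ([genome_set()]), `tss`, `genes`, `terms`,
#'   `essential`, `expr` (matrix), `supergroups`, `truth`
#'   (`$tss`, `$genes`), `config`. The caller's RNG state is preserved.
#' @export
simulate_promoter_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_tss
  w10 <- nrow(config$minus10_pwm)
  w35 <- nrow(config$minus35_pwm)
  ta_col <- .pwm_ta_col(config$minus10_pwm)
  if (ta_col + 5L > w10) {
    stop("minus10_pwm: TA anchor too close to the 3' end to carry a -7 base")
  }

  glen <- 2L * config$margin + n * config$tss_spacing
  pos <- config$margin + (seq_len(n) - 1L) * config$tss_spacing +
    sample(0:19, n, replace = TRUE)
  strand <- ifelse(stats::runif(n) < config$minus_strand_prob, "-", "+")
  genome <- sample(DNA_BASES, glen, replace = TRUE, prob = config$background)

  sample_site <- function(pwm) {
    vapply(seq_len(nrow(pwm)), function(j) {
      sample(DNA_BASES, 1L, prob = pwm[j, ])
    }, character(1))
  }
  write_site <- function(p, st, rel_start, site) {
    rels <- rel_start + seq_along(site) - 1L   # all negative, no 0 skip
    if (st == "+") {
      genome[p + rels] <<- site
    } else {
      genome[p - rels] <<- comp_base(site)
    }
  }

  planted10 <- stats::runif(n) < config$minus10_prob
  disc <- rep(NA_integer_, n)
  minus7 <- rep(NA_character_, n)
  site10 <- rep(NA_character_, n)
  rel10 <- rep(NA_integer_, n)
  planted35 <- rep(FALSE, n)
  spacer <- rep(NA_integer_, n)
  site35 <- rep(NA_character_, n)
  rel35 <- rep(NA_integer_, n)

  dd <- config$discriminator_distribution
  sd_ <- config$spacer_distribution
  for (i in seq_len(n)) {
    if (!planted10[i]) next
    d <- as.integer(sample(names(dd), 1L, prob = dd))
    s10 <- sample_site(config$minus10_pwm)
    b7 <- sample(DNA_BASES, 1L, prob = config$minus7_distribution)
    s10[ta_col + 5L] <- b7
    anchor <- -(d + 6L)                         # T of the TA lands here
    r10 <- anchor - (ta_col - 1L)
    write_site(pos[i], strand[i], r10, s10)
    disc[i] <- d; minus7[i] <- b7
    site10[i] <- paste(s10, collapse = ""); rel10[i] <- r10
    if (stats::runif(1L) < config$minus35_prob) {
      sp <- as.integer(sample(names(sd_), 1L, prob = sd_))
      s35 <- sample_site(config$minus35_pwm)
      r35 <- anchor - sp - w35                  # hexamer ends spacer+1 upstream
      write_site(pos[i], strand[i], r35, s35)
      planted35[i] <- TRUE; spacer[i] <- sp
      site35[i] <- paste(s35, collapse = ""); rel35[i] <- r35
    }
  }

  gene_id <- sprintf("g%05d", seq_len(n))
  tss <- data.frame(
    tss_id = sprintf("tss_%06d", seq_len(n)),
    replicon = "chr", position = pos, strand = strand,
    gene_id = gene_id, condition = "sim", stringsAsFactors = FALSE)

  genes <- data.frame(
    gene_id = gene_id, replicon = "chr",
    start = ifelse(strand == "+", pos + 25L, pmax(1L, pos - 324L)),
    end = ifelse(strand == "+", pmin(glen, pos + 324L), pos - 25L),
    strand = strand, stringsAsFactors = FALSE)

  class7 <- ifelse(planted10, ifelse(minus7 == "T", "T", "ACG"),
                   NA_character_)
  p0 <- config$essential_base_rate
  odds1 <- p0 / (1 - p0) * config$essentiality_odds_ratio
  p1 <- odds1 / (1 + odds1)
  p_ess <- ifelse(is.na(class7), p0, ifelse(class7 == "ACG", p1, p0))
  essential <- as.integer(stats::runif(n) < p_ess)

  term_ids <- sprintf("term%02d", seq_len(config$n_terms))
  q0 <- min(config$terms_per_gene / config$n_terms, 0.9)
  q_odds <- q0 / (1 - q0) * config$term_odds_ratio
  q1 <- q_odds / (1 + q_odds)
  membership <- matrix(stats::runif(n * config$n_terms) <
                         q0, nrow = n)
  if (config$enriched_term %in% term_ids) {
    jt <- match(config$enriched_term, term_ids)
    focal_rows <- which(!is.na(class7) & class7 == "T")
    membership[focal_rows, jt] <-
      stats::runif(length(focal_rows)) < q1
  }
  hit <- which(membership, arr.ind = TRUE)
  terms <- data.frame(gene_id = gene_id[hit[, 1L]],
                      term_id = term_ids[hit[, 2L]],
                      term_name = term_ids[hit[, 2L]],
                      ontology = "synthetic", stringsAsFactors = FALSE)
  terms <- terms[order(terms$gene_id, terms$term_id), ]
  rownames(terms) <- NULL

  supergroups <- data.frame(
    term_id = term_ids,
    supergroup = sprintf("SG%d", ((seq_len(config$n_terms) - 1L) %% 5L) + 1L),
    stringsAsFactors = FALSE)

  focal <- !is.na(class7) & class7 == "T" &
    membership[, match(config$enriched_term, term_ids)]
  tp <- seq_len(config$timepoints)
  expr <- config$expr_baseline +
    outer(ifelse(focal, config$expr_slope, 0), tp - 1L) +
    matrix(stats::rnorm(n * config$timepoints, sd = config$expr_noise_sd),
           nrow = n)
  rownames(expr) <- gene_id
  colnames(expr) <- sprintf("t%02d", tp)

  truth_tss <- data.frame(
    tss_id = tss$tss_id, gene_id = gene_id, position = pos,
    strand = strand, planted10 = planted10,
    minus10_rel_start = rel10, minus10_site = site10,
    ta_anchor = ifelse(planted10, -(disc + 6L), NA_integer_),
    minus7_base = minus7, minus7_class = class7,
    discriminator = disc, planted35 = planted35, spacer = spacer,
    minus35_rel_start = rel35, minus35_site = site35,
    stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene_id = gene_id, minus7_class = class7,
    essential = essential,
    trend_group = ifelse(focal, "rising", "flat"),
    stringsAsFactors = FALSE)

  out <- list(
    genome = genome_set(c(chr = paste(genome, collapse = ""))),
    tss = tss, genes = genes, terms = terms,
    essential = data.frame(gene_id = gene_id, essential = essential,
                           stringsAsFactors = FALSE),
    expr = expr, supergroups = supergroups,
    truth = list(tss = truth_tss, genes = truth_genes),
    config = config)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Write a simulated dataset to plain-text files
#'
#' @param dataset result of [simulate_promoter_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(dataset$genome)), fa)
  gr <- GenomicRanges::GRanges(
    seqnames = dataset$genes$replicon,
    ranges = IRanges::IRanges(dataset$genes$start, dataset$genes$end),
    strand = dataset$genes$strand,
    type = "gene", ID = dataset$genes$gene_id,
    locus_tag = dataset$genes$gene_id)
  gff <- file.path(dir, "genes.gff3")
  rtracklayer::export(gr, gff, format = "gff3")
  expr_df <- data.frame(gene_id = rownames(dataset$expr), dataset$expr,
                        check.names = FALSE)
  paths <- c(fa, tsv(dataset$tss, "tss.tsv"), gff,
             tsv(dataset$terms, "terms.tsv"),
             tsv(dataset$essential, "essential.tsv"),
             tsv(expr_df, "expr.tsv"),
             tsv(dataset$supergroups, "supergroups.tsv"),
             tsv(dataset$truth$tss, "truth_tss.tsv"),
             tsv(dataset$truth$genes, "truth_genes.tsv"))
  invisible(paths)
}

#' Verify a simulated dataset against its planted truth
#'
#' Re-extracts every planted -10 and -35 site from the emitted genome via
#' the window-extraction path and checks base-level identity with the
#' recorded truth. Any mismatch indicates a generator bug.
#'
#' @param dataset result of [simulate_promoter_dataset()].
#' @param truth defaults to `dataset$truth`.
#' @return list: `n_checked`, `n_mismatch`, `mismatches` (data.frame of
#'   `tss_id`, `element`, `expected`, `observed`).
#' @export
verify_truth <- function(dataset, truth = dataset$truth) {
  tt <- truth$tss
  mism <- list()
  n_checked <- 0L
  check <- function(i, rel_start, expected, element) {
    wlen <- nchar(expected)
    win <- extract_window(dataset$genome, dataset$tss[i, ],
                          rel_start, rel_start + wlen - 1L)
    obs <- if (is.null(win)) NA_character_ else win$seq
    n_checked <<- n_checked + 1L
    if (is.na(obs) || obs != expected) {
      mism[[length(mism) + 1L]] <<- data.frame(
        tss_id = dataset$tss$tss_id[i], element = element,
        expected = expected, observed = obs, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(tt))) {
    if (isTRUE(tt$planted10[i])) {
      check(i, tt$minus10_rel_start[i], tt$minus10_site[i], "minus10")
    }
    if (isTRUE(tt$planted35[i])) {
      check(i, tt$minus35_rel_start[i], tt$minus35_site[i], "minus35")
    }
  }
  mismatches <- if (length(mism)) do.call(rbind, mism) else
    data.frame(tss_id = character(), element = character(),
               expected = character(), observed = character())
  list(n_checked = n_checked, n_mismatch = nrow(mismatches),
       mismatches = mismatches)
}
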