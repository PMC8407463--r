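# End-to-end orchestration: windows -> motif discovery (two independent
# algorithms) -> TA anchoring and -7 classification -> -35 search ->
# distances -> summaries -> cross-method agreement -> enrichment ->
# expression trends. Every dropped TSS is counted by reason, and input
# TSS count equals calls plus categorized drops for each method.

#' Default pipeline configuration
#'
#' Mirrors the analysis settings the pipeline is built around: ZOOPS
#' finder on -19..-5 with widths 9-10, information finder on -15..-5; -35
#' search on -40..-28 (ZOOPS) / -37..-27 (information); occurrence
#' posterior threshold 0.5; duplicate-window spacing 5 bp; enrichment
#' thresholds 0.05 (essentiality) and 0.1 (functional terms).
#'
#' @param ... overrides for any field.
#' @return `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    zoops_minus10_window = c(-19L, -5L),
    zoops_minus35_window = c(-40L, -28L),
    info_minus10_window = c(-15L, -5L),
    info_minus35_window = c(-37L, -27L),
    minus10_widths = c(9L, 10L),
    minus35_widths = 6L,
    info_minus10_width = 9L,
    info_minus35_width = 6L,
    n_seeds = 50L,
    occurrence_threshold = 0.5,
    dedup_max_spacing = 5L,
    alpha_ess = 0.05,
    alpha_func = 0.1,
    distance_mode = "canonical",
    trend_controls = 1000L,
    trend_seed = 1L,
    universe = "called"  # or "all": all annotated genes
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$zoops_minus10_window[2] < 0L,
            cfg$info_minus10_window[2] < 0L,
            cfg$alpha_ess > 0, cfg$alpha_ess < 1,
            cfg$alpha_func > 0, cfg$alpha_func < 1)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar and vector fields map one-to-one onto [run_config()] fields.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# run one method's -10 branch; returns calls + drop accounting
.call_branch <- function(genome, tss, cfg, method) {
  if (method == "zoops") {
    wspec <- cfg$zoops_minus10_window
  } else {
    wspec <- cfg$info_minus10_window
  }
  win <- suppressWarnings(
    extract_windows(genome, tss, wspec[1], wspec[2]))
  drops <- attr(win, "dropped")
  win <- dedup_windows(win, tss, cfg$dedup_max_spacing)
  drops <- rbind(drops, attr(win, "dropped"))
  fit <- if (method == "zoops") {
    discover_motif(win, widths = cfg$minus10_widths, n_seeds = cfg$n_seeds)
  } else {
    info_maximize(win, w = cfg$info_minus10_width)
  }
  calls <- suppressWarnings(
    classify_promoters(fit, win, tss, cfg$occurrence_threshold))
  drops <- rbind(drops, attr(calls, "dropped"))
  list(fit = fit, windows = win, calls = calls, drops = drops)
}

#' Run the full promoter-architecture pipeline
#'
#' @param genome a [genome_set()] or path to a FASTA file.
#' @param tss TSS table or path to a TSV ([read_tss_table()]).
#' @param config a [run_config()].
#' @param terms optional gene/term mapping data.frame (or TSV path).
#' @param essential optional essentiality table `gene_id`, `essential`
#'   (or TSV path).
#' @param supergroups optional `term_id`, `supergroup` map.
#' @param expr optional expression matrix (genes x timepoints) or TSV
#'   with a `gene_id` first column.
#' @param out_dir optional directory for TSV outputs (`calls_zoops.tsv`,
#'   `calls_info.tsv`, `enrichment.tsv`, `report.json`).
#' @return `pipeline_report` list: per-method calls, summaries, drop
#'   accounting (`n_tss == nrow(calls) + sum(drops)` per method), motif
#'   models, agreement, enrichment tables and trend results (when the
#'   optional inputs are given), and the thresholds used.
#' @export
run_pipeline <- function(genome, tss, config = run_config(),
                         terms = NULL, essential = NULL,
                         supergroups = NULL, expr = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(genome) && !inherits(genome, "genome_set")) {
    genome <- read_genome(genome)
  }
  if (is.character(tss)) tss <- read_tss_table(tss)
  if (is.character(terms)) terms <- utils::read.delim(terms)
  if (is.character(essential)) essential <- utils::read.delim(essential)
  if (is.character(supergroups)) supergroups <- utils::read.delim(supergroups)
  if (is.character(expr)) {
    df <- utils::read.delim(expr, check.names = FALSE)
    expr <- as.matrix(df[, -1, drop = FALSE])
    rownames(expr) <- df[[1]]
  }

  message("promarch pipeline: ", nrow(tss), " TSSs; thresholds: ",
          "occurrence ", config$occurrence_threshold,
          ", alpha_ess ", config$alpha_ess,
          ", alpha_func ", config$alpha_func,
          ", dedup spacing ", config$dedup_max_spacing, " bp")

  branches <- list()
  for (method in c("zoops", "info")) {
    br <- .call_branch(genome, tss, config, method)
    m35 <- if (nrow(br$calls)) {
      if (method == "zoops") {
        find_minus35(genome, tss, br$calls,
                     config$zoops_minus35_window[1],
                     config$zoops_minus35_window[2],
                     finder = "zoops", widths = config$minus35_widths,
                     threshold = config$occurrence_threshold,
                     n_seeds = config$n_seeds)
      } else {
        find_minus35(genome, tss, br$calls,
                     config$info_minus35_window[1],
                     config$info_minus35_window[2],
                     finder = "info", widths = config$info_minus35_width)
      }
    } else NULL
    br$calls <- add_distances(br$calls, m35, mode = config$distance_mode)
    br$minus35 <- m35
    br$summary <- if (nrow(br$calls)) summarize_calls(br$calls) else NULL
    branches[[method]] <- br
  }

  agreement <- tryCatch(
    method_agreement(branches$zoops$calls, branches$info$calls),
    error = function(e) NA_real_)

  # enrichment consumes the information-finder calls (the branch with one
  # site per window, hence the larger call set)
  calls_primary <- branches$info$calls
  enrich <- NULL
  trend <- NULL
  if (nrow(calls_primary)) {
    universe <- if (identical(config$universe, "all") && !is.null(terms)) {
      unique(c(calls_primary$gene_id, terms$gene_id))
    } else {
      unique(calls_primary$gene_id)
    }
    universe <- universe[!is.na(universe)]
    by_class <- split(calls_primary$gene_id, calls_primary$minus7_class)
    enrich <- list()
    if (!is.null(essential)) {
      ess_map <- data.frame(
        gene_id = essential$gene_id[essential$essential == 1],
        term_id = "essential")
      enrich$essentiality <- do.call(rbind, lapply(names(by_class),
        function(cl) {
          test_class(intersect(unique(by_class[[cl]]), universe), universe,
                     ess_map, alpha = config$alpha_ess,
                     class_label = paste0("-7", if (cl == "T") "T" else
                                          "A/C/G"))
        }))
    }
    if (!is.null(terms)) {
      enrich$functional <- do.call(rbind, lapply(names(by_class),
        function(cl) {
          res <- test_class(intersect(unique(by_class[[cl]]), universe),
                            universe, terms, alpha = config$alpha_func,
                            class_label = paste0("-7", if (cl == "T") "T"
                                                 else "A/C/G"))
          if (!is.null(supergroups)) {
            res <- bin_supergroups(res, supergroups, terms)
          }
          res
        }))
    }
    if (!is.null(expr)) {
      focal <- intersect(unique(by_class[["T"]]), rownames(expr))
      if (length(focal) &&
          length(setdiff(rownames(expr), focal)) >= length(focal)) {
        trend <- trend_compare(expr, focal,
                               n_controls = config$trend_controls,
                               seed = config$trend_seed)
      }
    }
  }

  tabulate_drops <- function(drops) {
    if (!nrow(drops)) return(integer(0))
    vapply(split(drops$tss_id, drops$reason), length, integer(1))
  }
  report <- structure(list(
    n_tss = nrow(tss),
    config = config,
    methods = lapply(branches, function(br) list(
      model = if (!is.null(br$fit$model)) br$fit$model else NULL,
      calls = br$calls,
      minus35 = br$minus35,
      summary = br$summary,
      n_calls = nrow(br$calls),
      drops = tabulate_drops(br$drops),
      conserved = nrow(tss) == nrow(br$calls) + nrow(br$drops)
    )),
    agreement = agreement,
    enrichment = enrich,
    trend = trend
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(branches$zoops$calls,
                       file.path(out_dir, "calls_zoops.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(branches$info$calls,
                       file.path(out_dir, "calls_info.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrich)) {
      utils::write.table(do.call(rbind, lapply(names(enrich), function(nm) {
        cbind(analysis = nm,
              enrich[[nm]][, setdiff(names(enrich[[nm]]), "supergroup")])
      })), file.path(out_dir, "enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(
      n_tss = report$n_tss,
      agreement = report$agreement,
      methods = lapply(report$methods, function(m) list(
        n_calls = m$n_calls, drops = as.list(m$drops),
        conserved = m$conserved,
        minus7_fractions = if (!is.null(m$summary))
          as.list(m$summary$minus7_fractions) else NULL,
        spacer_mode = if (!is.null(m$summary)) m$summary$spacer_mode
          else NULL,
        discriminator_mode = if (!is.null(m$summary))
          m$summary$discriminator_mode else NULL))
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("promarch pipeline report:", x$n_tss, "TSSs in\n")
  for (nm in names(x$methods)) {
    m <- x$methods[[nm]]
    cat(sprintf("  [%s] %d calls; drops: %s; record conservation: %s\n",
                nm, m$n_calls,
                if (length(m$drops))
                  paste(sprintf("%s=%d", names(m$drops), m$drops),
                        collapse = ", ") else "none",
                m$conserved))
  }
  cat("  cross-method TA-anchor agreement:",
      if (is.na(x$agreement)) "NA" else sprintf("%.3f", x$agreement), "\n")
  invisible(x)
}

#' Serialize a motif model to JSON
#'
#' @param model a `motif_model`.
#' @param path output path.
#' @export
write_motif_json <- function(model, path) {
  jsonlite::write_json(list(
    width = model$w,
    matrix = apply(model$p, 1L, function(r) as.list(stats::setNames(r,
      DNA_BASES))),
    lambda = model$lambda,
    background = as.list(stats::setNames(as.numeric(model$background),
                                         DNA_BASES)),
    objective = model$objective,
    n_sites = model$n_sites
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
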