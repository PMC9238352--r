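#' Round half away from zero
#'
#' Matches the printed-table convention (62.35 -> 62.4), unlike base R's
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a DEG-percentage cell
#'
#' Renders the `DEGs (%)` column of the per-pathway results table:
#' `"<NDE> (<100 * NDE / pSize>)"` with the percentage rounded
#' half-away-from-zero to one decimal.
#'
#' @param pSize pathway size (gene count).
#' @param NDE DEG count on the pathway.
#' @return Character vector like `"43 (62.3)"`.
#' @export
format_deg_pct <- function(pSize, NDE) {
  pct <- round_half_away(100 * NDE / pSize, 1L)
  sprintf("%d (%.1f)", as.integer(NDE), pct)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Render a pathway scoring table in report format
#'
#' Columns `ID`, `Pathway Name`, `Status`, `pSize`, `DEGs (%)` and
#' `pGFdr` (scientific notation, 3 significant digits, with significance
#' stars at < 0.001, < 0.01, < 0.05), sorted ascending by `pGFdr`.
#'
#' @param rows a `spia_result` from [run_spia()] (or a data.frame with
#'   the same columns).
#' @return data.frame of formatted strings, one row per pathway.
#' @export
format_results_table <- function(rows) {
  rows <- as.data.frame(rows)
  rows <- rows[order(rows$pGFdr), , drop = FALSE]
  out <- data.frame(
    ID = rows$ID,
    `Pathway Name` = rows$Name,
    Status = ifelse(is.na(rows$Status), "NA", rows$Status),
    pSize = rows$pSize,
    `DEGs (%)` = format_deg_pct(rows$pSize, rows$NDE),
    pGFdr = paste0(formatC(rows$pGFdr, format = "E", digits = 2),
                   significance_stars(rows$pGFdr)),
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `paths` (real data: `expression`, `metadata`,
#' `kgml_dir`) or `simulate` (a [simulation_params()]) must be given.
#'
#' @param simulate a [simulation_params()] for synthetic runs, or `NULL`.
#' @param paths list with `expression`, `metadata`, `kgml_dir`, or `NULL`.
#' @param ko_gene knockout gene id; defaults to the simulation's.
#' @param n_boot bootstrap resamples for the perturbation null.
#' @param seed master seed, recorded in every output.
#' @param relation_weights subtype -> sign table for KGML parsing.
#' @param collapse_rule probe-collapse rule (see [collapse_probes()]).
#' @param venn_k top-k per Venn region.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, ko_gene = NULL,
                            n_boot = 2000L, seed = 1L,
                            relation_weights = default_relation_weights(),
                            collapse_rule = "max_mean", venn_k = 50L) {
  if (is.null(simulate) == is.null(paths))
    stop("exactly one of 'simulate' or 'paths' must be supplied")
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "simulation_params"))
    if (is.null(ko_gene)) ko_gene <- simulate$ko_gene
  } else {
    need <- c("expression", "metadata", "kgml_dir")
    if (!all(need %in% names(paths)))
      stop("paths must contain: ", paste(need, collapse = ", "))
    if (is.null(ko_gene)) stop("ko_gene is required for real-data runs")
  }
  structure(list(simulate = simulate, paths = paths, ko_gene = ko_gene,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 relation_weights = relation_weights,
                 collapse_rule = collapse_rule,
                 venn_k = as.integer(venn_k)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: either a `simulate:` block with
#' [simulation_params()] fields or a `paths:` block, plus the scalar
#' options.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim <- do.call(simulation_params, y$simulate)
  }
  rw <- if (is.null(y$relation_weights)) default_relation_weights()
        else unlist(y$relation_weights)
  pipeline_config(
    simulate = sim, paths = y$paths, ko_gene = y$ko_gene,
    n_boot = y$n_boot %||% 2000L, seed = y$seed %||% 1L,
    relation_weights = rw,
    collapse_rule = y$collapse_rule %||% "max_mean",
    venn_k = y$venn_k %||% 50L)
}

#' Run the full knockout-benchmark pipeline
#'
#' Stages, per contrast A/B/C: gene statistics (Welch), global-network
#' edge scoring, HES1 change-point threshold, DEG selection, pathway
#' perturbation scoring, and the KO-ROC metric panel on the `pG` scores;
#' then the three-way Venn partition across contrasts. All randomness is
#' derived from `config$seed`, so a fixed configuration reproduces
#' byte-identical outputs; stages run sequentially but every bootstrap
#' stream is keyed by pathway position, so parallel execution could not
#' change any value.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @return A `run_artifacts` list: `results` (per-contrast `stats`,
#'   `edge_scores`, `hes`, `degs`, `spia`, `roc`; plus `venn`,
#'   `collection`, `truth`), `manifest` (file, md5) and `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("kopathbench run, seed %d, n_boot %d",
                         config$seed, config$n_boot),
                 sprintf("config: collapse_rule=%s venn_k=%d ko_gene=%s",
                         config$collapse_rule, config$venn_k, config$ko_gene),
                 sprintf("relation_weights: %s",
                         paste(names(config$relation_weights),
                               config$relation_weights,
                               sep = "=", collapse = " ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      pc <- simulate_pathway_collection(config$simulate)
      em <- simulate_expression(config$simulate, pc$collection, pc$truth)
      list(collection = pc$collection, truth = pc$truth, em = em)
    })
    collection <- sim$collection; truth <- sim$truth; em <- sim$em
    log_lines <- c(log_lines,
                   sprintf("simulated: %d pathways (%d positive), %d genes",
                           length(collection$graphs),
                           length(truth$positive_pathway_ids),
                           nrow(em$values)))
  } else {
    collection <- stage("parse_kgml", {
      files <- sort(list.files(config$paths$kgml_dir,
                               pattern = "\\.xml$", full.names = TRUE))
      if (!length(files)) stop("no KGML files in ", config$paths$kgml_dir)
      pathway_collection(lapply(files, parse_kgml,
                                weight_table = config$relation_weights))
    })
    em <- stage("read_expression", {
      m <- read_expression(config$paths$expression, config$paths$metadata,
                           allow_duplicates = TRUE)
      collapse_probes(m, rule = config$collapse_rule)
    })
    collection$gene_universe <- union(collection$gene_universe,
                                      rownames(em$values))
  }

  net <- stage("merge_network", merge_global_network(collection))
  contrasts <- default_contrasts()
  results <- list()
  for (lbl in names(contrasts)) {
    stats <- stage(paste0("stats_", lbl),
                   compute_gene_stats(em, contrasts[[lbl]]))
    es <- stage(paste0("edge_scores_", lbl), score_edges(stats, net))
    hes <- stage(paste0("hes_", lbl), find_hes_threshold(es))
    degs <- stage(paste0("degs_", lbl), select_degs(es, hes, stats))
    spia <- stage(paste0("spia_", lbl),
                  run_spia(collection, stats, degs,
                           n_boot = config$n_boot, seed = config$seed))
    roc <- stage(paste0("roc_", lbl),
                 evaluate_method_scores(
                   collection, config$ko_gene,
                   stats::setNames(spia$pG, spia$ID)))
    results[[lbl]] <- list(stats = stats, edge_scores = es, hes = hes,
                           degs = degs, spia = spia, roc = roc)
    log_lines <- c(log_lines, sprintf(
      "contrast %s: HES1 %.4g, %d DEGs, %d pathways scored, AUC %.3f",
      lbl, hes$hes1_value, nrow(degs), nrow(spia), roc$auc))
    if (length(attr(spia, "excluded")))
      log_lines <- c(log_lines, sprintf(
        "contrast %s: excluded pathways: %s", lbl,
        paste(attr(spia, "excluded"), collapse = ", ")))
  }
  venn <- stage("venn", venn_partition(results$A$degs, results$B$degs,
                                       results$C$degs))

  artifacts <- list(results = c(results, list(
    venn = venn, collection = collection, truth = truth)),
    log = log_lines, manifest = NULL, out_dir = out_dir)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wr <- function(path) { files <<- c(files, path); path }
    for (lbl in names(contrasts)) {
      r <- results[[lbl]]
      write_gene_stats(r$stats, wr(file.path(out_dir,
        sprintf("stats_%s.tsv", lbl))))
      utils::write.table(as.data.frame(r$edge_scores),
        wr(file.path(out_dir, sprintf("edge_scores_%s.tsv", lbl))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(hes1_value = r$hes$hes1_value,
             changepoint_index = r$hes$changepoint_index,
             n_edges_retained = r$hes$n_edges_retained,
             seed = config$seed),
        wr(file.path(out_dir, sprintf("hes_%s.json", lbl))),
        auto_unbox = TRUE, digits = NA)
      utils::write.table(as.data.frame(r$degs),
        wr(file.path(out_dir, sprintf("degs_%s.tsv", lbl))),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_spia_results(r$spia, wr(file.path(out_dir,
        sprintf("spia_results_%s.tsv", lbl))))
      labels <- label_pathways_by_ko_gene(collection, config$ko_gene)
      bm <- ko_benchmark(labels, stats::setNames(r$spia$pG, r$spia$ID))
      write_roc_outputs(r$roc, bm,
        wr(file.path(out_dir, sprintf("roc_summary_%s.json", lbl))),
        wr(file.path(out_dir, sprintf("roc_points_%s.tsv", lbl))))
      utils::write.table(format_results_table(r$spia),
        wr(file.path(out_dir, sprintf("report_%s.tsv", lbl))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_venn_table(venn, lapply(results, `[[`, "degs"),
                     wr(file.path(out_dir, "venn.tsv")), k = config$venn_k)
    if (!is.null(truth))
      write_truth_json(truth, wr(file.path(out_dir, "truth.json")))
    writeLines(log_lines, wr(file.path(out_dir, "run.log")))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$manifest <- manifest
  }
  class(artifacts) <- "run_artifacts"
  artifacts
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("<run_artifacts>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
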