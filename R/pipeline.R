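# End-to-end orchestration: curate -> fingerprint -> network -> targets
# -> enrich, as one configured, logged, reproducible run. All thresholds
# default to the screening procedure's published values (edge Tc 0.4,
# selection average Tc 0.4, target mean score 0.1, support > 2, top 5).

#' Build and validate a pipeline run configuration
#'
#' @param library_path Compound table CSV (see [read_compound_table()]).
#' @param known_ids_path Text file, one known-active compound id per
#'   line.
#' @param predictions_path Long-format target-prediction CSV.
#' @param geneset_paths Named character vector of GMT files (names are
#'   source labels); at least two sources enable the top-k overlap
#'   report.
#' @param out_dir Output directory (created if absent).
#' @param edge_tc Inclusive Tc bound for network edges.
#' @param selection_avg_tc Strict bound for candidate selection.
#' @param target_score,target_support Retention filters of
#'   [aggregate_and_filter()].
#' @param top_k Top-k depth of the cross-source overlap.
#' @param radius,n_bits Fingerprint parameters.
#' @param averaging_mode Averaging set for [score_candidates()].
#' @param strip_salts,dedup Curation behavior (see
#'   [canonicalize_and_dedup()]).
#' @param seed Integer seed recorded in the report (the pipeline itself
#'   is deterministic; the seed matters for [simulate_study()] inputs).
#' @return A validated `run_config` list.
#' @export
run_config <- function(library_path, known_ids_path, predictions_path,
                       geneset_paths, out_dir,
                       edge_tc = 0.4, selection_avg_tc = 0.4,
                       target_score = 0.1, target_support = 2,
                       top_k = 5, radius = 2, n_bits = 2048,
                       averaging_mode = "all_knowns",
                       strip_salts = TRUE, dedup = TRUE, seed = 1) {
  cfg <- list(
    library_path = library_path, known_ids_path = known_ids_path,
    predictions_path = predictions_path,
    geneset_paths = as.list(geneset_paths), out_dir = out_dir,
    edge_tc = edge_tc, selection_avg_tc = selection_avg_tc,
    target_score = target_score, target_support = target_support,
    top_k = top_k, radius = radius, n_bits = n_bits,
    averaging_mode = averaging_mode, strip_salts = strip_salts,
    dedup = dedup, seed = as.integer(seed)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!in01(cfg$edge_tc)) stop("config error: edge_tc must lie in [0, 1]")
  if (!in01(cfg$selection_avg_tc)) {
    stop("config error: selection_avg_tc must lie in [0, 1]")
  }
  if (!in01(cfg$target_score)) {
    stop("config error: target_score must lie in [0, 1]")
  }
  if (cfg$target_support < 0 || cfg$target_support != round(cfg$target_support)) {
    stop("config error: target_support must be a non-negative integer")
  }
  if (cfg$top_k < 1) stop("config error: top_k must be at least 1")
  if (!cfg$averaging_mode %in% c("all_knowns", "neighbors_only")) {
    stop("config error: unknown averaging_mode '", cfg$averaging_mode, "'")
  }
  ecfp_name(cfg$radius)
  if (length(cfg$geneset_paths) > 0 && is.null(names(cfg$geneset_paths))) {
    names(cfg$geneset_paths) <-
      paste0("source", seq_along(cfg$geneset_paths))
  }
  invisible(cfg)
}

#' Read / write a run configuration file
#'
#' Configurations round-trip losslessly through a human-editable YAML
#' file.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config` returns the validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(
    cfg[c("library_path", "known_ids_path", "predictions_path", "out_dir",
          "edge_tc", "selection_avg_tc", "target_score", "target_support",
          "top_k", "radius", "n_bits", "averaging_mode", "strip_salts",
          "dedup", "seed")],
    list(geneset_paths = unlist(cfg$geneset_paths))
  ))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(...) message("[npscreen] ", ...)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes curation, fingerprinting/similarity, network construction,
#' target aggregation and enrichment in order, writing every stage
#' output under the configured directory:
#' `library_canonical.csv`, `rejections.tsv`, `candidate_scores.tsv`,
#' `network.graphml`, `network.sif`, `target_set.tsv`,
#' `enrichment_<source>.tsv`, `overlap.tsv`, and `report.yaml`. The run
#' is deterministic: identical configuration and inputs produce
#' identical outputs (the report's `timestamp` field is the only
#' run-varying line).
#'
#' @param config A `run_config`.
#' @return A `run_report` (invisibly): per-stage record counts, the
#'   configuration echo, package version and timestamp.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  pipeline_log("stage curate")
  library <- run_stage("curate", {
    lib <- read_compound_table(config$library_path)
    lib <- canonicalize_and_dedup(lib, strip_salts = config$strip_salts,
                                  dedup = config$dedup)
    known_ids <- readLines(config$known_ids_path, warn = FALSE)
    known_ids <- known_ids[nzchar(trimws(known_ids))]
    lib <- label_activity(lib, known_ids)
    write_compound_table(lib, file.path(out, "library_canonical.csv"))
    write_rejection_report(lib, file.path(out, "rejections.tsv"))
    lib
  })

  pipeline_log("stage network")
  net_out <- run_stage("network", {
    matrix <- pairwise_similarity(library, radius = config$radius,
                                  n_bits = config$n_bits)
    scores <- score_candidates(matrix,
                               selection_threshold = config$selection_avg_tc,
                               averaging_mode = config$averaging_mode,
                               edge_threshold = config$edge_tc)
    network <- build_network(matrix, edge_threshold = config$edge_tc)
    write_candidate_scores(scores, file.path(out, "candidate_scores.tsv"),
                           library = library)
    if (nrow(network$edges) > 0L) {
      export_network(network, file.path(out, "network.graphml"),
                     format = "graphml", scores = scores, library = library)
      export_network(network, file.path(out, "network.sif"), format = "sif")
    }
    list(matrix = matrix, scores = scores, network = network)
  })

  pipeline_log("stage targets")
  targets <- run_stage("targets", {
    preds <- read_target_predictions(config$predictions_path)
    tset <- aggregate_and_filter(preds,
                                 score_threshold = config$target_score,
                                 support_threshold = config$target_support)
    write_target_set(tset, file.path(out, "target_set.tsv"))
    list(predictions = preds, target_set = tset)
  })

  pipeline_log("stage enrich")
  enrich <- run_stage("enrich", {
    retained <- targets$target_set$gene_symbol[targets$target_set$retained]
    results <- list()
    for (label in names(config$geneset_paths)) {
      collection <- read_gmt(config$geneset_paths[[label]],
                             source_label = label)
      res <- ora(retained, collection)
      write_enrichment(res, file.path(out, paste0("enrichment_", label, ".tsv")))
      results[[label]] <- res
    }
    overlap <- NULL
    if (length(results) >= 2L) {
      overlap <- top_k_overlap(results[[1L]], results[[2L]],
                               k = config$top_k,
                               name_matcher = "normalized")
      utils::write.table(as.data.frame(overlap),
                         file.path(out, "overlap.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    list(results = results, overlap = overlap)
  })

  report <- run_stage("report", {
    rep <- list(
      package_version = as.character(utils::packageVersion("npscreen")),
      config = lapply(unclass(config), function(x)
        if (is.list(x)) lapply(x, as.character) else x),
      counts = list(
        compounds_read = nrow(library$records) + nrow(library$rejections),
        compounds_rejected = nrow(library$rejections),
        n_known = n_known(library),
        n_candidate = n_candidate(library),
        pairs_total = length(net_out$matrix),
        pairs_above_threshold = nrow(net_out$network$edges),
        candidates_selected = sum(net_out$scores$selected),
        predictions_rows = nrow(targets$predictions),
        targets_distinct = nrow(targets$target_set),
        targets_retained = sum(targets$target_set$retained),
        sets_tested = lapply(enrich$results, nrow),
        top_k_overlap = if (is.null(enrich$overlap)) character(0)
                        else as.list(enrich$overlap$shared_name)
      )
    )
    stopifnot(
      rep$counts$candidates_selected <= rep$counts$n_candidate,
      rep$counts$targets_retained <= rep$counts$targets_distinct
    )
    body <- yaml::as.yaml(rep)
    writeLines(c(body, paste0("timestamp: ",
                              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
               file.path(out, "report.yaml"))
    rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    structure(rep, class = "run_report")
  })
  pipeline_log("run complete: ", report$counts$candidates_selected,
               " candidates selected, ", report$counts$targets_retained,
               " targets retained")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  c0 <- x$counts
  cat("<run_report> npscreen ", x$package_version, "\n",
      "  compounds: ", c0$compounds_read, " read, ", c0$compounds_rejected,
      " rejected, ", c0$n_known, " known / ", c0$n_candidate, " candidate\n",
      "  similarity: ", c0$pairs_above_threshold, "/", c0$pairs_total,
      " pairs at threshold; ", c0$candidates_selected, " candidates selected\n",
      "  targets: ", c0$targets_retained, "/", c0$targets_distinct,
      " retained\n",
      "  overlap: ", if (length(c0$top_k_overlap) == 0) "(none)"
                     else paste(unlist(c0$top_k_overlap), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a complete synthetic study on disk
#'
#' Generates a compound library (planted analogs and decoys), target
#' predictions (planted retained targets) and two gene-set collections
#' (one planted enriched set), writes them in the exact formats the
#' pipeline reads, and returns a ready [run_config()] plus the truth
#' tables. The generated target predictions are conditioned on the
#' candidates the screening should select, mirroring how predictions are
#' obtained for screened compounds in practice.
#'
#' @param dir Directory for the synthetic inputs (created if absent).
#' @param seed Master seed; per-generator seeds derive from it.
#' @param lib_spec,pred_spec,gs_spec Optional generator specifications
#'   overriding the defaults (their seeds are re-derived from `seed`).
#' @return List with `config` (a `run_config` whose `out_dir` is
#'   `dir/out`), `truth` (list `compounds`, `targets`, `genesets`).
#' @export
simulate_study <- function(dir, seed = 1,
                           lib_spec = NULL, pred_spec = NULL,
                           gs_spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  if (is.null(lib_spec)) lib_spec <- library_spec(seed = seed)
  else lib_spec$seed <- seed
  if (is.null(pred_spec)) pred_spec <- prediction_spec(seed = seed + 1L)
  else pred_spec$seed <- seed + 1L
  if (is.null(gs_spec)) gs_spec <- geneset_spec(seed = seed + 2L)
  else gs_spec$seed <- seed + 2L

  gen_lib <- generate_library(lib_spec)
  write_compound_table(gen_lib$library, file.path(dir, "library.csv"))
  known <- gen_lib$library$records$compound_id[
    gen_lib$library$records$activity_status == "known_active"]
  writeLines(known, file.path(dir, "known_ids.txt"))
  utils::write.table(as.data.frame(gen_lib$truth),
                     file.path(dir, "truth_compounds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  gen_pred <- generate_predictions(gen_lib$library, pred_spec)
  utils::write.csv(as.data.frame(gen_pred$predictions),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  utils::write.table(as.data.frame(gen_pred$truth),
                     file.path(dir, "truth_targets.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  tset <- aggregate_and_filter(gen_pred$predictions)
  gen_gs <- generate_genesets(tset, gs_spec)
  write_gmt(gen_gs$source_a, file.path(dir, "pathways_a.gmt"))
  write_gmt(gen_gs$source_b, file.path(dir, "pathways_b.gmt"))
  writeLines(
    c(paste0("name_a\t", gen_gs$truth$name_a),
      paste0("name_b\t", gen_gs$truth$name_b),
      paste0("normalized\t", gen_gs$truth$normalized)),
    file.path(dir, "truth_genesets.tsv")
  )

  config <- run_config(
    library_path = file.path(dir, "library.csv"),
    known_ids_path = file.path(dir, "known_ids.txt"),
    predictions_path = file.path(dir, "predictions.csv"),
    geneset_paths = c(pathway_source_a = file.path(dir, "pathways_a.gmt"),
                      pathway_source_b = file.path(dir, "pathways_b.gmt")),
    out_dir = file.path(dir, "out"),
    seed = seed
  )
  write_run_config(config, file.path(dir, "config.yaml"))
  list(config = config,
       truth = list(compounds = gen_lib$truth, targets = gen_pred$truth,
                    genesets = gen_gs$truth))
}
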