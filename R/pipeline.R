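## End-to-end pipeline -------------------------------------------------------

#' Run the full content-analysis pipeline
#'
#' Executes the stages in the study order: ingest -> relevance filter ->
#' cleaning (retweet removal, same-user dedup) -> distress filter -> topic
#' classification -> co-occurrence network -> descriptive report. Every
#' stage's output is persisted under `out_dir` and a run manifest (config
#' hashes, seed, stage filter reports, file checksums, package version,
#' timestamps) is written so a run can be reproduced and audited. A stage
#' failure aborts with the stage name and cause.
#'
#' @param config Path to a YAML pipeline config, or an equivalent named
#'   list. Recognized fields: `corpus` (path to a JSONL corpus) or `synth`
#'   (a [generator_config()] argument list) as the input source;
#'   `cleaning_config`, `topic_config` (YAML lexicon paths; package
#'   defaults when omitted); `fp_mode` (`"span"`/`"veto"`); `out_dir`
#'   (required); `seed` (used for synthetic generation).
#' @return The run manifest, invisibly; side effect: stage outputs under
#'   `out_dir` (`cleaned_corpus.jsonl`, `assignments.jsonl`,
#'   `network.graphml`, `network_edges.csv`, `cooccurrence_matrix.csv`,
#'   `report.json`, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_data("pipeline config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop_data("pipeline config needs out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  reports <- list()

  ## ingest
  corp <- stage("ingest", {
    if (!is.null(config$corpus)) {
      suppressMessages(read_corpus(config$corpus))
    } else if (!is.null(config$synth)) {
      args <- config$synth
      if (!is.null(config$seed)) args$seed <- config$seed
      generate_corpus(do.call(generator_config, args))
    } else {
      stop("config needs either 'corpus' (path) or 'synth' (generator args)")
    }
  })

  lex <- stage("lexicons", {
    cc <- if (is.null(config$cleaning_config)) read_cleaning_config()
          else read_cleaning_config(config$cleaning_config)
    cc
  })

  f1 <- stage("relevance", relevance_filter(corp, lex$relevance))
  reports$relevance <- f1$report
  f2 <- stage("retweets", remove_retweets(f1$corpus))
  reports$retweets <- f2$report
  f3 <- stage("dedup", dedup_same_user(f2$corpus))
  reports$dedup <- f3$report
  f4 <- stage("distress", distress_filter(f3$corpus, lex$distress))
  reports$distress <- f4$report
  cleaned <- f4$corpus

  dict <- stage("topics", {
    td <- if (is.null(config$topic_config)) read_topic_dictionary()
          else read_topic_dictionary(config$topic_config)
    td
  })
  fp_mode <- config$fp_mode %||% "span"
  assignments <- stage("topics", classify_corpus(cleaned, dict$lexicon, dict$fp,
                                                 fp_mode = fp_mode))
  network <- stage("network", build_network(assignments))
  report <- stage("report", summarize_corpus(cleaned, assignments))

  paths <- list(
    cleaned_corpus = file.path(config$out_dir, "cleaned_corpus.jsonl"),
    assignments = file.path(config$out_dir, "assignments.jsonl"),
    network_graphml = file.path(config$out_dir, "network.graphml"),
    network_edges = file.path(config$out_dir, "network_edges.csv"),
    cooccurrence_matrix = file.path(config$out_dir, "cooccurrence_matrix.csv"),
    report = file.path(config$out_dir, "report.json")
  )
  write_corpus(cleaned, paths$cleaned_corpus)
  write_assignments(assignments, paths$assignments)
  export_sociogram(network, paths$network_graphml, "graphml")
  export_sociogram(network, paths$network_edges, "edgelist_csv")
  cooccurrence_matrix_csv(network, paths$cooccurrence_matrix)
  write_summary_report(report, paths$report)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ibdtopics")),
    timestamp = .ts_to_chr(Sys.time()),
    seed = config$seed,
    fp_mode = fp_mode,
    input = if (!is.null(config$corpus)) config$corpus else "synthetic",
    stages = lapply(reports, unclass),
    n_classified = length(assignments),
    n_multitopic_posts = network$n_multitopic_posts,
    outputs = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
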