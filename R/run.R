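# Batch pipeline runner: wires the stages in describe -> explore -> examine
# order with persistent filters. Each interactive dashboard panel of the
# workflow corresponds to a named output file, so a thin UI could be layered
# on top later. A manifest of every effective parameter is written with each
# run; manifest plus seed reproduce every table byte-for-byte.

#' Run one pipeline stage and write its artifacts
#'
#' Stages: `"synth"` generates a synthetic dataset with ground-truth
#' sidecar; `"describe"` writes per-variable frequency tables, a
#' submission-period table, a cross-tab and bar charts; `"explore"` writes
#' the word-correlation edge list with network plot and the topic-model
#' tables with a word cloud; `"examine"` writes the collated TF-IDF table,
#' per-term positive counts, the unique-record count, a histogram, and the
#' matched-record export. Filters are applied once, at load, and inherited
#' by every stage.
#'
#' @param stage One of `"describe"`, `"explore"`, `"examine"`, `"synth"`.
#' @param config Named list of run parameters:
#'   \describe{
#'     \item{input}{CSV path (all stages except `synth`).}
#'     \item{mapping}{`column_mapping` object or YAML path; default
#'       [default_mapping()].}
#'     \item{filters}{Named list role -> retained levels (optional).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{RNG seed (default 1).}
#'     \item{plots}{Write image files? Default `TRUE`.}
#'     \item{...}{Stage parameters: `freq_variable`, `prop_variable`,
#'       `granularity` (describe); `min_corr`, `min_count`, `k`, `alpha`,
#'       `beta`, `iterations`, `words_per_topic` (explore); `words_per_doc`,
#'       `search`, `terms`, `window`, `lexicon`, `export` (examine);
#'       `generator` (a [generator_config()], synth).}
#'   }
#' @return Invisibly, a named list of artifact paths (plus the manifest).
#' @export
run_stage <- function(stage = c("describe", "explore", "examine", "synth"),
                      config = list()) {
  stage <- match.arg(stage)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  plots <- config$plots %||% TRUE
  artifacts <- list()
  out <- function(name) file.path(out_dir, name)

  if (stage == "synth") {
    gen_cfg <- config$generator %||% generator_config(seed = seed)
    res <- generate_necropsy_data(gen_cfg, path = out("synthetic_records.csv"),
                                  truth_path = out("ground_truth.json"))
    artifacts$data <- out("synthetic_records.csv")
    artifacts$truth <- out("ground_truth.json")
  } else {
    mapping <- config$mapping %||% default_mapping()
    if (is.character(mapping)) mapping <- read_mapping(mapping)
    corpus <- read_export(config$input, mapping)
    if (!is.null(config$filters)) {
      corpus <- apply_filter(corpus, do.call(filter_spec, config$filters))
    }

    if (stage == "describe") {
      date_role <- intersect("submission_date", metadata_roles(corpus))
      for (role in setdiff(metadata_roles(corpus), date_role)) {
        ft <- frequency_table(corpus, role)
        p <- out(paste0("frequency_", role, ".csv"))
        readr::write_csv(ft, p, progress = FALSE)
        artifacts[[paste0("frequency_", role)]] <- p
        if (plots) {
          save_plot(plot_frequency(ft), out(paste0("frequency_", role, ".png")))
        }
      }
      if (length(date_role)) {
        pt <- period_table(corpus, config$granularity %||% "month")
        readr::write_csv(pt, out("period_table.csv"), progress = FALSE)
        artifacts$period_table <- out("period_table.csv")
      }
      roles <- metadata_roles(corpus)
      fv <- config$freq_variable %||% roles[1]
      pv <- config$prop_variable %||% setdiff(roles, fv)[1]
      ct <- cross_tab(corpus, fv, pv)
      readr::write_csv(ct, out("cross_tab.csv"), progress = FALSE)
      artifacts$cross_tab <- out("cross_tab.csv")
      if (plots) save_plot(plot_cross_tab(ct), out("cross_tab.png"))
    }

    if (stage == "explore") {
      dtm <- build_dtm(corpus, stoplist = resolve_stoplist(config))
      edges <- word_correlations(dtm,
                                 min_count = config$min_count %||% 5,
                                 min_corr = config$min_corr %||% 0.5)
      readr::write_csv(edges, out("correlation_edges.csv"), progress = FALSE)
      artifacts$correlation_edges <- out("correlation_edges.csv")
      if (plots && nrow(edges)) {
        save_plot(plot_correlation_network(edges, config$min_corr %||% 0.5,
                                           seed = seed),
                  out("correlation_network.png"))
      }
      k <- config$k %||% 3
      model <- fit_lda(dtm, k = k,
                       alpha = config$alpha %||% (50 / k),
                       beta = config$beta %||% 0.1,
                       iterations = config$iterations %||% 1000,
                       seed = seed)
      cloud <- topic_word_cloud(model, config$words_per_topic %||% 20)
      readr::write_csv(cloud, out("topic_words.csv"), progress = FALSE)
      theta <- tibble::as_tibble(model$theta, rownames = "accession_id")
      readr::write_csv(theta, out("document_topics.csv"), progress = FALSE)
      artifacts$topic_words <- out("topic_words.csv")
      artifacts$document_topics <- out("document_topics.csv")
      if (plots) save_plot(plot_topic_cloud(cloud, seed = seed), out("word_cloud.png"))
    }

    if (stage == "examine") {
      dtm <- build_dtm(corpus, stoplist = resolve_stoplist(config))
      tab <- top_tfidf_table(dtm, config$words_per_doc %||% 40)
      if (!is.null(config$search)) tab <- search_table(tab, config$search)
      readr::write_csv(tab, out("tfidf_table.csv"), progress = FALSE)
      artifacts$tfidf_table <- out("tfidf_table.csv")
      if (!is.null(config$terms)) {
        lexicon <- config$lexicon %||% negation_lexicon()
        if (is.character(lexicon)) lexicon <- load_negation_lexicon(lexicon)
        report <- positive_records(corpus, config$terms, lexicon = lexicon,
                                   window = config$window %||% 10)
        readr::write_csv(report$counts, out("finding_counts.csv"), progress = FALSE)
        writeLines(as.character(length(report$unique_records)),
                   out("unique_record_count.txt"))
        artifacts$finding_counts <- out("finding_counts.csv")
        artifacts$unique_record_count <- out("unique_record_count.txt")
        if (plots) save_plot(plot_findings(report), out("finding_histogram.png"))
        if (!is.null(config$export)) {
          export_positive(corpus, report, out(config$export))
          artifacts$export <- out(config$export)
        }
      }
    }
  }

  manifest <- list(
    stage = stage, seed = seed,
    parameters = config[setdiff(names(config), c("mapping", "lexicon", "generator"))],
    filters = if (stage != "synth" && exists("corpus", inherits = FALSE)) {
      corpus$provenance$filters
    } else character(),
    corpus_size = if (stage != "synth" && exists("corpus", inherits = FALSE)) {
      n_docs(corpus)
    } else NULL,
    artifacts = lapply(artifacts, as.character),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       null = "null")
  artifacts$manifest <- out("manifest.json")
  invisible(artifacts)
}

resolve_stoplist <- function(config) {
  sl <- config$stoplist %||% default_stopwords()
  if (is.character(sl) && length(sl) == 1L && file.exists(sl)) load_stopwords(sl) else sl
}

save_plot <- function(p, path) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)),
    error = function(e) warning("could not write plot ", path, ": ",
                                conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}
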