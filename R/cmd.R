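# Pipeline commands: thin wrappers that tie the modules together, read a
# run configuration, and write TSV/JSON artifacts. The Rscript front-end
# in inst/cli/eventlink.R dispatches to these.

default_run_config <- function() {
  list(
    tables = NULL,          # list(drug_target=, drug_disease=, target_disease=)
    synthetic = NULL,       # list(n_drugs=, ..., seed=) for simulate_pair_tables
    ratios = c(0.6, 0.1, 0.3),
    seed = 1L,
    out_dir = ".",
    hyperparams = list(
      lr = 1e-3, batch_size = 3840L, embedding_dim = 64L, dropout = 0.6,
      weight_decay = 1e-5, epochs = 200L, n_layers = 2L, k = 10L,
      negative_ratio = 1, positive_class_weight = 1, decoder = "product"
    )
  )
}

#' Read a run configuration
#'
#' Accepts a YAML file path or a list; missing keys fall back to the
#' defaults (Table-style hyperparameter names: `lr`, `batch_size`,
#' `embedding_dim`, `dropout`, `weight_decay`).
#'
#' @param config Path to a YAML file, a list, or NULL for defaults.
#' @return A complete configuration list.
#' @export
read_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(base, config)
  cfg$hyperparams <- modifyList(base$hyperparams, config$hyperparams %||% list())
  if (abs(sum(cfg$ratios) - 1) > 1e-8) abort("split ratios must sum to 1")
  cfg
}

config_hash <- function(cfg) {
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

write_provenance <- function(cfg, path) {
  prov <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package = "eventlink",
    version = as.character(utils::packageVersion("eventlink"))
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}

load_config_tables <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    do.call(simulate_pair_tables, cfg$synthetic)
  } else if (!is.null(cfg$tables)) {
    read_pair_tables(cfg$tables$drug_target, cfg$tables$drug_disease,
                     cfg$tables$target_disease, quiet = TRUE)
  } else {
    abort("Config must provide either `tables` paths or a `synthetic` block.")
  }
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate synthetic pair tables and write them to disk
#'
#' @param config See [read_run_config()]; must contain a `synthetic`
#'   block.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config = NULL) {
  cfg <- read_run_config(config)
  if (is.null(cfg$synthetic)) abort("cmd_simulate needs a `synthetic` config block")
  tables <- do.call(simulate_pair_tables, cfg$synthetic)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_tables(tables, cfg$out_dir)
  write_tsv_(attr(tables, "clusters"), file.path(cfg$out_dir, "clusters.tsv"))
  write_provenance(cfg, file.path(cfg$out_dir, "provenance.json"))
  invisible(cfg$out_dir)
}

#' Build and serialize the event–disease heterogeneous graph
#'
#' Reads (or simulates) the pair tables, derives events and the graph,
#' and writes `events.tsv`, `edges.tsv`, `vocab.tsv` plus a JSON summary
#' of the entity / event / edge counts.
#'
#' @param config See [read_run_config()].
#' @return The summary list, invisibly.
#' @export
cmd_build_graph <- function(config = NULL) {
  cfg <- read_run_config(config)
  tables <- load_config_tables(cfg)
  events <- build_events(tables)
  graph <- build_hetero_graph(events, tables$vocab)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  write_tsv_(events |>
               mutate(event_id = event) |>
               select(event_id, drug_id = drug, target_id = target),
             file.path(cfg$out_dir, "events.tsv"))
  dis_ids <- vocab_ids(tables$vocab, "disease")
  write_tsv_(graph$edges |>
               mutate(event_id = event, disease_id = dis_ids[disease + 1L]) |>
               select(event_id, disease_id),
             file.path(cfg$out_dir, "edges.tsv"))
  write_tsv_(tables$vocab, file.path(cfg$out_dir, "vocab.tsv"))

  summary <- list(
    n_drugs = n_of_kind(tables$vocab, "drug"),
    n_targets = n_of_kind(tables$vocab, "target"),
    n_diseases = n_of_kind(tables$vocab, "disease"),
    n_events = graph$n_events,
    n_edges = nrow(graph$edges)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_provenance(cfg, file.path(cfg$out_dir, "provenance.json"))
  inform(sprintf("Graph: %d drugs, %d targets, %d diseases -> %d events, %d edges",
                 summary$n_drugs, summary$n_targets, summary$n_diseases,
                 summary$n_events, summary$n_edges))
  invisible(summary)
}

build_pipeline_inputs <- function(cfg) {
  tables <- load_config_tables(cfg)
  events <- build_events(tables)
  graph <- build_hetero_graph(events, tables$vocab)
  seeds <- derive_seeds(cfg$seed, 2L)
  split <- split_edges(graph, ratios = cfg$ratios, seed = seeds[1]) |>
    sample_split_negatives(graph, ratio = cfg$hyperparams$negative_ratio,
                           seed = seeds[2])
  list(tables = tables, graph = graph, split = split)
}

fit_from_config <- function(cfg) {
  inp <- build_pipeline_inputs(cfg)
  hp <- cfg$hyperparams
  fit <- fit_event_gnn(
    inp$graph, inp$split,
    dim = hp$embedding_dim, n_layers = hp$n_layers, k = hp$k,
    epochs = hp$epochs, lr = hp$lr, batch_size = hp$batch_size,
    dropout = hp$dropout, weight_decay = hp$weight_decay,
    negative_ratio = hp$negative_ratio,
    positive_class_weight = hp$positive_class_weight,
    decoder = hp$decoder, seed = cfg$seed
  )
  list(fit = fit, inputs = inp)
}

#' Train the model and write checkpoint, history and metrics
#'
#' Writes `checkpoint.json` (named parameter arrays), `hyperparams.json`,
#' `history.tsv` (per-epoch loss and validation metrics), `metrics.json`
#' (validation and test reports at the best checkpoint) and
#' `provenance.json`. Reruns with an identical config and seed produce
#' byte-identical files.
#'
#' @param config See [read_run_config()].
#' @return The fitted `event_gnn`, invisibly.
#' @export
cmd_train <- function(config = NULL) {
  cfg <- read_run_config(config)
  res <- fit_from_config(cfg)
  fit <- res$fit
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  jsonlite::write_json(params_trainable(fit$params),
                       file.path(cfg$out_dir, "checkpoint.json"),
                       digits = NA, matrix = "rowmajor")
  jsonlite::write_json(fit$config, file.path(cfg$out_dir, "hyperparams.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_(format_history(fit$history), file.path(cfg$out_dir, "history.tsv"))
  metrics <- list(
    validation = as.list(evaluate_edges(fit, fit$split$val_pos,
                                        fit$split$val_neg)),
    test = as.list(evaluate_edges(fit))
  )
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, file.path(cfg$out_dir, "provenance.json"))
  invisible(fit)
}

# 5-decimal formatting of the metric columns, matching the report style
format_history <- function(history) {
  num <- vapply(history, is.numeric, logical(1)) & names(history) != "epoch"
  history[num] <- lapply(history[num], function(x) sprintf("%.5f", x))
  history
}

#' Evaluate a trained configuration on its test split and write reports
#'
#' Retrains deterministically from the config (checkpoints are exact
#' reruns under the stored seed) and writes `metrics.json`,
#' `metrics.tsv` and ROC/PR curve points as CSV.
#'
#' @param config See [read_run_config()].
#' @return The test metric report, invisibly.
#' @export
cmd_evaluate <- function(config = NULL) {
  cfg <- read_run_config(config)
  res <- fit_from_config(cfg)
  fit <- res$fit
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  emb <- fitted_embeddings(fit)
  edges <- bind_rows(fit$split$test_pos, fit$split$test_neg)
  labels <- c(rep(1, nrow(fit$split$test_pos)), rep(0, nrow(fit$split$test_neg)))
  prob <- edge_probability(decode_logits(fit$params, emb, edges))
  report <- metric_report(labels, prob)

  jsonlite::write_json(as.list(report), file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_(format_history(report), file.path(cfg$out_dir, "metrics.tsv"))
  utils::write.csv(roc_points(labels, prob),
                   file.path(cfg$out_dir, "roc_curve.csv"), row.names = FALSE)
  utils::write.csv(pr_points(labels, prob),
                   file.path(cfg$out_dir, "pr_curve.csv"), row.names = FALSE)
  write_provenance(cfg, file.path(cfg$out_dir, "provenance.json"))
  invisible(report)
}

#' Run the ablation experiment from a config and write the result table
#'
#' @param config See [read_run_config()]; optional keys `variants`
#'   (names) and `seeds`.
#' @return The ablation tibble, invisibly.
#' @export
cmd_ablate <- function(config = NULL) {
  cfg <- read_run_config(config)
  extra <- if (is.list(config)) config else list()
  variants <- extra$variants %||% names(ablation_variants())
  seeds <- extra$seeds %||% 1:5
  inp <- build_pipeline_inputs(cfg)
  hp <- cfg$hyperparams
  tab <- run_ablation(inp$graph, inp$split, variants = variants, seeds = seeds,
                      dim = hp$embedding_dim, k = hp$k, epochs = hp$epochs,
                      lr = hp$lr, batch_size = hp$batch_size,
                      dropout = hp$dropout, weight_decay = hp$weight_decay)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(format_history(tab), file.path(cfg$out_dir, "ablation.tsv"))
  write_provenance(cfg, file.path(cfg$out_dir, "provenance.json"))
  invisible(tab)
}

#' Predict ranked diseases for one event and write a TSV
#'
#' @param config See [read_run_config()].
#' @param event 0-based event index.
#' @param threshold Probability cut-off.
#' @return The prediction tibble, invisibly.
#' @export
cmd_predict <- function(config = NULL, event, threshold = 0.5) {
  cfg <- read_run_config(config)
  res <- fit_from_config(cfg)
  fit <- res$fit
  preds <- predict_links(fit, event = event, threshold = threshold)
  ev_row <- fit$graph$events[fit$graph$events$event == event, ]
  out <- tibble(
    event_id = event,
    drug_id = ev_row$drug, target_id = ev_row$target,
    disease_id = preds$disease_id,
    probability = sprintf("%.5f", preds$probability),
    rank = preds$rank
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(out, file.path(cfg$out_dir, "predictions.tsv"))
  invisible(preds)
}

#' Export a labelled edge list for prediction-graph visualization
#'
#' Emits up to `n_edges` event–disease edges labelled `train` (edges the
#' model was trained on), `test-correct` (test positives recovered at
#' the threshold) or `test-missed` (test positives the model failed to
#' recover) — the solid / predicted / missed semantics of a prediction
#' graph — as a TSV consumable by standard graph-drawing tools.
#'
#' @param fit A fitted `event_gnn`.
#' @param n_edges Maximum rows to emit (> 0).
#' @param threshold Probability threshold for calling a test edge
#'   recovered.
#' @param path Optional TSV output path.
#' @return Tibble `event_id`, `disease_id`, `status`.
#' @export
export_prediction_graph <- function(fit, n_edges = 100L, threshold = 0.5,
                                    path = NULL) {
  if (n_edges <= 0L) abort("n_edges must be positive")
  emb <- fitted_embeddings(fit)
  test_prob <- edge_probability(decode_logits(fit$params, emb,
                                              fit$split$test_pos))
  dis_ids <- vocab_ids(fit$graph$vocab, "disease")
  lab <- function(edges, status) {
    tibble(event_id = edges$event,
           disease_id = dis_ids[edges$disease + 1L],
           status = status)
  }
  out <- bind_rows(
    lab(fit$split$test_pos[test_prob >= threshold, ], "test-correct"),
    lab(fit$split$test_pos[test_prob < threshold, ], "test-missed"),
    lab(fit$split$train_pos, "train")
  )
  out <- head(out, n_edges)
  if (!is.null(path)) write_tsv_(out, path)
  out
}
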