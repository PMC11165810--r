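# Ablation harness over encoder depth, branch structure, gates and
# decoder variants.

#' Registry of ablation variants
#'
#' Nine named configurations covering encoder depth (one to three
#' layers), the two branches run separately, gate removal, and the three
#' decoders. `two_layer` combined with the product decoder is the default
#' model.
#'
#' @return Named list of configuration overrides for [fit_event_gnn()].
#' @export
ablation_variants <- function() {
  list(
    one_layer = list(n_layers = 1L),
    two_layer = list(n_layers = 2L),
    three_layer = list(n_layers = 3L),
    conv_only = list(attention = FALSE),
    attention_only = list(conv = FALSE),
    no_gate = list(gate = FALSE),
    decoder_product = list(decoder = "product"),
    decoder_single_linear = list(decoder = "single_linear"),
    decoder_bilinear = list(decoder = "bilinear")
  )
}

#' Run the ablation experiment
#'
#' Trains and evaluates every requested variant for every seed and
#' reports the mean of the six test metrics per variant.
#'
#' @param graph An [build_hetero_graph()] object.
#' @param split An [split_edges()] object.
#' @param variants Character vector of variant names (default: all nine).
#' @param seeds Integer seeds; metrics are averaged over them.
#' @param ... Further arguments (e.g. `epochs`, `dim`) passed to
#'   [fit_event_gnn()]; variant overrides take precedence.
#' @return Tibble: `variant`, the six mean metrics, `n_seeds`.
#' @export
run_ablation <- function(graph, split, variants = names(ablation_variants()),
                         seeds = 1:5, ...) {
  registry <- ablation_variants()
  unknown <- setdiff(variants, names(registry))
  if (length(unknown)) {
    abort(sprintf("Unknown variant(s): %s. Valid names: %s",
                  paste(unknown, collapse = ", "),
                  paste(names(registry), collapse = ", ")))
  }
  dots <- list(...)
  map_dfr(variants, function(v) {
    per_seed <- map_dfr(seeds, function(s) {
      args <- c(list(graph = graph, split = split, seed = s),
                modifyList(dots, registry[[v]]))
      fit <- do.call(fit_event_gnn, args)
      evaluate_edges(fit)
    })
    dplyr::bind_cols(tibble(variant = v),
                     as_tibble(as.list(colMeans(per_seed))),
                     tibble(n_seeds = length(seeds)))
  })
}
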