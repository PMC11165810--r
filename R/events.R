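#' Build event nodes from pairwise relation tables
#'
#' An event collapses a drug–target–disease ternary relation into a single
#' node: for every drug–target pair (X, Y) in the drug–target table, its
#' disease set Z is the intersection of the diseases associated with X and
#' the diseases associated with Y. Pairs with an empty intersection produce
#' no event — an event asserts that the pair treats at least one disease.
#'
#' @param tables A [pair_tables()] object.
#' @return A tibble with one row per event, ordered by drug then target
#'   index: columns `event` (0-based index), `drug`, `target` (identifiers),
#'   `drug_index`, `target_index`, `diseases` (list-column of disease
#'   identifiers), `disease_indices` (list-column of 0-based indices) and
#'   `n_diseases`.
#' @examples
#' ev <- build_events(fixture_tables())
#' ev[, c("event", "drug", "target", "n_diseases")]
#' @export
build_events <- function(tables) {
  stopifnot(inherits(tables, "pair_tables"))
  vocab <- tables$vocab

  # (drug, target, disease) triples where the drug treats the disease AND
  # the target is associated with it: exactly the intersection rule.
  triples <- tables$drug_target |>
    inner_join(tables$drug_disease, by = "drug",
               relationship = "many-to-many") |>
    inner_join(tables$target_disease, by = c("target", "disease"))

  if (nrow(triples) == 0L) {
    return(tibble(
      event = integer(), drug = character(), target = character(),
      drug_index = integer(), target_index = integer(),
      diseases = list(), disease_indices = list(), n_diseases = integer()
    ))
  }

  events <- triples |>
    mutate(
      drug_index = vocab_index(vocab, "drug", drug),
      target_index = vocab_index(vocab, "target", target),
      disease_index = vocab_index(vocab, "disease", disease)
    ) |>
    group_by(drug, target, drug_index, target_index) |>
    summarise(
      diseases = list(disease[order(disease_index)]),
      disease_indices = list(sort(disease_index)),
      n_diseases = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(drug_index, target_index) |>
    mutate(event = row_number() - 1L) |>
    select(event, drug, target, drug_index, target_index,
           diseases, disease_indices, n_diseases)

  events
}

#' Assemble the event–disease heterogeneous graph
#'
#' Nodes are of two types — events and diseases — and an (undirected)
#' edge joins event i to disease j whenever j belongs to event i's disease
#' set. Diseases absent from every event are retained as isolated nodes so
#' that disease indices (and one-hot feature columns) stay stable.
#'
#' @param events Event tibble from [build_events()].
#' @param vocab The entity vocabulary (`tables$vocab`); supplies the total
#'   disease count including isolated diseases.
#' @return An `event_graph` object: list with `n_events`, `n_diseases`,
#'   `edges` (tibble `event`, `disease`, 0-based indices), `events`
#'   (annotation tibble) and `vocab`.
#' @export
build_hetero_graph <- function(events, vocab) {
  if (nrow(events) == 0L) {
    abort("no events: cannot build a heterogeneous graph from an empty event list")
  }
  edges <- tibble(
    event = rep(events$event, events$n_diseases),
    disease = unlist(events$disease_indices)
  )
  stopifnot(!anyDuplicated(paste(edges$event, edges$disease)))
  graph <- structure(
    list(
      n_events = nrow(events),
      n_diseases = n_of_kind(vocab, "disease"),
      edges = edges,
      events = events,
      vocab = vocab
    ),
    class = "event_graph"
  )
  validate_event_graph(graph)
  graph
}

validate_event_graph <- function(graph) {
  with(graph, {
    stopifnot(
      all(edges$event >= 0L), all(edges$event < n_events),
      all(edges$disease >= 0L), all(edges$disease < n_diseases)
    )
  })
  invisible(graph)
}

#' @exportS3Method base::print
print.event_graph <- function(x, ...) {
  cat("<event_graph>\n")
  cat(sprintf("  events:   %d\n", x$n_events))
  cat(sprintf("  diseases: %d (%d linked)\n", x$n_diseases,
              length(unique(x$edges$disease))))
  cat(sprintf("  edges:    %d\n", nrow(x$edges)))
  invisible(x)
}

#' One-hot event feature matrix
#'
#' Builds the q x z binary matrix A whose entry A\[i, j\] is 1 exactly when
#' disease j belongs to event i's disease set; row i is the one-hot
#' encoding of event i's treated diseases.
#'
#' @param graph An [build_hetero_graph()] object.
#' @return A base matrix of 0/1 values with `n_events` rows and
#'   `n_diseases` columns.
#' @export
event_features <- function(graph) {
  stopifnot(inherits(graph, "event_graph"))
  A <- matrix(0, nrow = graph$n_events, ncol = graph$n_diseases)
  A[cbind(graph$edges$event + 1L, graph$edges$disease + 1L)] <- 1
  A
}

#' Random disease feature matrix
#'
#' Disease nodes carry no curated features; they are initialised with
#' i.i.d. standard-normal vectors, reproducible under `seed`.
#'
#' @param n_diseases Number of disease nodes.
#' @param dim Feature dimension (>= 1).
#' @param seed Integer seed.
#' @return A `n_diseases` x `dim` numeric matrix.
#' @export
disease_features <- function(n_diseases, dim, seed) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1) {
    abort("`dim` must be a positive integer.")
  }
  with_seed_(seed, matrix(rnorm(n_diseases * dim), nrow = n_diseases, ncol = dim))
}
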