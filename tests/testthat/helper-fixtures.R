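# Shared builders for small test graphs.

# Construct an event_graph directly from an edge list (bypassing the
# pair-table pipeline) for split / sampling / encoder tests.
make_test_graph <- function(q, z, edges) {
  vocab <- dplyr::bind_rows(
    tibble::tibble(kind = "drug", id = sprintf("D%02d", seq_len(q)),
                   index = seq_len(q) - 1L),
    tibble::tibble(kind = "target", id = sprintf("T%02d", seq_len(q)),
                   index = seq_len(q) - 1L),
    tibble::tibble(kind = "disease", id = sprintf("Z%02d", seq_len(z)),
                   index = seq_len(z) - 1L)
  )
  events <- tibble::tibble(
    event = seq_len(q) - 1L,
    drug = sprintf("D%02d", seq_len(q)),
    target = sprintf("T%02d", seq_len(q))
  )
  structure(
    list(n_events = q, n_diseases = z, edges = edges,
         events = events, vocab = vocab),
    class = "event_graph"
  )
}

# n distinct random (event, disease) pairs on a q x z grid
random_edges <- function(q, z, n, seed) {
  stopifnot(n <= q * z)
  keys <- withr::with_seed(seed, sample0 <- sample(q * z, n)) - 1L
  tibble::tibble(event = as.integer(keys %/% z),
                 disease = as.integer(keys %% z))
}

# a small planted-cluster graph + split, used by training-level tests
small_training_setup <- function(seed = 5, n_drugs = 20, n_targets = 12,
                                 n_diseases = 30, n_clusters = 2) {
  tabs <- simulate_pair_tables(n_drugs = n_drugs, n_targets = n_targets,
                               n_diseases = n_diseases,
                               n_clusters = n_clusters, seed = seed)
  graph <- build_hetero_graph(build_events(tabs), tabs$vocab)
  split <- split_edges(graph, seed = seed)
  list(tables = tabs, graph = graph, split = split)
}
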