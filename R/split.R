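#' Split graph edges into train / validation / test positives
#'
#' Uniformly permutes the edge set under `seed` and cuts it at
#' `floor(r1 * n)` and `floor((r1 + r2) * n)`, so with the default
#' 0.6/0.1/0.3 ratios and 100 edges the splits hold exactly 60/10/30
#' edges. The three sets partition the edge set.
#'
#' @param graph An [build_hetero_graph()] object with at least 10 edges.
#' @param ratios Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return An `edge_split` object: tibbles `train_pos`, `val_pos`,
#'   `test_pos` (columns `event`, `disease`), empty `train_neg`, `val_neg`,
#'   `test_neg` placeholders, plus `ratios` and `seed`.
#' @export
split_edges <- function(graph, ratios = c(0.6, 0.1, 0.3), seed = 1L) {
  stopifnot(inherits(graph, "event_graph"))
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    abort("`ratios` must be three numbers summing to 1.")
  }
  n <- nrow(graph$edges)
  if (n < 10L) {
    abort(sprintf("Need at least 10 edges to split; graph has %d.", n))
  }
  perm <- with_seed_(seed, sample.int(n))
  shuffled <- graph$edges[perm, ]
  n_train <- floor(ratios[1] * n)
  n_trval <- floor((ratios[1] + ratios[2]) * n)
  empty <- tibble(event = integer(), disease = integer())
  structure(
    list(
      train_pos = shuffled[seq_len(n_train), ],
      val_pos   = shuffled[seq(n_train + 1L, n_trval), ],
      test_pos  = shuffled[seq(n_trval + 1L, n), ],
      train_neg = empty, val_neg = empty, test_neg = empty,
      ratios = ratios, seed = as.integer(seed)
    ),
    class = "edge_split"
  )
}

#' @exportS3Method base::print
print.edge_split <- function(x, ...) {
  cat("<edge_split>\n")
  for (nm in c("train", "val", "test")) {
    cat(sprintf("  %-5s %4d positives, %4d negatives\n", nm,
                nrow(x[[paste0(nm, "_pos")]]), nrow(x[[paste0(nm, "_neg")]])))
  }
  invisible(x)
}

# integer key encoding an (event, disease) pair; doubles are exact well
# beyond any desk-scale q*z
pair_key <- function(event, disease, z) event * z + disease

#' Sample negative (non-)edges from an event–disease graph
#'
#' Draws `n` distinct (event, disease) pairs uniformly without replacement
#' from the complement of the graph's edge set, additionally avoiding the
#' pairs in `exclude` (e.g. negatives already assigned to another split).
#'
#' @param graph An [build_hetero_graph()] object.
#' @param n Number of negatives requested.
#' @param seed Integer seed.
#' @param exclude Optional tibble of `event`, `disease` pairs to avoid.
#' @return A tibble with columns `event`, `disease` (0-based indices).
#' @export
sample_negative_edges <- function(graph, n, seed = 1L, exclude = NULL) {
  stopifnot(inherits(graph, "event_graph"))
  q <- graph$n_events
  z <- graph$n_diseases
  total <- q * z
  forbidden <- pair_key(graph$edges$event, graph$edges$disease, z)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    forbidden <- c(forbidden, pair_key(exclude$event, exclude$disease, z))
  }
  forbidden <- unique(forbidden)
  avail <- total - length(forbidden)
  if (n > avail) {
    abort(sprintf(
      "graph too dense for requested negatives: asked for %d, only %d non-edges available",
      n, avail))
  }
  keys <- if (total <= 1e6) {
    # enumerate the complement exactly; index sampling avoids the
    # length-1 `sample(x, n)` pitfall
    pool <- setdiff(seq_len(total) - 1, forbidden)
    with_seed_(seed, pool[sample.int(length(pool), n)])
  } else {
    sample_keys_rejection(total, forbidden, n, seed)
  }
  tibble(event = as.integer(keys %/% z), disease = as.integer(keys %% z))
}

sample_keys_rejection <- function(total, forbidden, n, seed) {
  with_seed_(seed, {
    got <- numeric(0)
    guard <- 0L
    while (length(got) < n) {
      guard <- guard + 1L
      if (guard > 1000L) abort("negative sampling failed to converge")
      draw <- floor(runif(2L * (n - length(got)) + 10L) * total)
      draw <- draw[!(draw %in% forbidden)]
      got <- unique(c(got, draw))
    }
    got[seq_len(n)]
  })
}

#' Attach sampled negatives to an edge split
#'
#' Samples `ratio` negatives per positive for each of the three splits,
#' sequentially, so that no negative coincides with any observed edge or
#' with a negative of another split.
#'
#' @param split An [split_edges()] object.
#' @param graph The graph the split was built from.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return The split with `train_neg`, `val_neg`, `test_neg` filled.
#' @export
sample_split_negatives <- function(split, graph, ratio = 1, seed = 1L) {
  stopifnot(inherits(split, "edge_split"))
  seeds <- derive_seeds(seed, 3L)
  taken <- NULL
  for (i in seq_along(c("train", "val", "test"))) {
    nm <- c("train", "val", "test")[i]
    n_neg <- round(ratio * nrow(split[[paste0(nm, "_pos")]]))
    neg <- sample_negative_edges(graph, n_neg, seed = seeds[i], exclude = taken)
    split[[paste0(nm, "_neg")]] <- neg
    taken <- bind_rows(taken, neg)
  }
  split
}
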