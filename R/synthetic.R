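#' Simulate drug–target–disease pair tables with planted cluster structure
#'
#' Generates the three pairwise relation tables the pipeline consumes,
#' with a planted signal: drugs, targets and diseases are assigned
#' (balanced, then shuffled) to `n_clusters` latent clusters; drug–target
#' pairs form within a cluster with probability `p_dt` (and across
#' clusters at `0.05 * p_dt`); drug–disease and target–disease
#' associations are Bernoulli(`p_within`) when the two entities share a
#' cluster and Bernoulli(`p_between`) otherwise. Events derived from these
#' tables therefore carry cluster-coherent disease sets, so held-out
#' event–disease links are predictable from the observed structure.
#'
#' @param n_drugs,n_targets,n_diseases Entity counts.
#' @param n_clusters Number of latent clusters (must not exceed
#'   `n_diseases`).
#' @param p_within Within-cluster association probability for the two
#'   entity–disease tables.
#' @param p_between Cross-cluster association probability.
#' @param p_dt Within-cluster drug–target pairing probability.
#' @param seed Integer seed; the output is fully reproducible.
#' @return A [pair_tables()] object with an extra attribute `clusters`: a
#'   tibble (`kind`, `id`, `cluster`) of the ground-truth assignment.
#' @examples
#' tabs <- simulate_pair_tables(n_drugs = 12, n_targets = 8,
#'                              n_diseases = 20, n_clusters = 2, seed = 1)
#' tabs
#' @export
simulate_pair_tables <- function(n_drugs = 60, n_targets = 40,
                                 n_diseases = 120, n_clusters = 4,
                                 p_within = 0.9, p_between = 0.02,
                                 p_dt = 0.3, seed = 1L) {
  stopifnot_scalar_prob(p_within, "p_within")
  stopifnot_scalar_prob(p_between, "p_between")
  stopifnot_scalar_prob(p_dt, "p_dt")
  if (n_clusters < 1 || n_clusters > n_diseases) {
    abort(sprintf(
      "Infeasible config: n_clusters (%d) must be between 1 and n_diseases (%d).",
      n_clusters, n_diseases))
  }

  ids <- list(
    drug    = sprintf("D%03d", seq_len(n_drugs)),
    target  = sprintf("T%03d", seq_len(n_targets)),
    disease = sprintf("Z%03d", seq_len(n_diseases))
  )

  with_seed_(seed, {
    assign_clusters <- function(n) {
      if (n == 0L) return(integer(0))
      sample(rep_len(seq_len(n_clusters), n))
    }
    cl <- lapply(lengths(ids), assign_clusters)
    names(cl) <- names(ids)

    # Bernoulli edge table between two entity sets given per-pair probs
    draw_pairs <- function(ids_a, cl_a, ids_b, cl_b, p_same, p_diff) {
      if (length(ids_a) == 0L || length(ids_b) == 0L) {
        return(tibble(a = character(), b = character()))
      }
      same <- outer(cl_a, cl_b, `==`)
      p <- ifelse(same, p_same, p_diff)
      hit <- matrix(runif(length(p)) < p, nrow = length(ids_a))
      idx <- which(hit, arr.ind = TRUE)
      tibble(a = ids_a[idx[, 1]], b = ids_b[idx[, 2]]) |>
        arrange(a, b)
    }

    dt <- draw_pairs(ids$drug, cl$drug, ids$target, cl$target,
                     p_dt, 0.05 * p_dt)
    dd <- draw_pairs(ids$drug, cl$drug, ids$disease, cl$disease,
                     p_within, p_between)
    td <- draw_pairs(ids$target, cl$target, ids$disease, cl$disease,
                     p_within, p_between)

    out <- pair_tables(dt, dd, td)
    attr(out, "clusters") <- bind_rows(
      tibble(kind = "drug", id = ids$drug, cluster = cl$drug),
      tibble(kind = "target", id = ids$target, cluster = cl$target),
      tibble(kind = "disease", id = ids$disease, cluster = cl$disease)
    )
    out
  })
}

#' A tiny deterministic fixture dataset
#'
#' Hard-coded 3-drug / 3-target / 6-disease tables whose derived events
#' include the canonical example of an event node: the pair (X1, Y1)
#' treating the disease set \{Z1, Z2, Z6\}. Used in documentation and unit
#' tests; identical on every call.
#'
#' @return A [pair_tables()] object.
#' @export
fixture_tables <- function() {
  dt <- tibble(
    a = c("X1", "X2", "X3"),
    b = c("Y1", "Y2", "Y3")
  )
  dd <- tibble(
    a = c("X1", "X1", "X1", "X2", "X2", "X3", "X3"),
    b = c("Z1", "Z2", "Z6", "Z3", "Z4", "Z4", "Z5")
  )
  td <- tibble(
    a = c("Y1", "Y1", "Y1", "Y2", "Y2", "Y3", "Y3"),
    b = c("Z1", "Z2", "Z6", "Z3", "Z4", "Z4", "Z5")
  )
  pair_tables(dt, dd, td)
}
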