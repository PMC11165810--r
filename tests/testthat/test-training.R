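test_that("edge scoring is the embedding dot product", {
  set.seed(1)
  emb <- list(event = matrix(rnorm(5 * 64), 5, 64),
              disease = matrix(rnorm(4 * 64), 4, 64))
  edges <- tibble::tibble(event = c(0L, 2L, 4L), disease = c(0L, 3L, 1L))
  got <- score_edges(emb, edges)
  for (i in 1:3) {
    expect_equal(got[i], oracle_dot(emb$event[edges$event[i] + 1, ],
                                    emb$disease[edges$disease[i] + 1, ]))
  }
  # orthogonal embeddings score zero, identical unit vectors score one
  e2 <- list(event = matrix(c(1, 0), 1), disease = matrix(c(0, 1), 1))
  expect_equal(score_edges(e2, tibble::tibble(event = 0L, disease = 0L)), 0)
  e3 <- list(event = matrix(c(1, 0), 1), disease = matrix(c(1, 0), 1))
  expect_equal(score_edges(e3, tibble::tibble(event = 0L, disease = 0L)), 1)
  expect_error(score_edges(emb, tibble::tibble(event = 9L, disease = 0L)),
               "unknown")
})

test_that("edge probabilities are symmetric sigmoids of the logit", {
  expect_equal(edge_probability(0), 0.5)
  expect_equal(edge_probability(1), 1 / (1 + exp(-1)))
  x <- rnorm(20)
  expect_equal(edge_probability(x) + edge_probability(-x), rep(1, 20))
})

test_that("stable BCE agrees with the naive formula and never overflows", {
  expect_equal(bce_with_logits(0, 1), log(2))
  expect_lt(bce_with_logits(20, 1), 1e-8)
  set.seed(2)
  logits <- rnorm(10, sd = 3)
  labels <- rbinom(10, 1, 0.5)
  expect_equal(bce_with_logits(logits, labels),
               oracle_bce_naive(logits, labels), tolerance = 1e-9)
  expect_equal(bce_with_logits(logits, labels, positive_class_weight = 2.5),
               oracle_bce_naive(logits, labels, w = 2.5), tolerance = 1e-9)
  expect_true(is.finite(bce_with_logits(c(1e4, -1e4), c(0, 1))))
  expect_error(bce_with_logits(c(1, 2), c(1, 2)), "binary")
})

test_that("training reduces the loss on a separable synthetic graph", {
  setup <- small_training_setup(seed = 5)
  fit <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 50L,
                       seed = 5)
  expect_lt(fit$history$loss[50], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("training is bit-reproducible under a fixed seed", {
  setup <- small_training_setup(seed = 6)
  f1 <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 8L, seed = 3)
  f2 <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 8L, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("a zero learning rate leaves parameters untouched", {
  setup <- small_training_setup(seed = 7)
  f1 <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 1L,
                      lr = 0, seed = 2)
  f3 <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 4L,
                      lr = 0, seed = 2)
  expect_equal(f1$final_params, f3$final_params, tolerance = 1e-14)
})

test_that("message passing consumes only training positives", {
  setup <- small_training_setup(seed = 8)
  fit <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 2L, seed = 1)
  expect_identical(fit$mp_edges, setup$split$train_pos)
  key <- function(e) paste(e$event, e$disease)
  expect_length(intersect(key(fit$mp_edges),
                          c(key(setup$split$val_pos),
                            key(setup$split$test_pos))), 0)
})

test_that("the returned checkpoint is at least as good as the final epoch", {
  setup <- small_training_setup(seed = 9)
  fit <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 25L,
                       seed = 4)
  expect_gte(fit$best_val_auc, fit$history$auc[nrow(fit$history)])
  expect_equal(fit$best_val_auc, max(fit$history$auc))
})

test_that("predicted disease rankings follow the decoder scores", {
  setup <- small_training_setup(seed = 10)
  fit <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 10L,
                       seed = 1)
  z <- setup$graph$n_diseases
  all_links <- predict_links(fit, event = 0, threshold = 0)
  expect_equal(nrow(all_links), z)   # vacuous filter keeps every disease
  expect_equal(nrow(predict_links(fit, event = 0, threshold = 1)), 0L)

  # ordering equals a brute-force sort of independently computed dot products
  emb <- fitted_embeddings(fit)
  probs <- vapply(seq_len(z) - 1L, function(j) {
    1 / (1 + exp(-oracle_dot(emb$event[1, ], emb$disease[j + 1, ])))
  }, numeric(1))
  expect_equal(all_links$disease, order(-probs, seq_len(z)) - 1L)
  expect_equal(all_links$probability, sort(probs, decreasing = TRUE))
  expect_error(predict_links(fit, event = setup$graph$n_events), "event")
})

test_that("tidiers expose history and summary; autoplot returns a ggplot", {
  setup <- small_training_setup(seed = 11)
  fit <- fit_event_gnn(setup$graph, setup$split, dim = 8L, epochs = 5L, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "loss", "auc", "accuracy", "f1", "precision",
                     "recall", "aupr"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})
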