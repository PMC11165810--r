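# Decoder, loss, optimizer and the training loop.

#' Score event–disease pairs by embedding dot product
#'
#' The default decoder: the logit for an edge (u, v) is the elementwise
#' product of the event and disease embeddings aggregated (summed) over
#' the embedding dimension.
#'
#' @param embeddings List with matrices `event` and `disease` (from
#'   [encode()]).
#' @param edges Tibble with 0-based `event`, `disease` columns.
#' @return Numeric vector of logits, one per edge.
#' @export
score_edges <- function(embeddings, edges) {
  e <- edges$event + 1L
  d <- edges$disease + 1L
  if (any(e < 1L) || any(e > nrow(embeddings$event)) ||
      any(d < 1L) || any(d > nrow(embeddings$disease))) {
    abort("Edge refers to an unknown node index.")
  }
  rowSums(embeddings$event[e, , drop = FALSE] *
            embeddings$disease[d, , drop = FALSE])
}

#' Convert a logit into an edge probability
#'
#' @param logit Finite numeric vector.
#' @return `sigmoid(logit)`, in (0, 1).
#' @export
edge_probability <- function(logit) sigmoid(logit)

#' Weighted binary cross-entropy on logits
#'
#' Numerically stable form: per-sample loss
#' `w*y*softplus(-x) + (1-y)*softplus(x)`, averaged over samples. Safe
#' for |logit| up to 1e4 and beyond.
#'
#' @param logits Numeric vector.
#' @param labels 0/1 vector of the same length.
#' @param positive_class_weight Weight w applied to positive samples.
#' @return Scalar mean loss.
#' @export
bce_with_logits <- function(logits, labels, positive_class_weight = 1) {
  if (length(logits) != length(labels)) abort("logits and labels differ in length")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  w <- positive_class_weight
  mean(w * labels * softplus(-logits) + (1 - labels) * softplus(logits))
}

# d(loss)/d(logit) for the mean weighted BCE above
bce_grad <- function(logits, labels, positive_class_weight = 1) {
  w <- positive_class_weight
  ((1 - labels) * sigmoid(logits) - w * labels * sigmoid(-logits)) /
    length(logits)
}

# ---- decoder variants -----------------------------------------------------

decode_logits <- function(params, emb, edges) {
  e <- edges$event + 1L
  d <- edges$disease + 1L
  E <- emb$event[e, , drop = FALSE]
  D <- emb$disease[d, , drop = FALSE]
  switch(params$decoder,
    product = rowSums(E * D),
    single_linear = as.numeric(cbind(E, D) %*% params$w_dec) + params$b_dec,
    bilinear = rowSums((E %*% params$B_dec) * D)
  )
}

# Backward through the decoder: given dlogit per edge, accumulate
# gradients on the final embeddings and on decoder parameters.
decode_backward <- function(params, emb, edges, dlogit, grads) {
  e <- edges$event + 1L
  d <- edges$disease + 1L
  E <- emb$event[e, , drop = FALSE]
  D <- emb$disease[d, , drop = FALSE]
  dE_rows <- dD_rows <- NULL
  if (params$decoder == "product") {
    dE_rows <- dlogit * D
    dD_rows <- dlogit * E
  } else if (params$decoder == "single_linear") {
    dim <- params$dim
    w1 <- params$w_dec[seq_len(dim)]
    w2 <- params$w_dec[dim + seq_len(dim)]
    dE_rows <- outer(dlogit, w1)
    dD_rows <- outer(dlogit, w2)
    grads$w_dec <- grads$w_dec + as.numeric(crossprod(cbind(E, D), dlogit))
    grads$b_dec <- grads$b_dec + sum(dlogit)
  } else { # bilinear
    dE_rows <- dlogit * (D %*% Matrix::t(params$B_dec))
    dD_rows <- dlogit * (E %*% params$B_dec)
    grads$B_dec <- grads$B_dec + crossprod(E, dlogit * D)
  }
  dEv <- scatter_add(matrix(0, nrow(emb$event), params$dim), e, dE_rows)
  dDi <- scatter_add(matrix(0, nrow(emb$disease), params$dim), d, dD_rows)
  list(dEv = dEv, dDi = dDi, grads = grads)
}

# ---- nested-list parameter algebra and Adam -------------------------------

# Apply f leafwise over parallel nested lists; matches children by name
# when available so differently ordered structures still align.
nl_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    keys <- names(xs[[1]]) %||% seq_along(xs[[1]])
    out <- lapply(keys, function(k) {
      do.call(nl_map, c(list(f), lapply(xs, `[[`, k)))
    })
    names(out) <- names(xs[[1]])
    out
  } else {
    do.call(f, xs)
  }
}

params_trainable <- function(params) {
  out <- list()
  for (nm in trainable_names(params)) out[[nm]] <- params[[nm]]
  out$layers <- params$layers
  out
}

params_restore <- function(params, theta) {
  for (nm in trainable_names(params)) params[[nm]] <- theta[[nm]]
  params$layers <- theta$layers
  params
}

adam_init <- function(theta) {
  list(m = nl_map(function(x) { x[] <- 0; x }, theta),
       v = nl_map(function(x) { x[] <- 0; x }, theta),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- nl_map(function(g, th) g + weight_decay * th, grads, theta)
  }
  state$m <- nl_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nl_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  theta <- nl_map(function(th, m, v) {
    th - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, theta, state$m, state$v)
  list(theta = theta, state = state)
}

# ---- training -------------------------------------------------------------

#' Fit the event–disease link prediction model
#'
#' Trains the gated convolution+attention encoder with the chosen decoder
#' by full-graph backpropagation and Adam, framing link prediction as
#' binary classification over positive edges and sampled negatives.
#' Message passing in every epoch uses only the training positives, so
#' validation and test edges never leak into the adjacency. Validation
#' metrics are computed every epoch and the parameters with the best
#' validation AUC are returned.
#'
#' @param graph An [build_hetero_graph()] object.
#' @param split An [split_edges()] object built from `graph`; if its
#'   negative sets are empty they are sampled here (1:`negative_ratio`).
#' @param features Optional list of `event` / `disease` feature matrices;
#'   defaults to [event_features()] and [disease_features()] with
#'   dimension `dim`.
#' @param dim Embedding dimension (default 64).
#' @param n_layers Encoder layers (default 2).
#' @param k Neighbour sample size for the convolution branch.
#' @param epochs Training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Edge-batch size (default 3840); smaller splits run
#'   as a single full batch.
#' @param dropout Dropout rate between encoder layers (default 0.6).
#' @param weight_decay L2 penalty added to gradients (default 1e-5).
#' @param negative_ratio Negatives sampled per positive (default 1).
#' @param positive_class_weight BCE weight on positive samples.
#' @param resample_negatives Resample training negatives every epoch
#'   instead of fixing them at split time.
#' @param conv,attention,gate,decoder Architecture switches, see
#'   [init_encoder_params()].
#' @param seed Integer seed controlling every source of randomness.
#' @param permute_labels Permute the training labels (a null-signal
#'   control; leaves validation/test labels intact).
#' @param verbose Print a progress line every 25 epochs.
#' @return An `event_gnn` object: best-validation-AUC `params`,
#'   `final_params`, a `history` tibble (epoch, loss, the six validation
#'   metrics), `best_epoch`, the `split` (with negatives filled), the
#'   message-passing edges, features and configuration.
#' @export
fit_event_gnn <- function(graph, split, features = NULL,
                          dim = 64L, n_layers = 2L, k = 10L,
                          epochs = 200L, lr = 1e-3, batch_size = 3840L,
                          dropout = 0.6, weight_decay = 1e-5,
                          negative_ratio = 1, positive_class_weight = 1,
                          resample_negatives = FALSE,
                          conv = TRUE, attention = TRUE, gate = TRUE,
                          decoder = "product",
                          seed = 1L, permute_labels = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(graph, "event_graph"), inherits(split, "edge_split"))
  if (nrow(split$train_pos) == 0L) abort("empty train split")
  seeds <- derive_seeds(seed, 6L)

  if (is.null(features)) {
    features <- list(
      event = event_features(graph),
      disease = disease_features(graph$n_diseases, dim, seed = seeds[1])
    )
  }
  if (nrow(split$train_neg) == 0L) {
    split <- sample_split_negatives(split, graph, ratio = negative_ratio,
                                    seed = seeds[2])
  }

  params <- init_encoder_params(
    n_events = graph$n_events, n_event_feats = ncol(features$event),
    n_disease_feats = ncol(features$disease),
    dim = dim, n_layers = n_layers, k = k,
    conv = conv, attention = attention, gate = gate, decoder = decoder,
    seed = seeds[3]
  )

  # message passing strictly on training positives
  mp_edges <- split$train_pos
  ctx <- gnn_context(graph$n_events, graph$n_diseases, mp_edges)

  train_edges <- bind_rows(split$train_pos, split$train_neg)
  train_labels <- c(rep(1, nrow(split$train_pos)), rep(0, nrow(split$train_neg)))
  if (permute_labels) {
    train_labels <- with_seed_(seeds[4], sample(train_labels))
  }
  val_edges <- bind_rows(split$val_pos, split$val_neg)
  val_labels <- c(rep(1, nrow(split$val_pos)), rep(0, nrow(split$val_neg)))

  theta <- params_trainable(params)
  opt <- adam_init(theta)
  epoch_seeds <- derive_seeds(seeds[5], epochs)
  resample_seeds <- derive_seeds(seeds[6], epochs)

  history <- vector("list", epochs)
  best <- list(auc = -Inf, theta = theta, epoch = 0L)

  for (ep in seq_len(epochs)) {
    if (resample_negatives && ep > 1L) {
      neg <- sample_negative_edges(
        graph, nrow(split$train_pos) * negative_ratio,
        seed = resample_seeds[ep],
        exclude = bind_rows(split$val_neg, split$test_neg))
      train_edges <- bind_rows(split$train_pos, neg)
      train_labels <- c(rep(1, nrow(split$train_pos)), rep(0, nrow(neg)))
    }

    n_ex <- nrow(train_edges)
    batch_seeds <- derive_seeds(epoch_seeds[ep], 2L)
    ord <- with_seed_(batch_seeds[1], sample.int(n_ex))
    starts <- seq(1L, n_ex, by = batch_size)
    ep_loss <- 0
    for (bi in seq_along(starts)) {
      idx <- ord[seq(starts[bi], min(starts[bi] + batch_size - 1L, n_ex))]
      batch <- train_edges[idx, ]
      labels <- train_labels[idx]

      params <- params_restore(params, theta)
      fwd <- gnn_forward(params, ctx, features$event, features$disease,
                         training = TRUE, dropout = dropout,
                         sample_seed = batch_seeds[2] + bi,
                         keep_cache = TRUE)
      emb <- list(event = fwd$event, disease = fwd$disease)
      logits <- decode_logits(params, emb, batch)
      ep_loss <- ep_loss + bce_with_logits(logits, labels,
                                           positive_class_weight) * length(idx)

      grads <- zero_like_params(params)
      dlogit <- bce_grad(logits, labels, positive_class_weight)
      dec <- decode_backward(params, emb, batch, dlogit, grads)
      dH_final <- rbind(dec$dEv, dec$dDi)
      grads <- gnn_backward(params, ctx, fwd$cache, dH_final)
      for (nm in setdiff(trainable_names(params),
                         c("M_event", "M_disease", "E_event"))) {
        grads[[nm]] <- dec$grads[[nm]]
      }

      step <- adam_step(theta, align_grads(grads, params), opt, lr,
                        weight_decay)
      theta <- step$theta
      opt <- step$state
    }
    ep_loss <- ep_loss / n_ex

    params <- params_restore(params, theta)
    emb_eval <- gnn_forward(params, ctx, features$event, features$disease,
                            training = FALSE)
    val_metrics <- metric_report(
      val_labels,
      edge_probability(decode_logits(params, emb_eval, val_edges)))
    history[[ep]] <- tibble(epoch = ep, loss = ep_loss) |>
      dplyr::bind_cols(val_metrics)
    if (val_metrics$auc > best$auc) {
      best <- list(auc = val_metrics$auc, theta = theta, epoch = ep)
    }
    if (verbose && (ep %% 25L == 0L || ep == 1L)) {
      inform(sprintf("epoch %4d  loss %.5f  val AUC %.5f", ep, ep_loss,
                     val_metrics$auc))
    }
  }

  structure(
    list(
      params = params_restore(params, best$theta),
      final_params = params_restore(params, theta),
      history = bind_rows(history),
      best_epoch = best$epoch,
      best_val_auc = best$auc,
      split = split,
      mp_edges = mp_edges,
      features = features,
      graph = graph,
      config = list(dim = dim, n_layers = n_layers, k = k, epochs = epochs,
                    lr = lr, batch_size = batch_size, dropout = dropout,
                    weight_decay = weight_decay,
                    negative_ratio = negative_ratio,
                    positive_class_weight = positive_class_weight,
                    conv = conv, attention = attention, gate = gate,
                    decoder = decoder, seed = as.integer(seed))
    ),
    class = "event_gnn"
  )
}

# Reorder the gradient structure to the exact shape of theta
# (trainable_names, then layers) so nl_map aligns leaf by leaf.
align_grads <- function(grads, params) {
  out <- list()
  for (nm in trainable_names(params)) out[[nm]] <- grads[[nm]]
  out$layers <- grads$layers
  out
}

#' @exportS3Method base::print
print.event_gnn <- function(x, ...) {
  cat("<event_gnn>\n")
  cat(sprintf("  %d events, %d diseases; %d train / %d val / %d test positives\n",
              x$graph$n_events, x$graph$n_diseases,
              nrow(x$split$train_pos), nrow(x$split$val_pos),
              nrow(x$split$test_pos)))
  cat(sprintf("  dim %d, %d layer(s), decoder '%s'%s%s%s\n",
              x$config$dim, x$config$n_layers, x$config$decoder,
              if (!x$config$conv) ", no conv" else "",
              if (!x$config$attention) ", no attention" else "",
              if (!x$config$gate) ", no gates" else ""))
  cat(sprintf("  best validation AUC %.5f at epoch %d of %d\n",
              x$best_val_auc, x$best_epoch, x$config$epochs))
  invisible(x)
}

#' Embeddings from a fitted model
#'
#' Deterministic evaluation-mode encoding with the best-validation
#' parameters, message passing on the training positives only.
#' @param fit An `event_gnn` object.
#' @param params Parameter set to use (defaults to the best checkpoint).
#' @return List of `event` and `disease` embedding matrices.
#' @export
fitted_embeddings <- function(fit, params = fit$params) {
  ctx <- gnn_context(fit$graph$n_events, fit$graph$n_diseases, fit$mp_edges)
  out <- gnn_forward(params, ctx, fit$features$event, fit$features$disease,
                     training = FALSE)
  out[c("event", "disease")]
}

#' Rank candidate diseases for one event
#'
#' Scores the event against all diseases with the fitted decoder and
#' returns those with probability at or above `threshold`, sorted by
#' decreasing probability (ties broken by disease index).
#'
#' @param fit An `event_gnn` object.
#' @param event 0-based event index.
#' @param threshold Probability cut-off in \[0, 1\].
#' @return Tibble `disease` (0-based index), `disease_id`, `probability`,
#'   `rank`.
#' @export
predict_links <- function(fit, event, threshold = 0.5) {
  stopifnot(inherits(fit, "event_gnn"))
  if (event < 0 || event >= fit$graph$n_events) {
    abort(sprintf("No event with index %s.", format(event)))
  }
  stopifnot_scalar_prob(threshold, "threshold")
  emb <- fitted_embeddings(fit)
  z <- fit$graph$n_diseases
  cand <- tibble(event = rep(as.integer(event), z), disease = seq_len(z) - 1L)
  prob <- edge_probability(decode_logits(fit$params, emb, cand))
  ids <- vocab_ids(fit$graph$vocab, "disease")
  out <- tibble(disease = cand$disease, disease_id = ids[cand$disease + 1L],
                probability = prob)
  out <- out[out$probability >= threshold, ]
  out <- out[order(-out$probability, out$disease), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
predict.event_gnn <- function(object, event, threshold = 0.5, ...) {
  predict_links(object, event = event, threshold = threshold)
}

#' Evaluate a fitted model on labelled edge sets
#'
#' Scores `pos_edges` and `neg_edges`, labels them by membership, and
#' returns the six-metric report.
#'
#' @param fit An `event_gnn` object.
#' @param pos_edges,neg_edges Tibbles of `event`, `disease` pairs;
#'   default to the fit's test split.
#' @param threshold Probability threshold for the confusion-based metrics.
#' @return One-row tibble: `auc`, `accuracy`, `f1`, `precision`,
#'   `recall`, `aupr`.
#' @export
evaluate_edges <- function(fit, pos_edges = fit$split$test_pos,
                           neg_edges = fit$split$test_neg,
                           threshold = 0.5) {
  if (nrow(pos_edges) == 0L || nrow(neg_edges) == 0L) {
    abort("Both positive and negative edge sets must be non-empty.")
  }
  emb <- fitted_embeddings(fit)
  edges <- bind_rows(pos_edges, neg_edges)
  labels <- c(rep(1, nrow(pos_edges)), rep(0, nrow(neg_edges)))
  prob <- edge_probability(decode_logits(fit$params, emb, edges))
  metric_report(labels, prob, threshold = threshold)
}
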