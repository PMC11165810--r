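# Independent brute-force reference implementations. These deliberately
# use straight-line loops and the naive formulas, never the package's
# vectorised code paths.

# events by triple-nested enumeration over the id universes
oracle_events <- function(dt, dd, td) {
  drugs <- sort(unique(c(dt[[1]], dd[[1]])))
  targets <- sort(unique(c(dt[[2]], td[[1]])))
  diseases <- sort(unique(c(dd[[2]], td[[2]])))
  out <- list()
  for (x in drugs) for (y in targets) {
    if (!any(dt[[1]] == x & dt[[2]] == y)) next
    zset <- character(0)
    for (z in diseases) {
      if (any(dd[[1]] == x & dd[[2]] == z) && any(td[[1]] == y & td[[2]] == z)) {
        zset <- c(zset, z)
      }
    }
    if (length(zset)) out[[length(out) + 1L]] <- list(drug = x, target = y,
                                                      diseases = zset)
  }
  out
}

# AUC by exhaustive pairwise concordance, ties 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  }
  tot / (length(pos) * length(neg))
}

# step-wise AUPR by explicit threshold sweep
oracle_aupr <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

oracle_confusion <- function(labels, probs, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(labels)) {
    pred <- probs[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_gate <- function(h, W, b) {
  d <- length(h)
  out <- numeric(d)
  for (t in seq_len(d)) {
    s <- b[t]
    for (c in seq_len(d)) s <- s + W[t, c] * h[c]
    out[t] <- h[t] * (1 / (1 + exp(-s)))
  }
  out
}

oracle_conv <- function(h_self, neighbors, W) {
  d <- length(h_self)
  Z <- numeric(d)
  n <- 1L + if (is.null(neighbors)) 0L else nrow(neighbors)
  for (t in seq_len(d)) {
    acc <- h_self[t]
    if (!is.null(neighbors)) for (j in seq_len(nrow(neighbors))) {
      acc <- acc + neighbors[j, t]
    }
    Z[t] <- acc / n
  }
  cat_vec <- c(h_self, Z)
  out <- numeric(d)
  for (t in seq_len(d)) {
    acc <- 0
    for (c in seq_along(cat_vec)) acc <- acc + W[t, c] * cat_vec[c]
    out[t] <- max(acc, 0)
  }
  out
}

oracle_attention_weights <- function(h_i, neighbors, Wv, a, slope = 0.2) {
  d <- length(h_i)
  ui <- as.numeric(Wv %*% h_i)
  scores <- numeric(nrow(neighbors))
  for (j in seq_len(nrow(neighbors))) {
    uj <- as.numeric(Wv %*% neighbors[j, ])
    raw <- sum(a * c(ui, uj))
    scores[j] <- if (raw > 0) raw else slope * raw
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

oracle_bce_naive <- function(logits, labels, w = 1) {
  p <- 1 / (1 + exp(-logits))
  mean(-(w * labels * log(p) + (1 - labels) * log(1 - p)))
}

oracle_dot <- function(u, v) {
  acc <- 0
  for (t in seq_along(u)) acc <- acc + u[t] * v[t]
  acc
}
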