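# Encoder: per-type projection, sample-and-aggregate convolution branch,
# typed attention branch, sigmoid gate units, residual fusion.
#
# Two parallel implementations live here on purpose:
#  * single-node reference operations (project_features, conv_update,
#    attention_coefficients, attention_update, gate) — the math stated one
#    node at a time, exported and unit-tested;
#  * a vectorised full-graph forward pass (gnn_forward) used for training,
#    which caches every intermediate so gnn_backward() can run analytic
#    backpropagation. Tests check the two agree and that gradients match
#    finite differences.

LRELU_SLOPE <- 0.2

#' Initialise encoder parameters
#'
#' All weight matrices use Glorot-uniform initialisation under `seed`.
#' The trainable event embedding (concatenated with the one-hot event
#' features before projection) is initialised from N(0, 0.1^2).
#'
#' @param n_events Number of event nodes (rows of the trainable event
#'   embedding).
#' @param n_event_feats Width of the raw event feature matrix (the one-hot
#'   disease dimension z).
#' @param n_disease_feats Width of the raw disease feature matrix.
#' @param dim Embedding dimension d.
#' @param n_layers Number of encoder layers L (>= 1).
#' @param k Neighbour sample size for the convolution branch.
#' @param event_embed_dim Width of the trainable event embedding
#'   (default `dim`).
#' @param conv,attention,gate Logical switches for the two branches and
#'   the gate units (used by the ablation harness).
#' @param decoder One of `"product"`, `"single_linear"`, `"bilinear"`.
#' @param seed Integer seed.
#' @return An `encoder_params` list of named parameter arrays plus
#'   hyperparameter fields.
#' @export
init_encoder_params <- function(n_events, n_event_feats, n_disease_feats,
                                dim = 64L, n_layers = 2L, k = 10L,
                                event_embed_dim = dim,
                                conv = TRUE, attention = TRUE, gate = TRUE,
                                decoder = c("product", "single_linear", "bilinear"),
                                seed = 1L) {
  decoder <- match.arg(decoder)
  if (n_layers < 1L) abort("n_layers (L) must be >= 1")
  if (k < 1L) abort("neighbour sample size k must be >= 1")
  if (!conv && !attention) abort("at least one of conv/attention must be active")

  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nrow = nr, ncol = nc)
  }

  with_seed_(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      list(
        Wc = glorot(dim, 2L * dim),
        Wv_event = glorot(dim, dim),
        Wv_disease = glorot(dim, dim),
        a = runif(2L * dim, -0.1, 0.1),
        U = glorot(dim, 2L * dim),
        Wgc = glorot(dim, dim), bgc = numeric(dim),
        Wga = glorot(dim, dim), bga = numeric(dim)
      )
    })
    dec <- switch(decoder,
      product = list(),
      single_linear = list(w_dec = runif(2L * dim, -0.1, 0.1), b_dec = 0),
      bilinear = list(B_dec = glorot(dim, dim))
    )
    structure(
      c(list(
        M_event = glorot(dim, n_event_feats + event_embed_dim),
        M_disease = glorot(dim, n_disease_feats),
        E_event = matrix(rnorm(n_events * event_embed_dim, sd = 0.1),
                         nrow = n_events),
        layers = layers
      ), dec,
      list(dim = dim, n_layers = n_layers, k = k,
           event_embed_dim = event_embed_dim,
           conv = conv, attention = attention, gate = gate,
           decoder = decoder)),
      class = "encoder_params"
    )
  })
}

trainable_names <- function(params) {
  base <- c("M_event", "M_disease", "E_event")
  dec <- switch(params$decoder,
    product = character(0),
    single_linear = c("w_dec", "b_dec"),
    bilinear = "B_dec"
  )
  c(base, dec)
}

# ---- single-node reference operations -------------------------------------

#' Project raw node features into the shared embedding space
#'
#' Applies the per-type transformation h' = M h to every row of `H`.
#'
#' @param H Feature matrix, one node per row.
#' @param M Projection matrix, `d` rows, `ncol(H)` columns.
#' @return Matrix with `nrow(H)` rows and `d` columns.
#' @export
project_features <- function(H, M) {
  H <- as.matrix(H)
  if (ncol(H) != ncol(M)) {
    abort(sprintf("Shape mismatch: features have %d columns, projection expects %d.",
                  ncol(H), ncol(M)))
  }
  H %*% Matrix::t(M)
}

#' Sample neighbours of a node in the event–disease graph
#'
#' Returns the full neighbourhood when the degree is at most `k`,
#' otherwise a uniform sample of `k` distinct neighbours under `seed`.
#' An isolated node yields an empty vector.
#'
#' @param graph An [build_hetero_graph()] object.
#' @param type `"event"` or `"disease"`.
#' @param index 0-based node index.
#' @param k Sample size.
#' @param seed Integer seed.
#' @return 0-based integer vector of neighbour indices (opposite type).
#' @export
sample_neighbors <- function(graph, type = c("event", "disease"), index, k,
                             seed = 1L) {
  type <- match.arg(type)
  n <- if (type == "event") graph$n_events else graph$n_diseases
  if (index < 0 || index >= n) abort(sprintf("No %s node with index %d.", type, index))
  nb <- if (type == "event") {
    graph$edges$disease[graph$edges$event == index]
  } else {
    graph$edges$event[graph$edges$disease == index]
  }
  if (length(nb) <= k) return(sort(nb))
  with_seed_(seed, sort(sample(nb, k)))
}

#' Convolution-branch update for one node
#'
#' Mean-aggregates the node's own vector with its (sampled) neighbour
#' vectors, concatenates the result with the node vector, and maps through
#' a fully connected layer with ReLU: out = relu(W \[h_self || Z\]) with
#' Z = mean(\{h_self\} u neighbours). With no neighbours Z reduces to
#' h_self.
#'
#' @param h_self Numeric vector (length d).
#' @param neighbor_vectors Matrix with one neighbour per row, or NULL.
#' @param W Weight matrix d x 2d.
#' @param aggregate `"mean"` (default), `"sum"` or `"max"`.
#' @return Numeric vector of length d.
#' @export
conv_update <- function(h_self, neighbor_vectors = NULL, W,
                        aggregate = c("mean", "sum", "max")) {
  aggregate <- match.arg(aggregate)
  stacked <- rbind(matrix(h_self, nrow = 1), neighbor_vectors)
  Z <- switch(aggregate,
    mean = colMeans(stacked),
    sum = colSums(stacked),
    max = apply(stacked, 2, max)
  )
  as.numeric(relu(W %*% c(h_self, Z)))
}

#' Attention coefficients over a neighbourhood
#'
#' Raw score for neighbour j: e_ij = leaky_relu(a^T \[W h_i || W h_j\])
#' with negative slope 0.2; returned weights are the softmax over the
#' neighbourhood and sum to 1.
#'
#' @param h_i Centre node vector.
#' @param neighbor_vectors Matrix, one neighbour per row (>= 1 row).
#' @param Wv Attention transform (d x d), indexed by the neighbour type.
#' @param a Attention parameter vector, length 2d.
#' @return Numeric vector of weights, one per neighbour, summing to 1.
#' @export
attention_coefficients <- function(h_i, neighbor_vectors, Wv, a) {
  if (is.null(neighbor_vectors) || nrow(neighbor_vectors) == 0L) {
    abort("attention undefined on empty neighborhood")
  }
  u_i <- as.numeric(Wv %*% h_i)
  d <- length(u_i)
  a1 <- a[seq_len(d)]
  a2 <- a[d + seq_len(d)]
  scores <- apply(neighbor_vectors, 1, function(h_j) {
    u_j <- as.numeric(Wv %*% h_j)
    leaky_relu(sum(a1 * u_i) + sum(a2 * u_j), LRELU_SLOPE)
  })
  w <- exp(scores - max(scores))
  unname(w / sum(w))
}

#' Attention-branch update for one node
#'
#' Aggregates transformed neighbours with the given weights into the
#' semantic-level representation h' = sum_j w_j (Wv h_j), then fuses it
#' with the node-level representation: out = U relu(\[h_i || h'\]), the
#' linear map U restoring dimension d after concatenation.
#'
#' @param h_i Centre node vector.
#' @param neighbor_vectors Matrix, one neighbour per row.
#' @param weights Normalised attention weights (one per neighbour).
#' @param Wv Attention transform (d x d).
#' @param U Fusion map d x 2d.
#' @return Numeric vector of length d.
#' @export
attention_update <- function(h_i, neighbor_vectors, weights, Wv, U) {
  transformed <- neighbor_vectors %*% Matrix::t(Wv)
  h_prime <- as.numeric(crossprod(transformed, weights))
  as.numeric(U %*% relu(c(h_i, h_prime)))
}

#' Sigmoid gate unit
#'
#' Elementwise filter out = h * sigmoid(W h + b) controlling how much of
#' a branch's output flows on; each output magnitude is strictly below the
#' corresponding input magnitude.
#'
#' @param h Numeric vector.
#' @param W Gate weight matrix (d x d).
#' @param b Gate bias vector (length d).
#' @return Numeric vector, same length as `h`.
#' @export
gate <- function(h, W, b) {
  as.numeric(h * sigmoid(W %*% h + b))
}

# ---- vectorised full-graph forward / backward -----------------------------

# Precomputed message-passing context shared across a training run.
# mp_edges: tibble(event, disease), 0-based. Unified node indexing:
# events 1..q, diseases q+1..q+z (1-based).
gnn_context <- function(q, z, mp_edges) {
  N <- q + z
  ev <- mp_edges$event + 1L
  di <- mp_edges$disease + 1L + q

  make_group <- function(t, s) {
    utgt <- sort(unique(t))
    code <- match(t, utgt)
    list(t = t, s = s, utgt = utgt, code = code,
         idx = split(seq_along(t), code))
  }

  # adjacency lists in unified indexing, for conv-branch sampling
  adj <- vector("list", N)
  if (length(ev)) {
    by_ev <- split(di, ev)
    adj[as.integer(names(by_ev))] <- by_ev
    by_di <- split(ev, di)
    adj[as.integer(names(by_di))] <- by_di
  }

  list(
    q = q, z = z, N = N,
    adj = adj,
    to_event = make_group(t = ev, s = di),   # messages disease -> event
    to_disease = make_group(t = di, s = ev)  # messages event -> disease
  )
}

# Row-stochastic self+neighbour aggregation matrix with <= k sampled
# neighbours per node. k = Inf keeps full neighbourhoods (deterministic).
conv_sampler <- function(ctx, k, seed = NULL) {
  build <- function() {
    rows <- integer(0); cols <- integer(0)
    for (i in seq_len(ctx$N)) {
      nb <- ctx$adj[[i]]
      if (!is.null(nb) && length(nb) > k) nb <- sample(nb, k)
      rows <- c(rows, rep.int(i, 1L + length(nb)))
      cols <- c(cols, i, nb)
    }
    S <- sparseMatrix(i = rows, j = cols, x = 1, dims = c(ctx$N, ctx$N))
    S / Matrix::rowSums(S)
  }
  if (is.finite(k)) with_seed_(seed, build()) else build()
}

# Attention over one directed-edge group. Returns contribution to Hattn
# plus the cache needed for backprop.
attn_group_forward <- function(grp, u, Hattn) {
  if (length(grp$t) == 0L) return(list(Hattn = Hattn, cache = NULL))
  d <- ncol(u)
  bu <- as.numeric(u %*% attr(u, "a1"))
  cu <- as.numeric(u %*% attr(u, "a2"))
  epre <- bu[grp$t] + cu[grp$s]
  e <- leaky_relu(epre, LRELU_SLOPE)
  m <- group_max(e, grp$code, grp$idx)
  w <- exp(e - m)
  denom <- as.numeric(rowsum(w, grp$code))
  alpha <- w / denom[grp$code]
  contrib <- rowsum(alpha * u[grp$s, , drop = FALSE], grp$code)
  Hattn[grp$utgt, ] <- Hattn[grp$utgt, , drop = FALSE] + contrib
  list(Hattn = Hattn, cache = list(epre = epre, alpha = alpha))
}

# Full forward pass. Returns embeddings split by type; with keep_cache a
# cache sufficient for gnn_backward().
gnn_forward <- function(params, ctx, A_event, X_disease,
                        training = FALSE, dropout = 0,
                        sample_seed = NULL, keep_cache = FALSE) {
  q <- ctx$q; z <- ctx$z; d <- params$dim
  L <- params$n_layers
  k_eff <- if (training) params$k else Inf

  X_event <- cbind(A_event, params$E_event)
  H <- rbind(project_features(X_event, params$M_event),
             project_features(X_disease, params$M_disease))

  seeds <- if (training) derive_seeds(sample_seed %||% 1L, 2L * L) else rep(NA, 2L * L)
  cache <- list(X_event = X_event, X_disease = X_disease, layers = vector("list", L))

  for (l in seq_len(L)) {
    lay <- params$layers[[l]]
    lcache <- list(H = H)
    H_next <- H  # residual

    if (params$conv) {
      S <- conv_sampler(ctx, k_eff, seed = seeds[2L * l - 1L])
      Zc <- as.matrix(S %*% H)
      Cpre <- cbind(H, Zc) %*% Matrix::t(lay$Wc)
      C <- relu(Cpre)
      if (params$gate) {
        sc <- sigmoid(sweep(C %*% Matrix::t(lay$Wgc), 2, lay$bgc, `+`))
        Gc <- C * sc
      } else {
        sc <- NULL; Gc <- C
      }
      H_next <- H_next + Gc
      lcache <- c(lcache, list(S = S, Zc = Zc, Cpre = Cpre, C = C, sc = sc))
    }

    if (params$attention) {
      a1 <- lay$a[seq_len(d)]
      a2 <- lay$a[d + seq_len(d)]
      uE <- H %*% Matrix::t(lay$Wv_event)
      uD <- H %*% Matrix::t(lay$Wv_disease)
      attr(uE, "a1") <- a1; attr(uE, "a2") <- a2
      attr(uD, "a1") <- a1; attr(uD, "a2") <- a2
      Hattn <- matrix(0, ctx$N, d)
      ge <- attn_group_forward(ctx$to_event, uD, Hattn)     # disease-type messages
      gd <- attn_group_forward(ctx$to_disease, uE, ge$Hattn) # event-type messages
      Hattn <- gd$Hattn
      P <- cbind(H, Hattn)
      Apre <- relu(P)
      Aout <- Apre %*% Matrix::t(lay$U)
      if (params$gate) {
        sa <- sigmoid(sweep(Aout %*% Matrix::t(lay$Wga), 2, lay$bga, `+`))
        Ga <- Aout * sa
      } else {
        sa <- NULL; Ga <- Aout
      }
      H_next <- H_next + Ga
      lcache <- c(lcache, list(uE = uE, uD = uD,
                               att_event = ge$cache, att_disease = gd$cache,
                               P = P, Apre = Apre, Aout = Aout, sa = sa))
    }

    if (training && dropout > 0 && l < L) {
      mask <- with_seed_(seeds[2L * l],
                         matrix(as.numeric(runif(ctx$N * d) >= dropout),
                                ctx$N, d) / (1 - dropout))
      H_next <- H_next * mask
      lcache$mask <- mask
    }

    cache$layers[[l]] <- lcache
    H <- H_next
  }

  out <- list(event = H[seq_len(q), , drop = FALSE],
              disease = H[q + seq_len(z), , drop = FALSE])
  if (keep_cache) out$cache <- cache
  out
}

attn_group_backward <- function(grp, gcache, u, dHattn, du, da_acc) {
  if (length(grp$t) == 0L) return(list(du = du, da = da_acc))
  a1 <- attr(u, "a1"); a2 <- attr(u, "a2")
  alpha <- gcache$alpha
  dHt <- dHattn[grp$t, , drop = FALSE]
  us <- u[grp$s, , drop = FALSE]
  dalpha <- rowSums(dHt * us)
  du <- scatter_add(du, grp$s, alpha * dHt)
  sums_t <- as.numeric(rowsum(alpha * dalpha, grp$code))
  de <- alpha * (dalpha - sums_t[grp$code])
  dpre <- de * ifelse(gcache$epre > 0, 1, LRELU_SLOPE)
  dbu <- as.numeric(rowsum(dpre, grp$code))
  du <- scatter_add(du, grp$utgt, outer(dbu, a1))
  du <- scatter_add(du, grp$s, outer(dpre, a2))
  ut <- u[grp$t, , drop = FALSE]
  da <- c(colSums(dpre * ut), colSums(dpre * us))
  list(du = du, da = da_acc + da)
}

# Analytic gradients of a scalar loss w.r.t. all trainable parameters,
# given dH_final (N x d) from the decoder/loss backward.
gnn_backward <- function(params, ctx, cache, dH_final) {
  d <- params$dim
  L <- params$n_layers
  grads <- zero_like_params(params)
  dH <- dH_final

  for (l in rev(seq_len(L))) {
    lay <- params$layers[[l]]
    lc <- cache$layers[[l]]
    if (!is.null(lc$mask)) dH <- dH * lc$mask
    H <- lc$H
    dH_in <- dH  # residual path

    if (params$conv) {
      dGc <- dH
      if (params$gate) {
        t2 <- (dGc * lc$C) * lc$sc * (1 - lc$sc)
        dC <- dGc * lc$sc + t2 %*% lay$Wgc
        grads$layers[[l]]$Wgc <- grads$layers[[l]]$Wgc + crossprod(t2, lc$C)
        grads$layers[[l]]$bgc <- grads$layers[[l]]$bgc + colSums(t2)
      } else {
        dC <- dGc
      }
      dCpre <- dC * (lc$Cpre > 0)
      grads$layers[[l]]$Wc <- grads$layers[[l]]$Wc +
        crossprod(dCpre, cbind(H, lc$Zc))
      dcat <- dCpre %*% lay$Wc
      dH_in <- dH_in + dcat[, seq_len(d), drop = FALSE]
      dZc <- dcat[, d + seq_len(d), drop = FALSE]
      dH_in <- dH_in + as.matrix(Matrix::t(lc$S) %*% dZc)
    }

    if (params$attention) {
      dGa <- dH
      if (params$gate) {
        t2 <- (dGa * lc$Aout) * lc$sa * (1 - lc$sa)
        dAout <- dGa * lc$sa + t2 %*% lay$Wga
        grads$layers[[l]]$Wga <- grads$layers[[l]]$Wga + crossprod(t2, lc$Aout)
        grads$layers[[l]]$bga <- grads$layers[[l]]$bga + colSums(t2)
      } else {
        dAout <- dGa
      }
      dApre <- dAout %*% lay$U
      grads$layers[[l]]$U <- grads$layers[[l]]$U + crossprod(dAout, lc$Apre)
      dP <- dApre * (lc$P > 0)
      dH_in <- dH_in + dP[, seq_len(d), drop = FALSE]
      dHattn <- dP[, d + seq_len(d), drop = FALSE]

      duD <- matrix(0, ctx$N, d)
      duE <- matrix(0, ctx$N, d)
      da <- numeric(2L * d)
      be <- attn_group_backward(ctx$to_event, lc$att_event, lc$uD,
                                dHattn, duD, da)
      duD <- be$du
      bd <- attn_group_backward(ctx$to_disease, lc$att_disease, lc$uE,
                                dHattn, duE, be$da)
      duE <- bd$du
      grads$layers[[l]]$a <- grads$layers[[l]]$a + bd$da
      grads$layers[[l]]$Wv_disease <- grads$layers[[l]]$Wv_disease +
        crossprod(duD, H)
      grads$layers[[l]]$Wv_event <- grads$layers[[l]]$Wv_event +
        crossprod(duE, H)
      dH_in <- dH_in + duD %*% lay$Wv_disease + duE %*% lay$Wv_event
    }

    dH <- dH_in
  }

  q <- ctx$q
  dH_evt <- dH[seq_len(q), , drop = FALSE]
  dH_dis <- dH[q + seq_len(ctx$z), , drop = FALSE]
  grads$M_event <- grads$M_event + crossprod(dH_evt, cache$X_event)
  grads$M_disease <- grads$M_disease + crossprod(dH_dis, cache$X_disease)
  dX_evt <- dH_evt %*% params$M_event
  emb_cols <- ncol(cache$X_event) - params$event_embed_dim + seq_len(params$event_embed_dim)
  grads$E_event <- grads$E_event + dX_evt[, emb_cols, drop = FALSE]
  grads
}

zero_like_params <- function(params) {
  zero <- function(x) { x[] <- 0; x }
  g <- list(
    M_event = zero(params$M_event),
    M_disease = zero(params$M_disease),
    E_event = zero(params$E_event),
    layers = lapply(params$layers, function(lay) lapply(lay, zero))
  )
  for (nm in setdiff(trainable_names(params), c("M_event", "M_disease", "E_event"))) {
    g[[nm]] <- zero(params[[nm]])
  }
  g
}

#' Encode a graph into node embeddings
#'
#' Runs the full encoder: per-type feature projection, then `n_layers`
#' rounds in which the convolution branch (neighbour sampling, mean
#' aggregation, fully connected + ReLU) and the attention branch
#' (typed attention weights, weighted aggregation, concat + linear
#' fusion) run in parallel, each branch passes through a sigmoid gate,
#' and the gated branches are summed with a residual connection from the
#' layer input. Dropout is applied between layers during training only;
#' with `training = FALSE` the pass uses full neighbourhoods and is a
#' deterministic pure function of (graph, features, params).
#'
#' @param graph An [build_hetero_graph()] object, or a tibble of
#'   (`event`, `disease`) message-passing edges.
#' @param features List with matrices `event` (q x z one-hot) and
#'   `disease` (z x f).
#' @param params An [init_encoder_params()] object.
#' @param seed Seed for neighbour sampling / dropout when `training`.
#' @param training Apply neighbour subsampling and dropout.
#' @param dropout Dropout rate in \[0, 1).
#' @return List with embedding matrices `event` (q x d) and `disease`
#'   (z x d).
#' @export
encode <- function(graph, features, params, seed = 1L,
                   training = FALSE, dropout = 0) {
  edges <- if (inherits(graph, "event_graph")) graph$edges else graph
  q <- nrow(features$event)
  z <- nrow(features$disease)
  ctx <- gnn_context(q, z, edges)
  out <- gnn_forward(params, ctx, features$event, features$disease,
                     training = training, dropout = dropout,
                     sample_seed = seed)
  out[c("event", "disease")]
}
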