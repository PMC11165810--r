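test_that("feature projection is the per-row linear map", {
  set.seed(1)
  H <- matrix(rnorm(15), 3, 5)
  expect_equal(project_features(H, diag(5)), H)
  expect_equal(project_features(H, matrix(0, 4, 5)), matrix(0, 3, 4))
  M <- matrix(rnorm(20), 4, 5)
  got <- project_features(H, M)
  for (i in 1:3) expect_equal(got[i, ], as.numeric(M %*% H[i, ]))
  expect_error(project_features(H, matrix(0, 4, 6)), "mismatch")
})

test_that("neighbour sampling returns full under-full neighbourhoods and true subsets", {
  g <- make_test_graph(4, 10, tibble::tibble(
    event = c(0L, 0L, rep(1L, 10)),
    disease = c(0L, 1L, 0:9)
  ))
  expect_equal(sample_neighbors(g, "event", 0, k = 5, seed = 1), c(0L, 1L))
  s <- sample_neighbors(g, "event", 1, k = 3, seed = 1)
  expect_length(s, 3)
  expect_true(all(s %in% 0:9))
  expect_identical(s, sample_neighbors(g, "event", 1, k = 3, seed = 1))
  expect_equal(sample_neighbors(g, "event", 2, k = 3, seed = 1), integer(0))
  expect_equal(sample_neighbors(g, "disease", 0, k = 5, seed = 1), c(0L, 1L))
})

test_that("convolution update matches the scalar-by-scalar composition", {
  set.seed(2)
  d <- 4
  W <- matrix(rnorm(d * 2 * d), d, 2 * d)
  h <- rnorm(d)
  nb <- matrix(rnorm(3 * d), 3, d)
  expect_equal(conv_update(h, nb, W), oracle_conv(h, nb, W))
  # no neighbours: Z reduces to the node itself
  expect_equal(conv_update(h, NULL, W),
               as.numeric(pmax(W %*% c(h, h), 0)))
  # null propagation
  expect_equal(conv_update(rep(0, d), matrix(0, 2, d), W), rep(0, d))
})

test_that("attention coefficients are a softmax over leaky-relu scores", {
  set.seed(3)
  d <- 4
  Wv <- matrix(rnorm(d * d), d, d)
  a <- rnorm(2 * d)
  h <- rnorm(d)
  expect_equal(attention_coefficients(h, matrix(rnorm(d), 1, d), Wv, a), 1)
  u <- rnorm(d)
  expect_equal(attention_coefficients(h, rbind(u, u), Wv, a), c(0.5, 0.5))
  nb <- matrix(rnorm(3 * d), 3, d)
  w <- attention_coefficients(h, nb, Wv, a)
  expect_equal(w, oracle_attention_weights(h, nb, Wv, a))
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_error(attention_coefficients(h, NULL, Wv, a), "empty neighborhood")
})

test_that("attention update aggregates transformed neighbours by weight", {
  set.seed(4)
  d <- 3
  Wv <- matrix(rnorm(d * d), d, d)
  U <- matrix(rnorm(d * 2 * d), d, 2 * d)
  h <- rnorm(d)
  nb <- matrix(rnorm(4 * d), 4, d)
  # degenerate attention picks out one neighbour
  expect_equal(attention_update(h, nb, c(1, 0, 0, 0), Wv, U),
               as.numeric(U %*% pmax(c(h, Wv %*% nb[1, ]), 0)))
  # convexity fixed point: identical neighbours ignore the weights
  u <- rnorm(d)
  same <- rbind(u, u, u)
  for (w in list(c(1, 0, 0), c(0.2, 0.3, 0.5))) {
    expect_equal(attention_update(h, same, w, Wv, U),
                 as.numeric(U %*% pmax(c(h, Wv %*% u), 0)))
  }
  # term-by-term summation oracle
  w <- c(0.1, 0.4, 0.25, 0.25)
  hp <- colSums(w * t(apply(nb, 1, function(x) as.numeric(Wv %*% x))))
  expect_equal(attention_update(h, nb, w, Wv, U),
               as.numeric(U %*% pmax(c(h, hp), 0)))
})

test_that("the gate unit filters elementwise through a sigmoid", {
  set.seed(5)
  d <- 4
  h <- rnorm(d)
  expect_equal(gate(h, matrix(0, d, d), rep(0, d)), 0.5 * h)
  # saturated gate passes the signal through
  expect_equal(gate(h, matrix(0, d, d), rep(8, d)), h, tolerance = 4e-4)
  W <- matrix(rnorm(d * d), d, d)
  b <- rnorm(d)
  expect_equal(gate(h, W, b), oracle_gate(h, W, b))
  # gated magnitude never exceeds the input magnitude
  for (s in 1:20) {
    h <- rnorm(d); W <- matrix(rnorm(d * d), d, d); b <- rnorm(d)
    expect_true(all(abs(gate(h, W, b)) <= abs(h)))
  }
})

test_that("encode is deterministic, pure without dropout, and equivariant", {
  g <- make_test_graph(6, 8, random_edges(6, 8, 20, seed = 6))
  feats <- list(event = event_features(g), disease = disease_features(8, 5, 1))
  p <- init_encoder_params(6, 8, 5, dim = 4, n_layers = 2, seed = 3)
  e1 <- encode(g, feats, p)
  e2 <- encode(g, feats, p)
  expect_identical(e1, e2)
  # training mode with the same seed is also reproducible
  t1 <- encode(g, feats, p, seed = 9, training = TRUE, dropout = 0.3)
  t2 <- encode(g, feats, p, seed = 9, training = TRUE, dropout = 0.3)
  expect_identical(t1, t2)

  # permuting event indices permutes embedding rows identically
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  g_perm <- make_test_graph(6, 8, tibble::tibble(
    event = match(g$edges$event + 1L, perm) - 1L,
    disease = g$edges$disease
  ))
  p_perm <- p
  p_perm$E_event <- p$E_event[perm, ]
  feats_perm <- list(event = feats$event[perm, ], disease = feats$disease)
  e_perm <- encode(g_perm, feats_perm, p_perm)
  expect_equal(e_perm$event[match(seq_len(6), perm), ], e1$event,
               tolerance = 1e-12)
  expect_equal(e_perm$disease, e1$disease, tolerance = 1e-12)
})

test_that("with zero layer weights the encoder reduces to the projected inputs", {
  g <- make_test_graph(4, 5, random_edges(4, 5, 12, seed = 7))
  feats <- list(event = event_features(g), disease = disease_features(5, 3, 2))
  p <- init_encoder_params(4, 5, 3, dim = 3, n_layers = 2, seed = 4)
  for (l in seq_along(p$layers)) {
    p$layers[[l]] <- lapply(p$layers[[l]], function(x) { x[] <- 0; x })
  }
  emb <- encode(g, feats, p)
  H0 <- rbind(project_features(cbind(feats$event, p$E_event), p$M_event),
              project_features(feats$disease, p$M_disease))
  expect_equal(emb$event, H0[1:4, ], tolerance = 1e-12)
  expect_equal(emb$disease, H0[5:9, ], tolerance = 1e-12)
})

test_that("one encoder layer matches the composition of the single-node operations", {
  # straight-line per-node reimplementation of one full layer (full
  # neighbourhoods, no dropout) compared against the vectorised encoder
  g <- make_test_graph(3, 4, tibble::tibble(event = c(0L, 0L, 1L, 2L),
                                            disease = c(0L, 1L, 1L, 3L)))
  feats <- list(event = event_features(g), disease = disease_features(4, 3, 5))
  p <- init_encoder_params(3, 4, 3, dim = 3, n_layers = 1, seed = 8)
  emb <- encode(g, feats, p)

  H0 <- rbind(project_features(cbind(feats$event, p$E_event), p$M_event),
              project_features(feats$disease, p$M_disease))
  lay <- p$layers[[1]]
  nbrs <- list(c(4, 5), 5, 7, 1, c(1, 2), integer(0), 3)  # unified 1-based
  expected <- matrix(0, 7, 3)
  for (i in 1:7) {
    nb <- nbrs[[i]]
    nbmat <- if (length(nb)) H0[nb, , drop = FALSE] else NULL
    cpart <- conv_update(H0[i, ], nbmat, lay$Wc)
    gc <- gate(cpart, lay$Wgc, lay$bgc)
    if (length(nb)) {
      Wv <- if (i <= 3) lay$Wv_disease else lay$Wv_event
      w <- attention_coefficients(H0[i, ], nbmat, Wv, lay$a)
      apart <- attention_update(H0[i, ], nbmat, w, Wv, lay$U)
    } else {
      apart <- as.numeric(lay$U %*% pmax(c(H0[i, ], rep(0, 3)), 0))
    }
    ga <- gate(apart, lay$Wga, lay$bga)
    expected[i, ] <- H0[i, ] + gc + ga
  }
  expect_equal(emb$event, expected[1:3, ], tolerance = 1e-10)
  expect_equal(emb$disease, expected[4:7, ], tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  g_edges <- tibble::tibble(event = c(0L, 0L, 1L, 1L, 2L),
                            disease = c(0L, 1L, 1L, 2L, 3L))
  q <- 3L; z <- 4L; d <- 3L
  feats <- list(event = matrix(rbinom(q * z, 1, 0.5), q, z),
                disease = matrix(rnorm(z * 4), z, 4))
  params <- init_encoder_params(q, z, 4, dim = d, n_layers = 2, seed = 7)
  ctx <- eventlink:::gnn_context(q, z, g_edges)
  batch <- tibble::tibble(event = c(0L, 1L, 2L, 0L), disease = c(0L, 2L, 3L, 3L))
  labels <- c(1, 1, 1, 0)
  loss_fn <- function(p) {
    f <- eventlink:::gnn_forward(p, ctx, feats$event, feats$disease)
    bce_with_logits(eventlink:::decode_logits(p, f, batch), labels)
  }
  fwd <- eventlink:::gnn_forward(params, ctx, feats$event, feats$disease,
                                 keep_cache = TRUE)
  emb <- list(event = fwd$event, disease = fwd$disease)
  logits <- eventlink:::decode_logits(params, emb, batch)
  dec <- eventlink:::decode_backward(params, emb, batch,
                                     eventlink:::bce_grad(logits, labels),
                                     eventlink:::zero_like_params(params))
  g <- eventlink:::gnn_backward(params, ctx, fwd$cache,
                                rbind(dec$dEv, dec$dDi))
  check <- function(get, set, ga) {
    arr <- get(params)
    for (i in sample(length(arr), min(4, length(arr)))) {
      eps <- 1e-6
      fd <- (loss_fn(set(params, replace(arr, i, arr[i] + eps))) -
             loss_fn(set(params, replace(arr, i, arr[i] - eps)))) / (2 * eps)
      expect_equal(get(ga)[i], fd, tolerance = 1e-5)
    }
  }
  check(function(p) p$M_event, function(p, v) { p$M_event <- v; p }, g)
  check(function(p) p$E_event, function(p, v) { p$E_event <- v; p }, g)
  for (l in 1:2) for (nm in c("Wc", "Wv_event", "Wv_disease", "a", "U",
                              "Wgc", "bga")) {
    check(function(p) p$layers[[l]][[nm]],
          function(p, v) { p$layers[[l]][[nm]] <- v; p },
          list(layers = g$layers))
  }
})

test_that("layer count must be positive", {
  expect_error(init_encoder_params(3, 4, 4, dim = 3, n_layers = 0), "L")
})
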