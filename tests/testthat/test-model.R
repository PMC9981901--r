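# The model forward pass: GRU semantics, layer updates, super-node
# readout, fusion, and agreement between the reference R implementation,
# the compiled fast path, and the straight-line oracle.

zero_params <- function(hyper) {
  p <- init_params(hyper)
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  out <- zero(unclass(p))
  class(out) <- "mogat_params"
  out
}

test_that("GRU update matches the closed-form endpoints", {
  d <- 4L
  gru0 <- list(W_r = matrix(0, d, 2 * d), W_z = matrix(0, d, 2 * d),
               W_h = matrix(0, d, 2 * d))
  h <- c(1, -2, 0.5, 3)
  res <- gru_update(h, rep(0, d), gru0)
  expect_equal(res$r, rep(0.5, d))
  expect_equal(res$z, rep(0.5, d))
  expect_equal(res$h_candidate, rep(0, d))
  expect_equal(res$h_new, 0.5 * h)

  # z -> 1 keeps the previous state; z -> 0 takes the candidate
  big <- gru0
  big$W_z <- matrix(50, d, 2 * d)
  expect_equal(gru_update(h, rep(1, d), big)$h_new, h, tolerance = 1e-10)
  small <- gru0
  small$W_z <- matrix(-50, d, 2 * d)
  res <- gru_update(h, rep(1, d), small)
  expect_equal(res$h_new, res$h_candidate, tolerance = 1e-10)
  expect_error(gru_update(h, rep(0, 3), gru0), "dimension")
})

test_that("GRU gates stay strictly inside their ranges", {
  set.seed(5)
  d <- 5L
  for (i in 1:20) {
    gru <- list(W_r = matrix(stats::rnorm(2 * d * d, sd = 2), d, 2 * d),
                W_z = matrix(stats::rnorm(2 * d * d, sd = 2), d, 2 * d),
                W_h = matrix(stats::rnorm(2 * d * d, sd = 2), d, 2 * d))
    res <- gru_update(stats::rnorm(d), stats::rnorm(d), gru)
    expect_true(all(res$r > 0 & res$r < 1))
    expect_true(all(res$z > 0 & res$z < 1))
    expect_true(all(res$h_candidate > -1 & res$h_candidate < 1))
  }
})

test_that("initial node states are the projected features through the leaky ReLU", {
  hy <- tiny_hyper()
  g <- build_graph("CNN")
  set.seed(2)
  p <- init_params(hy)
  h0 <- init_node_states(g, p)
  # independent matrix multiply
  ref <- g$atom_features %*% t(p$proj)
  ref <- ifelse(ref >= 0, ref, 0.01 * ref)
  expect_equal(h0, ref, tolerance = 1e-12)
  p0 <- zero_params(hy)
  expect_true(all(init_node_states(g, p0) == 0))
})

test_that("a single-atom molecule attends to itself with weight one", {
  hy <- tiny_hyper()
  g <- build_graph("C")
  set.seed(3)
  p <- init_params(hy)
  lay <- node_embedding_layer(init_node_states(g, p), g, p$layers[[1]], 1L)
  expect_equal(lay$attention[[1]]$neighbors, 1L)
  expect_equal(lay$attention[[1]]$weights, 1.0)
  ro <- super_node_readout(lay$states, p$super[[1]], hy$tau)
  expect_equal(ro$atom_attention, 1.0)
})

test_that("symmetric two-atom graphs stay symmetric through a layer", {
  hy <- tiny_hyper()
  g <- fixture_graphs(golden_dir = NULL)$ethane
  set.seed(6)
  p <- init_params(hy)
  st <- init_node_states(g, p)
  expect_equal(st[1, ], st[2, ])
  lay <- node_embedding_layer(st, g, p$layers[[1]], 1L)
  expect_equal(lay$states[1, ], lay$states[2, ], tolerance = 1e-12)
})

test_that("layer and readout match the straight-line oracle on a 3-atom path", {
  hy <- tiny_hyper()
  g <- fixture_graphs(golden_dir = NULL)$path3
  set.seed(7)
  p <- init_params(hy)
  fw <- forward(g, p, hy)
  expect_equal(fw$prediction, oracle_forward(g, p, hy), tolerance = 1e-8)
})

test_that("super-node readout is permutation equivariant", {
  hy <- tiny_hyper()
  g <- build_graph("CCO")
  set.seed(8)
  p <- init_params(hy)
  st <- init_node_states(g, p)
  ro <- super_node_readout(st, p$super[[1]], hy$tau)
  perm <- c(3L, 1L, 2L)
  ro_p <- super_node_readout(st[perm, ], p$super[[1]], hy$tau)
  expect_equal(ro_p$embedding, ro$embedding, tolerance = 1e-6)
  expect_equal(ro_p$atom_attention, ro$atom_attention[perm], tolerance = 1e-6)
  expect_equal(sum(ro$atom_attention), 1, tolerance = 1e-6)
})

test_that("all-zero parameters predict exactly the head bias", {
  hy <- tiny_hyper()
  p0 <- zero_params(hy)
  p0$fc_b <- 1.7
  fw <- forward(build_graph("CNN"), p0, hy)
  expect_equal(fw$prediction, 1.7)
})

test_that("kappa = 1 degenerates to a single-order readout with identity fusion", {
  hy <- tiny_hyper(kappa = 1L)
  set.seed(9)
  p <- init_params(hy)
  fw <- forward(build_graph("CNN"), p, hy)
  expect_equal(nrow(fw$trace$G), 1L)
  expect_equal(fw$trace$layer_weights, rbind(1))
  expect_equal(fw$trace$final_embedding, as.numeric(fw$trace$G[1, ]))
})

test_that("forward is deterministic and permutation invariant", {
  hy <- tiny_hyper(d_g = 8L)
  set.seed(10)
  p <- init_params(hy)
  g <- build_graph("OC1CCCCC1")
  f1 <- forward(g, p, hy)
  f2 <- forward(g, p, hy)
  expect_identical(f1$prediction, f2$prediction)
  set.seed(11)
  for (i in 1:5) {
    perm <- sample(g$n_atoms)
    fp <- forward(permute_graph(g, perm), p, hy)
    expect_equal(fp$prediction, f1$prediction, tolerance = 1e-5)
  }
})

test_that("attention rows sum to one everywhere in the trace", {
  hy <- tiny_hyper()
  set.seed(12)
  p <- init_params(hy)
  fw <- forward(build_graph("CC(=O)O"), p, hy)
  for (lay in fw$trace$layers) {
    for (att in lay$edge_attention) {
      expect_equal(sum(att$weights), 1, tolerance = 1e-6)
    }
    expect_equal(sum(lay$atom_attention), 1, tolerance = 1e-6)
  }
  expect_equal(unname(rowSums(fw$trace$layer_weights)), rep(1, hy$kappa),
               tolerance = 1e-6)
})

test_that("compiled fast path agrees with the R reference implementation", {
  set.seed(13)
  hy <- tiny_hyper(kappa = 3L, tau = 2L, d_g = 9L)
  p <- init_params(hy)
  for (smi in c("C", "CNN", "c1ccccc1", "CC(=O)O")) {
    g <- build_graph(smi)
    fr <- forward(g, p, hy)
    fc <- mogat:::forward_fast(g, p, hy)
    expect_equal(fc$prediction, fr$prediction, tolerance = 1e-10, info = smi)
    expect_equal(fc$G, fr$trace$G, tolerance = 1e-10, info = smi)
    expect_equal(fc$atom_attention,
                 do.call(rbind, fr$trace$atom_attention),
                 tolerance = 1e-10, info = smi)
  }
  # and with dropout masks supplied explicitly
  hy_d <- hyper_params(kappa = 3L, tau = 2L, d_g = 9L, dropout_rate = 0.4)
  g <- build_graph("CNN")
  set.seed(14)
  masks <- dropout_masks(g$n_atoms, hy_d)
  fr <- forward(g, p, hy, masks = masks)
  fc <- mogat:::forward_fast(g, p, hy, masks = masks)
  expect_equal(fc$prediction, fr$prediction, tolerance = 1e-10)
})

test_that("compiled gradients match central finite differences", {
  set.seed(15)
  hy <- tiny_hyper(kappa = 2L, tau = 2L, d_g = 5L)
  p <- init_params(hy)
  g <- build_graph("CNN", target = 1.34)
  tn <- mogat:::graph_tensors(g)
  gr <- mogat:::.mogat_grad_cpp(tn$X, tn$off, tn$idx, tn$pairB, unclass(p),
                                hy$tau, tn$y, NULL)
  flat <- unlist(unclass(p), use.names = FALSE)
  gflat <- unlist(gr$grads, use.names = FALSE)
  lossfn <- function(th) {
    pp <- utils::relist(th, skeleton = unclass(p))
    pr <- mogat:::.mogat_forward_cpp(tn$X, tn$off, tn$idx, tn$pairB, pp,
                                     hy$tau, NULL)$prediction
    (pr - tn$y)^2
  }
  idx <- sort(sample(length(flat), 80))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (lossfn(up) - lossfn(dn)) / (2 * eps)
  }, numeric(1))
  relerr <- abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx]))
  expect_lt(max(relerr), 1e-4)
})

test_that("parameter count is a deterministic function of the hyperparameters", {
  hy <- hyper_params(kappa = 2L, tau = 2L, d_g = 10L)
  set.seed(16)
  expected <- local({
    d <- 10L
    per_layer <- function(first) {
      (2 * d + if (first) 10 else 0) + d * d + 3 * d * 2 * d  # w, V, GRU
    }
    sup <- 2 * d + d * d + 3 * d * 2 * d
    d * 39 + per_layer(TRUE) + per_layer(FALSE) + 2 * sup + d + 1
  })
  expect_equal(count_params(init_params(hy)), expected)
  expect_equal(count_params(init_params(hy)), expected)  # independent of RNG
})

test_that("checkpoints round-trip and validate shapes", {
  hy <- tiny_hyper(d_g = 5L)
  set.seed(17)
  p <- init_params(hy)
  model <- structure(list(params = p, hyper = hy, best_epoch = 3L,
                          val_rmse = 0.5), class = "mogat_model")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params$proj, p$proj)
  expect_equal(back$hyper$d_g, 5L)
  g <- build_graph("CNN")
  expect_equal(predict(back, g), predict(model, g))
  # corrupt a shape
  bad <- readRDS(path)
  bad$params$fc_w <- bad$params$fc_w[-1]
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "shapes")
})
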