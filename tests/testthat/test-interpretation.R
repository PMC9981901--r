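# Atom attribution and substitution experiments.

fit_model_stub <- function(hy, seed = 23) {
  set.seed(seed)
  structure(list(params = init_params(hy), hyper = hy),
            class = "mogat_model")
}

test_that("a single-atom molecule gets importance one", {
  hy <- tiny_hyper()
  set.seed(22)
  fw <- forward(build_graph("C"), init_params(hy), hy)
  imp <- atom_importance(fw)
  expect_equal(imp$scores, 1.0)
})

test_that("importance respects molecular symmetry and normalization", {
  hy <- tiny_hyper(d_g = 8L)
  set.seed(24)
  p <- init_params(hy)
  # OCO: the two terminal oxygens are automorphic
  fw <- forward(build_graph("OCO"), p, hy)
  imp <- atom_importance(fw)
  expect_equal(sum(imp$scores), 1, tolerance = 1e-6)
  expect_true(all(imp$scores >= 0))
  expect_equal(imp$scores[1], imp$scores[3], tolerance = 1e-6)
})

test_that("importance equals a brute-force recomputation from the trace", {
  hy <- tiny_hyper()
  g <- fixture_graphs(golden_dir = NULL)$path3
  set.seed(25)
  p <- init_params(hy)
  fw <- forward(g, p, hy)
  imp <- atom_importance(fw)
  # recompute with explicit loops over the stored attention tensors
  A <- fw$trace$layer_weights
  w <- numeric(hy$kappa)
  for (k in seq_len(hy$kappa)) w[k] <- mean(A[, k])
  raw <- rep(0, g$n_atoms)
  for (k in seq_len(hy$kappa)) {
    raw <- raw + w[k] * fw$trace$atom_attention[[k]]
  }
  expect_equal(imp$scores, raw / sum(raw), tolerance = 1e-8)
})

test_that("importance is permutation-invariant up to atom relabeling", {
  hy <- tiny_hyper(d_g = 8L)
  set.seed(26)
  p <- init_params(hy)
  g <- build_graph("CCN")
  perm <- c(3L, 1L, 2L)
  imp <- atom_importance(forward(g, p, hy))
  imp_p <- atom_importance(forward(permute_graph(g, perm), p, hy))
  expect_equal(imp_p$scores, imp$scores[perm], tolerance = 1e-6)
})

test_that("substituting the middle nitrogen of methyl hydrazine gives ethylamine", {
  g <- build_graph("CNN")
  sub <- substitute_atom(g, 2L, "C")
  expect_equal(sort(sub$mol$symbols), c("C", "C", "N"))
  expect_equal(nrow(sub$bonds), 2L)
  # features equal a direct build of the substituted molecule
  ref <- build_graph("CCN")
  expect_equal(sub$atom_features[order(sub$mol$symbols), ],
               ref$atom_features[order(ref$mol$symbols), ])
})

test_that("substituting an atom by itself is a no-op", {
  g <- build_graph("CNN")
  sub <- substitute_atom(g, 2L, "N")
  expect_equal(sub$atom_features, g$atom_features)
  expect_equal(sub$bond_features, g$bond_features)
})

test_that("aromaticity-breaking substitutions are rejected", {
  furan <- build_graph("c1ccoc1")
  expect_error(substitute_atom(furan, 4L, "C"), "aromatic")
  # valence violation: nitrogen cannot carry four bonds
  neop <- build_graph("CC(C)(C)C")
  expect_error(substitute_atom(neop, 2L, "N"), "valence")
  expect_error(substitute_atom(neop, 9L, "N"), "out of range")
})

test_that("substitution experiments report both sides and a zero-delta no-op", {
  hy <- tiny_hyper(d_g = 8L)
  model <- fit_model_stub(hy)
  g <- build_graph("CNN")
  rep0 <- substitution_experiment(model, g, 2L, "N")
  expect_equal(rep0$delta, 0)
  expect_identical(rep0$original_prediction, rep0$modified_prediction)
  rep1 <- substitution_experiment(model, g, 2L, "C")
  expect_s3_class(rep1$original_importance, "atom_importance")
  expect_s3_class(rep1$modified_importance, "atom_importance")
  expect_equal(rep1$delta,
               rep1$modified_prediction - rep1$original_prediction)
  expect_equal(rep1$replacement$old_symbol, "N")
})

test_that("importance exports round-trip losslessly", {
  hy <- tiny_hyper()
  set.seed(27)
  p <- init_params(hy)
  g <- build_graph("CNN")
  imp <- atom_importance(forward(g, p, hy))
  path <- tempfile(fileext = ".csv")
  export_importance(g, imp, path)
  back <- read_importance(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$score, imp$scores, tolerance = 1e-15)
  expect_equal(back$atom_index, 1:3)
  expect_equal(back$symbol, c("C", "N", "N"))
  # empty input writes a header-only file
  export_importance(list(), list(), path)
  expect_equal(nrow(read_importance(path)), 0L)
})
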