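# Splitting protocol, training behaviour and random hyperparameter search.
# Training tests run at reduced embedding dimension; the full-size
# benchmark lives in the acceptance suite.

make_tiny_dataset <- function(n = 40, seed = 5) {
  ds <- generate_dataset(synthetic_spec(n_molecules = n, seed = seed,
                                        size_range = c(2L, 6L)))
  mapply(build_graph, ds$data$smiles, ds$data$target, SIMPLIFY = FALSE)
}

test_that("splits use floor-then-remainder arithmetic", {
  s10 <- split_dataset(10, seed = 1)
  expect_equal(lengths(s10), c(train = 8L, val = 1L, test = 1L))
  s <- split_dataset(1128, seed = 1)
  expect_equal(lengths(s), c(train = 902L, val = 112L, test = 114L))
  # disjoint and exhaustive
  expect_equal(sort(c(s$train, s$val, s$test)), 1:1128)
  expect_identical(split_dataset(1128, seed = 9), split_dataset(1128, seed = 9))
  expect_error(split_dataset(2), "at least 3")
})

test_that("evaluate computes RMSE and R^2 with the documented conventions", {
  hy <- tiny_hyper(d_g = 4L)
  set.seed(18)
  model <- structure(list(params = init_params(hy), hyper = hy),
                     class = "mogat_model")
  g <- build_graph("CNN")
  pred <- predict(model, g)
  # perfect prediction
  g$target <- pred
  expect_warning(evaluate(model, list(g)), "zero spread")
  ev <- suppressWarnings(evaluate(model, list(g)))
  expect_equal(ev$rmse, 0, tolerance = 1e-12)
  expect_true(is.na(ev$r_squared))
  # hand-computed case: preds (0,0) vs y (1,-1) has RMSE 1 and R^2 0
  resid <- c(0, 0) - c(1, -1)
  expect_equal(sqrt(mean(resid^2)), 1)
  expect_equal(1 - sum(resid^2) / sum((c(1, -1) - 0)^2), 0)
  expect_error(evaluate(model, list()), "empty")
})

test_that("zero epochs returns the initialization unchanged", {
  graphs <- make_tiny_dataset()
  hy <- tiny_hyper(d_g = 6L, seed = 3L)
  hy$epochs <- 0L
  m <- train(graphs[1:30], graphs[31:40], hy)
  set.seed(hy$seed)
  expect_equal(m$params$proj, init_params(hy)$proj)
  expect_equal(m$best_epoch, 0L)
})

test_that("training fits constant targets and reduces the loss", {
  graphs <- make_tiny_dataset()
  const <- lapply(graphs, function(g) { g$target <- 2.5; g })
  hy <- hyper_params(kappa = 2L, tau = 1L, d_g = 12L, dropout_rate = 0,
                     learning_rate = 0.01, epochs = 200L, seed = 2L)
  m <- train(const[1:30], const[31:40], hy, batch_size = 8L)
  preds <- predict(m, const[31:40])
  expect_true(all(abs(preds - 2.5) < 0.1))
  # loss decreases over training on the real synthetic targets
  hy2 <- hyper_params(kappa = 2L, tau = 1L, d_g = 12L, dropout_rate = 0.2,
                      learning_rate = 0.01, epochs = 50L, seed = 2L)
  m2 <- train(graphs[1:30], graphs[31:40], hy2)
  expect_lt(m2$history$train_loss[50], m2$history$train_loss[1])
  expect_equal(nrow(m2$history), 50L)
  expect_true(all(is.finite(m2$history$val_rmse)))
})

test_that("training is reproducible for a fixed seed", {
  graphs <- make_tiny_dataset()
  hy <- hyper_params(kappa = 1L, tau = 1L, d_g = 8L, epochs = 3L, seed = 4L)
  m1 <- train(graphs[1:30], graphs[31:40], hy)
  m2 <- train(graphs[1:30], graphs[31:40], hy)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$fc_w, m2$params$fc_w)
})

test_that("random search samples inside the canonical grid and ranks by RMSE", {
  graphs <- make_tiny_dataset()
  grid <- search_grid()
  rs <- random_search(graphs, budget = 3, seed = 6, epochs = 1L,
                      d_g_max = 150L)
  expect_equal(nrow(rs$leaderboard), 3L)
  expect_true(all(rs$leaderboard$kappa %in% grid$kappa))
  expect_true(all(rs$leaderboard$tau %in% grid$tau))
  expect_true(all(rs$leaderboard$d_g %in% grid$d_g))
  expect_true(all(rs$leaderboard$dropout_rate %in% grid$dropout_rate))
  expect_true(all(rs$leaderboard$learning_rate %in% grid$learning_rate))
  expect_true(!is.unsorted(rs$leaderboard$val_rmse))
  expect_equal(rs$best$d_g,
               rs$leaderboard$d_g[1])
  rs2 <- random_search(graphs, budget = 3, seed = 6, epochs = 1L,
                       d_g_max = 150L)
  expect_identical(rs$leaderboard, rs2$leaderboard)
  # budget 1 returns the single sampled configuration
  rs1 <- random_search(graphs, budget = 1, seed = 8, epochs = 1L,
                       d_g_max = 100L)
  expect_equal(nrow(rs1$leaderboard), 1L)
})

test_that("the repeated protocol reports the arithmetic mean over repeats", {
  graphs <- make_tiny_dataset(40)
  hy <- hyper_params(kappa = 1L, tau = 1L, d_g = 6L, epochs = 1L, seed = 1L)
  res <- run_protocol(graphs, hy, n_repeats = 5L, seed = 3L)
  expect_equal(nrow(res$per_repeat), 5L)
  expect_equal(res$rmse, mean(res$per_repeat$rmse))
  expect_equal(res$r_squared, mean(res$per_repeat$r_squared))
})
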