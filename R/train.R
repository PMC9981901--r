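# Training protocol: random 80/10/10 splits with repeats, Adam with L2
# weight decay and best-on-validation parameter selection, and random
# hyperparameter search over the canonical grid.

#' Split a dataset into train/validation/test index sets
#'
#' Sizes are `floor(0.8 n)`, `floor(0.1 n)` and the remainder, after a
#' seeded shuffle. The three sets are disjoint and exhaustive.
#'
#' @param n number of molecules (or a list of graphs)
#' @param seed shuffle seed
#' @param train_fraction,val_fraction fractions for the first two sets
#' @return list with integer index vectors `train`, `val`, `test`
#' @export
split_dataset <- function(n, seed = 1L, train_fraction = 0.8,
                          val_fraction = 0.1) {
  if (is.list(n)) n <- length(n)
  if (n < 3L) stop("need at least 3 molecules to split", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(train_fraction * n)
  n_val <- floor(val_fraction * n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n]))
}

params_add <- function(a, b, scale = 1) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- params_add(a[[nm]], b[[nm]], scale)
    a
  } else a + scale * b
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(flat, skeleton) {
  out <- utils::relist(flat, skeleton = unclass(skeleton))
  class(out) <- "mogat_params"
  out
}

#' Train the model
#'
#' Minimizes mean squared error with Adam and L2 weight decay, evaluating
#' the validation RMSE after every epoch and keeping the parameters that
#' achieved the best one. Dropout masks are resampled per molecule and
#' epoch; gradients are averaged over mini-batches and clipped to a global
#' norm of 5 before the Adam step.
#'
#' @param train_graphs,val_graphs lists of `mol_graph` objects with targets
#' @param hyper a [hyper_params()] object
#' @param batch_size molecules per Adam step
#' @param verbose print per-epoch losses
#' @return a `mogat_model`: best parameters, hyperparameters, training
#'   `history` (per-epoch train loss and validation RMSE), `best_epoch`
#'   and `val_rmse`
#' @export
train <- function(train_graphs, val_graphs, hyper, batch_size = 32L,
                  verbose = FALSE) {
  stopifnot(length(train_graphs) > 0L, length(val_graphs) > 0L)
  set.seed(hyper$seed)
  params <- init_params(hyper)
  skeleton <- params
  theta <- flatten_params(params)

  train_t <- lapply(train_graphs, graph_tensors)
  val_t <- lapply(val_graphs, graph_tensors)
  y_val <- vapply(val_graphs, function(g) g$target, numeric(1))
  y_train <- vapply(train_graphs, function(g) g$target, numeric(1))
  Xs <- lapply(train_t, `[[`, "X")
  offs <- lapply(train_t, `[[`, "off")
  idxs <- lapply(train_t, `[[`, "idx")
  pairBs <- lapply(train_t, `[[`, "pairB")
  vXs <- lapply(val_t, `[[`, "X")
  voffs <- lapply(val_t, `[[`, "off")
  vidxs <- lapply(val_t, `[[`, "idx")
  vpairBs <- lapply(val_t, `[[`, "pairB")

  use_dropout <- hyper$dropout_rate > 0
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(rmse = Inf, theta = theta, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_rmse = numeric(0))

  val_rmse <- function(th) {
    p <- relist_params(th, skeleton)
    preds <- .mogat_predict_batch_cpp(vXs, voffs, vidxs, vpairBs,
                                      unclass(p), hyper$tau)
    sqrt(mean((preds - y_val)^2))
  }

  if (hyper$epochs == 0L) {
    return(structure(list(params = params, hyper = hyper, history = history,
                          best_epoch = 0L, val_rmse = val_rmse(theta)),
                     class = "mogat_model"))
  }

  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample(length(train_t))
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, length(ord))]
      p <- relist_params(theta, skeleton)
      masks <- if (use_dropout) {
        lapply(batch, function(i) dropout_masks(nrow(train_t[[i]]$X), hyper))
      }
      res <- .mogat_grad_batch_cpp(Xs[batch], offs[batch], idxs[batch],
                                   pairBs[batch], unclass(p), hyper$tau,
                                   y_train[batch], masks)
      batch_loss <- res$loss
      if (!is.finite(batch_loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      }
      g <- flatten_params(res$grads) / length(batch) +
        hyper$weight_decay * theta
      gn <- sqrt(sum(g^2))
      if (gn > 5) g <- g * (5 / gn)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - hyper$learning_rate * mhat / (sqrt(vhat) + eps)
      epoch_loss <- epoch_loss + batch_loss
      nb <- nb + length(batch)
    }
    epoch_loss <- epoch_loss / nb
    rmse <- val_rmse(theta)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_rmse = rmse))
    if (rmse < best$rmse) best <- list(rmse = rmse, theta = theta,
                                       epoch = epoch)
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  val RMSE %.4f",
                      epoch, epoch_loss, rmse))
    }
  }
  structure(list(params = relist_params(best$theta, skeleton), hyper = hyper,
                 history = history, best_epoch = best$epoch,
                 val_rmse = best$rmse),
            class = "mogat_model")
}

#' Evaluate a trained model on a test set
#'
#' @param model a `mogat_model`
#' @param test_graphs non-empty list of `mol_graph` objects with targets
#' @return list with `rmse`, `r_squared` (`NA` with a warning when the
#'   test targets have zero spread), `residuals` (predicted minus
#'   experimental), `predictions` and `targets`
#' @export
evaluate <- function(model, test_graphs) {
  if (length(test_graphs) == 0L) stop("empty test set", call. = FALSE)
  preds <- predict(model, test_graphs)
  y <- vapply(test_graphs, function(g) g$target, numeric(1))
  resid <- preds - y
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else {
    warning("R^2 undefined: test targets have zero spread", call. = FALSE)
    NA_real_
  }
  list(rmse = rmse, r_squared = r2, residuals = resid,
       predictions = preds, targets = y)
}

#' Repeated random-split protocol
#'
#' Repeats the 80/10/10 random split `n_repeats` times, trains a model on
#' each split and reports per-repeat metrics with their arithmetic mean.
#'
#' @param graphs full dataset (list of `mol_graph`)
#' @param hyper a [hyper_params()] object (its seed is offset per repeat)
#' @param n_repeats number of repeats
#' @param seed base seed controlling the splits
#' @return list with `per_repeat` (data.frame of rmse/r_squared per repeat),
#'   `rmse` and `r_squared` (means), and the last repeat's model
#' @export
run_protocol <- function(graphs, hyper, n_repeats = 5L, seed = 1L) {
  rows <- NULL
  model <- NULL
  for (rep in seq_len(n_repeats)) {
    sp <- split_dataset(length(graphs), seed = seed + rep - 1L)
    hy <- hyper
    hy$seed <- hyper$seed + rep - 1L
    model <- train(graphs[sp$train], graphs[sp$val], hy)
    ev <- evaluate(model, graphs[sp$test])
    rows <- rbind(rows, data.frame(repeat_id = rep, rmse = ev$rmse,
                                   r_squared = ev$r_squared))
  }
  list(per_repeat = rows, rmse = mean(rows$rmse),
       r_squared = mean(rows$r_squared), model = model)
}

#' Random hyperparameter search
#'
#' Samples `budget` configurations uniformly from the canonical grid
#' ([search_grid()]), trains each on the given split and ranks them by
#' validation RMSE.
#'
#' @param graphs dataset (list of `mol_graph`)
#' @param budget number of sampled configurations
#' @param seed RNG seed (sampling, split and training)
#' @param grid candidate values per hyperparameter
#' @param epochs,d_g_max optional overrides to keep searches desk-scale:
#'   epochs per candidate, and a cap on the sampled embedding dimension
#'   (`NULL` keeps the full grid)
#' @return list with `best` (a [hyper_params()] object) and `leaderboard`
#'   (data.frame sorted by validation RMSE)
#' @export
random_search <- function(graphs, budget, seed = 1L, grid = search_grid(),
                          epochs = 30L, d_g_max = NULL) {
  stopifnot(budget >= 1L)
  if (!is.null(d_g_max)) grid$d_g <- grid$d_g[grid$d_g <= d_g_max]
  set.seed(seed)
  configs <- lapply(seq_len(budget), function(i) {
    hyper_params(kappa = sample(grid$kappa, 1L), tau = sample(grid$tau, 1L),
                 d_g = sample(grid$d_g, 1L),
                 dropout_rate = sample(grid$dropout_rate, 1L),
                 learning_rate = sample(grid$learning_rate, 1L),
                 epochs = epochs, seed = seed)
  })
  sp <- split_dataset(length(graphs), seed = seed)
  lb <- NULL
  for (i in seq_along(configs)) {
    hy <- configs[[i]]
    val <- tryCatch(train(graphs[sp$train], graphs[sp$val], hy)$val_rmse,
                    error = function(e) Inf)
    lb <- rbind(lb, data.frame(config = i, kappa = hy$kappa, tau = hy$tau,
                               d_g = hy$d_g, dropout_rate = hy$dropout_rate,
                               learning_rate = hy$learning_rate,
                               val_rmse = val))
  }
  lb <- lb[order(lb$val_rmse), ]
  list(best = configs[[lb$config[1]]], leaderboard = lb)
}

#' Save a model checkpoint
#'
#' @param model a `mogat_model`
#' @param path destination file
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "mogat-checkpoint", version = 1L,
              hyper = unclass(model$hyper), params = unclass(model$params),
              best_epoch = model$best_epoch, val_rmse = model$val_rmse)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint, validating parameter shapes
#'
#' @param path checkpoint file written by [save_checkpoint()]
#' @return a `mogat_model`
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mogat-checkpoint")) {
    stop("not a model checkpoint", call. = FALSE)
  }
  hyper <- do.call(hyper_params, obj$hyper[c("kappa", "tau", "d_g",
                                             "dropout_rate", "learning_rate",
                                             "weight_decay", "epochs", "seed")])
  params <- obj$params
  class(params) <- "mogat_params"
  d <- hyper$d_g
  ok <- identical(dim(params$proj), c(d, atom_feature_length())) &&
    length(params$layers) == hyper$kappa &&
    length(params$super) == hyper$kappa &&
    length(params$fc_w) == d &&
    all(vapply(params$layers, function(l) {
      identical(dim(l$W_r), c(d, 2L * d)) && identical(dim(l$V), c(d, d))
    }, logical(1)))
  if (!ok) stop("checkpoint parameter shapes are inconsistent", call. = FALSE)
  structure(list(params = params, hyper = hyper, history = NULL,
                 best_epoch = obj$best_epoch, val_rmse = obj$val_rmse),
            class = "mogat_model")
}
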