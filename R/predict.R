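# Fast prediction path through the compiled core.

# CSR tensors consumed by the compiled forward/backward; computed once per
# graph and cached on the graph object by the training loop
graph_tensors <- function(graph) {
  n <- graph$n_atoms
  idx <- integer(0)
  off <- integer(n + 1L)
  pair_feats <- vector("list", 0L)
  for (v in seq_len(n)) {
    nbrs <- neighbors_of(graph, v)
    idx <- c(idx, nbrs - 1L)
    for (nn in nbrs) {
      pair_feats[[length(pair_feats) + 1L]] <- bond_feature_between(graph, v, nn)
    }
    off[v + 1L] <- length(idx)
  }
  list(X = graph$atom_features, off = off, idx = idx,
       pairB = matrix(unlist(pair_feats), nrow = bond_feature_length()),
       y = graph$target)
}

forward_fast <- function(graph, params, hyper, masks = NULL, tensors = NULL) {
  tn <- if (is.null(tensors)) graph_tensors(graph) else tensors
  .mogat_forward_cpp(tn$X, tn$off, tn$idx, tn$pairB, unclass(params),
                     hyper$tau, masks)
}

#' Predict logS for molecular graphs
#'
#' @param object a trained `mogat_model`
#' @param graphs a single `mol_graph` or a list of them
#' @param ... unused
#' @return numeric vector of predictions
#' @export
predict.mogat_model <- function(object, graphs, ...) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  vapply(graphs, function(g) {
    forward_fast(g, object$params, object$hyper)$prediction
  }, numeric(1))
}

#' @export
print.mogat_model <- function(x, ...) {
  cat(sprintf(
    "<mogat_model> kappa=%d tau=%d d_g=%d; best epoch %s (val RMSE %.4f)\n",
    x$hyper$kappa, x$hyper$tau, x$hyper$d_g,
    if (is.null(x$best_epoch)) "-" else x$best_epoch,
    if (is.null(x$val_rmse)) NA_real_ else x$val_rmse))
  invisible(x)
}
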