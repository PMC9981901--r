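# Atom-level attribution and atom-substitution experiments.

#' Atom importance scores from a forward trace
#'
#' Each message-passing layer's super-node readout places attention
#' weights over the atoms; the per-layer weight is the column mean of the
#' layer-fusion attention matrix (how much all queries attend to that
#' layer). The combined score per atom is the fusion-weighted sum of the
#' per-layer atom attentions, normalized to sum to one.
#'
#' @param fw a `mogat_forward` object from [forward()]
#' @return object of class `atom_importance`: `scores` (per atom, summing
#'   to 1), `per_layer` (kappa x n matrix of raw atom attentions) and
#'   `layer_weights`
#' @export
atom_importance <- function(fw) {
  tr <- fw$trace
  kappa <- nrow(tr$G)
  n <- tr$n_atoms
  per_layer <- do.call(rbind, tr$atom_attention)
  w <- colMeans(rbind(tr$layer_weights))
  scores <- as.numeric(t(per_layer) %*% w)
  scores <- scores / sum(scores)
  structure(list(scores = scores, per_layer = per_layer, layer_weights = w),
            class = "atom_importance")
}

#' @export
print.atom_importance <- function(x, ...) {
  cat("<atom_importance>", paste(sprintf("%.3f", x$scores), collapse = " "),
      "\n")
  invisible(x)
}

#' Replace one atom's element and re-derive the molecule
#'
#' The replacement edits the molecular graph (bond skeleton preserved),
#' emits a fresh SMILES and re-featurizes it, so implicit hydrogens,
#' hybridization and aromaticity are recomputed consistently. The
#' replaced atom is reset to a neutral, isotope-free state; chemically
#' invalid replacements (valence violations, broken aromatic rings)
#' raise an error.
#'
#' @param graph a `mol_graph`
#' @param index 1-based atom index to replace
#' @param new_symbol element symbol of the replacement
#' @return a re-featurized `mol_graph` (atom order may differ from the
#'   input; it follows the emitted SMILES)
#' @export
substitute_atom <- function(graph, index, new_symbol) {
  mol <- graph$mol
  if (index < 1L || index > length(mol$symbols)) {
    stop("atom index out of range", call. = FALSE)
  }
  mol$symbols[index] <- new_symbol
  mol$charge[index] <- 0L
  mol$radical[index] <- 0L
  mol$atoms[[index]]$isotope <- NA_integer_
  mol$atoms[[index]]$chiral <- ""
  mol$atoms[[index]]$hcount <- NA_integer_  # re-derive on parse
  smiles <- write_smiles(mol)
  build_graph(smiles)
}

#' Atom-substitution experiment
#'
#' Predicts the property before and after replacing one atom and pairs
#' the predictions with both molecules' atom importance maps.
#'
#' @param model a trained `mogat_model`
#' @param graph a `mol_graph`
#' @param index atom index to replace
#' @param new_symbol element symbol of the replacement
#' @return object of class `substitution_report`: `original`/`modified`
#'   predictions, `delta` (modified - original), both `atom_importance`
#'   maps, both graphs and a description of the edit
#' @export
substitution_experiment <- function(model, graph, index, new_symbol) {
  modified <- substitute_atom(graph, index, new_symbol)
  fw0 <- forward(graph, model$params, model$hyper)
  fw1 <- forward(modified, model$params, model$hyper)
  structure(list(
    original_prediction = fw0$prediction,
    modified_prediction = fw1$prediction,
    delta = fw1$prediction - fw0$prediction,
    original_importance = atom_importance(fw0),
    modified_importance = atom_importance(fw1),
    original_graph = graph, modified_graph = modified,
    replacement = list(index = index, old_symbol = graph$mol$symbols[index],
                       new_symbol = new_symbol)
  ), class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("<substitution_report> %s -> %s at atom %d: %.4f -> %.4f (delta %+0.4f)\n",
              x$replacement$old_symbol, x$replacement$new_symbol,
              x$replacement$index, x$original_prediction,
              x$modified_prediction, x$delta))
  invisible(x)
}

#' Export atom importance scores to CSV
#'
#' One row per atom with the molecule's SMILES, atom index, element
#' symbol and score, written at full precision so that a read-back
#' reproduces the scores exactly.
#'
#' @param graphs a `mol_graph` or list of them (may be empty)
#' @param importances matching `atom_importance` object(s)
#' @param path output file
#' @export
export_importance <- function(graphs, importances, path) {
  if (inherits(graphs, "mol_graph")) {
    graphs <- list(graphs)
    importances <- list(importances)
  }
  rows <- data.frame(smiles = character(0), atom_index = integer(0),
                     symbol = character(0), score = character(0))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    sc <- importances[[i]]$scores
    rows <- rbind(rows, data.frame(
      smiles = g$smiles, atom_index = seq_len(g$n_atoms),
      symbol = g$mol$symbols, score = sprintf("%.17g", sc)))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back an importance export
#'
#' @param path file written by [export_importance()]
#' @return data.frame with columns smiles, atom_index, symbol, score
#' @export
read_importance <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}
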