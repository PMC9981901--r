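# The multi-order graph attention model: initial projection, kappa
# attention+GRU node-embedding layers, a per-layer super-node readout
# updated tau times, scaled dot-product fusion of the per-layer graph
# embeddings, and a one-layer fully connected prediction head.
#
# This file holds the reference R implementation, which records a full
# trace for interpretation; training uses the compiled fast path in
# src/mogat_core.cpp, which is pinned to this implementation by tests.

#' Model hyperparameters
#'
#' @param kappa number of node-embedding (message-passing) layers; each
#'   additional layer widens the neighbouring order absorbed by an atom
#'   state by one bond
#' @param tau number of super-node (graph-embedding) GRU updates per layer
#' @param d_g embedding dimension
#' @param dropout_rate dropout applied to context vectors and to the fused
#'   embedding during training
#' @param learning_rate Adam step size
#' @param weight_decay L2 penalty coefficient
#' @param epochs maximum training epochs
#' @param seed RNG seed used for initialization, shuffling and dropout
#' @return object of class `mogat_hyper`
#' @export
hyper_params <- function(kappa = 2L, tau = 2L, d_g = 200L,
                         dropout_rate = 0.2, learning_rate = 0.01,
                         weight_decay = 1e-5, epochs = 60L, seed = 1L) {
  stopifnot(kappa >= 1L, tau >= 1L, d_g >= 1L,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, weight_decay >= 0, epochs >= 0L)
  structure(list(kappa = as.integer(kappa), tau = as.integer(tau),
                 d_g = as.integer(d_g), dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "mogat_hyper")
}

#' Hyperparameter search grid
#'
#' The canonical random-search ranges: kappa and tau in 1..6, embedding
#' dimension from 100 to 400 in steps of 50, dropout from 0.1 to 0.5 in
#' steps of 0.1, and learning rate in (0.1, 0.01, 0.001, 0.0001).
#' @return named list of candidate values per hyperparameter
#' @export
search_grid <- function() {
  list(kappa = 1:6, tau = 1:6,
       d_g = c(100L, 150L, 200L, 250L, 300L, 350L, 400L),
       dropout_rate = c(0.1, 0.2, 0.3, 0.4, 0.5),
       learning_rate = c(0.1, 0.01, 0.001, 0.0001))
}

glorot <- function(nrow, ncol = 1L) {
  limit <- sqrt(6 / (nrow + ncol))
  m <- matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
  if (ncol == 1L) as.numeric(m) else m
}

#' Initialize model parameters
#'
#' Uniform Glorot (fan-based) initialization using the current RNG state;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param hyper a [hyper_params()] object
#' @return object of class `mogat_params`: input projection, per-layer
#'   attention and GRU weights for the atom updates, per-layer (shared
#'   across the tau updates) attention and GRU weights for the super node,
#'   and the fully connected head
#' @export
init_params <- function(hyper) {
  d <- hyper$d_g
  fa <- atom_feature_length()
  fb <- bond_feature_length()
  layers <- vector("list", hyper$kappa)
  super <- vector("list", hyper$kappa)
  for (k in seq_len(hyper$kappa)) {
    wlen <- 2L * d + if (k == 1L) fb else 0L
    layers[[k]] <- list(w = glorot(wlen), V = glorot(d, d),
                        W_r = glorot(d, 2L * d), W_z = glorot(d, 2L * d),
                        W_h = glorot(d, 2L * d))
    super[[k]] <- list(w = glorot(2L * d), V = glorot(d, d),
                       W_r = glorot(d, 2L * d), W_z = glorot(d, 2L * d),
                       W_h = glorot(d, 2L * d))
  }
  structure(list(proj = glorot(d, fa), layers = layers, super = super,
                 fc_w = glorot(d), fc_b = 0),
            class = "mogat_params")
}

#' Number of learnable scalars in a parameter set
#' @param params a `mogat_params` object
#' @export
count_params <- function(params) {
  total <- length(params$proj) + length(params$fc_w) + 1L
  for (k in seq_along(params$layers)) {
    for (p in params$layers[[k]]) total <- total + length(p)
    for (p in params$super[[k]]) total <- total + length(p)
  }
  total
}

#' Gated recurrent unit update
#'
#' Reset gate \code{r = sigma(W_r [h; c])}, update gate
#' \code{z = sigma(W_z [h; c])}, candidate \code{h' = tanh(W_h [r * h; c])},
#' new state \code{h_new = (1 - z) * h' + z * h} (elementwise products).
#'
#' @param h_prev previous hidden state
#' @param ctx context vector
#' @param gru list with matrices `W_r`, `W_z`, `W_h` (each d x 2d)
#' @return list with `r`, `z`, `h_candidate`, `h_new`
#' @export
gru_update <- function(h_prev, ctx, gru) {
  if (length(h_prev) != length(ctx) ||
      ncol(gru$W_r) != length(h_prev) + length(ctx)) {
    stop("GRU input dimensions do not match the parameters", call. = FALSE)
  }
  hc <- c(h_prev, ctx)
  r <- stats::plogis(as.numeric(gru$W_r %*% hc))
  z <- stats::plogis(as.numeric(gru$W_z %*% hc))
  h_cand <- tanh(as.numeric(gru$W_h %*% c(r * h_prev, ctx)))
  list(r = r, z = z, h_candidate = h_cand,
       h_new = (1 - z) * h_cand + z * h_prev)
}

#' Initial node states
#'
#' Projects the 39-entry atom feature vectors into the embedding space
#' and applies the leaky ReLU.
#'
#' @param graph a [build_graph()] object
#' @param params a [init_params()] object
#' @return n x d_g matrix of initial hidden states
#' @export
init_node_states <- function(graph, params) {
  h <- graph$atom_features %*% t(params$proj)
  leaky_relu(h)
}

# neighbour set with the self-loop fallback for isolated atoms
neighbors_of <- function(graph, v) {
  nb <- graph$adjacency[[v]]
  if (length(nb) == 0L) v else nb
}

bond_feature_between <- function(graph, v, n) {
  if (v == n) return(numeric(bond_feature_length()))  # self-loop: zero bond
  idx <- which((graph$bonds$i == v & graph$bonds$j == n) |
                 (graph$bonds$i == n & graph$bonds$j == v))[1]
  graph$bond_features[idx, ]
}

#' One node-embedding (message-passing) layer
#'
#' For every atom, attention logits over its bonded neighbours, softmax
#' weights, an ELU context vector (optionally dropped out) and a GRU
#' state update. All atoms update synchronously from the incoming states.
#' In the first layer the neighbour term of the attention logit is
#' extended with the bond features of the connecting bond.
#'
#' @param states n x d matrix of incoming node states
#' @param graph a [build_graph()] object
#' @param layer list of layer parameters (`w`, `V`, `W_r`, `W_z`, `W_h`)
#' @param layer_index 1-based layer number (controls the bond-feature term)
#' @param mask optional n x d dropout mask applied to the context vectors
#' @return list with `states` (updated n x d matrix), `attention` (per-atom
#'   list of neighbour indices and weights) and `contexts`
#' @export
node_embedding_layer <- function(states, graph, layer, layer_index,
                                 mask = NULL) {
  n <- graph$n_atoms
  new_states <- states
  attention <- vector("list", n)
  contexts <- matrix(0, n, ncol(states))
  for (v in seq_len(n)) {
    nbrs <- neighbors_of(graph, v)
    logits <- vapply(nbrs, function(nn) {
      extra <- if (layer_index == 1L) bond_feature_between(graph, v, nn)
               else numeric(0)
      neighbor_logit(states[v, ], states[nn, ], layer$w, extra)
    }, numeric(1))
    s <- neighbor_weights(logits)
    ctx <- context_vector(s, states[nbrs, , drop = FALSE], layer$V)
    if (!is.null(mask)) ctx <- ctx * mask[v, ]
    contexts[v, ] <- ctx
    upd <- gru_update(states[v, ], ctx, layer)
    new_states[v, ] <- upd$h_new
    attention[[v]] <- list(neighbors = nbrs, weights = s)
  }
  list(states = new_states, attention = attention, contexts = contexts)
}

#' Super-node readout of a graph embedding
#'
#' The virtual super node is connected to every atom. Its state starts as
#' the elementwise sum of the node states and is refined `tau` times by
#' attention over all atoms followed by a GRU update. The atom attention
#' weights of the last update are returned as the layer's atom importance.
#'
#' @param states n x d matrix of node states after the current layer
#' @param super list of super-node parameters (`w`, `V`, `W_r`, `W_z`, `W_h`)
#' @param tau number of GRU refinements
#' @param masks optional list of `tau` dropout mask vectors for the context
#' @return list with `embedding` (length-d graph embedding) and
#'   `atom_attention` (weights over atoms, summing to 1)
#' @export
super_node_readout <- function(states, super, tau, masks = NULL) {
  h_super <- colSums(states)
  n <- nrow(states)
  a <- NULL
  for (t in seq_len(tau)) {
    logits <- vapply(seq_len(n), function(v) {
      neighbor_logit(h_super, states[v, ], super$w)
    }, numeric(1))
    a <- neighbor_weights(logits)
    ctx <- context_vector(a, states, super$V)
    if (!is.null(masks)) ctx <- ctx * masks[[t]]
    h_super <- gru_update(h_super, ctx, super)$h_new
  }
  list(embedding = h_super, atom_attention = a)
}

#' Full forward pass
#'
#' Runs the initial projection, all message-passing layers (reading out a
#' graph embedding after every layer), the scaled dot-product fusion of
#' the per-layer embeddings, and the prediction head. Records the full
#' layer trace needed for atom attribution.
#'
#' @param graph a [build_graph()] object
#' @param params a [init_params()] object
#' @param hyper the matching [hyper_params()] object
#' @param masks optional dropout masks (training only): list with elements
#'   `layer_ctx` (per-layer n x d matrices), `super_ctx` (per-layer lists
#'   of tau vectors) and `final` (length-d vector)
#' @return list of class `mogat_forward` with `prediction` (scalar logS)
#'   and `trace` (per-layer node states, contexts, edge attention, graph
#'   embeddings, atom attention, fusion weights and the final embedding)
#' @export
forward <- function(graph, params, hyper, masks = NULL) {
  kappa <- hyper$kappa
  states <- init_node_states(graph, params)
  layers <- vector("list", kappa)
  G <- matrix(0, kappa, hyper$d_g)
  atom_attention <- vector("list", kappa)
  for (k in seq_len(kappa)) {
    lay <- node_embedding_layer(states, graph, params$layers[[k]], k,
                                mask = if (!is.null(masks)) masks$layer_ctx[[k]])
    states <- lay$states
    ro <- super_node_readout(states, params$super[[k]], hyper$tau,
                             masks = if (!is.null(masks)) masks$super_ctx[[k]])
    G[k, ] <- ro$embedding
    atom_attention[[k]] <- ro$atom_attention
    layers[[k]] <- list(states = states, contexts = lay$contexts,
                        edge_attention = lay$attention,
                        h_super = ro$embedding,
                        atom_attention = ro$atom_attention)
  }
  A <- layer_attention(G)
  final <- fuse_embeddings(G, A)
  if (!is.null(masks)) final <- final * masks$final
  prediction <- sum(params$fc_w * final) + params$fc_b
  structure(list(
    prediction = prediction,
    trace = list(layers = layers, G = G, layer_weights = A,
                 atom_attention = atom_attention, final_embedding = final,
                 n_atoms = graph$n_atoms)
  ), class = "mogat_forward")
}

#' Generate dropout masks for one training forward pass
#'
#' Inverted-dropout masks (0 or 1/(1-p)) for the context vectors of every
#' layer and super-node update and for the fused embedding. Uses the
#' current RNG state.
#'
#' @param n_atoms number of atoms in the molecule
#' @param hyper a [hyper_params()] object
#' @return mask list as consumed by [forward()]
#' @export
dropout_masks <- function(n_atoms, hyper) {
  p <- hyper$dropout_rate
  d <- hyper$d_g
  draw <- function(len) {
    (stats::runif(len) >= p) / (1 - p)
  }
  list(
    layer_ctx = lapply(seq_len(hyper$kappa), function(k) {
      matrix(draw(n_atoms * d), n_atoms, d)
    }),
    super_ctx = lapply(seq_len(hyper$kappa), function(k) {
      lapply(seq_len(hyper$tau), function(t) draw(d))
    }),
    final = draw(d)
  )
}
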