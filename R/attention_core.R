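# Attention primitives shared by the node-level message passing and the
# multi-order (layer-level) readout fusion. Pure functions, no model state.

#' Leaky rectified linear unit
#'
#' Identity for non-negative inputs, slope 0.01 otherwise.
#' @param x numeric vector
#' @export
leaky_relu <- function(x) ifelse(x >= 0, x, 0.01 * x)

#' Exponential linear unit
#'
#' Identity for positive inputs, `exp(x) - 1` otherwise.
#' @param x numeric vector
#' @export
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

#' Attention logit for a node/neighbour pair
#'
#' The concatenated pair of hidden states (optionally extended by bond
#' features) is mapped to a scalar by the weight vector `w` and passed
#' through the leaky ReLU.
#'
#' @param h_v hidden state of the node being updated
#' @param h_n hidden state of the neighbour
#' @param w weight vector of length `length(h_v) + length(h_n) + length(extra)`
#' @param extra optional extra features appended to the neighbour term
#'   (bond features in the first message-passing layer)
#' @return scalar logit
#' @export
neighbor_logit <- function(h_v, h_n, w, extra = numeric(0)) {
  z <- c(h_v, h_n, extra)
  if (length(w) != length(z)) {
    stop(sprintf("attention weight length %d does not match input length %d",
                 length(w), length(z)), call. = FALSE)
  }
  leaky_relu(sum(w * z))
}

#' Softmax attention weights over a neighbourhood
#'
#' Numerically stabilized by max subtraction. The neighbour set must be
#' non-empty; callers are responsible for the self-loop fallback on
#' isolated atoms.
#'
#' @param logits numeric vector of attention logits, one per neighbour
#' @return weights summing to one
#' @export
neighbor_weights <- function(logits) {
  if (length(logits) == 0L) {
    stop("empty neighbour set: apply the self-loop fallback before softmax",
         call. = FALSE)
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Attention-weighted context vector
#'
#' `c_v = ELU(sum_n s_vn * V %*% h_n)` with the ELU applied componentwise.
#'
#' @param weights attention weights over the neighbours (must sum to 1)
#' @param h_neighbors matrix with one neighbour state per row
#' @param V square projection matrix in the state dimension
#' @return context vector
#' @export
context_vector <- function(weights, h_neighbors, V) {
  h_neighbors <- matrix(h_neighbors, nrow = length(weights))
  if (ncol(V) != ncol(h_neighbors)) {
    stop("projection matrix does not match the state dimension", call. = FALSE)
  }
  pre <- as.numeric(crossprod(h_neighbors, weights))  # sum_n s_vn h_n
  elu(as.numeric(V %*% pre))
}

#' Scaled dot-product attention over a stack of graph embeddings
#'
#' `A = softmax(G G^T / sqrt(d_G))`, row-wise, where each of the k rows of
#' `G` is the graph embedding read out after one message-passing layer.
#'
#' @param G k x d_G matrix of per-layer graph embeddings
#' @return k x k row-stochastic weight matrix
#' @export
layer_attention <- function(G) {
  G <- rbind(G)
  S <- (G %*% t(G)) / sqrt(ncol(G))
  t(apply(S, 1L, neighbor_weights))
}

#' Fuse per-layer graph embeddings into the final embedding
#'
#' The attention matrix re-expresses every layer's embedding as a convex
#' combination of all layers; the final embedding is the mean of those k
#' re-expressed rows, which treats all neighbouring orders symmetrically
#' and reduces to the single embedding when k = 1.
#'
#' @param G k x d_G matrix of per-layer graph embeddings
#' @param A k x k row-stochastic attention matrix from [layer_attention()]
#' @return final graph embedding (length d_G)
#' @export
fuse_embeddings <- function(G, A) {
  G <- rbind(G)
  A <- rbind(A)
  colMeans(A %*% G)
}
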