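# Independent straight-line reimplementation of the full forward pass
# (explicit loops, naive softmax/activations), used as the numerical
# oracle. Deliberately shares no code with the package internals beyond
# reading the graph/parameter containers.

oracle_forward <- function(graph, params, hyper) {
  X <- graph$atom_features
  n <- nrow(X)
  d <- hyper$d_g
  softmax_naive <- function(z) exp(z) / sum(exp(z))
  lrelu_s <- function(x) if (x >= 0) x else 0.01 * x
  elu_v <- function(x) ifelse(x > 0, x, exp(x) - 1)
  sigma_v <- function(x) 1 / (1 + exp(-x))

  bond_feat <- function(v, nn) {
    if (v == nn) return(rep(0, 10))
    bidx <- which((graph$bonds$i == v & graph$bonds$j == nn) |
                    (graph$bonds$i == nn & graph$bonds$j == v))[1]
    graph$bond_features[bidx, ]
  }

  H <- matrix(0, n, d)
  for (v in seq_len(n)) {
    z <- as.numeric(params$proj %*% X[v, ])
    H[v, ] <- ifelse(z >= 0, z, 0.01 * z)
  }
  G <- matrix(0, hyper$kappa, d)
  for (k in seq_len(hyper$kappa)) {
    lp <- params$layers[[k]]
    Hnew <- H
    for (v in seq_len(n)) {
      nbrs <- graph$adjacency[[v]]
      if (length(nbrs) == 0L) nbrs <- v
      e <- numeric(length(nbrs))
      for (q in seq_along(nbrs)) {
        vec <- c(H[v, ], H[nbrs[q], ])
        if (k == 1L) vec <- c(vec, bond_feat(v, nbrs[q]))
        e[q] <- lrelu_s(sum(lp$w * vec))
      }
      s <- softmax_naive(e)
      m <- rep(0, d)
      for (q in seq_along(nbrs)) {
        m <- m + s[q] * as.numeric(lp$V %*% H[nbrs[q], ])
      }
      ctx <- elu_v(m)
      hp <- H[v, ]
      r <- sigma_v(as.numeric(lp$W_r %*% c(hp, ctx)))
      z <- sigma_v(as.numeric(lp$W_z %*% c(hp, ctx)))
      hc <- tanh(as.numeric(lp$W_h %*% c(r * hp, ctx)))
      Hnew[v, ] <- (1 - z) * hc + z * hp
    }
    H <- Hnew
    sp <- params$super[[k]]
    g <- rep(0, d)
    for (v in seq_len(n)) g <- g + H[v, ]
    for (t in seq_len(hyper$tau)) {
      e <- numeric(n)
      for (v in seq_len(n)) e[v] <- lrelu_s(sum(sp$w * c(g, H[v, ])))
      a <- softmax_naive(e)
      m <- rep(0, d)
      for (v in seq_len(n)) m <- m + a[v] * as.numeric(sp$V %*% H[v, ])
      ctx <- elu_v(m)
      r <- sigma_v(as.numeric(sp$W_r %*% c(g, ctx)))
      z <- sigma_v(as.numeric(sp$W_z %*% c(g, ctx)))
      hc <- tanh(as.numeric(sp$W_h %*% c(r * g, ctx)))
      g <- (1 - z) * hc + z * g
    }
    G[k, ] <- g
  }
  S <- (G %*% t(G)) / sqrt(d)
  A <- matrix(0, hyper$kappa, hyper$kappa)
  for (i in seq_len(hyper$kappa)) A[i, ] <- softmax_naive(S[i, ])
  AG <- A %*% G
  fused <- rep(0, d)
  for (i in seq_len(hyper$kappa)) fused <- fused + AG[i, ] / hyper$kappa
  sum(params$fc_w * fused) + params$fc_b
}

# reorder the atoms of a graph by `perm` (new index of old atom i is
# match(i, perm)); rebuilt container only, no re-parsing
permute_graph <- function(graph, perm) {
  inv <- match(seq_len(graph$n_atoms), perm)
  bonds <- data.frame(i = inv[graph$bonds$i], j = inv[graph$bonds$j])
  adj <- vector("list", graph$n_atoms)
  for (v in seq_len(graph$n_atoms)) adj[[v]] <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  structure(list(n_atoms = graph$n_atoms,
                 atom_features = graph$atom_features[perm, , drop = FALSE],
                 bonds = bonds, bond_features = graph$bond_features,
                 adjacency = adj, smiles = graph$smiles,
                 target = graph$target, mol = NULL),
            class = "mol_graph")
}

tiny_hyper <- function(kappa = 2L, tau = 2L, d_g = 6L, seed = 1L) {
  hyper_params(kappa = kappa, tau = tau, d_g = d_g, dropout_rate = 0,
               epochs = 2L, seed = seed)
}

random_test_smiles <- function(n, seed = 1) {
  ds <- generate_dataset(synthetic_spec(n_molecules = n, seed = seed))
  ds$data$smiles
}
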