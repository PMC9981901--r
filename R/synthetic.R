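# Synthetic group-contribution benchmark: molecule-like graphs with a
# known additive per-element ground truth, so that training, evaluation
# and attribution can all be tested against an exact reference without
# any external dataset.

#' Per-element contribution table
#'
#' Additive contributions to the synthetic solubility target, loosely
#' modeled on group-contribution scales where nitrogen- and
#' oxygen-containing fragments raise aqueous solubility and hydrocarbon
#' and thio fragments lower it.
#'
#' @param values named numeric vector of per-element contributions
#'   (at least two distinct elements, finite values)
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @export
contribution_table <- function(values = c(C = -0.35, N = 0.8, O = 1.05,
                                          S = -1.0),
                               noise_sd = 0.3) {
  stopifnot(length(values) >= 2L, all(is.finite(values)),
            !is.null(names(values)), noise_sd >= 0)
  structure(list(values = values, noise_sd = noise_sd),
            class = "contribution_table")
}

#' Specification of a synthetic dataset
#'
#' @param n_molecules number of molecules
#' @param size_range min/max heavy-atom count
#' @param ring_prob probability of closing one ring per molecule
#' @param seed RNG seed
#' @param table a [contribution_table()]
#' @export
synthetic_spec <- function(n_molecules = 600L, size_range = c(2L, 12L),
                           ring_prob = 0.3, seed = 7L,
                           table = contribution_table()) {
  stopifnot(n_molecules >= 1L, size_range[1] >= 1L,
            size_range[2] >= size_range[1], ring_prob >= 0, ring_prob <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 size_range = as.integer(size_range),
                 ring_prob = ring_prob, seed = as.integer(seed),
                 table = table),
            class = "synthetic_spec")
}

# lowest standard valence caps used when growing random trees
.SYNTH_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)

skeleton_to_smiles <- function(symbols, bi, bj) {
  n <- length(symbols)
  mol <- list(symbols = symbols, aromatic = rep(FALSE, n),
              charge = rep(0L, n), radical = rep(0L, n),
              hcount = rep(NA_integer_, n),
              atoms = replicate(n, list(isotope = NA_integer_),
                                simplify = FALSE),
              bond_i = bi, bond_j = bj,
              bond_order = rep(1, length(bi)),
              bond_aromatic = rep(FALSE, length(bi)),
              adj = adjacency_list(n, bi, bj))
  write_smiles(mol)
}

#' Generate a synthetic group-contribution dataset
#'
#' Molecules are random valence-respecting trees (optionally closed into
#' one ring) over the elements of the contribution table; the target is
#' the sum of per-atom contributions plus Gaussian noise. Every emitted
#' SMILES parses with [build_graph()]. Deterministic given the seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `data` (data.frame smiles/target), `contributions`
#'   (per molecule, the named per-atom contribution vector) and `spec`
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  vals <- spec$table$values
  elements <- names(vals)
  caps <- .SYNTH_VALENCE[elements]
  if (anyNA(caps)) {
    stop("contribution table contains elements without a valence rule",
         call. = FALSE)
  }
  smiles <- character(spec$n_molecules)
  target <- numeric(spec$n_molecules)
  contribs <- vector("list", spec$n_molecules)
  for (m in seq_len(spec$n_molecules)) {
    n <- sample(spec$size_range[1]:spec$size_range[2], 1L)
    sym <- sample(elements, n, replace = TRUE)
    deg <- integer(n)
    cap <- unname(caps[sym])
    bi <- integer(0); bj <- integer(0)
    ok <- TRUE
    if (n > 1L) {
      for (k in 2:n) {
        free <- which(deg[seq_len(k - 1L)] < cap[seq_len(k - 1L)])
        if (length(free) == 0L) {
          stop("infeasible valence constraints while growing a molecule",
               call. = FALSE)
        }
        at <- if (length(free) == 1L) free else sample(free, 1L)
        bi <- c(bi, at); bj <- c(bj, k)
        deg[at] <- deg[at] + 1L
        deg[k] <- deg[k] + 1L
      }
      if (n >= 3L && stats::runif(1) < spec$ring_prob) {
        free <- which(deg < cap)
        if (length(free) >= 2L) {
          adj <- adjacency_list(n, bi, bj)
          pairs <- utils::combn(free, 2L)
          cand <- which(apply(pairs, 2L, function(p) {
            !(p[2] %in% adj[[p[1]]])
          }))
          if (length(cand) > 0L) {
            pick <- pairs[, if (length(cand) == 1L) cand else sample(cand, 1L)]
            bi <- c(bi, pick[1]); bj <- c(bj, pick[2])
            deg[pick] <- deg[pick] + 1L
          }
        }
      }
    }
    smiles[m] <- skeleton_to_smiles(sym, bi, bj)
    contribs[[m]] <- stats::setNames(unname(vals[sym]), sym)
    target[m] <- sum(contribs[[m]]) +
      stats::rnorm(1L, 0, spec$table$noise_sd)
  }
  list(data = data.frame(smiles = smiles, target = target,
                         stringsAsFactors = FALSE),
       contributions = contribs, spec = spec)
}

#' Hand-built fixture graphs with golden feature tensors
#'
#' Small molecules used throughout the test-suite: methyl hydrazine
#' ("CNN"), methane ("C"), ethane ("CC", a symmetric two-atom graph) and
#' a three-atom path ("CCO") whose feature matrix is replaced by a fixed
#' synthetic pattern for controlled numerical oracles. The "CNN" feature
#' tensors are checked against golden CSV files; a mismatch raises an
#' error describing the first differing entries.
#'
#' @param golden_dir directory holding the golden CSVs (defaults to the
#'   copies installed with the package); `NULL` skips the check
#' @return named list of `mol_graph` objects
#' @export
fixture_graphs <- function(golden_dir = system.file("extdata", "fixtures",
                                                    package = "mogat")) {
  cnn <- build_graph("CNN", target = 1.34)
  methane <- build_graph("C")
  ethane <- build_graph("CC")
  path3 <- build_graph("CCO")
  # synthetic, deterministic feature pattern for numerical oracles
  n <- path3$n_atoms
  path3$atom_features <- matrix(
    sin(seq_len(n * atom_feature_length())),
    n, atom_feature_length())
  if (!is.null(golden_dir) && nzchar(golden_dir)) {
    check_golden <- function(mat, file) {
      path <- file.path(golden_dir, file)
      if (!file.exists(path)) {
        stop(sprintf("golden file '%s' missing", path), call. = FALSE)
      }
      gold <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(gold) <- NULL
      if (!isTRUE(all.equal(unname(mat), gold, tolerance = 1e-12))) {
        diff <- which(abs(mat - gold) > 1e-12, arr.ind = TRUE)
        stop(sprintf(
          "fixture features diverge from golden file '%s' at [%s]: got %s, expected %s",
          file, paste(diff[1, ], collapse = ","),
          mat[diff[1, 1], diff[1, 2]], gold[diff[1, 1], diff[1, 2]]),
          call. = FALSE)
      }
    }
    check_golden(cnn$atom_features, "cnn_atom_features.csv")
    check_golden(cnn$bond_features, "cnn_bond_features.csv")
  }
  list(cnn = cnn, methane = methane, ethane = ethane, path3 = path3)
}
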