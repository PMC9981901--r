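# Molecular graphs with standard atom/bond feature blocks.

.SYMBOL_CATEGORIES <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As",
                        "Se", "Br", "Te", "I", "At", "metal")
.HYB_CATEGORIES <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")
.BOND_CATEGORIES <- c("single", "double", "triple", "aromatic")
.STEREO_CATEGORIES <- c("none", "any", "Z", "E")

#' Number of entries in the atom feature vector
#' @export
atom_feature_length <- function() 16L + 6L + 1L + 1L + 6L + 1L + 5L + 1L + 2L

#' Number of entries in the bond feature vector
#' @export
bond_feature_length <- function() 4L + 1L + 1L + 4L

onehot <- function(value, categories, clip = FALSE) {
  v <- numeric(length(categories))
  idx <- match(value, categories)
  if (is.na(idx)) {
    if (!clip) stop("value outside categories with clip = FALSE")
    idx <- length(categories)
  }
  v[idx] <- 1
  v
}

#' Featurize one atom of a parsed molecule
#'
#' Builds the 39-entry atom descriptor: a 16-way element one-hot
#' (B, C, N, O, F, Si, P, S, Cl, As, Se, Br, Te, I, At, metal — any other
#' element falls in the metal bin), a 6-way heavy-atom degree one-hot
#' (0-5, clipped), formal charge and radical-electron integers, a 6-way
#' hybridization one-hot (sp, sp2, sp3, sp3d, sp3d2, other), an
#' aromaticity flag, a 5-way attached-hydrogen one-hot (0-4, clipped),
#' a chiral-centre flag, and a 2-way R/S one-hot (all-zero when the CIP
#' label cannot be assigned).
#'
#' @param mol a parsed molecule as produced internally by [build_graph()]
#'   (available as the `mol` element of a molecular graph)
#' @param index atom index (1-based, heavy atoms only)
#' @return numeric vector of length [atom_feature_length()]
#' @export
featurize_atom <- function(mol, index) {
  stopifnot(index >= 1L, index <= length(mol$symbols))
  sym <- mol$symbols[index]
  symbol_slot <- if (sym %in% .SYMBOL_CATEGORIES[1:15]) sym else "metal"
  deg <- min(mol$degree[index], 5L)
  hyd <- min(mol$hcount[index], 4L)
  chiral <- as.numeric(isTRUE(mol$chiral_flag[index]))
  cip <- mol$cip_label[index]
  c(onehot(symbol_slot, .SYMBOL_CATEGORIES),
    onehot(as.character(deg), as.character(0:5), clip = TRUE),
    mol$charge[index],
    mol$radical[index],
    onehot(mol$hybridization[index], .HYB_CATEGORIES, clip = TRUE),
    as.numeric(mol$aromatic[index]),
    onehot(as.character(hyd), as.character(0:4), clip = TRUE),
    chiral,
    if (chiral > 0 && cip == "R") 1 else 0,
    if (chiral > 0 && cip == "S") 1 else 0)
}

#' Featurize one bond of a parsed molecule
#'
#' Builds the 10-entry bond descriptor: a 4-way bond-type one-hot
#' (single, double, triple, aromatic), a conjugation flag, an in-ring
#' flag, and a 4-way stereo one-hot (StereoNone, StereoAny, StereoZ,
#' StereoE). Unrecognized stereo annotations map to StereoNone.
#'
#' @inheritParams featurize_atom
#' @param index bond index (1-based, in parse order)
#' @return numeric vector of length [bond_feature_length()]
#' @export
featurize_bond <- function(mol, index) {
  stopifnot(index >= 1L, index <= length(mol$bond_i))
  type <- if (mol$bond_aromatic[index]) "aromatic"
          else switch(as.character(mol$bond_order[index]),
                      "1" = "single", "2" = "double", "3" = "triple", "single")
  stereo <- mol$bond_stereo[index]
  if (!(stereo %in% .STEREO_CATEGORIES)) stereo <- "none"
  c(onehot(type, .BOND_CATEGORIES),
    as.numeric(mol$bond_conjugated[index]),
    as.numeric(mol$bond_ring[index]),
    onehot(stereo, .STEREO_CATEGORIES))
}

#' Build a featurized molecular graph from a SMILES string
#'
#' Heavy atoms become nodes (hydrogens stay implicit and enter only via
#' the attached-hydrogen feature); bonds are undirected edges stored once
#' and expanded to a symmetric adjacency list.
#'
#' @param smiles SMILES string
#' @param target optional measured property value (logS)
#' @return an object of class `mol_graph` with elements `n_atoms`,
#'   `atom_features` (n x 39 matrix), `bonds` (data.frame i, j),
#'   `bond_features` (m x 10 matrix), `adjacency` (list of neighbour
#'   index vectors), `smiles`, `target`, and the parsed molecule `mol`
#' @examples
#' g <- build_graph("CNN", target = 1.34)
#' g$n_atoms
#' @export
build_graph <- function(smiles, target = NA_real_) {
  mol <- parse_smiles(smiles)
  n <- length(mol$symbols)
  af <- t(vapply(seq_len(n), function(a) featurize_atom(mol, a),
                 numeric(atom_feature_length())))
  m <- length(mol$bond_i)
  bf <- if (m > 0L) {
    t(vapply(seq_len(m), function(b) featurize_bond(mol, b),
             numeric(bond_feature_length())))
  } else matrix(numeric(0), 0L, bond_feature_length())
  structure(list(
    n_atoms = n,
    atom_features = af,
    bonds = data.frame(i = mol$bond_i, j = mol$bond_j),
    bond_features = bf,
    adjacency = mol$adj,
    smiles = smiles,
    target = target,
    mol = mol
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds%s\n", x$smiles, x$n_atoms,
              nrow(x$bonds),
              if (!is.na(x$target)) sprintf(", target %.4g", x$target) else ""))
  invisible(x)
}

#' Read a SMILES/property dataset from CSV
#'
#' Expects a header with a SMILES column and a numeric target column.
#' Rows whose SMILES cannot be parsed are skipped with a warning and
#' counted in the `n_skipped` attribute.
#'
#' @param path CSV file path
#' @param smiles_col,target_col column names
#' @return list of `mol_graph` objects with attribute `n_skipped`
#' @export
read_dataset <- function(path, smiles_col = "smiles",
                         target_col = "measured log solubility in mols per litre") {
  if (!file.exists(path)) stop(sprintf("dataset file '%s' not found", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!(smiles_col %in% names(df))) {
    stop(sprintf("missing SMILES column '%s'", smiles_col), call. = FALSE)
  }
  if (!(target_col %in% names(df))) {
    stop(sprintf("missing target column '%s'", target_col), call. = FALSE)
  }
  graphs <- list()
  skipped <- 0L
  for (r in seq_len(nrow(df))) {
    g <- tryCatch(build_graph(df[[smiles_col]][r],
                              as.numeric(df[[target_col]][r])),
                  error = function(e) e)
    if (inherits(g, "error")) {
      warning(sprintf("row %d skipped: %s", r, conditionMessage(g)),
              call. = FALSE)
      skipped <- skipped + 1L
    } else {
      graphs[[length(graphs) + 1L]] <- g
    }
  }
  attr(graphs, "n_skipped") <- skipped
  graphs
}

#' Write a SMILES/property dataset to CSV
#'
#' @param data data.frame with columns `smiles` and `target`
#' @param path output CSV path
#' @param smiles_col,target_col column names to write
#' @export
write_dataset <- function(data, path, smiles_col = "smiles",
                          target_col = "measured log solubility in mols per litre") {
  out <- data.frame(a = data$smiles, b = data$target, check.names = FALSE)
  names(out) <- c(smiles_col, target_col)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SMILES emission (DFS with ring-closure digits). Tetrahedral and
# double-bond stereo annotations are not emitted.

#' Emit a SMILES string for a parsed molecule
#'
#' @param mol parsed molecule (the `mol` element of a [build_graph()] result)
#' @return SMILES string (stereo annotations are dropped)
#' @export
write_smiles <- function(mol) {
  n <- length(mol$symbols)
  nb <- length(mol$bond_i)
  bond_of <- function(u, v) {
    which((mol$bond_i == u & mol$bond_j == v) |
            (mol$bond_i == v & mol$bond_j == u))[1]
  }
  bond_token <- function(b, from_arom, to_arom) {
    if (mol$bond_aromatic[b]) return("")
    o <- mol$bond_order[b]
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (from_arom && to_arom) return("-")  # single bond between aromatic atoms
    ""
  }
  atom_token <- function(a) {
    sym <- mol$symbols[a]
    arom <- mol$aromatic[a]
    plain <- sym %in% .ORGANIC_SUBSET && mol$charge[a] == 0L &&
      mol$radical[a] == 0L && is.na(mol$atoms[[a]]$isotope)
    if (plain && !arom) return(sym)
    if (plain && arom && !(sym %in% c("N", "P") && mol$hcount[a] > 0L)) {
      return(tolower(sym))
    }
    body <- if (arom) tolower(sym) else sym
    h <- mol$hcount[a]
    htxt <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
    q <- mol$charge[a]
    qtxt <- if (q > 0L) paste0("+", if (q > 1L) q else "") else
            if (q < 0L) paste0("-", if (q < -1L) -q else "") else ""
    paste0("[", body, htxt, qtxt, "]")
  }

  visited <- logical(n)
  used_bond <- logical(nb)
  ring_digit <- 0L
  closures <- vector("list", n)  # digits to print at the ring-opening atom
  # Bonds are classified at recursion time, so a cycle edge is always
  # discovered at its deeper endpoint: the digit (with any bond symbol)
  # is printed there, and the ancestor - still on the recursion stack -
  # prints the matching digit after its own branches return.
  emit <- function(a, from_bond) {
    visited[a] <<- TRUE
    inc <- which(mol$bond_i == a | mol$bond_j == a)
    my_digits <- character(0)
    branches <- character(0)
    for (b in inc) {
      if (!is.na(from_bond) && b == from_bond) next
      if (used_bond[b]) next
      other <- if (mol$bond_i[b] == a) mol$bond_j[b] else mol$bond_i[b]
      used_bond[b] <<- TRUE
      bt <- bond_token(b, mol$aromatic[a], mol$aromatic[other])
      if (visited[other]) {
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit < 10L) as.character(ring_digit)
             else paste0("%", ring_digit)
        my_digits <- c(my_digits, paste0(bt, d))
        closures[[other]] <<- c(closures[[other]], d)
      } else {
        branches <- c(branches, paste0(bt, emit(other, b)))
      }
    }
    body <- paste0(atom_token(a), paste0(my_digits, collapse = ""),
                   paste0(unlist(closures[[a]]), collapse = ""))
    if (length(branches) > 1L) {
      body <- paste0(body,
                     paste0("(", branches[-length(branches)], ")",
                            collapse = ""),
                     branches[length(branches)])
    } else if (length(branches) == 1L) {
      body <- paste0(body, branches)
    }
    body
  }
  emit(1L, NA_integer_)
}
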