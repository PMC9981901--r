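# SMILES parsing and chemical perception.
#
# The parser covers the SMILES subset needed for small-molecule property
# datasets: organic-subset atoms (B C N O F P S Cl Br I and aromatic
# b c n o p s), bracket atoms with isotope/charge/H-count/tetrahedral
# chirality, branches, ring closures (digits and %nn), bond orders
# - = # :, and directional bonds / \ for double-bond stereo. Disconnected
# structures (".") are rejected. Perception derives ring membership,
# aromaticity (per-ring Hueckel count on 5- and 6-membered rings),
# implicit hydrogens, hybridization, conjugation, CIP R/S labels and
# double-bond E/Z labels.

.ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As", "Se",
               "Br", "Te", "I", "At")

# default valences used for implicit-hydrogen assignment; multiple entries
# mean the smallest valence >= current bond-order sum is used
.VALENCES <- list(B = 3, C = 4, N = 3, O = 2, F = 1, P = c(3, 5),
                  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

# group (outer-shell) electron counts for lone-pair bookkeeping
.VALENCE_ELECTRONS <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                        S = 6, Cl = 7, As = 5, Se = 6, Br = 7, Te = 6,
                        I = 7, At = 7)

.ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                     Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
                     K = 19, Ca = 20, Fe = 26, Zn = 30, As = 33, Se = 34,
                     Br = 35, Te = 52, I = 53, At = 85)

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S", "Se", "As")

atomic_number <- function(symbol) {
  z <- .ATOMIC_NUMBERS[symbol]
  z[is.na(z)] <- 99L  # unknown/metal: heavier than anything tabulated
  unname(z)
}

smiles_parse_error <- function(smiles, msg) {
  stop(sprintf("cannot parse SMILES '%s': %s", smiles, msg), call. = FALSE)
}

#' @noRd
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()      # per-atom property lists
  bonds <- list()      # list(i, j, order, dir) as written (i before j)
  norder <- list()     # per-atom ordered neighbour slots (for stereo)

  prev <- 0L           # index of the atom the next bond attaches to
  stack <- integer(0)  # branch stack
  pending_order <- NA  # bond symbol seen since last atom
  pending_dir <- 0L
  rings <- list()      # open ring closures: key -> list(atom, order, dir, slot)

  add_atom <- function(sym, aromatic, charge = 0L, hcount = NA_integer_,
                       isotope = NA_integer_, chiral = "") {
    atoms[[length(atoms) + 1L]] <<- list(
      symbol = sym, aromatic = aromatic, charge = as.integer(charge),
      hcount = hcount, isotope = isotope, chiral = chiral,
      bracket = !is.na(hcount) || chiral != "" || charge != 0L)
    norder[[length(atoms)]] <<- integer(0)
    length(atoms)
  }

  add_bond <- function(i, j, order, dir) {
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = order,
                                         dir = dir)
    norder[[i]] <<- c(norder[[i]], j)
    norder[[j]] <<- c(norder[[j]], i)
  }

  finish_atom <- function(idx) {
    if (prev > 0L) {
      add_bond(prev, idx, pending_order, pending_dir)
    } else if (!is.na(pending_order)) {
      smiles_parse_error(smiles, "bond symbol with no preceding atom")
    }
    prev <<- idx
    pending_order <<- NA
    pending_dir <<- 0L
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "(") {
      if (prev == 0L) smiles_parse_error(smiles, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) smiles_parse_error(smiles, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pending_order)) {
        smiles_parse_error(smiles, "two consecutive bond symbols")
      }
      pending_order <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = "ar",
                              "/" = 1, "\\" = 1)
      pending_dir <- switch(ch, "/" = 1L, "\\" = -1L, 0L)
      i <- i + 1L
    } else if (ch == ".") {
      smiles_parse_error(smiles, "disconnected structures ('.') unsupported")
    } else if (grepl("[0-9%]", ch)) {
      if (prev == 0L) smiles_parse_error(smiles, "ring closure before atom")
      if (ch == "%") {
        if (i + 2L > n || !grepl("[0-9]", chars[i + 1L]) ||
            !grepl("[0-9]", chars[i + 2L])) {
          smiles_parse_error(smiles, "bad %nn ring closure")
        }
        key <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        if (op$atom == prev) smiles_parse_error(smiles, "self ring bond")
        order <- pending_order
        if (!is.na(op$order) && !is.na(order) && !identical(op$order, order)) {
          smiles_parse_error(smiles, "conflicting ring-bond orders")
        }
        if (is.na(order)) order <- op$order
        dir <- if (pending_dir != 0L) -pending_dir else op$dir
        # the closure occupies the slot reserved when the ring was opened
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev,
                                            order = order, dir = dir)
        norder[[op$atom]][op$slot] <- prev
        norder[[prev]] <- c(norder[[prev]], op$atom)
        rings[[key]] <- NULL
        pending_order <- NA
        pending_dir <- 0L
      } else {
        norder[[prev]] <- c(norder[[prev]], NA_integer_)  # reserve slot
        rings[[key]] <- list(atom = prev, order = pending_order,
                             dir = pending_dir,
                             slot = length(norder[[prev]]))
        pending_order <- NA
        pending_dir <- 0L
      }
    } else if (ch == "[") {
      close <- NA_integer_
      for (k in seq(i + 1L, min(n, i + 24L))) {
        if (chars[k] == "]") { close <- k; break }
      }
      if (is.na(close)) smiles_parse_error(smiles, "unterminated '['")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regexec(
        "^([0-9]*)([A-Z][a-z]?|as|se|b|c|n|o|p|s)(@@|@)?(H[0-9]*)?((?:\\+{1,3}|-{1,3})[0-9]*)?$",
        body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L) {
        smiles_parse_error(smiles, sprintf("bad bracket atom '[%s]'", body))
      }
      isotope <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
      rawsym <- parts[3]
      aromatic <- rawsym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      sym <- if (aromatic) {
        paste0(toupper(substr(rawsym, 1, 1)), substring(rawsym, 2))
      } else rawsym
      chiral <- parts[4]
      hc <- if (nzchar(parts[5])) {
        if (parts[5] == "H") 1L else as.integer(substring(parts[5], 2))
      } else 0L
      charge <- 0L
      if (nzchar(parts[6])) {
        sgn <- if (substr(parts[6], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", parts[6])
        nsym <- nchar(gsub("[^+-]", "", parts[6]))
        charge <- sgn * if (nzchar(digits)) as.integer(digits) else nsym
      }
      idx <- add_atom(sym, aromatic, charge, hc, isotope, chiral)
      was_first <- prev == 0L
      finish_atom(idx)
      # implicit-H slot for tetrahedral stereo: first slot if the atom
      # opens the SMILES, otherwise immediately after the preceding atom
      if (chiral != "" && hc == 1L) {
        at <- if (was_first) 0L else 1L
        norder[[idx]] <- append(norder[[idx]], 0L, after = at)
      }
      i <- close + 1L
    } else if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE)
      finish_atom(idx)
      i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      idx <- add_atom(ch, FALSE)
      finish_atom(idx)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      finish_atom(idx)
      i <- i + 1L
    } else {
      smiles_parse_error(smiles, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0L) smiles_parse_error(smiles, "unclosed branch")
  if (length(rings) > 0L) smiles_parse_error(smiles, "unclosed ring bond")
  if (length(atoms) == 0L) smiles_parse_error(smiles, "no atoms")
  if (!is.na(pending_order)) {
    smiles_parse_error(smiles, "dangling bond symbol")
  }

  mol <- list(smiles = smiles, atoms = atoms, bonds = bonds,
              norder = norder)
  perceive_molecule(mol)
}

# ---------------------------------------------------------------------------
# perception

bond_df <- function(mol) {
  nb <- length(mol$bonds)
  data.frame(
    i = vapply(mol$bonds, `[[`, integer(1) + 0L, "i"),
    j = vapply(mol$bonds, `[[`, integer(1) + 0L, "j"),
    stringsAsFactors = FALSE)
}

adjacency_list <- function(natoms, bi, bj) {
  adj <- vector("list", natoms)
  for (b in seq_along(bi)) {
    adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b])
    adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
  }
  adj
}

# a bond is in a ring iff its endpoints stay connected after removing it
bond_in_ring <- function(natoms, bi, bj) {
  nb <- length(bi)
  vapply(seq_len(nb), function(b) {
    keep <- setdiff(seq_len(nb), b)
    adj <- adjacency_list(natoms, bi[keep], bj[keep])
    seen <- logical(natoms)
    queue <- bi[b]
    seen[queue] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[bj[b]]
  }, logical(1))
}

# smallest ring through each ring bond (shortest alternative path between
# its endpoints); covers fused systems like naphthalene ring-by-ring
find_rings <- function(natoms, bi, bj, ring_bond) {
  rings <- list()
  keys <- character(0)
  for (b in which(ring_bond)) {
    keep <- setdiff(seq_along(bi), b)
    adj <- adjacency_list(natoms, bi[keep], bj[keep])
    # BFS shortest path from bi[b] to bj[b]
    parent <- rep(NA_integer_, natoms)
    seen <- logical(natoms)
    queue <- bi[b]; seen[bi[b]] <- TRUE
    while (length(queue) > 0L && !seen[bj[b]]) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w) }
      }
    }
    if (!seen[bj[b]]) next
    path <- bj[b]
    while (path[1] != bi[b]) path <- c(parent[path[1]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

lone_pairs <- function(symbol, charge, bond_used) {
  ve <- .VALENCE_ELECTRONS[symbol]
  if (is.na(ve)) return(0L)
  max(0L, as.integer(floor((ve - charge - bond_used) / 2)))
}

perceive_molecule <- function(mol) {
  natoms <- length(mol$atoms)
  sym <- vapply(mol$atoms, `[[`, character(1), "symbol")
  aromatic <- vapply(mol$atoms, `[[`, logical(1), "aromatic")
  charge <- vapply(mol$atoms, `[[`, integer(1), "charge")

  nb <- length(mol$bonds)
  bi <- if (nb) vapply(mol$bonds, function(b) as.integer(b$i), integer(1)) else integer(0)
  bj <- if (nb) vapply(mol$bonds, function(b) as.integer(b$j), integer(1)) else integer(0)
  border <- vector("list", nb)
  bdir <- if (nb) vapply(mol$bonds, function(b) as.integer(b$dir), integer(1)) else integer(0)
  for (b in seq_len(nb)) border[[b]] <- mol$bonds[[b]]$order

  # connectivity check
  adj <- adjacency_list(natoms, bi, bj)
  seen <- logical(natoms); seen[1] <- TRUE; queue <- 1L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) smiles_parse_error(mol$smiles, "molecule is disconnected")

  # provisional default bonds: aromatic between two aromatic atoms, else single
  order_num <- numeric(nb)  # numeric order with aromatic as "ar"
  is_ar_bond <- logical(nb)
  for (b in seq_len(nb)) {
    o <- border[[b]]
    if (is.na(o) || is.null(o)) {
      if (aromatic[bi[b]] && aromatic[bj[b]]) { is_ar_bond[b] <- TRUE; order_num[b] <- 1.5 }
      else order_num[b] <- 1
    } else if (identical(o, "ar")) {
      is_ar_bond[b] <- TRUE; order_num[b] <- 1.5
    } else order_num[b] <- as.numeric(o)
  }

  ring_bond <- if (nb) bond_in_ring(natoms, bi, bj) else logical(0)
  # aromatic default bonds outside rings (e.g. biphenyl bridge) are single
  demote <- is_ar_bond & !ring_bond &
    vapply(seq_len(nb), function(b) is.na(border[[b]]) || is.null(border[[b]]), logical(1))
  if (nb) { is_ar_bond[demote] <- FALSE; order_num[demote] <- 1 }

  ring_atom <- logical(natoms)
  if (nb) { ring_atom[unique(c(bi[ring_bond], bj[ring_bond]))] <- TRUE }
  for (a in which(aromatic)) {
    if (!ring_atom[a]) {
      smiles_parse_error(mol$smiles, "aromatic atom outside any ring")
    }
  }

  heavy_degree <- vapply(seq_len(natoms), function(a) length(adj[[a]]), integer(1))

  # implicit hydrogens
  hcount <- integer(natoms)
  for (a in seq_len(natoms)) {
    hc <- mol$atoms[[a]]$hcount
    inc <- which(bi == a | bj == a)
    n_ar <- sum(is_ar_bond[inc])
    kek_sum <- sum(order_num[inc][!is_ar_bond[inc]])
    if (!is.na(hc)) {
      hcount[a] <- hc
      next
    }
    if (!(sym[a] %in% .ORGANIC_SUBSET)) {
      smiles_parse_error(mol$smiles,
        sprintf("atom '%s' outside the organic subset must be bracketed", sym[a]))
    }
    vals <- .VALENCES[[sym[a]]]
    if (aromatic[a]) {
      # aromatic atom uses one pi electron beyond its sigma framework;
      # unbracketed aromatic n/p is pyridine-type (pyrrole-type needs [nH])
      used <- n_ar + kek_sum + if (sym[a] %in% c("C", "B", "N", "P")) 1 else 0
      v <- vals[vals >= used]
      hcount[a] <- if (length(v)) as.integer(max(0, min(v) - used)) else 0L
    } else {
      used <- kek_sum
      v <- vals[vals >= used]
      if (!length(v)) {
        smiles_parse_error(mol$smiles,
          sprintf("valence %g too high for atom %d (%s)", used, a, sym[a]))
      }
      hcount[a] <- as.integer(min(v) - used)
    }
  }

  # valence sanity for bracketed organic-subset atoms
  for (a in seq_len(natoms)) {
    if (!(sym[a] %in% names(.VALENCES)) || aromatic[a]) next
    inc <- which(bi == a | bj == a)
    used <- sum(order_num[inc]) + hcount[a]
    maxv <- max(.VALENCES[[sym[a]]]) + abs(charge[a])
    if (used > maxv + 1e-9) {
      smiles_parse_error(mol$smiles,
        sprintf("valence %g exceeds maximum for atom %d (%s)", used, a, sym[a]))
    }
  }

  # ring list for aromaticity perception
  rings <- if (nb) find_rings(natoms, bi, bj, ring_bond) else list()

  bond_index <- function(u, v) which((bi == u & bj == v) | (bi == v & bj == u))[1]

  # Hueckel check of one ring; atoms/bonds may be aromatic-flagged or kekulized
  ring_pi <- function(ring) {
    pi_total <- 0
    for (a in ring) {
      if (!(sym[a] %in% .AROMATIC_OK)) return(NA_real_)
      inc <- which(bi == a | bj == a)
      dbl <- inc[order_num[inc] == 2 & !is_ar_bond[inc]]
      dbl_in_ring <- any(vapply(dbl, function(b) {
        other <- if (bi[b] == a) bj[b] else bi[b]
        other %in% ring || ring_atom[other]
      }, logical(1)))
      if (length(dbl) > 0 && !dbl_in_ring) {
        pi_total <- pi_total + 0  # exocyclic double bond (e.g. quinone C=O)
      } else if (dbl_in_ring) {
        pi_total <- pi_total + 1
      } else if (aromatic[a] && sym[a] == "C" && charge[a] == 0) {
        pi_total <- pi_total + 1
      } else if (sym[a] %in% c("N", "P")) {
        # pyrrole-type (H or three connections) donates the lone pair
        donates <- hcount[a] > 0 || heavy_degree[a] >= 3
        pi_total <- pi_total + if (donates) 2 else 1
      } else if (sym[a] %in% c("O", "S", "Se")) {
        pi_total <- pi_total + 2
      } else if (sym[a] == "C" && charge[a] == -1) {
        pi_total <- pi_total + 2
      } else if (sym[a] == "C" || sym[a] == "B") {
        lp <- lone_pairs(sym[a], charge[a], sum(order_num[inc]) + hcount[a])
        if (hcount[a] + sum(order_num[inc]) >= max(.VALENCES[[sym[a]]]))
          return(NA_real_)  # saturated atom: ring cannot be aromatic
        pi_total <- pi_total + if (lp > 0) 2 else 0
      } else return(NA_real_)
    }
    pi_total
  }

  # perceive aromatic rings (5/6-membered, all ring bonds in the cycle)
  for (ring in rings) {
    if (!(length(ring) %in% c(5L, 6L))) next
    ring_bonds <- vapply(seq_along(ring), function(k) {
      bond_index(ring[k], ring[if (k == length(ring)) 1L else k + 1L])
    }, numeric(1))
    if (anyNA(ring_bonds)) next
    already <- all(aromatic[ring])
    kek_ok <- all(sym[ring] %in% .AROMATIC_OK) &&
      all(vapply(ring, function(a) {
        inc <- which(bi == a | bj == a)
        any(order_num[inc] >= 2) || any(is_ar_bond[inc]) ||
          sym[a] %in% c("N", "O", "S", "P", "Se") || aromatic[a]
      }, logical(1)))
    if (!already && !kek_ok) next
    pi <- ring_pi(ring)
    if (is.na(pi)) next
    if (pi %% 4 == 2) {
      aromatic[ring] <- TRUE
      is_ar_bond[ring_bonds] <- TRUE
      order_num[ring_bonds] <- 1.5
    }
  }

  # every aromatic-flagged atom must now sit in a fully aromatic ring
  for (a in which(aromatic)) {
    ok <- any(vapply(rings, function(r) a %in% r && all(aromatic[r]) &&
                       (length(r) %in% c(5L, 6L)), logical(1)))
    if (!ok) {
      smiles_parse_error(mol$smiles,
        sprintf("atom %d is marked aromatic but no valid aromatic ring contains it", a))
    }
  }
  # and each fully aromatic-flagged ring must satisfy the 4n+2 rule
  for (ring in rings) {
    if (!(length(ring) %in% c(5L, 6L))) next
    if (!all(aromatic[ring])) next
    pi <- ring_pi(ring)
    if (is.na(pi) || pi %% 4 != 2) {
      smiles_parse_error(mol$smiles,
        sprintf("ring {%s} violates the 4n+2 aromaticity rule",
                paste(ring, collapse = ",")))
    }
  }

  # radicals (organic-subset elements only; metals and exotics get 0)
  radical <- integer(natoms)
  for (a in seq_len(natoms)) {
    if (!(sym[a] %in% names(.VALENCES)) || aromatic[a]) next
    if (!isTRUE(mol$atoms[[a]]$bracket)) next
    inc <- which(bi == a | bj == a)
    used <- sum(order_num[inc]) + hcount[a]
    eff <- default_valence_charged(sym[a], charge[a])
    radical[a] <- max(0L, as.integer(round(eff - used)))
  }

  # hybridization
  hyb <- character(natoms)
  for (a in seq_len(natoms)) {
    inc <- which(bi == a | bj == a)
    n_triple <- sum(order_num[inc] == 3)
    n_double <- sum(order_num[inc] == 2 & !is_ar_bond[inc])
    if (!(sym[a] %in% names(.VALENCE_ELECTRONS))) {
      hyb[a] <- "other"
    } else if (aromatic[a]) {
      hyb[a] <- "sp2"
    } else if (n_triple >= 1 || n_double >= 2) {
      hyb[a] <- "sp"
    } else if (n_double == 1) {
      hyb[a] <- "sp2"
    } else {
      used <- sum(order_num[inc]) + hcount[a]
      lp <- lone_pairs(sym[a], charge[a], used)
      steric <- heavy_degree[a] + hcount[a] + lp
      hyb[a] <- switch(as.character(steric), "1" = "other", "2" = "sp",
                       "3" = "sp2", "4" = "sp3", "5" = "sp3d",
                       "6" = "sp3d2", "other")
    }
  }

  # conjugation
  conj <- is_ar_bond
  lp_donor <- vapply(seq_len(natoms), function(a) {
    if (!(sym[a] %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I"))) return(FALSE)
    inc <- which(bi == a | bj == a)
    lone_pairs(sym[a], charge[a], sum(order_num[inc]) + hcount[a]) > 0
  }, logical(1))
  has_pi <- vapply(seq_len(natoms), function(a) {
    inc <- which(bi == a | bj == a)
    any(order_num[inc] >= 2 | is_ar_bond[inc])
  }, logical(1))
  for (a in seq_len(natoms)) {
    inc <- which(bi == a | bj == a)
    if (length(inc) < 2L) next
    for (b1 in inc) {
      if (!(order_num[b1] >= 2 || is_ar_bond[b1])) next
      for (b2 in inc) {
        if (b2 == b1 || order_num[b2] != 1 || is_ar_bond[b2]) next
        far <- if (bi[b2] == a) bj[b2] else bi[b2]
        if (lp_donor[far] || has_pi[far]) {
          conj[b1] <- TRUE
          conj[b2] <- TRUE
        }
      }
    }
  }

  mol$symbols <- sym
  mol$aromatic <- aromatic
  mol$charge <- charge
  mol$hcount <- hcount
  mol$radical <- radical
  mol$hybridization <- hyb
  mol$degree <- heavy_degree
  mol$ring_atom <- ring_atom
  mol$adj <- adj
  mol$bond_i <- bi
  mol$bond_j <- bj
  mol$bond_order <- order_num
  mol$bond_aromatic <- is_ar_bond
  mol$bond_ring <- ring_bond
  mol$bond_conjugated <- conj
  mol$bond_dir <- bdir
  mol$rings <- rings

  mol <- assign_bond_stereo(mol)
  assign_atom_stereo(mol)
}

default_valence_charged <- function(symbol, charge) {
  base <- max(.VALENCES[[symbol]])
  if (charge == 0) return(base)
  # isoelectronic shifts for common charged species
  key <- paste0(symbol, charge)
  shifts <- c("N1" = 4, "O1" = 3, "S1" = 3, "P1" = 4, "C-1" = 3, "N-1" = 2,
              "O-1" = 1, "S-1" = 1, "B-1" = 4)
  if (key %in% names(shifts)) return(unname(shifts[key]))
  max(0, base - abs(charge))
}

# --------------------------------------------------------------------------
# CIP-style priority comparison (atomic-number hierarchical digraph with
# phantom atoms for multiple bonds; ties beyond depth 12 are unresolved)

cip_compare <- function(mol, root, a, b, max_depth = 12L) {
  expand <- function(frontier) {
    # frontier: list of entries list(atom, parent); phantom entries have
    # atom = -z (terminal, encoded by negative atomic number)
    nums <- numeric(0)
    nxt <- list()
    for (e in frontier) {
      if (e$atom < 0L) { nums <- c(nums, -e$atom); next }
      nums <- c(nums, atomic_number(mol$symbols[e$atom]))
      kids <- list()
      for (w in mol$adj[[e$atom]]) {
        if (w == e$parent) next
        kids[[length(kids) + 1L]] <- list(atom = w, parent = e$atom)
      }
      inc <- which(mol$bond_i == e$atom | mol$bond_j == e$atom)
      for (bb in inc) {
        other <- if (mol$bond_i[bb] == e$atom) mol$bond_j[bb] else mol$bond_i[bb]
        extra <- if (mol$bond_aromatic[bb]) 1L
                 else max(0L, as.integer(round(mol$bond_order[bb])) - 1L)
        if (extra > 0L) {
          for (k in seq_len(extra)) {
            kids[[length(kids) + 1L]] <-
              list(atom = -atomic_number(mol$symbols[other]), parent = e$atom)
          }
        }
      }
      # implicit hydrogens become terminal phantom H
      if (mol$hcount[e$atom] > 0L) {
        for (k in seq_len(mol$hcount[e$atom])) {
          kids[[length(kids) + 1L]] <- list(atom = -1L, parent = e$atom)
        }
      }
      nxt <- c(nxt, kids)
    }
    list(nums = sort(nums, decreasing = TRUE), nxt = nxt)
  }

  fa <- list(if (a == 0L) list(atom = -1L, parent = root) else list(atom = a, parent = root))
  fb <- list(if (b == 0L) list(atom = -1L, parent = root) else list(atom = b, parent = root))
  for (depth in seq_len(max_depth)) {
    ea <- expand(fa); eb <- expand(fb)
    la <- max(length(ea$nums), length(eb$nums))
    va <- c(ea$nums, rep(0, la - length(ea$nums)))
    vb <- c(eb$nums, rep(0, la - length(eb$nums)))
    cmp <- which(va != vb)
    if (length(cmp)) return(if (va[cmp[1]] > vb[cmp[1]]) 1L else -1L)
    fa <- ea$nxt; fb <- eb$nxt
    if (length(fa) == 0L && length(fb) == 0L) return(0L)
  }
  0L
}

permutation_sign <- function(perm) {
  sgn <- 1L
  perm <- as.integer(perm)
  for (x in seq_along(perm)) {
    for (y in seq_len(x - 1L)) if (perm[y] > perm[x]) sgn <- -sgn
  }
  sgn
}

assign_atom_stereo <- function(mol) {
  natoms <- length(mol$atoms)
  chiral_flag <- logical(natoms)
  cip_label <- rep("", natoms)
  for (a in seq_len(natoms)) {
    mark <- mol$atoms[[a]]$chiral
    if (mark == "") next
    chiral_flag[a] <- TRUE
    nbrs <- mol$norder[[a]]  # 0 encodes the implicit H
    if (length(nbrs) != 4L || anyNA(nbrs)) next
    cmp <- matrix(0L, 4, 4)
    for (x in 1:4) for (y in 1:4) {
      if (x < y) {
        cmp[x, y] <- cip_compare(mol, a, nbrs[x], nbrs[y])
        cmp[y, x] <- -cmp[x, y]
      }
    }
    wins <- rowSums(cmp > 0)
    if (length(unique(wins)) != 4L) next  # unresolved tie: leave unlabeled
    # orientation algebra: the ordered neighbour tuple carries a parity
    # (+1 for @@, -1 for @); permuting it into CIP-priority order flips
    # the parity by the permutation sign, and R corresponds to +1
    ord <- order(wins, decreasing = TRUE)
    orient <- if (mark == "@@") 1L else -1L
    cip_label[a] <- if (orient * permutation_sign(ord) > 0) "R" else "S"
  }
  mol$chiral_flag <- chiral_flag
  mol$cip_label <- cip_label
  mol
}

assign_bond_stereo <- function(mol) {
  nb <- length(mol$bond_i)
  stereo <- rep("none", nb)
  if (nb == 0L) { mol$bond_stereo <- stereo; return(mol) }
  bi <- mol$bond_i; bj <- mol$bond_j
  for (b in seq_len(nb)) {
    if (mol$bond_order[b] != 2 || mol$bond_ring[b]) next
    u <- bi[b]; v <- bj[b]
    dir_for <- function(center) {
      inc <- which((bi == center | bj == center) & mol$bond_dir != 0 &
                     mol$bond_order == 1)
      if (!length(inc)) return(NULL)
      bb <- inc[1]
      far <- if (bi[bb] == center) bj[bb] else bi[bb]
      # normalize symbol to orientation far -> center
      d <- mol$bond_dir[bb]
      if (bi[bb] == center) d <- -d
      list(ref = far, d = d, bond = bb)
    }
    du <- dir_for(u); dv <- dir_for(v)
    if (is.null(du) || is.null(dv)) next
    # normalized (ref->u) vs (v->ref): flip the v side back
    s1 <- du$d
    s2 <- -dv$d
    trans <- s1 == s2
    flip <- 0L
    resolved <- TRUE
    for (side in list(list(center = u, ref = du$ref, other = v),
                      list(center = v, ref = dv$ref, other = u))) {
      subs <- setdiff(mol$adj[[side$center]], side$other)
      alt <- setdiff(subs, side$ref)
      altn <- if (length(alt)) alt[1] else 0L  # implicit H
      cmpv <- cip_compare(mol, side$center, side$ref, altn)
      if (cmpv == 0L) { resolved <- FALSE; break }
      if (cmpv < 0L) flip <- flip + 1L
    }
    if (!resolved) { stereo[b] <- "any"; next }
    if (flip %% 2 == 1) trans <- !trans
    stereo[b] <- if (trans) "E" else "Z"
  }
  mol$bond_stereo <- stereo
  mol
}
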