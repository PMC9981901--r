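# Featurization and graph construction. Expected feature values for the
# named molecules were cross-checked against an independent
# cheminformatics toolkit before being frozen here.

sym_block <- 1:16
deg_block <- 17:22
charge_col <- 23
radical_col <- 24
hyb_block <- 25:30
arom_col <- 31
hyd_block <- 32:36
chiral_col <- 37
cip_block <- 38:39

sym_names <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As", "Se",
               "Br", "Te", "I", "At", "metal")
hyb_names <- c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other")

test_that("atom feature vector has the documented block layout", {
  g <- build_graph("CNN")
  expect_equal(ncol(g$atom_features), 39L)
  expect_equal(atom_feature_length(), 39L)
  expect_equal(bond_feature_length(), 10L)
  expect_length(sym_block, 16L)
  expect_length(hyb_block, 6L)
  expect_length(hyd_block, 5L)
})

test_that("methane carbon: degree 0, four hydrogens, sp3, not aromatic", {
  f <- build_graph("C")$atom_features[1, ]
  expect_equal(which(f[sym_block] == 1), match("C", sym_names))
  expect_equal(which(f[deg_block] == 1), 1L)  # degree 0
  expect_equal(which(f[hyd_block] == 1), 5L)  # 4 hydrogens
  expect_equal(which(f[hyb_block] == 1), match("sp3", hyb_names))
  expect_equal(f[arom_col], 0)
})

test_that("sodium maps to the metal category", {
  f <- build_graph("[Na+]")$atom_features[1, ]
  expect_equal(which(f[sym_block] == 1), 16L)
  expect_equal(f[charge_col], 1)
})

test_that("aromatic benzene carbon: aromatic, sp2, degree 2", {
  for (smi in c("c1ccccc1", "C1=CC=CC=C1")) {
    f <- build_graph(smi)$atom_features[1, ]
    expect_equal(f[arom_col], 1)
    expect_equal(which(f[hyb_block] == 1), match("sp2", hyb_names))
    expect_equal(which(f[deg_block] == 1), 3L)  # degree 2
    expect_equal(which(f[hyd_block] == 1), 2L)  # 1 hydrogen
  }
})

test_that("bond features for ethane, benzene and E-2-butene", {
  eth <- build_graph("CC")$bond_features[1, ]
  expect_equal(eth[1:4], c(1, 0, 0, 0))  # single
  expect_equal(eth[5], 0)                # not conjugated
  expect_equal(eth[6], 0)                # not in ring
  expect_equal(eth[7:10], c(1, 0, 0, 0)) # StereoNone

  benz <- build_graph("c1ccccc1")$bond_features[1, ]
  expect_equal(benz[1:4], c(0, 0, 0, 1)) # aromatic
  expect_equal(benz[6], 1)               # in ring

  but <- build_graph("C/C=C/C")
  dbl <- which(but$bond_features[, 2] == 1)
  expect_length(dbl, 1L)
  expect_equal(but$bond_features[dbl, 7:10], c(0, 0, 0, 1))  # StereoE
  cis <- build_graph("C/C=C\\C")
  dbl <- which(cis$bond_features[, 2] == 1)
  expect_equal(cis$bond_features[dbl, 7:10], c(0, 0, 1, 0))  # StereoZ
})

test_that("CIP labels follow the tetrahedral annotation", {
  ala_s <- build_graph("N[C@@H](C)C(=O)O")  # L-alanine, S
  expect_equal(ala_s$atom_features[2, chiral_col], 1)
  expect_equal(ala_s$atom_features[2, cip_block], c(0, 1))
  ala_r <- build_graph("N[C@H](C)C(=O)O")
  expect_equal(ala_r$atom_features[2, cip_block], c(1, 0))
  # unannotated centre: no chirality flags at all
  plain <- build_graph("NC(C)C(=O)O")
  expect_true(all(plain$atom_features[, chiral_col] == 0))
  expect_true(all(plain$atom_features[, cip_block] == 0))
})

test_that("one-hot block invariants hold on generated and named molecules", {
  smis <- c("CNN", "c1ccncc1", "CC(=O)O", "C#N", "OC1C(O)C(O)C(O)C(O)C1O",
            "CCS", "BrCCl", "FC(F)(F)F", random_test_smiles(30, seed = 3))
  for (smi in smis) {
    g <- build_graph(smi)
    af <- g$atom_features
    expect_true(all(rowSums(af[, sym_block, drop = FALSE]) == 1), info = smi)
    expect_true(all(rowSums(af[, deg_block, drop = FALSE]) == 1), info = smi)
    expect_true(all(rowSums(af[, hyb_block, drop = FALSE]) == 1), info = smi)
    expect_true(all(rowSums(af[, hyd_block, drop = FALSE]) == 1), info = smi)
    # chirality type all-zero whenever the chiral flag is off
    off <- af[, chiral_col] == 0
    expect_true(all(af[off, cip_block] == 0), info = smi)
    if (nrow(g$bond_features) > 0) {
      bf <- g$bond_features
      expect_true(all(rowSums(bf[, 1:4, drop = FALSE]) == 1), info = smi)
      expect_true(all(rowSums(bf[, 7:10, drop = FALSE]) == 1), info = smi)
    }
    # adjacency symmetric and consistent with the bond list
    for (b in seq_len(nrow(g$bonds))) {
      expect_true(g$bonds$j[b] %in% g$adjacency[[g$bonds$i[b]]])
      expect_true(g$bonds$i[b] %in% g$adjacency[[g$bonds$j[b]]])
    }
  }
})

test_that("methyl hydrazine is a 3-atom, 2-bond path and building is deterministic", {
  g1 <- build_graph("CNN")
  g2 <- build_graph("CNN")
  expect_equal(g1$n_atoms, 3L)
  expect_equal(nrow(g1$bonds), 2L)
  expect_identical(g1$atom_features, g2$atom_features)
  expect_identical(g1$bond_features, g2$bond_features)
  expect_equal(g1$adjacency[[2]], c(1L, 3L))
})

test_that("invalid SMILES raise informative parse errors", {
  expect_error(build_graph("not_a_smiles"), "not_a_smiles")
  expect_error(build_graph("C(("), "cannot parse")
  expect_error(build_graph("C1CC"), "ring")
  expect_error(build_graph("C=C=C=C=C=C(=C)(=C)C"), "valence")
})

test_that("datasets round-trip through CSV with skip accounting", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("smiles,logS", "CNN,1.34"), path)
  graphs <- read_dataset(path, smiles_col = "smiles", target_col = "logS")
  expect_length(graphs, 1L)
  expect_equal(graphs[[1]]$target, 1.34)
  expect_equal(attr(graphs, "n_skipped"), 0L)

  writeLines("smiles,logS", path)
  expect_length(read_dataset(path, target_col = "logS"), 0L)

  writeLines(c("smiles,logS", "CNN,1.34", "xyz##,0.0", "CCO,-0.1"), path)
  expect_warning(graphs <- read_dataset(path, target_col = "logS"),
                 "skipped")
  expect_length(graphs, 2L)
  expect_equal(attr(graphs, "n_skipped"), 1L)

  expect_error(read_dataset(tempfile(), target_col = "logS"), "not found")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_dataset(path, target_col = "logS"), "SMILES column")
})

test_that("emitted SMILES re-parse to the same atom multiset and bond count", {
  smis <- c("CNN", "c1ccccc1", "OC1CCCCC1", "CC(=O)O", "c1cc[nH]c1",
            "CN1CCC1", "c1ccc2ccccc2c1")
  for (smi in smis) {
    g <- build_graph(smi)
    out <- write_smiles(g$mol)
    g2 <- build_graph(out)
    expect_equal(sort(g2$mol$symbols), sort(g$mol$symbols), info = smi)
    expect_equal(nrow(g2$bonds), nrow(g$bonds), info = smi)
    expect_equal(sort(g2$mol$hcount), sort(g$mol$hcount), info = smi)
  }
})
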