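test_that("PDB parsing handles single atoms, bond perception and CONECT", {
  one <- paste0("HETATM    1  C1  LIG A   1       0.000   0.000   0.000",
                "  1.00  0.00           C")
  mol <- parse_pdb(one)
  expect_equal(n_atoms(mol), 1)
  expect_equal(nrow(mol$bonds), 0)
  expect_equal(mol$atoms$element, "C")

  ## two carbons 1.54 A apart, no CONECT: perceived (1.54 <= 0.76+0.76+0.45)
  two <- c(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  LIG A   1       1.540   0.000   0.000  1.00  0.00           C")
  mol2 <- parse_pdb(two)
  expect_equal(nrow(mol2$bonds), 1)

  ## CONECT wins over perception and deduplicates reciprocal records
  three <- c(two,
    "HETATM    3  C3  LIG A   1       8.000   0.000   0.000  1.00  0.00           C",
    "CONECT    1    3",
    "CONECT    3    1")
  mol3 <- parse_pdb(three)
  expect_equal(nrow(mol3$bonds), 1)
  expect_equal(c(mol3$bonds$i, mol3$bonds$j), c(1L, 3L))
})

test_that("PDB parsing falls back to the atom-name field for the element", {
  line <- "HETATM    1  CL1 LIG A   1       0.000   0.000   0.000  1.00  0.00"
  expect_equal(parse_pdb(line)$atoms$element, "Cl")
})

test_that("PDB parsing rejects unsupported elements and malformed records", {
  se <- paste0("HETATM    1 SE1  LIG A   1       0.000   0.000   0.000",
               "  1.00  0.00          SE")
  expect_error(parse_pdb(se), "Se")
  bad <- "HETATM    1  C1  LIG A   1       x.xxx   0.000   0.000"
  expect_error(parse_pdb(bad), "line 1")
  expect_error(parse_pdb("REMARK nothing here"), "ATOM")
})

test_that("SDF V2000 round-trips atoms, bonds and orders exactly", {
  ethane <- paste(c("ethane", "  test", "",
                    "  2  1  0  0  0  0  0  0  0  0999 V2000",
                    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                    "  1  2  1  0", "M  END", "$$$$"), collapse = "\n")
  mol <- parse_sdf(ethane)
  expect_equal(n_atoms(mol), 2)
  expect_equal(mol$bonds$order, 1L)

  ## aromatic convention: V2000 order 4
  benz <- parse_smiles("c1ccccc1")
  benz <- embed_coordinates(benz)
  back <- parse_sdf(write_sdf(benz))
  expect_equal(back$atoms$element, benz$atoms$element)
  expect_equal(back$bonds[, c("i", "j", "order", "aromatic")],
               benz$bonds[, c("i", "j", "order", "aromatic")])
  expect_equal(sum(back$bonds$aromatic), 6)

  ## parse_sdf(write_sdf(mol)) round-trip on generated molecules
  spec <- synth_spec(seed = 99)
  for (i in 1:5) {
    m <- generate_molecule(spec, i)
    m2 <- parse_sdf(write_sdf(m))
    expect_equal(m2$atoms$element, m$atoms$element)
    expect_equal(m2$bonds[, c("i", "j", "order", "aromatic")],
                 m$bonds[, c("i", "j", "order", "aromatic")])
  }
})

test_that("SDF parsing rejects degenerate or inconsistent blocks", {
  empty <- paste(c("mol", "", "", "  0  0  0  0  0  0  0  0  0  0999 V2000",
                   "M  END"), collapse = "\n")
  expect_error(parse_sdf(empty), "no atoms")
  short <- paste(c("mol", "", "", "  3  0  0  0  0  0  0  0  0  0999 V2000",
                   "    0.0000    0.0000    0.0000 C   0  0"), collapse = "\n")
  expect_error(parse_sdf(short), "counts")
})

test_that("SMILES subset: valence fill, rings, branches, brackets", {
  m <- parse_smiles("C")
  expect_equal(n_atoms(m), 5)            # 1 C + 4 implicit H
  expect_equal(nrow(m$bonds), 4)

  ring <- parse_smiles("C1CCCCC1")
  expect_equal(sum(ring$atoms$element == "C"), 6)
  expect_equal(sum(ring$atoms$element == "H"), 12)
  ri <- find_rings(ring)
  expect_length(ri$rings, 1)
  expect_equal(length(ri$rings[[1]]), 6)

  iso <- parse_smiles("CC(C)C")          # isobutane
  expect_equal(sum(iso$atoms$element == "C"), 4)
  expect_equal(sum(iso$atoms$element == "H"), 10)

  eth <- parse_smiles("C=C")
  expect_equal(sum(eth$atoms$element == "H"), 4)
  expect_equal(max(eth$bonds$order), 2L)

  amm <- parse_smiles("[NH4+]")
  expect_equal(n_atoms(amm), 5)
  expect_equal(amm$atoms$formal_charge[1], 1L)
})

test_that("SMILES rejects malformed and unsupported input", {
  expect_error(parse_smiles("C("), "parenthesis")
  expect_error(parse_smiles("C1CC"), "ring closure")
  expect_error(parse_smiles("F/C=C/F"), "stereo")
  expect_error(parse_smiles("C[Se]C"), "Se")
})

test_that("bond perception follows the covalent-radius window", {
  at <- function(d) data.frame(element = c("C", "C"), name = "C",
                               x = c(0, d), y = 0, z = 0, formal_charge = 0L)
  expect_equal(nrow(perceive_bonds(at(1.54))), 1)   # 1.54 <= 1.97
  expect_equal(nrow(perceive_bonds(at(3.00))), 0)   # 3.00 >  1.97
  expect_equal(nrow(perceive_bonds(at(0.10))), 0)   # below clash floor
  expect_error(perceive_bonds(data.frame(element = "C", name = "C",
                                         x = NA_real_, y = 0, z = 0)),
               "coordinates")
})

test_that("bond perception is stable under atom reordering", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    xyz <- matrix(stats::runif(n * 3, 0, 4), n, 3)
    atoms <- data.frame(element = sample(c("C", "N", "O"), n, replace = TRUE),
                        name = "X", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        formal_charge = 0L)
    b1 <- perceive_bonds(atoms)
    perm <- sample.int(n)
    b2 <- perceive_bonds(atoms[perm, ])   # row k is original atom perm[k]
    back <- cbind(pmin(perm[b2$i], perm[b2$j]), pmax(perm[b2$i], perm[b2$j]))
    expect_setequal(paste(b1$i, b1$j), paste(back[, 1], back[, 2]))
  }
})

test_that("valence caps reject overbonded molecules", {
  atoms <- data.frame(element = c("O", "H", "H", "H"), name = "X",
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      formal_charge = 0L)
  bonds <- data.frame(i = 1L, j = 2:4, order = 1L, aromatic = FALSE)
  expect_error(molecule(atoms, bonds), "valence cap")
})

test_that("ring perception: trees, benzene, naphthalene", {
  pentane <- graph_molecule(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  ri <- find_rings(pentane)
  expect_length(ri$rings, 0)
  expect_true(all(ri$atom_ring_count == 0))
  expect_true(all(ri$atom_min_ring_size == 0))

  benzene <- graph_molecule(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                    c(5, 6), c(1, 6)))
  rb <- find_rings(benzene)
  expect_length(rb$rings, 1)
  expect_equal(sort(rb$rings[[1]]), 1:6)
  expect_true(all(rb$atom_min_ring_size == 6))
  expect_true(all(rb$atom_max_ring_size == 6))

  ## naphthalene heavy-atom skeleton: 10 atoms, 11 bonds -> 2 basis rings
  naph_edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6),
                     c(5, 7), c(7, 8), c(8, 9), c(9, 10), c(6, 10))
  naph <- graph_molecule(10, naph_edges)
  rn <- find_rings(naph)
  expect_length(rn$rings, 2)
  expect_length(rn$ring_systems, 1)
  expect_equal(rn$ring_systems[[1]]$n_rings, 2)
  expect_equal(rn$ring_systems[[1]]$n_atoms, 10)
  cycles <- all_simple_cycles(10, naph_edges)
  for (r in rn$rings) {
    expect_true(paste(sort(r), collapse = "-") %in% cycles)
    expect_true(is_simple_cycle(naph, r))
  }
})

test_that("cycle-basis size obeys |E| - |V| + 1 on random connected graphs", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    extra <- sample(0:3, 1)
    edges <- random_connected_graph(n, extra)
    mol <- graph_molecule(n, edges, validate = FALSE)
    ri <- find_rings(mol)
    expect_length(ri$rings, length(edges) - n + 1)
  }
})
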