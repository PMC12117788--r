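test_that("a minimal hand-written PDB parses into the expected structure", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0, "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 3.2, 1.4, 0, "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.9, -1.0, 1.0, "C"),
    "END")
  s <- read_structure(lines)
  expect_equal(n_atoms(s), 5)
  expect_equal(nrow(residues(s)), 1)
  expect_equal(residues(s)$resname, "ALA")
  expect_equal(nrow(het_groups(s)), 0)
  expect_equal(s$atoms$x[2], 1.458)
})

test_that("synthetic poly-alanine round-trips through the reader with known counts", {
  b <- make_toy_structure(3, seed = 7)
  s <- read_structure(b$pdb_lines)
  expect_equal(n_atoms(s), 15)
  expect_equal(nrow(residues(s)), 3)
  expect_equal(nrow(het_groups(s)), 0)
  expect_equal(residues(s)$key, b$truth$residue_keys)
})

test_that("read -> write -> read preserves atoms, keys and coordinates to PDB precision", {
  b <- make_toy_structure(5, seed = 3, probe_distance = 4)
  s1 <- read_structure(b$pdb_lines)
  tf <- tempfile(fileext = ".pdb")
  write_structure(s1, tf)
  s2 <- read_structure(tf)
  expect_equal(n_atoms(s2), n_atoms(s1))
  expect_equal(s2$atoms$name, s1$atoms$name)
  expect_equal(residues(s2)$key, residues(s1)$key)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s1$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("empty or record-free input is rejected", {
  expect_error(read_structure(c("HEADER    NOTHING", "END")), "no ATOM")
  expect_error(read_structure(""), "empty")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
  s <- read_structure(lines)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 5.0)
})

test_that("preparation keeps chains, strips waters, filters het groups and is idempotent", {
  # two chains + waters + two het codes
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2, 1.4, 0, "C"),
    pdb_atom_line(4, "N", "GLY", "B", 1, 10, 0, 0, "N"),
    pdb_atom_line(5, "CA", "GLY", "B", 1, 11.4, 0, 0, "C"),
    pdb_atom_line(6, "O", "HOH", "A", 101, 5, 5, 5, "O", het = TRUE),
    pdb_atom_line(7, "O", "HOH", "A", 102, 6, 6, 6, "O", het = TRUE),
    pdb_atom_line(8, "FE", "HEM", "A", 200, 3, 3, 3, "FE", het = TRUE),
    pdb_atom_line(9, "C1", "XYZ", "A", 201, 8, 8, 8, "C", het = TRUE),
    "END")
  s <- read_structure(lines)
  cfg <- preparation_config("A", het_to_keep = "HEM")
  p <- suppressMessages(prepare_structure(s, cfg))
  expect_setequal(unique(p$atoms$chain), "A")
  expect_false(any(p$atoms$resname %in% c("HOH", "XYZ")))
  expect_true("HEM" %in% p$atoms$resname)
  p2 <- suppressMessages(prepare_structure(p, cfg))
  expect_identical(p2$atoms, p$atoms)
  expect_error(prepare_structure(s, preparation_config("Z")),
               "available chains")
  expect_warning(prepare_structure(s, preparation_config("B", het_to_keep = "HEM")),
                 "not present")
})

test_that("radius assignment is a pure lookup that touches nothing else", {
  b <- make_toy_structure(4, seed = 2)
  s <- read_structure(b$pdb_lines)
  t0 <- vdw_table()
  s2 <- assign_radii(s, t0)
  expect_false(anyNA(s2$atoms$vdw))
  expect_equal(s2$atoms$vdw, unname(t0[s2$atoms$elem]))
  expect_identical(s2$atoms[, c("x", "y", "z", "name")],
                   s$atoms[, c("x", "y", "z", "name")])
  # a table missing the iron entry must name the orphan atom
  fe <- mini_structure(data.frame(
    name = "FE", elem = "FE", resname = "HEM", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, het = TRUE))
  expect_error(assign_radii(fe, structure(c(C = 1.7), set = "toy")), "FE")
})

test_that("ligand reading handles SDF and docked-pose PDB input", {
  sdf <- c("probe", "  built by hand", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    1.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.5000    0.0000    1.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "M  END", "$$$$")
  lig <- read_ligand(sdf)
  expect_equal(n_atoms(lig), 2)
  expect_setequal(lig$atoms$elem, c("C", "O"))
  expect_true(all(lig$atoms$het))
  # flat (z = 0) coordinates trigger a 2D warning
  sdf2d <- sub("    0.0000    0.0000    1.0000", "    0.0000    0.0000    0.0000",
               sub("    1.5000    0.0000    1.0000",
                   "    1.5000    0.0000    0.0000", sdf))
  expect_warning(read_ligand(sdf2d), "2D")
  # PDB pose: coordinates come back exactly as written
  pose <- c(pdb_atom_line(1, "C1", "OMP", "X", 900, 1.25, -2.5, 3.75, "C",
                          het = TRUE), "END")
  lp <- read_ligand(pose)
  expect_equal(as.numeric(lp$atoms[1, c("x", "y", "z")]), c(1.25, -2.5, 3.75))
})

test_that("ligand merge places the ligand in the het groups without touching the protein", {
  b <- make_toy_structure(4, seed = 2)
  s <- read_structure(b$pdb_lines)
  lig <- mini_structure(data.frame(
    name = c("C1", "O1"), elem = c("C", "O"), resname = "LIG", chain = "X",
    resno = 900, x = c(20, 21.4), y = 0, z = 0, het = TRUE))
  s2 <- add_ligand(s, lig)
  expect_equal(n_atoms(s2), n_atoms(s) + 2)
  expect_equal(nrow(het_groups(s2)), 1)
  expect_identical(s2$atoms[seq_len(n_atoms(s)), c("x", "y", "z")],
                   s$atoms[, c("x", "y", "z")])
})

test_that("ideal-geometry hydrogen placement adds amide hydrogens at sane geometry", {
  b <- make_toy_structure(6, seed = 1)
  s <- read_structure(b$pdb_lines)
  p <- suppressWarnings(
    prepare_structure(s, preparation_config("A", add_hydrogens = TRUE)))
  expect_equal(p$metadata$hydrogen_mode, "explicit-polar")
  hs <- p$atoms[p$atoms$elem == "H", ]
  expect_equal(nrow(hs), 5)  # one amide H per residue after the first
  # each H sits ~1.01 A from its nitrogen
  for (i in seq_len(nrow(hs))) {
    n <- p$atoms[p$atoms$resno == hs$resno[i] & p$atoms$name == "N", ]
    d <- sqrt((hs$x[i] - n$x)^2 + (hs$y[i] - n$y)^2 + (hs$z[i] - n$z)^2)
    expect_equal(d, 1.01, tolerance = 1e-6)
  }
})
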