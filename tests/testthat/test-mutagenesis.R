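lib <- rotamer_library()

test_that("mutation labels parse and mismatches are caught", {
  m <- mutation_spec("A297V")
  expect_equal(m$resno, 297)
  expect_equal(m$wt, "A")
  expect_equal(m$alt, "V")
  expect_error(mutation_spec("297V"), "A297V")
  s <- read_structure(make_toy_structure(4, seed = 1)$pdb_lines)
  expect_error(apply_mutation(s, mutation_spec("G2V"), lib), "mismatch")
  expect_error(apply_mutation(s, mutation_spec("A99V"), lib), "no residue")
})

test_that("identity mutation leaves every coordinate untouched", {
  s <- read_structure(make_toy_structure(5, seed = 1)$pdb_lines)
  m <- apply_mutation(s, mutation_spec("A3A"), lib)
  expect_identical(m$atoms, s$atoms)
  expect_equal(m$metadata$mutations[[1]]$label, "A3A")
})

test_that("mutation to glycine strips the side chain entirely", {
  s <- read_structure(make_toy_structure(5, seed = 1)$pdb_lines)
  m <- apply_mutation(s, mutation_spec("A3G"), lib)
  r3 <- m$atoms[m$atoms$resno == 3 & !m$atoms$het, ]
  expect_setequal(r3$name, c("N", "CA", "C", "O"))
  expect_equal(r3$resname[1], rep("GLY", 1))
})

test_that("alanine-to-valine builds the full valine side chain on a fixed backbone", {
  s <- read_structure(make_toy_structure(7, seed = 1)$pdb_lines)
  m <- apply_mutation(s, mutation_spec("A4V"), lib)
  r4 <- m$atoms[m$atoms$resno == 4 & !m$atoms$het, ]
  expect_equal(r4$resname[1], "VAL")
  expect_setequal(r4$name, c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  # backbone atoms bit-identical to the wild type
  for (nm in c("N", "CA", "C", "O")) {
    expect_identical(
      as.numeric(m$atoms[m$atoms$resno == 4 & m$atoms$name == nm,
                         c("x", "y", "z")]),
      as.numeric(s$atoms[s$atoms$resno == 4 & s$atoms$name == nm,
                         c("x", "y", "z")]))
  }
  # every other residue untouched
  strip <- function(df) { rownames(df) <- NULL; df }
  expect_identical(strip(m$atoms[m$atoms$resno != 4, c("name", "x", "y", "z")]),
                   strip(s$atoms[s$atoms$resno != 4, c("name", "x", "y", "z")]))
})

test_that("side-chain placement agrees with an independent rotation-matrix oracle", {
  s <- read_structure(make_toy_structure(6, seed = 1)$pdb_lines)
  # single-rotamer library: cysteine at chi1 = -65
  single <- lib
  single$rotamers <- data.frame(aa = "CYS", rot = 1L, chi1 = -65,
                                chi2 = NA, chi3 = NA, chi4 = NA, prob = 1)
  m <- apply_mutation(s, mutation_spec("A3C"), single)
  r3 <- m$atoms[m$atoms$resno == 3 & !m$atoms$het, ]
  g <- function(nm) as.numeric(r3[r3$name == nm, c("x", "y", "z")])
  cb_expect <- oracle_place_atom(g("C"), g("N"), g("CA"), 1.53, 110.5, -122.6)
  expect_equal(g("CB"), cb_expect, tolerance = 1e-9)
  sg_expect <- oracle_place_atom(g("N"), g("CA"), cb_expect, 1.808, 114.4, -65)
  expect_equal(g("SG"), sg_expect, tolerance = 1e-9)
  # and the realised internal coordinates round-trip
  expect_equal(cypvar:::point_torsion(g("N"), g("CA"), g("CB"), g("SG")), -65,
               tolerance = 1e-6)
  expect_equal(cypvar:::point_angle(g("CA"), g("CB"), g("SG")), 114.4,
               tolerance = 1e-6)
})

test_that("every buildable amino acid produces its complete heavy-atom set", {
  # completeness of the topology table: mutate the same site to all 20
  s <- read_structure(make_toy_structure(9, seed = 1)$pdb_lines)
  expected_extra <- list(
    ALA = "CB", ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("CB", "CG", "OD1", "ND2"), ASP = c("CB", "CG", "OD1", "OD2"),
    CYS = c("CB", "SG"), GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"), GLY = character(0),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"), LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"), MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"), SER = c("CB", "OG"), THR = c("CB", "OG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c("CB", "CG1", "CG2"))
  for (aa1 in names(cypvar:::AA1)) {
    m <- apply_mutation(s, mutation_spec(paste0("A5", aa1)), lib)
    r <- m$atoms[m$atoms$resno == 5 & !m$atoms$het, ]
    expect_setequal(r$name,
                    c("N", "CA", "C", "O", expected_extra[[cypvar:::AA1[[aa1]]]]))
    # all bonds have sensible lengths (no atom placed on top of another)
    xyz <- as.matrix(r[, c("x", "y", "z")])
    expect_gt(min(dist(xyz)), 1.1)
  }
})

test_that("rotamer choice is the clash-count argmin with deterministic tie-breaks", {
  env <- matrix(c(0, 0, 0), ncol = 3)
  env_r <- 1.7
  cand <- function(x, prob, rot) {
    list(coords = matrix(c(x, 0, 0), ncol = 3, dimnames = list("CG", NULL)),
         elem = "C", prob = prob, rot = rot)
  }
  # one candidate returns itself
  expect_equal(select_rotamer(list(cand(10, 1, 1)), env, env_r)$index, 1)
  # clashing candidate (overlap 1.0) loses to the clear one
  sel <- select_rotamer(list(cand(2.4, 0.9, 1), cand(10, 0.1, 2)), env, env_r)
  expect_equal(sel$index, 2)
  expect_equal(sel$clashes, c(1L, 0L))
  # equal clash counts: higher probability wins, then lower index
  sel2 <- select_rotamer(list(cand(10, 0.2, 1), cand(11, 0.5, 2)), env, env_r)
  expect_equal(sel2$index, 2)
  sel3 <- select_rotamer(list(cand(10, 0.5, 1), cand(11, 0.5, 2)), env, env_r)
  expect_equal(sel3$index, 1)
  # probability rule ignores clashes
  sel4 <- select_rotamer(list(cand(2.4, 0.9, 1), cand(10, 0.1, 2)), env, env_r,
                         rule = "probability")
  expect_equal(sel4$index, 1)
})

test_that("selection equals the brute-force clash argmin on random candidates", {
  radii <- vdw_table()
  for (seed in 1:5) {
    set.seed(seed)
    env <- matrix(runif(30, -4, 4), ncol = 3)
    env_r <- rep(1.7, nrow(env))
    cands <- lapply(1:5, function(i) {
      co <- matrix(runif(9, -4, 4), ncol = 3,
                   dimnames = list(c("CB", "CG", "CD"), NULL))
      list(coords = co, elem = c("C", "C", "C"), prob = runif(1), rot = i)
    })
    sel <- select_rotamer(cands, env, env_r)
    brute <- vapply(cands, function(cn) {
      n <- 0L
      for (i in seq_len(nrow(cn$coords))) for (j in seq_len(nrow(env))) {
        d <- sqrt(sum((cn$coords[i, ] - env[j, ])^2))
        if (1.7 + env_r[j] - d >= 0.6) n <- n + 1L
      }
      n
    }, integer(1))
    expect_equal(sel$clashes, brute)
    probs <- vapply(cands, `[[`, numeric(1), "prob")
    expect_equal(sel$index, order(brute, -probs)[1])
  }
})

test_that("mutation is deterministic and round-trips backbone and residue name", {
  s <- read_structure(make_toy_structure(7, seed = 1)$pdb_lines)
  m1 <- apply_mutation(s, mutation_spec("A4F"), lib)
  m2 <- apply_mutation(s, mutation_spec("A4F"), lib)
  expect_identical(m1$atoms, m2$atoms)
  back <- apply_mutation(m1, mutation_spec("F4A"), lib)
  r4 <- back$atoms[back$atoms$resno == 4 & !back$atoms$het, ]
  expect_equal(r4$resname[1], "ALA")
  for (nm in c("N", "CA", "C", "O")) {
    expect_identical(
      as.numeric(r4[r4$name == nm, c("x", "y", "z")]),
      as.numeric(s$atoms[s$atoms$resno == 4 & s$atoms$name == nm,
                         c("x", "y", "z")]))
  }
})
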