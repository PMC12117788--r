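two_atoms <- function(d, elem = c("C", "C")) {
  mini_structure(data.frame(
    name = paste0(elem, 1:2), elem = elem, resname = "PRB", chain = "X",
    resno = 1:2, x = c(0, d), y = 0, z = 0, het = TRUE))
}

test_that("overlap arithmetic matches touching-sphere intuition and is symmetric", {
  a <- list(x = 0, y = 0, z = 0, vdw = 1.7)
  b <- list(x = 3.4, y = 0, z = 0, vdw = 1.7)
  expect_equal(compute_overlap(a, b), 0)
  b$x <- 2.8
  expect_equal(compute_overlap(a, b), 0.6)
  expect_equal(compute_overlap(b, a), compute_overlap(a, b))
  expect_warning(ov <- compute_overlap(a, list(x = 0, y = 0, z = 0, vdw = 1.5)),
                 "coincident")
  expect_equal(ov, 3.2)
  expect_error(compute_overlap(a, list(x = 1, y = 0, z = 0, vdw = NA)), "radius")
})

test_that("overlap equals the direct formula on random atom pairs", {
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(6, -50, 50)
    r <- runif(2, 1.2, 2.0)
    a <- list(x = p[1], y = p[2], z = p[3], vdw = r[1])
    b <- list(x = p[4], y = p[5], z = p[6], vdw = r[2])
    d <- sqrt(sum((p[1:3] - p[4:6])^2))
    expect_equal(compute_overlap(a, b), r[1] + r[2] - d, tolerance = 1e-9)
  }
})

test_that("apolar pairs never form hydrogen bonds; polar pairs obey the relaxed criteria", {
  s <- assign_radii(two_atoms(3.0))
  expect_equal(nrow(find_hbonds(s)), 0)
  # N...O at 2.9 A within base 2.9 + relax 0.4 -> bond (no antecedent: angle passes)
  s2 <- assign_radii(two_atoms(2.9, elem = c("N", "O")))
  expect_equal(nrow(find_hbonds(s2)), 2)  # stored from both donor views
  # beyond the relaxed limit -> none
  s3 <- assign_radii(two_atoms(3.5, elem = c("N", "O")))
  expect_equal(nrow(find_hbonds(s3)), 0)
})

test_that("backbone amide geometry in a helix yields i -> i+4 hydrogen bonds", {
  s <- assign_radii(read_structure(make_toy_structure(8, seed = 1)$pdb_lines))
  hb <- find_hbonds(s)
  expect_gt(nrow(hb), 0)
  pairs <- unique(data.frame(
    don = s$atoms$resno[hb$i], acc = s$atoms$resno[hb$j],
    de = s$atoms$elem[hb$i], ae = s$atoms$elem[hb$j]))
  nh_oc <- pairs[pairs$de == "N" & pairs$ae == "O", ]
  expect_true(any(abs(nh_oc$don - nh_oc$acc) == 4))
})

test_that("the donor-angle criterion rejects occluded geometries", {
  # donor N with a heavy antecedent C placed so the C-N...O angle is ~0:
  # acceptor sits behind the antecedent
  s <- mini_structure(data.frame(
    name = c("C", "N", "O"), elem = c("C", "N", "O"),
    resname = c("AAA", "AAA", "BBB"), chain = "A", resno = c(1, 1, 2),
    x = c(1.4, 0, 2.8), y = 0, z = 0, het = FALSE))
  s <- assign_radii(s)
  hb <- find_hbonds(s)
  # N -> O direction blocked (angle 0 < 70); O as donor has no antecedent, so
  # the O -> N view is still stored
  expect_false(any(s$atoms$elem[hb$i] == "N"))
})

test_that("contact records honour cutoffs, the H-bond allowance and closed boundaries", {
  p <- interaction_params()
  s <- assign_radii(two_atoms(3.81))
  expect_equal(nrow(find_contacts(s, 1)), 0)        # overlap -0.41 < -0.4
  s <- assign_radii(two_atoms(3.80))
  expect_equal(nrow(find_contacts(s, 1)), 1)        # exactly -0.4: included
  s <- assign_radii(two_atoms(2.80))
  rec <- find_contacts(s, 1)
  expect_equal(rec$klass, "clash")                  # exactly 0.6: clash
  s <- assign_radii(two_atoms(2.79))
  rec <- find_contacts(s, 1)
  expect_equal(rec$overlap, 0.61, tolerance = 1e-9)
  expect_equal(rec$klass, "clash")
  # same overlap but H-bonded: effective 0.21 -> contact, still recorded
  hb <- data.frame(i = 1L, j = 2L, distance = 2.79, angle = NA,
                   mode = "heavy-atom")
  rec2 <- find_contacts(s, 1, hbonds = hb)
  expect_equal(rec2$klass, "contact")
  expect_true(rec2$is_hbond)
  expect_equal(rec2$effective_overlap, 0.21, tolerance = 1e-9)
  expect_error(find_contacts(s, integer(0)), "selection")
})

test_that("selection/environment roles do not change overlap or class", {
  b <- make_contact_fixture(60, box_size = 14, seed = 5)
  s <- b$input$structure
  fwd <- find_contacts(s, b$input$selection, b$input$environment)
  rev <- find_contacts(s, b$input$environment, b$input$selection)
  key_f <- paste(pmin(fwd$i, fwd$j), pmax(fwd$i, fwd$j))
  key_r <- paste(pmin(rev$i, rev$j), pmax(rev$i, rev$j))
  expect_setequal(key_f, key_r)
  m <- match(key_f, key_r)
  expect_equal(fwd$overlap, rev$overlap[m], tolerance = 1e-9)
  expect_equal(fwd$klass, rev$klass[m])
})

test_that("accelerated neighbour search equals the exhaustive scan on seeded fixtures", {
  for (seed in 1:12) {
    n <- sample(40:120, 1)
    b <- make_contact_fixture(n, box_size = 16, seed = seed)
    got <- find_contacts(b$input$structure, b$input$selection,
                         b$input$environment)
    want <- b$truth$records
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$overlap, want$overlap, tolerance = 1e-9)
    expect_equal(got$is_hbond, want$is_hbond)
    expect_equal(got$klass, want$klass)
  }
})

test_that("shrinking a pair distance never removes a record or downgrades a clash", {
  rank_of <- function(d) {
    s <- assign_radii(two_atoms(d))
    rec <- find_contacts(s, 1)
    if (nrow(rec) == 0) 0L else if (rec$klass == "contact") 1L else 2L
  }
  ds <- seq(4.2, 0.4, by = -0.2)
  ranks <- vapply(ds, rank_of, integer(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("clash distances follow the side-chain-direct / backbone-CA rule", {
  # mutated residue 1 (single CB atom stand-in), partner residue with
  # backbone O + CA, and a het ligand atom
  s <- mini_structure(data.frame(
    name = c("N", "CA", "CB", "N", "CA", "O", "C1"),
    elem = c("N", "C", "C", "N", "C", "O", "C"),
    resname = c("ALA", "ALA", "ALA", "GLY", "GLY", "GLY", "LIG"),
    chain = c("A", "A", "A", "A", "A", "A", "X"),
    resno = c(10, 10, 10, 11, 11, 11, 900),
    x = c(-3, -1.5, 0, 2.0, 3.9, 2.0, 0),
    y = c(0, 1, 0, 0, 0, 2.0, 2.5),
    z = 0, het = c(rep(FALSE, 6), TRUE)))
  s <- assign_radii(s)
  cb <- which(s$atoms$name == "CB")
  lig <- which(s$atoms$name == "C1")
  o <- which(s$atoms$name == "O" & s$atoms$resno == 11)
  # ligand partner: direct distance (2.5 A by construction)
  rec_lig <- data.frame(i = cb, j = lig, distance = 2.5, overlap = 0.9,
                        is_hbond = FALSE, effective_overlap = 0.9,
                        klass = "clash")
  expect_equal(clash_distance(s, rec_lig, "A:10"), 2.5, tolerance = 1e-9)
  # backbone O partner: distance to that residue's CA (3.9 A from CB at origin)
  rec_bb <- data.frame(i = cb, j = o, distance = sqrt(2^2 + 2^2),
                       overlap = 0.6, is_hbond = FALSE,
                       effective_overlap = 0.6, klass = "clash")
  expect_equal(clash_distance(s, rec_bb, "A:10"), 3.9, tolerance = 1e-9)
  # side-chain partner would be direct: CA is backbone, CB is not
  rec_err <- data.frame(i = lig, j = lig, distance = 0, overlap = 0,
                        is_hbond = FALSE, effective_overlap = 0,
                        klass = "clash")
  expect_error(clash_distance(s, rec_err, "A:10"), "mutated residue")
  # missing CA in the partner residue is an error
  s2 <- s
  s2$atoms <- s2$atoms[s2$atoms$name != "CA" | s2$atoms$resno != 11, ]
  rec_bb2 <- rec_bb
  rec_bb2$j <- which(s2$atoms$name == "O" & s2$atoms$resno == 11)
  rec_bb2$i <- which(s2$atoms$name == "CB")
  expect_error(clash_distance(s2, rec_bb2, "A:10"), "CA")
})

test_that("variant reports count site interactions and flag constructed clashes", {
  b <- make_toy_structure(7, seed = 1, probe_distance = 6, probe_residue = 4)
  wt <- assign_radii(read_structure(b$pdb_lines))
  # identity: zero difference, clash count equal in both states
  rep0 <- variant_report(wt, wt, "A:4", label = "A4A")
  expect_equal(rep0$difference, 0)
  expect_equal(rep0$n_interactions_wt, rep0$n_interactions_mut)
  # constructed mutant: move the site CB to overlap the probe by 0.7
  mut <- wt
  probe <- which(mut$atoms$resname == "PRB")
  cb <- which(mut$atoms$resno == 4 & mut$atoms$name == "CB")
  target <- as.numeric(mut$atoms[probe, c("x", "y", "z")])
  dirv <- c(1, 0, 0)
  newpos <- target - (1.7 + 1.7 - 0.7) * dirv
  mut$atoms[cb, c("x", "y", "z")] <- as.list(newpos)
  rep1 <- variant_report(wt, mut, "A:4", label = "A4X")
  probe_clashes <- rep1$records$mut[rep1$records$mut$j == probe &
                                      rep1$records$mut$klass == "clash", ]
  expect_equal(nrow(probe_clashes), 1)
  expect_gte(rep1$n_clashes_mut, 1)
  expect_equal(rep1$conventions$counting_unit, "atom-pairs")
  expect_equal(rep1$conventions$radius_set, "bondi")
  # clash distance for the het partner is the direct distance (2.7 A)
  expect_equal(clash_distance(mut, probe_clashes, "A:4"), 2.7,
               tolerance = 1e-9)
  # structures differing outside the site are rejected
  bad <- wt
  bad$atoms$x[bad$atoms$resno == 2][1] <- 99
  expect_error(variant_report(wt, bad, "A:4"), "outside the site")
})
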