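# Seeded generators for every input the pipeline consumes, each bundled with
# ground truth computed by routines independent of the analysis modules they
# exercise. All generators are pure functions of (parameters, seed).

with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

new_fixture_bundle <- function(input, truth, seed, params) {
  structure(list(input = input, truth = truth, seed = seed, params = params),
            class = "fixture_bundle")
}

# Ideal poly-alanine backbone (N, CA, C, O, CB per residue) built by NeRF
# chaining with the given phi/psi; omega fixed at 180.
build_polyala <- function(n_residues, phi, psi) {
  res <- vector("list", n_residues)
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  c_at <- ca + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues)) {
    o <- place_atom(n, ca, c_at, 1.231, 120.5, psi + 180)
    cb <- place_atom(c_at, n, ca, 1.53, 110.5, -122.6)
    res[[i]] <- rbind(N = n, CA = ca, C = c_at, O = o, CB = cb)
    if (i < n_residues) {
      n_next <- place_atom(n, ca, c_at, 1.329, 116.2, psi)
      ca_next <- place_atom(ca, c_at, n_next, 1.458, 121.7, 180)
      c_next <- place_atom(c_at, n_next, ca_next, 1.525, 111.2, phi)
      n <- n_next; ca <- ca_next; c_at <- c_next
    }
  }
  res
}

#' Generate an ideal poly-alanine toy structure
#'
#' Builds an ideal-geometry poly-alanine fold (alpha-helix phi/psi -57/-47 or
#' beta-strand -120/+120), optionally planting a single het probe atom at a
#' known distance from one residue's CB. The bundle's ground truth records
#' the atom count, residue keys and the planted probe distance, all computed
#' during construction (not by the structure reader).
#'
#' @param n_residues number of residues (>= 3).
#' @param geometry `"helix"` or `"strand"`.
#' @param seed RNG seed (recorded; construction itself is deterministic).
#' @param probe_distance if non-`NULL`, plant a het carbon at this distance
#'   (A) from the CB of `probe_residue`, along the CA->CB direction.
#' @param probe_residue residue index carrying the probe.
#' @return A `fixture_bundle` with `input` = the structure (plus `pdb_lines`)
#'   and `truth` = list(n_atoms, residue_keys, probe_distance, probe_serial).
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "strand"),
                               seed = 1, probe_distance = NULL,
                               probe_residue = ceiling(n_residues / 2)) {
  geometry <- match.arg(geometry)
  if (n_residues < 3) stop("n_residues must be >= 3")
  ang <- if (geometry == "helix") c(-57, -47) else c(-120, 120)
  res <- build_polyala(n_residues, ang[1], ang[2])
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    m <- res[[i]]
    for (nm in rownames(m)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, elem = substr(nm, 1, 1), resname = "ALA",
        chain = "A", resno = i, icode = "", x = m[nm, 1], y = m[nm, 2],
        z = m[nm, 3], occ = 1, het = FALSE, vdw = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  truth <- list(n_atoms = nrow(atoms),
                residue_keys = paste0("A:", seq_len(n_residues)),
                probe_distance = NULL, probe_serial = NULL)
  if (!is.null(probe_distance)) {
    m <- res[[probe_residue]]
    dir <- unit_vec(m["CB", ] - m["CA", ])
    p <- m["CB", ] + probe_distance * dir
    atoms <- rbind(atoms, data.frame(
      serial = nrow(atoms) + 1L, name = "C1", elem = "C", resname = "PRB",
      chain = "X", resno = 900L, icode = "", x = p[1], y = p[2], z = p[3],
      occ = 1, het = TRUE, vdw = NA_real_, stringsAsFactors = FALSE))
    truth$probe_distance <- probe_distance
    truth$probe_serial <- nrow(atoms)
    truth$n_atoms <- nrow(atoms)
  }
  s <- new_structure(atoms, source = sprintf("toy-%s-%d", geometry, n_residues))
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  bundle <- new_fixture_bundle(
    input = list(structure = s, pdb_lines = readLines(tf, warn = FALSE)),
    truth = truth, seed = seed,
    params = list(n_residues = n_residues, geometry = geometry,
                  probe_distance = probe_distance,
                  probe_residue = probe_residue))
  bundle$pdb_lines <- bundle$input$pdb_lines
  bundle
}

# Independent brute-force truth for contact fixtures: plain double loop over
# cross pairs, no neighbour search, no calls into the contact engine.
brute_force_contacts <- function(atoms, sel, env, params) {
  radii <- vdw_table()
  r <- unname(radii[match(atoms$elem, names(radii))])
  polar <- atoms$elem %in% c("N", "O", "S")
  recs <- list()
  for (i in sel) {
    for (j in env) {
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      ov <- r[i] + r[j] - d
      if (ov < params$contact_overlap_cutoff) next
      hb <- FALSE
      if (polar[i] && polar[j]) {
        base <- params$hbond_base_dist[hb_pair_key(atoms$elem[i], atoms$elem[j])]
        hb <- !is.na(base) && d <= base + params$hbond_dist_relax
      }
      eff <- ov - if (hb) params$hbond_allowance else 0
      recs[[length(recs) + 1]] <- data.frame(
        i = i, j = j, distance = d, overlap = ov, is_hbond = hb,
        effective_overlap = eff,
        klass = if (eff >= params$clash_overlap_cutoff) "clash" else "contact",
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(contact_empty())
  out <- do.call(rbind, recs)
  out[order(out$i, out$j), ]
}

#' Generate a random-atom contact fixture with exhaustive ground truth
#'
#' Atoms are dropped uniformly in a cubic box with elements drawn from
#' {C, N, O, S} at fixed weights; each atom is its own het group, so no
#' bonded-pair exclusions apply. The first half of the atoms form the
#' selection, the rest the environment, and the truth is the full O(n^2)
#' cross-pair contact/clash enumeration under the supplied parameters,
#' computed by an independent double-loop routine.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param box_size cube edge (A).
#' @param seed RNG seed.
#' @param params an [interaction_params()].
#' @return A `fixture_bundle` with `input$structure` (radii assigned),
#'   `input$selection`, `input$environment` and `truth$records`.
#' @export
make_contact_fixture <- function(n_atoms, box_size = 20, seed = 1,
                                 params = interaction_params()) {
  stopifnot(n_atoms >= 2)
  atoms <- with_seed_local(seed, {
    elem <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                   prob = c(0.55, 0.2, 0.2, 0.05))
    data.frame(
      serial = seq_len(n_atoms), name = paste0(elem, seq_len(n_atoms)),
      elem = elem, resname = "PRB", chain = "X", resno = seq_len(n_atoms),
      icode = "", x = stats::runif(n_atoms, 0, box_size),
      y = stats::runif(n_atoms, 0, box_size),
      z = stats::runif(n_atoms, 0, box_size), occ = 1, het = TRUE,
      vdw = NA_real_, stringsAsFactors = FALSE)
  })
  sel <- seq_len(max(1, floor(n_atoms / 2)))
  env <- setdiff(seq_len(n_atoms), sel)
  truth <- brute_force_contacts(atoms, sel, env, params)
  s <- assign_radii(new_structure(atoms, source = sprintf("contact-fixture-%d", seed)))
  new_fixture_bundle(
    input = list(structure = s, selection = sel, environment = env),
    truth = list(records = truth),
    seed = seed,
    params = list(n_atoms = n_atoms, box_size = box_size,
                  interaction = params))
}

#' Generate a five-predictor score table with known call pattern
#'
#' Each (variant, predictor) cell is independently deleterious with
#' probability `deleterious_fraction`; raw scores are then drawn uniformly
#' from ranges strictly on the corresponding side of the default thresholds,
#' so each variant's true call pattern - and hence its expected
#' fraction-mode ensemble score - is known by construction.
#'
#' @param n_variants number of variants.
#' @param deleterious_fraction probability a call is deleterious, in `[0,1]`.
#' @param seed RNG seed.
#' @return A `fixture_bundle` with `input$table` (columns `variant` + five
#'   predictors) and `truth$scores` (expected ensemble score per variant)
#'   plus `truth$calls` (the planted logical matrix).
#' @export
make_score_table <- function(n_variants, deleterious_fraction, seed = 1) {
  stopifnot(deleterious_fraction >= 0, deleterious_fraction <= 1)
  ranges <- list(
    lrt = list(del = c(0, 0.0005), ben = c(0.1, 1)),
    mutation_assessor = list(del = c(2.5, 5), ben = c(0, 1)),
    provean = list(del = c(-10, -4), ben = c(-1, 1)),
    vest3 = list(del = c(0.7, 1), ben = c(0, 0.3)),
    cadd = list(del = c(25, 40), ben = c(0, 10)))
  with_seed_local(seed, {
    calls <- matrix(stats::runif(n_variants * 5) < deleterious_fraction,
                    nrow = n_variants,
                    dimnames = list(NULL, PREDICTORS))
    tab <- data.frame(variant = sprintf("V%03d", seq_len(n_variants)),
                      stringsAsFactors = FALSE)
    for (p in PREDICTORS) {
      rg <- ranges[[p]]
      del <- stats::runif(n_variants, rg$del[1], rg$del[2])
      ben <- stats::runif(n_variants, rg$ben[1], rg$ben[2])
      tab[[p]] <- ifelse(calls[, p], del, ben)
    }
    new_fixture_bundle(
      input = list(table = tab),
      truth = list(scores = rowMeans(calls), calls = calls),
      seed = seed,
      params = list(n_variants = n_variants,
                    deleterious_fraction = deleterious_fraction))
  })
}

#' Generate triplicate assay data with lognormal noise
#'
#' Replicate product-formation rates for a variant and its wild-type
#' reference, drawn lognormally (mean-preserving) around the true means with
#' the stated coefficient of variation; multiplicative noise matches the way
#' assay SDs scale with the mean. The reference batch is rescaled so its
#' sample mean is exactly 100 arbitrary units: in relative-activity assays
#' the wild-type batch mean *defines* the 100% basis of each expression set,
#' so the noise that matters for recovery lives on the relative
#' measurements. `cv = 0` returns the exact true rates.
#'
#' @param true_activity_pct true relative activity (percent of reference).
#' @param cv coefficient of variation of the replicate noise (>= 0).
#' @param n_replicates replicates per group (>= 2; assays usually use 3).
#' @param seed RNG seed.
#' @return A `fixture_bundle` with `input$rates`, `input$reference_rates`
#'   and `truth$true_activity_pct`.
#' @export
make_assay_data <- function(true_activity_pct, cv = 0.3, n_replicates = 3,
                            seed = 1) {
  stopifnot(cv >= 0, n_replicates >= 2, true_activity_pct >= 0)
  ref_mean <- 100
  var_mean <- true_activity_pct
  draw <- function(mu, n) {
    if (cv == 0 || mu == 0) return(rep(mu, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed_local(seed, {
    rates <- draw(var_mean, n_replicates)
    ref <- draw(ref_mean, n_replicates)
    if (mean(ref) > 0) ref <- ref * ref_mean / mean(ref)
    new_fixture_bundle(
      input = list(rates = rates, reference_rates = ref),
      truth = list(true_activity_pct = true_activity_pct),
      seed = seed,
      params = list(cv = cv, n_replicates = n_replicates))
  })
}

#' Hollow-cylinder channel fixture with analytic ground truth
#'
#' Carbon atoms on a cylinder around the z axis (open at the top), with a
#' heme-like FE atom at the base. The widest escape path runs up the axis;
#' its probe-excess bottleneck clearance is analytically
#' `min(radius - r_C, origin_radius - r_Fe) - probe`: the wall limits the
#' clearance on the axis, and because every path must start inside the
#' origin sphere around the iron, the iron's own excluded sphere caps the
#' starting clearance at `origin_radius - r_Fe`. Residues can be planted at
#' known distances for proximity classification tests.
#'
#' @param radius cylinder radius to atom centres (A).
#' @param height cylinder height (A).
#' @param seed RNG seed (recorded; construction is deterministic).
#' @param ring_spacing vertical spacing of atom rings (A).
#' @param n_per_ring atoms per ring.
#' @param origin_radius origin-sphere radius assumed for the analytic truth
#'   (must match the `channel_params` used on the fixture; default 5).
#' @param probe_radius probe radius assumed for the truth (default 1.4).
#' @return A `fixture_bundle` with `input$structure` (radii assigned) and
#'   `truth$bottleneck` as above.
#' @export
make_tube_fixture <- function(radius = 6, height = 14, seed = 1,
                              ring_spacing = 1.2, n_per_ring = 24,
                              origin_radius = 5, probe_radius = 1.4) {
  zs <- seq(0, height, by = ring_spacing)
  ang <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  rows <- list()
  serial <- 0L
  for (z in zs) {
    for (a in ang) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = paste0("C", serial), elem = "C",
        resname = "TUB", chain = "X", resno = serial, icode = "",
        x = radius * cos(a), y = radius * sin(a), z = z, occ = 1, het = TRUE,
        vdw = NA_real_, stringsAsFactors = FALSE)
    }
  }
  # floor of atoms closing the bottom, plus the FE origin just above it
  fl <- expand.grid(x = seq(-radius, radius, by = 1.2),
                    y = seq(-radius, radius, by = 1.2))
  fl <- fl[fl$x^2 + fl$y^2 <= radius^2, ]
  for (i in seq_len(nrow(fl))) {
    serial <- serial + 1L
    rows[[serial]] <- data.frame(
      serial = serial, name = paste0("C", serial), elem = "C",
      resname = "TUB", chain = "X", resno = serial, icode = "",
      x = fl$x[i], y = fl$y[i], z = -1.2, occ = 1, het = TRUE,
      vdw = NA_real_, stringsAsFactors = FALSE)
  }
  serial <- serial + 1L
  rows[[serial]] <- data.frame(
    serial = serial, name = "FE", elem = "FE", resname = "HEM", chain = "X",
    resno = serial, icode = "", x = 0, y = 0, z = 2, occ = 1, het = TRUE,
    vdw = NA_real_, stringsAsFactors = FALSE)
  s <- assign_radii(new_structure(do.call(rbind, rows), source = "tube-fixture"))
  tab <- vdw_table()
  bneck <- min(radius - unname(tab["C"]),
               origin_radius - unname(tab["FE"])) - probe_radius
  new_fixture_bundle(
    input = list(structure = s),
    truth = list(bottleneck = bneck, axis = c(0, 0, 1)),
    seed = seed,
    params = list(radius = radius, height = height,
                  ring_spacing = ring_spacing, n_per_ring = n_per_ring,
                  origin_radius = origin_radius, probe_radius = probe_radius))
}
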