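# Rotamer-based in-silico mutagenesis: replace a residue's side chain with
# that of a target amino acid, keeping the backbone fixed.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

aa_three <- function(one) {
  out <- AA1[toupper(one)]
  if (anyNA(out)) stop("unknown amino acid code: ", one)
  unname(out)
}

aa_one <- function(three) {
  out <- names(AA1)[match(toupper(three), AA1)]
  if (anyNA(out)) stop("unknown amino acid code: ", three)
  out
}

#' Specify a point mutation
#'
#' @param label mutation label in `<wt><number><alt>` form, e.g. `"A297V"`.
#' @param chain chain identifier the residue lives on (default `"A"`).
#' @return A `mutation_spec` list with fields `chain`, `resno`, `wt`, `alt`,
#'   `label`.
#' @examples
#' mutation_spec("A297V")
#' @export
mutation_spec <- function(label, chain = "A") {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m) != 4) stop("label must look like A297V, got: ", label)
  structure(list(chain = chain, resno = as.integer(m[3]),
                 wt = toupper(m[2]), alt = toupper(m[4]), label = toupper(label)),
            class = "mutation_spec")
}

#' Load a rotamer library
#'
#' A backbone-independent library of common side-chain rotamers (chi angles in
#' degrees plus a prior probability per rotamer, probabilities summing to one
#' per amino acid) together with ideal internal geometry for side-chain
#' construction. A compact default library is bundled; any file in the same
#' tabular format (`aa rot chi1 chi2 chi3 chi4 prob`) can be substituted.
#'
#' @param file path to a rotamer table; default: the bundled library.
#' @return A `rotamer_library` object.
#' @export
rotamer_library <- function(file = system.file("extdata", "rotamers.tsv",
                                               package = "cypvar")) {
  rot <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sums <- tapply(rot$prob, rot$aa, sum)
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop("rotamer probabilities must sum to 1 per amino acid; off for: ",
         paste(names(sums)[off], collapse = ", "))
  }
  chis <- as.matrix(rot[, c("chi1", "chi2", "chi3", "chi4")])
  if (any(chis <= -180 | chis > 180, na.rm = TRUE)) {
    stop("chi angles must lie in (-180, 180]")
  }
  topo <- utils::read.table(system.file("extdata", "sidechain_topology.tsv",
                                        package = "cypvar"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  structure(list(rotamers = rot, topology = topo, file = file),
            class = "rotamer_library")
}

# Build the side-chain heavy atoms (CB onward) of `aa3` on a fixed backbone.
# n, ca, c: backbone coordinates; chis: numeric chi angles (degrees).
# Returns a matrix with one named row per placed atom.
build_sidechain <- function(aa3, n, ca, c, chis, topology) {
  placed <- list(N = n, CA = ca, C = c)
  out <- list()
  if (aa3 != "GLY") {
    # C-N-CA-CB improper of -122.6 degrees fixes L-chirality
    cb <- place_atom(c, n, ca, 1.53, 110.5, -122.6)
    placed$CB <- cb
    out$CB <- cb
  }
  rows <- topology[topology$aa == aa3, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tors <- if (r$chi > 0) {
      if (length(chis) < r$chi || is.na(chis[r$chi])) {
        stop("rotamer lacks chi", r$chi, " needed for ", aa3)
      }
      chis[r$chi] + r$offset
    } else {
      r$offset
    }
    pos <- place_atom(placed[[r$ref_a]], placed[[r$ref_b]], placed[[r$ref_c]],
                      r$bond, r$angle, tors)
    placed[[r$atom]] <- pos
    out[[r$atom]] <- pos
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Choose a rotamer candidate against a fixed environment
#'
#' Deterministic selection rule: the candidate with the fewest clashes
#' (van der Waals overlap at or above the clash cutoff) against the
#' environment wins; ties are broken by higher library probability, then by
#' lower candidate index. A pure probability ranking is available as an
#' alternative rule.
#'
#' @param candidates list of candidates, each a list with `coords` (matrix,
#'   rownames = atom names), `elem` (element per atom), `prob`, `rot` (id).
#' @param env_coords matrix of environment atom coordinates.
#' @param env_radii van der Waals radii of the environment atoms.
#' @param params an [interaction_params()].
#' @param rule `"min-clash"` (default) or `"probability"`.
#' @param radii radius table used for the candidate atoms.
#' @return List: `index` of the chosen candidate and per-candidate `clashes`.
#' @export
select_rotamer <- function(candidates, env_coords, env_radii,
                           params = interaction_params(),
                           rule = c("min-clash", "probability"),
                           radii = vdw_table()) {
  rule <- match.arg(rule)
  stopifnot(length(candidates) >= 1)
  clashes <- vapply(candidates, function(cand) {
    if (is.null(cand$coords) || nrow(cand$coords) == 0 ||
        is.null(env_coords) || nrow(env_coords) == 0) return(0L)
    r_cand <- unname(radii[match(toupper(cand$elem), names(radii))])
    d <- sqrt(outer(rowSums(cand$coords^2), rowSums(env_coords^2), "+") -
                2 * cand$coords %*% t(env_coords))
    ov <- outer(r_cand, env_radii, "+") - d
    sum(ov >= params$clash_overlap_cutoff)
  }, integer(1))
  probs <- vapply(candidates, function(cand) cand$prob, numeric(1))
  idx <- if (rule == "min-clash") {
    order(clashes, -probs, seq_along(candidates))[1]
  } else {
    order(-probs, seq_along(candidates))[1]
  }
  list(index = idx, clashes = clashes)
}

#' Apply a point mutation to a structure
#'
#' Keeps all backbone atoms of the site fixed, removes the old side chain and
#' rebuilds the target amino acid's side chain from rotamer chi angles with
#' ideal internal geometry. Every other residue, the heme and any ligand are
#' untouched. The selected rotamer and its clash count are recorded in the
#' structure's provenance metadata.
#'
#' @param s a `cyp_structure` (radii need not be assigned yet).
#' @param m a [mutation_spec()].
#' @param lib a [rotamer_library()].
#' @param rule rotamer selection rule, see [select_rotamer()].
#' @param params interaction parameters used for clash counting.
#' @return The mutated `cyp_structure`.
#' @examples
#' s <- read_structure(make_toy_structure(8, seed = 1)$pdb_lines)
#' mut <- apply_mutation(s, mutation_spec("A4V"), rotamer_library())
#' @export
apply_mutation <- function(s, m, lib = rotamer_library(),
                           rule = c("min-clash", "probability"),
                           params = interaction_params()) {
  stopifnot(inherits(s, "cyp_structure"), inherits(m, "mutation_spec"),
            inherits(lib, "rotamer_library"))
  rule <- match.arg(rule)
  idx <- which(s$atoms$chain == m$chain & s$atoms$resno == m$resno & !s$atoms$het)
  if (length(idx) == 0) {
    stop("no residue ", m$chain, ":", m$resno, " in structure")
  }
  if (any(diff(idx) != 1)) {
    stop("atoms of residue ", m$chain, ":", m$resno,
         " are not contiguous in the atom table")
  }
  res <- s$atoms[idx, , drop = FALSE]
  found_aa <- res$resname[1]
  if (found_aa != aa_three(m$wt)) {
    stop("wild-type mismatch at ", m$chain, ":", m$resno, ": expected ",
         aa_three(m$wt), ", found ", found_aa)
  }
  prov <- list(label = m$label, chain = m$chain, resno = m$resno, rule = rule)
  if (m$wt == m$alt) {
    out <- s
    prov$rotamer <- NA_integer_
    prov$clashes <- NA_integer_
    out$metadata$mutations <- c(out$metadata$mutations, list(prov))
    return(out)
  }
  bb <- c("N", "CA", "C")
  if (!all(bb %in% res$name)) {
    stop("residue ", m$chain, ":", m$resno, " lacks backbone atom(s): ",
         paste(setdiff(bb, res$name), collapse = ", "))
  }
  get_xyz <- function(nm) as.numeric(res[res$name == nm, c("x", "y", "z")][1, ])
  alt3 <- aa_three(m$alt)
  keep <- res$name %in% backbone_names()
  rot <- lib$rotamers[lib$rotamers$aa == alt3, , drop = FALSE]
  if (nrow(rot) == 0) stop("rotamer library has no entries for ", alt3)
  candidates <- lapply(seq_len(nrow(rot)), function(i) {
    chis <- as.numeric(rot[i, c("chi1", "chi2", "chi3", "chi4")])
    coords <- build_sidechain(alt3, get_xyz("N"), get_xyz("CA"), get_xyz("C"),
                              chis, lib$topology)
    list(coords = coords,
         elem = if (is.null(coords)) character(0) else guess_element(rownames(coords)),
         prob = rot$prob[i], rot = rot$rot[i],
         chis = chis)
  })
  env <- s$atoms[-idx, , drop = FALSE]
  radii <- vdw_table()
  env_r <- env$vdw
  if (anyNA(env_r)) env_r <- unname(radii[match(toupper(env$elem), names(radii))])
  env_r[is.na(env_r)] <- 1.7
  sel <- select_rotamer(candidates, as.matrix(env[, c("x", "y", "z")]), env_r,
                        params = params, rule = rule, radii = radii)
  chosen <- candidates[[sel$index]]
  new_bb <- res[keep, , drop = FALSE]
  new_bb$resname <- alt3
  side <- NULL
  if (!is.null(chosen$coords)) {
    nsc <- nrow(chosen$coords)
    side <- data.frame(
      serial = max(s$atoms$serial) + seq_len(nsc),
      name = rownames(chosen$coords),
      elem = chosen$elem, resname = alt3, chain = m$chain,
      resno = m$resno, icode = res$icode[1],
      x = chosen$coords[, 1], y = chosen$coords[, 2], z = chosen$coords[, 3],
      occ = 1, het = FALSE,
      vdw = if (all(!is.na(s$atoms$vdw))) {
        unname(radii[match(chosen$elem, names(radii))])
      } else NA_real_,
      stringsAsFactors = FALSE)
  }
  new_res <- rbind(new_bb, side)
  before <- s$atoms[seq_len(nrow(s$atoms)) < min(idx), , drop = FALSE]
  after <- s$atoms[seq_len(nrow(s$atoms)) > max(idx), , drop = FALSE]
  out <- s
  out$atoms <- rbind(before, new_res, after)
  rownames(out$atoms) <- NULL
  prov$rotamer <- chosen$rot
  prov$chis <- chosen$chis[!is.na(chosen$chis)]
  prov$clashes <- sel$clashes[sel$index]
  out$metadata$mutations <- c(out$metadata$mutations, list(prov))
  out
}
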