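# Reading, preparing and writing protein/ligand structures.
#
# A structure is held as a flat atom table (one row per atom) plus metadata.
# Coordinates are Angstrom; residue numbering follows PDB author numbering.

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resname`,
#'   `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`, `het`, `vdw`.
#' @param source free-text identifier of where the structure came from.
#' @param metadata optional list of extra metadata entries.
#' @return An object of class `cyp_structure`.
#' @export
new_structure <- function(atoms, source = "unknown", metadata = list()) {
  required <- c("serial", "name", "elem", "resname", "chain", "resno",
                "icode", "x", "y", "z", "occ", "het", "vdw")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("non-finite coordinates for atom serial(s): ",
         paste(utils::head(atoms$serial[bad], 5), collapse = ", "))
  }
  if (any(atoms$elem == "" | is.na(atoms$elem))) {
    stop("every atom needs an element symbol")
  }
  if (any(!is.na(atoms$vdw) & atoms$vdw <= 0)) {
    stop("assigned van der Waals radii must be positive")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  key <- residue_key_of(atoms)
  protein_keys <- unique(key[!atoms$het])
  metadata$source <- source
  structure(list(atoms = atoms, metadata = metadata), class = "cyp_structure")
}

residue_key_of <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno, atoms$icode)
}

guess_element <- function(name) {
  # PDB atom names: element is the leading alphabetic part, minus Greek-letter
  # remoteness codes; two-letter elements (FE, CL, BR, ZN) appear verbatim.
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- c("FE", "CL", "BR", "ZN", "MG", "MN", "NA", "SE", "CU")
  ifelse(nm %in% two, nm, substr(nm, 1, 1))
}

#' Read a structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations by
#' keeping the highest-occupancy conformer (ties go to altloc 'A'), and flags
#' het groups (waters, heme, ligands).
#'
#' @param x path to a PDB file, or a character vector of PDB-format lines.
#' @return A `cyp_structure`.
#' @examples
#' pdb <- make_toy_structure(3, seed = 1)$pdb_lines
#' s <- read_structure(pdb)
#' n_atoms(s)
#' @export
read_structure <- function(x) {
  path <- as_pdb_path(x)
  if (!any(grepl("^(ATOM|HETATM)", readLines(path, warn = FALSE)))) {
    stop("input contains no ATOM or HETATM records")
  }
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)))
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution: within each (chain, resno, icode, atom name) group keep
  # the highest-occupancy record; tie -> altloc 'A' (then first on file order)
  akey <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(akey, -at$o, at$alt != "A", at$alt, seq_len(nrow(at)))
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), ]
  at <- at[order(at$eleno), ]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, elem = toupper(elem),
    resname = at$resid, chain = at$chain, resno = at$resno,
    icode = at$insert, x = at$x, y = at$y, z = at$z, occ = at$o,
    het = at$type == "HETATM", vdw = NA_real_,
    stringsAsFactors = FALSE)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("malformed coordinate field at ATOM/HETATM record with serial ",
         paste(atoms$serial[bad], collapse = ", "))
  }
  src <- if (length(x) == 1 && file.exists(x)) basename(x) else "pdb-text"
  new_structure(atoms, source = src)
}

as_pdb_path <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) return(x)
  if (length(x) == 1) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  if (length(x) == 0 || !any(nzchar(x))) stop("empty PDB input")
  tf <- tempfile(fileext = ".pdb")
  writeLines(x, tf)
  tf
}

#' Structure preparation settings
#'
#' Mirrors the usual crystal-structure cleanup before contact analysis: keep
#' one protein chain, drop waters and all het groups except the heme.
#'
#' @param chains_to_keep character vector of chain identifiers (required).
#' @param het_to_keep het residue codes to retain (default `"HEM"`).
#' @param remove_waters drop HOH/WAT records (default TRUE).
#' @param add_hydrogens place ideal-geometry polar hydrogens (default FALSE;
#'   the heavy-atom-only convention is the package default, see the vignette).
#' @return A `prep_config` list.
#' @export
preparation_config <- function(chains_to_keep, het_to_keep = "HEM",
                               remove_waters = TRUE, add_hydrogens = FALSE) {
  if (missing(chains_to_keep) || length(chains_to_keep) == 0) {
    stop("chains_to_keep must name at least one chain")
  }
  structure(list(chains_to_keep = as.character(chains_to_keep),
                 het_to_keep = as.character(het_to_keep),
                 remove_waters = isTRUE(remove_waters),
                 add_hydrogens = isTRUE(add_hydrogens)),
            class = "prep_config")
}

#' Prepare a structure for analysis
#'
#' Keeps the configured chains, removes waters, filters het groups to the
#' configured codes (heme by default) and optionally adds ideal-geometry
#' polar hydrogens. The input object is not modified. Idempotent.
#'
#' @param s a `cyp_structure`.
#' @param cfg a [preparation_config()].
#' @return The prepared `cyp_structure`.
#' @export
prepare_structure <- function(s, cfg) {
  stopifnot(inherits(s, "cyp_structure"), inherits(cfg, "prep_config"))
  at <- s$atoms
  avail <- unique(at$chain)
  absent <- setdiff(cfg$chains_to_keep, avail)
  if (length(absent) > 0) {
    stop("chain(s) ", paste(absent, collapse = ", "),
         " not present; available chains: ", paste(avail, collapse = ", "))
  }
  at <- at[at$chain %in% cfg$chains_to_keep, , drop = FALSE]
  water <- at$het & at$resname %in% c("HOH", "WAT", "DOD")
  if (cfg$remove_waters) at <- at[!water, , drop = FALSE]
  het_codes <- unique(at$resname[at$het & !(at$resname %in% c("HOH", "WAT", "DOD"))])
  missing_het <- setdiff(cfg$het_to_keep, het_codes)
  if (length(missing_het) > 0 && nrow(at) > 0 && !isTRUE(s$metadata$prepared)) {
    warning("het code(s) not present in structure: ",
            paste(missing_het, collapse = ", "))
  }
  dropped <- setdiff(het_codes, cfg$het_to_keep)
  if (length(dropped) > 0) {
    message("removing het group(s): ", paste(dropped, collapse = ", "))
  }
  keep_het <- !at$het | at$resname %in% c(cfg$het_to_keep,
                                          if (!cfg$remove_waters) c("HOH", "WAT", "DOD"))
  at <- at[keep_het, , drop = FALSE]
  if (nrow(at) == 0) stop("preparation removed every atom")
  out <- new_structure(at, source = s$metadata$source, metadata = s$metadata)
  out$metadata$prepared <- TRUE
  out$metadata$preparation <- cfg
  if (cfg$add_hydrogens && !any(out$atoms$elem == "H")) {
    out <- add_polar_hydrogens(out)
  }
  out$metadata$hydrogen_mode <-
    if (any(out$atoms$elem == "H")) "explicit-polar" else "heavy-atom"
  out
}

# Ideal-geometry placement of the polar hydrogens that matter for H-bond
# geometry: backbone amide H (bisector of C(i-1)-N and CA-N, 1.01 A) and
# hydroxyl/thiol H on SER/THR/TYR/CYS placed anti to the CA-CB (CZ-CE1) bond.
add_polar_hydrogens <- function(s) {
  at <- s$atoms
  prot <- at[!at$het, , drop = FALSE]
  keys <- unique(residue_key_of(prot))
  new_rows <- list()
  next_serial <- max(at$serial) + 1L
  coords_of <- function(df, nm) {
    i <- which(df$name == nm)
    if (length(i) == 0) return(NULL)
    as.numeric(df[i[1], c("x", "y", "z")])
  }
  for (i in seq_along(keys)) {
    res <- prot[residue_key_of(prot) == keys[i], , drop = FALSE]
    n <- coords_of(res, "N"); ca <- coords_of(res, "CA")
    if (i > 1 && !is.null(n) && !is.null(ca) && res$resname[1] != "PRO") {
      prev <- prot[residue_key_of(prot) == keys[i - 1], , drop = FALSE]
      cprev <- coords_of(prev, "C")
      if (!is.null(cprev) && prev$chain[1] == res$chain[1]) {
        h <- n + 1.01 * unit_vec(unit_vec(n - cprev) + unit_vec(n - ca))
        new_rows[[length(new_rows) + 1]] <-
          h_row(res, "H", h, next_serial); next_serial <- next_serial + 1L
      }
    }
    hx <- switch(res$resname[1],
                 SER = c("CB", "OG", "HG"), THR = c("CB", "OG1", "HG1"),
                 CYS = c("CB", "SG", "HG"), TYR = c("CE1", "OH", "HH"),
                 NULL)
    if (!is.null(hx)) {
      b <- coords_of(res, hx[1]); o <- coords_of(res, hx[2])
      a <- coords_of(res, if (res$resname[1] == "TYR") "CZ" else "CA")
      if (!is.null(a) && !is.null(b) && !is.null(o)) {
        bl <- if (hx[1] == "CB" && res$resname[1] == "CYS") 1.34 else 0.96
        h <- place_atom(a, b, o, bl, 109.5, 180)
        new_rows[[length(new_rows) + 1]] <-
          h_row(res, hx[3], h, next_serial); next_serial <- next_serial + 1L
      }
    }
  }
  if (length(new_rows) == 0) return(s)
  add <- do.call(rbind, new_rows)
  out <- s
  out$atoms <- rbind(at, add)
  ord <- order(out$atoms$het, out$atoms$chain, out$atoms$resno,
               out$atoms$icode, out$atoms$serial)
  out$atoms <- out$atoms[ord, ]
  rownames(out$atoms) <- NULL
  out
}

h_row <- function(res, name, xyz, serial) {
  data.frame(serial = serial, name = name, elem = "H",
             resname = res$resname[1], chain = res$chain[1],
             resno = res$resno[1], icode = res$icode[1],
             x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
             het = FALSE, vdw = NA_real_, stringsAsFactors = FALSE)
}

#' Element-based van der Waals radius table
#'
#' Bondi-type radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, Fe 2.00 A).
#' The radius-set name travels with every downstream report so interaction
#' counts are attributable to the convention used.
#'
#' @param set name of the radius set; only `"bondi"` is bundled.
#' @return Named numeric vector of radii (Angstrom) with a `set` attribute.
#' @export
vdw_table <- function(set = "bondi") {
  set <- match.arg(set)
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         "F" = 1.47, CL = 1.75, BR = 1.85, FE = 2.00, ZN = 1.39, MG = 1.73,
         "NA" = 2.27, SE = 1.90, CU = 1.40, MN = 2.00)
  stopifnot(all(r > 0.5 & r < 3.0))
  attr(r, "set") <- set
  r
}

#' Assign van der Waals radii to every atom
#'
#' Pure element-wise lookup; coordinates and atom counts are untouched.
#'
#' @param s a `cyp_structure`.
#' @param table radius table from [vdw_table()] (or a named numeric vector
#'   with a `set` attribute).
#' @return The structure with `vdw` filled in for every atom.
#' @export
assign_radii <- function(s, table = vdw_table()) {
  stopifnot(inherits(s, "cyp_structure"))
  idx <- match(toupper(s$atoms$elem), names(table))
  if (anyNA(idx)) {
    bad <- is.na(idx)
    stop("no radius for element(s): ",
         paste(unique(paste0(s$atoms$elem[bad], " (atom ", s$atoms$name[bad], ")")),
               collapse = ", "))
  }
  s$atoms$vdw <- unname(table[idx])
  s$metadata$radius_set <- attr(table, "set")
  s
}

#' Read a small-molecule ligand from SDF (V2000) or PDB text
#'
#' @param x path or character lines of an SDF V2000 or PDB file.
#' @param resname residue code given to the ligand (default `"LIG"`).
#' @return A one-group `cyp_structure` with `het = TRUE` for every atom.
#' @export
read_ligand <- function(x, resname = "LIG") {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  if (any(grepl("^(ATOM|HETATM)", lines))) {
    s <- read_structure(lines)
    s$atoms$het <- TRUE
    s$atoms$resname <- resname
    return(s)
  }
  if (!any(grepl("V2000", lines))) stop("input is neither PDB nor SDF V2000")
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package")
  }
  tf <- tempfile(fileext = ".sdf")
  writeLines(lines, tf)
  sdf <- ChemmineR::read.SDFset(tf)
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 0) stop("SDF record contains no atoms")
  elem <- toupper(gsub("_.*$", "", rownames(ab)))
  xyz <- ab[, 1:3, drop = FALSE]
  if (all(abs(xyz[, 3]) < 1e-9) && nrow(ab) > 1) {
    warning("ligand coordinates look 2D (all z = 0)")
  }
  atoms <- data.frame(
    serial = seq_len(nrow(ab)),
    name = paste0(elem, seq_len(nrow(ab))), elem = elem,
    resname = resname, chain = "X", resno = 900L, icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    het = TRUE, vdw = NA_real_, stringsAsFactors = FALSE)
  new_structure(atoms, source = "ligand")
}

#' Merge a ligand into a structure's het groups
#'
#' @param s a `cyp_structure`.
#' @param lig a ligand `cyp_structure` (e.g. from [read_ligand()]), assumed to
#'   share the receptor's coordinate frame (a docked pose).
#' @return Combined `cyp_structure`.
#' @export
add_ligand <- function(s, lig) {
  stopifnot(inherits(s, "cyp_structure"), inherits(lig, "cyp_structure"))
  la <- lig$atoms
  la$serial <- max(s$atoms$serial) + seq_len(nrow(la))
  la$het <- TRUE
  used <- unique(s$atoms$resno[s$atoms$chain %in% la$chain])
  if (any(la$resno %in% used)) la$resno <- max(s$atoms$resno) + 1L
  out <- s
  out$atoms <- rbind(s$atoms, la)
  rownames(out$atoms) <- NULL
  out
}

#' Write a structure as a fixed-column PDB file
#'
#' @param s a `cyp_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  stopifnot(inherits(s, "cyp_structure"))
  at <- s$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = at$chain,
                   insert = ifelse(at$icode == "", NA, at$icode),
                   o = at$occ, b = rep(0, nrow(at)), elesy = at$elem)
  invisible(file)
}

# ---- accessors ------------------------------------------------------------

#' @export
print.cyp_structure <- function(x, ...) {
  at <- x$atoms
  cat("<cyp_structure> ", x$metadata$source, "\n", sep = "")
  cat("  atoms: ", nrow(at), " (", sum(at$het), " hetero)\n", sep = "")
  cat("  chains: ", paste(unique(at$chain), collapse = " "), "\n", sep = "")
  cat("  residues: ", length(unique(residue_key_of(at[!at$het, , drop = FALSE]))),
      "; het groups: ", nrow(het_groups(x)), "\n", sep = "")
  if (!is.null(x$metadata$radius_set)) {
    cat("  radius set: ", x$metadata$radius_set, "\n", sep = "")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `cyp_structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Residue table of the polymer part of a structure
#'
#' @param s a `cyp_structure`.
#' @return data.frame with one row per (chain, resno, icode) residue.
#' @export
residues <- function(s) {
  at <- s$atoms[!s$atoms$het, , drop = FALSE]
  key <- residue_key_of(at)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             icode = at$icode[first], resname = at$resname[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' Het groups (waters, heme, ligands) of a structure
#'
#' @param s a `cyp_structure`.
#' @return data.frame with one row per het group.
#' @export
het_groups <- function(s) {
  at <- s$atoms[s$atoms$het, , drop = FALSE]
  if (nrow(at) == 0) {
    return(data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), resname = character(0),
                      n_atoms = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste0(at$chain, ":", at$resno, at$icode, ":", at$resname)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             icode = at$icode[first], resname = at$resname[first],
             n_atoms = as.integer(table(key)[key[first]]),
             stringsAsFactors = FALSE)
}

#' Row indices of the atoms of one residue
#'
#' @param s a `cyp_structure`.
#' @param key residue key `"chain:resno"` (with optional insertion code), or
#'   separate `chain`/`resno` via the `chain` and `resno` arguments.
#' @param chain,resno alternative to `key`.
#' @return Integer vector of row indices into `s$atoms`.
#' @export
residue_atoms <- function(s, key = NULL, chain = NULL, resno = NULL) {
  if (is.null(key)) key <- paste0(chain, ":", resno)
  idx <- which(residue_key_of(s$atoms) == key & !s$atoms$het)
  if (length(idx) == 0) stop("no residue with key ", key)
  idx
}

backbone_names <- function() c("N", "CA", "C", "O", "OXT", "H", "HA")

#' JSON-ready structure summary
#'
#' @param s a `cyp_structure`.
#' @return List of counts and identifiers suitable for `jsonlite::toJSON`.
#' @export
structure_summary <- function(s) {
  hg <- het_groups(s)
  list(source = s$metadata$source,
       n_atoms = n_atoms(s),
       n_residues = nrow(residues(s)),
       chains = unique(s$atoms$chain),
       het_codes = unique(hg$resname),
       radius_set = s$metadata$radius_set,
       hydrogen_mode = s$metadata$hydrogen_mode)
}
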