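# Contact, clash and hydrogen-bond detection by van der Waals overlap.
#
# Definitions: overlap(a, b) = r_a + r_b - d(a, b). A pair is a contact when
# overlap >= -0.4 A; it is a clash when the effective overlap (overlap minus a
# 0.4 A allowance for hydrogen-bonded pairs) is >= 0.6 A. Both thresholds use
# "or greater" (closed) semantics.

#' Interaction detection parameters
#'
#' Defaults follow the standard overlap-based convention: clash at effective
#' overlap >= 0.6 A, contact at overlap >= -0.4 A, 0.4 A subtracted from the
#' overlap of hydrogen-bonded pairs, and hydrogen-bond criteria relaxed by
#' 0.4 A / 20 degrees relative to the base geometric table.
#'
#' @param clash_overlap_cutoff clash threshold on effective overlap (A).
#' @param hbond_allowance subtracted from the overlap of H-bonded pairs (A).
#' @param contact_overlap_cutoff contact threshold on raw overlap (A).
#' @param hbond_dist_relax added to the base donor-acceptor distance limit (A).
#' @param hbond_angle_relax subtracted from the base minimum angle (degrees).
#' @param hbond_base_dist named base donor-acceptor distance limits (A) per
#'   element pair (keys like `"N|O"`; order-insensitive).
#' @param hbond_base_angle base minimum antecedent-donor-acceptor angle
#'   (degrees) before relaxation.
#' @param exclude_bonded exclude 1-2 and 1-3 neighbour pairs across the
#'   peptide bond (default TRUE).
#' @return An `interaction_params` list.
#' @export
interaction_params <- function(clash_overlap_cutoff = 0.6,
                               hbond_allowance = 0.4,
                               contact_overlap_cutoff = -0.4,
                               hbond_dist_relax = 0.4,
                               hbond_angle_relax = 20,
                               hbond_base_dist = c("N|N" = 3.0, "N|O" = 2.9,
                                                   "O|O" = 2.8, "N|S" = 3.3,
                                                   "O|S" = 3.3, "S|S" = 3.5),
                               hbond_base_angle = 90,
                               exclude_bonded = TRUE) {
  stopifnot(clash_overlap_cutoff > contact_overlap_cutoff,
            hbond_allowance >= 0, hbond_dist_relax >= 0,
            hbond_angle_relax >= 0)
  structure(list(clash_overlap_cutoff = clash_overlap_cutoff,
                 hbond_allowance = hbond_allowance,
                 contact_overlap_cutoff = contact_overlap_cutoff,
                 hbond_dist_relax = hbond_dist_relax,
                 hbond_angle_relax = hbond_angle_relax,
                 hbond_base_dist = hbond_base_dist,
                 hbond_base_angle = hbond_base_angle,
                 exclude_bonded = isTRUE(exclude_bonded)),
            class = "interaction_params")
}

#' Van der Waals overlap of two atoms
#'
#' `overlap = r_a + r_b - d(a, b)`; symmetric in its arguments.
#'
#' @param a,b atoms: one-row data.frames (or named vectors/lists) with `x`,
#'   `y`, `z` and `vdw`.
#' @return Overlap in Angstrom. Coincident atoms return `r_a + r_b` with a
#'   warning.
#' @examples
#' a <- list(x = 0, y = 0, z = 0, vdw = 1.7)
#' b <- list(x = 3.4, y = 0, z = 0, vdw = 1.7)
#' compute_overlap(a, b)  # 0: spheres exactly touching
#' @export
compute_overlap <- function(a, b) {
  pa <- as.numeric(c(a$x, a$y, a$z))
  pb <- as.numeric(c(b$x, b$y, b$z))
  if (is.null(a$vdw) || is.null(b$vdw) || is.na(a$vdw) || is.na(b$vdw)) {
    stop("both atoms need an assigned van der Waals radius")
  }
  d <- vec_norm(pa - pb)
  if (d < 1e-12) {
    warning("coincident atoms: overlap equals the radius sum")
    return(as.numeric(a$vdw + b$vdw))
  }
  as.numeric(a$vdw) + as.numeric(b$vdw) - d
}

hb_pair_key <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "|")
}

# Heavy-atom bonded neighbours, inferred from distance within a residue plus
# the peptide C(i)-N(i+1) link. Used for H-bond angle antecedents and for the
# 1-2/1-3 exclusion rule.
bonded_pairs <- function(s) {
  at <- s$atoms
  key <- residue_key_of(at)
  pairs <- list()
  for (k in unique(key)) {
    idx <- which(key == k & !at$het)
    if (length(idx) < 2) next
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    lim <- outer(at$elem[idx] == "S", at$elem[idx] == "S", "|")
    lim <- ifelse(lim, 2.1, 1.85)
    hinv <- outer(at$elem[idx] == "H", at$elem[idx] == "H", "|")
    lim[hinv] <- 1.25
    hit <- which(d > 0 & d < lim, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) > 0) {
      pairs[[length(pairs) + 1]] <- cbind(idx[hit[, 1]], idx[hit[, 2]])
    }
  }
  # het groups: within-group bonds by the same distance rule
  for (k in unique(paste0(key, ":", at$resname)[at$het])) {
    idx <- which(paste0(key, ":", at$resname) == k & at$het)
    if (length(idx) < 2) next
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d > 0 & d < 1.9, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) > 0) {
      pairs[[length(pairs) + 1]] <- cbind(idx[hit[, 1]], idx[hit[, 2]])
    }
  }
  # peptide bond C(i) - N(i+1) between consecutive protein residues
  prot <- which(!at$het)
  if (length(prot) > 0) {
    rk <- unique(key[prot])
    if (length(rk) > 1) {
      for (i in seq_len(length(rk) - 1)) {
        ci <- which(key == rk[i] & at$name == "C" & !at$het)
        nj <- which(key == rk[i + 1] & at$name == "N" & !at$het)
        if (length(ci) == 1 && length(nj) == 1 &&
            at$chain[ci] == at$chain[nj]) {
          d <- vec_norm(as.numeric(at[ci, c("x", "y", "z")]) -
                          as.numeric(at[nj, c("x", "y", "z")]))
          if (d < 1.85) pairs[[length(pairs) + 1]] <- cbind(ci, nj)
        }
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

neighbours_of <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

# Expand a bond list to 1-2 and 1-3 pair keys ("i|j", i < j)
excluded_pair_keys <- function(bonds) {
  if (nrow(bonds) == 0) return(character(0))
  one_two <- bonds
  adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  one_three <- list()
  for (mid in names(adj)) {
    nb <- unique(adj[[mid]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      one_three[[mid]] <- t(cmb)
    }
  }
  all <- rbind(one_two, do.call(rbind, one_three))
  unique(paste(pmin(all[, 1], all[, 2]), pmax(all[, 1], all[, 2]), sep = "|"))
}

#' Detect hydrogen bonds by relaxed geometric criteria
#'
#' Heavy-atom mode (the default when no hydrogens are present): a donor
#' candidate (N, O or S) and an acceptor candidate (N, O or S) form a bond
#' when their distance is at most the base limit for that element pair plus
#' the distance relax, and the angle antecedent-donor-acceptor is at least
#' the base minimum angle minus the angle relax (donors without a bonded
#' heavy neighbour pass the angle test). With explicit hydrogens present, the
#' hydrogen-acceptor distance (base limit minus 0.9 A, plus relax) and the
#' donor-H-acceptor angle (>= 120 degrees minus relax) are used instead.
#'
#' @param s a `cyp_structure` with elements assigned.
#' @param params an [interaction_params()].
#' @return data.frame with columns `i`, `j` (atom row indices, `i` donor),
#'   `distance`, `angle`, `mode`. Structures without N/O/S atoms give zero
#'   rows.
#' @export
find_hbonds <- function(s, params = interaction_params()) {
  at <- s$atoms
  polar <- which(at$elem %in% c("N", "O", "S"))
  if (length(polar) < 2) {
    return(hbond_empty())
  }
  bonds <- bonded_pairs(s)
  key <- residue_key_of(at)
  has_h <- any(at$elem == "H")
  out <- list()
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (di in polar) {
    nb <- neighbours_of(bonds, di)
    h_nb <- nb[at$elem[nb] == "H"]
    heavy_nb <- nb[at$elem[nb] != "H"]
    for (ai in polar) {
      if (ai == di) next
      if (key[ai] == key[di] && at$het[ai] == at$het[di]) next
      base <- params$hbond_base_dist[hb_pair_key(at$elem[di], at$elem[ai])]
      if (is.na(base)) next
      if (has_h && length(h_nb) > 0) {
        lim <- base - 0.9 + params$hbond_dist_relax
        ok <- FALSE
        best <- c(Inf, NA)
        for (hi in h_nb) {
          dha <- vec_norm(xyz[hi, ] - xyz[ai, ])
          ang <- point_angle(xyz[di, ], xyz[hi, ], xyz[ai, ])
          if (dha <= lim && ang >= 120 - params$hbond_angle_relax) {
            ok <- TRUE
            if (dha < best[1]) best <- c(dha, ang)
          }
        }
        if (ok) {
          out[[length(out) + 1]] <- data.frame(
            i = di, j = ai, distance = best[1], angle = best[2],
            mode = "explicit-h", stringsAsFactors = FALSE)
        }
      } else {
        dda <- vec_norm(xyz[di, ] - xyz[ai, ])
        if (dda > base + params$hbond_dist_relax) next
        if (length(heavy_nb) > 0) {
          angs <- vapply(heavy_nb, function(b)
            point_angle(xyz[b, ], xyz[di, ], xyz[ai, ]), numeric(1))
          if (max(angs) < params$hbond_base_angle - params$hbond_angle_relax) next
          ang <- max(angs)
        } else {
          ang <- NA_real_
        }
        out[[length(out) + 1]] <- data.frame(
          i = di, j = ai, distance = dda, angle = ang,
          mode = "heavy-atom", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(hbond_empty())
  hb <- do.call(rbind, out)
  hb[order(hb$i, hb$j), ]
}

hbond_empty <- function() {
  data.frame(i = integer(0), j = integer(0), distance = numeric(0),
             angle = numeric(0), mode = character(0), stringsAsFactors = FALSE)
}

contact_empty <- function() {
  data.frame(i = integer(0), j = integer(0), distance = numeric(0),
             overlap = numeric(0), is_hbond = logical(0),
             effective_overlap = numeric(0), klass = character(0),
             stringsAsFactors = FALSE)
}

#' Find contacts and clashes between a selection and its environment
#'
#' Reports every selection-environment atom pair with raw overlap at or above
#' the contact cutoff. The effective overlap subtracts the hydrogen-bond
#' allowance for H-bonded pairs; pairs whose effective overlap reaches the
#' clash cutoff are classed `"clash"`, the rest `"contact"` (every clash is a
#' contact). Atoms in the same residue as the selection, and 1-2/1-3
#' neighbours across the peptide bond, are excluded. Neighbour search uses a
#' cell list; results are identical to an exhaustive pairwise scan.
#'
#' @param s a `cyp_structure` with radii assigned.
#' @param selection integer atom row indices (e.g. from [residue_atoms()]).
#' @param environment integer atom row indices; default: all atoms outside
#'   the selection's residue(s).
#' @param hbonds H-bond pair table from [find_hbonds()]; computed when `NULL`.
#' @param params an [interaction_params()].
#' @return data.frame of contact records: `i` (selection atom), `j`
#'   (environment atom), `distance`, `overlap`, `is_hbond`,
#'   `effective_overlap`, `klass`.
#' @export
find_contacts <- function(s, selection, environment = NULL, hbonds = NULL,
                          params = interaction_params()) {
  at <- s$atoms
  if (length(selection) == 0) stop("selection must contain at least one atom")
  if (anyNA(at$vdw[selection])) stop("assign radii before contact analysis")
  key <- residue_key_of(at)
  sel_keys <- unique(paste0(key[selection], "|", at$het[selection]))
  if (is.null(environment)) {
    environment <- which(!(paste0(key, "|", at$het) %in% sel_keys))
  } else {
    environment <- setdiff(environment,
                           which(paste0(key, "|", at$het) %in% sel_keys))
  }
  if (length(environment) == 0) return(contact_empty())
  if (anyNA(at$vdw[environment])) stop("assign radii before contact analysis")
  if (is.null(hbonds)) hbonds <- find_hbonds(s, params)
  hb_keys <- if (nrow(hbonds) > 0) {
    paste(pmin(hbonds$i, hbonds$j), pmax(hbonds$i, hbonds$j), sep = "|")
  } else character(0)
  excl <- if (params$exclude_bonded) {
    excluded_pair_keys(bonded_pairs(s))
  } else character(0)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  dmax <- 2 * max(at$vdw[c(selection, environment)]) - params$contact_overlap_cutoff
  # cell list over the environment
  cell <- floor(sweep(xyz[environment, , drop = FALSE], 2,
                      apply(xyz, 2, min)) / dmax)
  cell_key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cell_map <- split(environment, cell_key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- list()
  mins <- apply(xyz, 2, min)
  for (si in selection) {
    sc <- floor((xyz[si, ] - mins) / dmax)
    nb_keys <- paste(sc[1] + offsets[, 1], sc[2] + offsets[, 2],
                     sc[3] + offsets[, 3], sep = ",")
    cand <- unlist(cell_map[nb_keys], use.names = FALSE)
    if (length(cand) == 0) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[si, ])^2))
    ov <- at$vdw[si] + at$vdw[cand] - d
    hit <- ov >= params$contact_overlap_cutoff
    if (!any(hit)) next
    cand <- cand[hit]; d <- d[hit]; ov <- ov[hit]
    pk <- paste(pmin(si, cand), pmax(si, cand), sep = "|")
    drop <- pk %in% excl
    if (any(drop)) {
      cand <- cand[!drop]; d <- d[!drop]; ov <- ov[!drop]; pk <- pk[!drop]
    }
    if (length(cand) == 0) next
    ishb <- pk %in% hb_keys
    eff <- ov - ifelse(ishb, params$hbond_allowance, 0)
    out[[length(out) + 1]] <- data.frame(
      i = si, j = cand, distance = d, overlap = ov, is_hbond = ishb,
      effective_overlap = eff,
      klass = ifelse(eff >= params$clash_overlap_cutoff, "clash", "contact"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(contact_empty())
  res <- do.call(rbind, out)
  res <- res[order(res$i, res$j), ]
  rownames(res) <- NULL
  res
}

#' Quantified distance at a clash site
#'
#' Two-case rule: if the clash partner is a side-chain atom or belongs to a
#' het group (ligand, heme), the direct atom-atom distance is reported; if
#' the partner is a backbone atom of a neighbouring residue, the distance
#' from the mutated-residue atom to that residue's alpha carbon is reported
#' as the reference.
#'
#' @param s a `cyp_structure`.
#' @param rec one contact record (a one-row slice of [find_contacts()]
#'   output) involving at least one atom of the mutated residue.
#' @param site_key residue key `"chain:resno"` of the mutated residue.
#' @return Distance in Angstrom.
#' @export
clash_distance <- function(s, rec, site_key) {
  at <- s$atoms
  key <- residue_key_of(at)
  ij <- c(rec$i, rec$j)
  in_site <- key[ij] == site_key & !at$het[ij]
  if (!any(in_site)) stop("record does not involve the mutated residue ", site_key)
  mut_atom <- ij[which(in_site)[1]]
  partner <- ij[ij != mut_atom][1]
  if (length(partner) == 0 || is.na(partner)) partner <- ij[2]
  p_mut <- as.numeric(at[mut_atom, c("x", "y", "z")])
  if (at$het[partner] || !(at$name[partner] %in% backbone_names())) {
    return(vec_norm(p_mut - as.numeric(at[partner, c("x", "y", "z")])))
  }
  ca <- which(key == key[partner] & at$name == "CA" & !at$het)
  if (length(ca) == 0) {
    stop("partner residue ", key[partner], " has no CA atom")
  }
  vec_norm(p_mut - as.numeric(at[ca[1], c("x", "y", "z")]))
}

#' Wild-type vs mutant interaction report for one variant site
#'
#' Counts the interactions (contact records, hydrogen-bonded pairs included)
#' between the site residue's atoms and all other atoms (other residues,
#' heme, ligand) in the wild-type and mutant structures, and the unfavourable
#' clashes in the mutant. "Interactions" are counted as atom pairs; the
#' counting conventions (radius set, hydrogen mode, rotamer rule) are
#' recorded in the report so deviations are attributable.
#'
#' @param wt,mut `cyp_structure`s identical everywhere except the site.
#' @param site_key residue key `"chain:resno"`.
#' @param params an [interaction_params()].
#' @param label variant label for the report (default from mut provenance).
#' @return A `variant_report` list: `label`, `n_interactions_wt`,
#'   `n_interactions_mut`, `difference`, `n_clashes_mut`, `records` (both
#'   states), `clash_distances`, `conventions`.
#' @export
variant_report <- function(wt, mut, site_key, params = interaction_params(),
                           label = NULL) {
  stopifnot(inherits(wt, "cyp_structure"), inherits(mut, "cyp_structure"))
  wk <- residue_key_of(wt$atoms)
  mk <- residue_key_of(mut$atoms)
  w_other <- wt$atoms[wk != site_key | wt$atoms$het, , drop = FALSE]
  m_other <- mut$atoms[mk != site_key | mut$atoms$het, , drop = FALSE]
  if (nrow(w_other) != nrow(m_other) ||
      any(w_other$name != m_other$name) ||
      max(abs(as.matrix(w_other[, c("x", "y", "z")]) -
              as.matrix(m_other[, c("x", "y", "z")]))) > 1e-6) {
    first <- if (nrow(w_other) == nrow(m_other)) {
      diffs <- which(w_other$name != m_other$name |
                       abs(w_other$x - m_other$x) > 1e-6 |
                       abs(w_other$y - m_other$y) > 1e-6 |
                       abs(w_other$z - m_other$z) > 1e-6)
      paste0(w_other$name[diffs[1]], " ", wk[wk != site_key][diffs[1]])
    } else "atom counts differ"
    stop("wild-type and mutant differ outside the site: ", first)
  }
  wt_rec <- find_contacts(wt, residue_atoms(wt, site_key), params = params)
  mut_rec <- find_contacts(mut, residue_atoms(mut, site_key), params = params)
  clash_rows <- mut_rec[mut_rec$klass == "clash", , drop = FALSE]
  cd <- if (nrow(clash_rows) > 0) {
    vapply(seq_len(nrow(clash_rows)), function(i)
      clash_distance(mut, clash_rows[i, ], site_key), numeric(1))
  } else numeric(0)
  if (is.null(label)) {
    mlist <- mut$metadata$mutations
    label <- if (length(mlist) > 0) mlist[[length(mlist)]]$label else site_key
  }
  structure(list(
    label = label, site = site_key,
    n_interactions_wt = nrow(wt_rec),
    n_interactions_mut = nrow(mut_rec),
    difference = nrow(mut_rec) - nrow(wt_rec),
    n_clashes_mut = nrow(clash_rows),
    records = list(wt = wt_rec, mut = mut_rec),
    clash_distances = cd,
    conventions = list(
      radius_set = mut$metadata$radius_set,
      hydrogen_mode = if (is.null(mut$metadata$hydrogen_mode)) "heavy-atom"
                      else mut$metadata$hydrogen_mode,
      rotamer_rule = {
        mlist <- mut$metadata$mutations
        if (length(mlist) > 0) mlist[[length(mlist)]]$rule else NA_character_
      },
      counting_unit = "atom-pairs")),
    class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat("<variant_report> ", x$label, " at ", x$site, "\n", sep = "")
  cat("  interactions wt/mut: ", x$n_interactions_wt, "/",
      x$n_interactions_mut, " (difference ", x$difference, ")\n", sep = "")
  cat("  unfavourable clashes in mutant: ", x$n_clashes_mut, "\n", sep = "")
  cat("  conventions: ", x$conventions$radius_set, ", ",
      x$conventions$hydrogen_mode, ", unit = ",
      x$conventions$counting_unit, "\n", sep = "")
  invisible(x)
}
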