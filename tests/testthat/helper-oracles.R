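# Independent oracle routines used to cross-check the package's geometry,
# contact and channel code. These deliberately take different computational
# routes than the implementation.

# Rodrigues-rotation construction of an atom from internal coordinates:
# start from the extension of the b->c bond, bend by (180 - angle) about the
# normal of the a-b-c plane, then rotate by the torsion about the b->c axis.
oracle_place_atom <- function(a, b, c, bond, angle, torsion) {
  rot <- function(v, axis, theta) {
    axis <- axis / sqrt(sum(axis^2))
    th <- theta * pi / 180
    v * cos(th) + pracma_cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  }
  pracma_cross <- function(u, v) {
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  }
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n_plane <- pracma_cross(b - a, bc)
  d0 <- bond * bc                      # straight extension of b->c
  d1 <- rot(d0, n_plane, 180 - angle)  # bend into the a-b-c plane (torsion 0)
  d2 <- rot(d1, bc, torsion)           # spin to the requested torsion
  c + d2
}

# O(V^2) max-min (widest-bottleneck) Dijkstra on a 6-connected grid.
# clear: clearance per node; nodes with clearance <= 0 are impassable.
oracle_maxmin_dijkstra <- function(clear, dims, src, targets) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  neigh <- function(i) {
    i0 <- i - 1L
    ix <- i0 %% nx; iy <- (i0 %/% nx) %% ny; iz <- i0 %/% (nx * ny)
    out <- integer(0)
    if (ix > 0) out <- c(out, i - 1L)
    if (ix < nx - 1L) out <- c(out, i + 1L)
    if (iy > 0) out <- c(out, i - nx)
    if (iy < ny - 1L) out <- c(out, i + nx)
    if (iz > 0) out <- c(out, i - nx * ny)
    if (iz < nz - 1L) out <- c(out, i + nx * ny)
    out
  }
  cap <- rep(-Inf, n)
  if (clear[src] <= 0) return(-Inf)
  cap[src] <- clear[src]
  done <- logical(n)
  repeat {
    u <- which.max(ifelse(done, -Inf, cap))
    if (done[u] || cap[u] == -Inf) break
    done[u] <- TRUE
    for (v in neigh(u)) {
      if (!done[v] && clear[v] > 0) {
        cap[v] <- max(cap[v], min(cap[u], clear[v]))
      }
    }
    if (all(done | cap == -Inf)) break
  }
  best <- max(cap[targets])
  if (best == -Inf) -Inf else best
}

# Build a tiny hand-specified structure from a coordinate table.
mini_structure <- function(df, source = "mini") {
  defaults <- data.frame(serial = seq_len(nrow(df)), occ = 1, icode = "",
                         vdw = NA_real_, stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$het)) df$het <- FALSE
  new_structure(df[, c("serial", "name", "elem", "resname", "chain", "resno",
                       "icode", "x", "y", "z", "occ", "het", "vdw")],
                source = source)
}

# One-line PDB ATOM record with fixed columns (independent of the writer).
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          elem = substr(name, 1, 1), het = FALSE) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, x, y, z, 1, 0, elem)
}
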