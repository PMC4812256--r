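# Programmatic fixtures: tiny PDB texts, minimal DCD writer, hand-built
# trajectories. Everything is generated at test time; nothing binary is
# stored in the repository.

pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z, ele) {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("ATOM  %5d %4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          eleno, name, resid, chain, resno, x, y, z, ele)
}

# Gly-Ala-Gly tripeptide, 19 atoms (backbone + hydrogens), coordinates in
# Angstrom chosen by hand
write_gag_pdb <- function(path) {
  spec <- list(
    # resno, resid, atoms (elety, ele, x, y, z)
    list(1, "GLY", list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"),
                        c("H", "H"), c("HA2", "H"), c("HA3", "H"))),
    list(2, "ALA", list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"),
                        c("CB", "C"), c("HB", "H"))),
    list(3, "GLY", list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"),
                        c("H", "H"), c("HA2", "H"))))
  lines <- character(); k <- 0
  for (res in spec) {
    for (a in res[[3]]) {
      k <- k + 1
      lines <- c(lines, pdb_atom_line(k, a[1], res[[2]], "A", res[[1]],
                                      10 * res[[1]] + k * 0.5, k * 0.25, 0,
                                      a[2]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(k)
}

# minimal CHARMM-style DCD writer (header + fixed-length coordinate records)
write_dcd_minimal <- function(path, coords_list) {
  con <- file(path, "wb")
  on.exit(close(con))
  natoms <- nrow(coords_list[[1]])
  nf <- length(coords_list)
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "synthetic dcd fixture"), con, nchars = 80,
            eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natoms), con, size = 4)
  writeBin(4L, con, size = 4)
  for (co in coords_list) {
    for (k in 1:3) {
      writeBin(as.integer(4 * natoms), con, size = 4)
      writeBin(as.numeric(co[, k]), con, size = 4)
      writeBin(as.integer(4 * natoms), con, size = 4)
    }
  }
  invisible(path)
}

# C-alpha-only topology with one atom per residue
ca_topology <- function(n_res) {
  topology(elety = rep("CA", n_res), resno = seq_len(n_res))
}

# trajectory from a list of (natoms x 3) coordinate matrices in nm
traj_from_coords <- function(topology, coords_list, dt = 1) {
  xyz <- do.call(rbind, lapply(coords_list, function(m) as.vector(t(m))))
  trajectory(topology, xyz, dt = dt)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# trajectory whose frames are rigid-body motions of a single conformation
rigid_motion_traj <- function(ref_trj, n, seed = 1) {
  set.seed(seed)
  co <- frame_coords(ref_trj, 1)
  frames <- lapply(seq_len(n), function(i) {
    R <- random_rotation()
    sweep(co %*% t(R), 2, stats::rnorm(3, sd = 2), "+")
  })
  traj_from_coords(ref_trj$topology, frames)
}

# apply one fixed rigid motion to every frame of a trajectory
apply_rigid_motion <- function(trj, R, shift) {
  for (f in seq_len(n_frames(trj))) {
    co <- frame_coords(trj, f) %*% t(R)
    co <- sweep(co, 2, shift, "+")
    trj <- allocross:::set_frame_coords(trj, f, co)
  }
  trj
}
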