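# Shared in-code fixtures for the test suite.

# n-bead linear-chain topology with uniform parameters
chain_topology <- function(n, b0 = 0.47, kb = 1250, theta0 = 120,
                           ktheta = 25, angle_form = "harmonic",
                           kphi = 5, mult = 1L, phi0 = 0, type = "C1",
                           charge = 0, name = "CHAIN") {
  beads <- data.frame(name = paste0("B", seq_len(n)), type = type,
                      mass = 72, charge = charge, stringsAsFactors = FALSE)
  bonds <- if (n >= 2) data.frame(i = 1:(n - 1), j = 2:n, b0 = b0, kb = kb)
           else data.frame()
  angles <- if (n >= 3) data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
                                   theta0 = theta0, ktheta = ktheta,
                                   form = angle_form,
                                   stringsAsFactors = FALSE)
            else data.frame()
  dihedrals <- if (n >= 4) data.frame(i = 1:(n - 3), j = 2:(n - 2),
                                      k = 3:(n - 1), l = 4:n,
                                      form = "periodic", phi0 = phi0,
                                      kphi = kphi, mult = mult,
                                      C0 = NA_real_, C1 = NA_real_,
                                      C2 = NA_real_, C3 = NA_real_,
                                      C4 = NA_real_, C5 = NA_real_,
                                      stringsAsFactors = FALSE)
               else data.frame()
  new_topology(name, beads, bonds, angles, dihedrals)
}

# matching declarative scheme (one atom per bead) for a chain
chain_scheme <- function(n, name = "CHAIN", type = "C1") {
  new_scheme(stats::setNames(list(list(
    beads = lapply(seq_len(n), function(i)
      list(name = paste0("B", i), type = type, atoms = paste0("B", i),
           charge = 0)),
    bonds = if (n >= 2) lapply(1:(n - 1), function(k) c(k, k + 1L))
            else list(),
    angles = if (n >= 3) lapply(1:(n - 2), function(k) c(k, k + 1L, k + 2L))
             else list(),
    dihedrals = if (n >= 4) lapply(1:(n - 3), function(k)
      c(k, k + 1L, k + 2L, k + 3L)) else list())), name))
}

# quick frame from coordinate rows
quick_frame <- function(xyz, mass = 72, box = NULL, name_prefix = "B",
                        molecule_name = "CHAIN", molecule_id = 1L,
                        type = "C1") {
  xyz <- as.matrix(xyz)
  new_frame(data.frame(name = paste0(name_prefix, seq_len(nrow(xyz))),
                       type = type, mass = mass,
                       molecule_id = molecule_id,
                       molecule_name = molecule_name,
                       element = NA_character_, stringsAsFactors = FALSE),
            xyz, box)
}

# random rigid transform applied to a frame
apply_rigid <- function(frame, axis, angle, shift) {
  u <- axis / sqrt(sum(axis^2))
  R <- diag(3) * cos(angle) +
    (1 - cos(angle)) * tcrossprod(u) +
    sin(angle) * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                       c(-u[2], u[1], 0))
  frame$xyz <- frame$xyz %*% t(R) +
    matrix(shift, natoms(frame), 3, byrow = TRUE)
  frame
}

# independent rotation-construction dihedral oracle: place the fourth
# particle by rotating a cis-positioned reference about the central bond
dihedral_by_rotation <- function(phi_deg, r1 = c(0.3, -0.4, 0.1),
                                 r2 = c(0, 0, 0),
                                 r3 = c(0.5, 0.2, -0.1), blen = 0.4) {
  ax <- (r3 - r2) / sqrt(sum((r3 - r2)^2))
  v1 <- r2 - r1
  perp <- v1 - sum(v1 * ax) * ax
  perp <- perp / sqrt(sum(perp^2))
  r4cis <- r3 - perp * blen            # dihedral exactly 0 by construction
  rot <- function(v, u, a)
    v * cos(a) + c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                   u[1] * v[2] - u[2] * v[1]) * sin(a) +
      u * sum(u * v) * (1 - cos(a))
  r4 <- r3 + rot(r4cis - r3, ax, phi_deg * pi / 180)
  rbind(r1, r2, r3, r4)
}
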