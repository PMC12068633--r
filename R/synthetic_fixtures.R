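## Deterministic, seeded generators for toy molecules, Boltzmann
## conformer ensembles, Brownian trajectories and box assembly.
## Every generator is a pure function of (spec, seed): the global RNG
## state is saved and restored around each call.

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Rotate vector v about unit axis u by angle a (radians), Rodrigues.
.rotate_about <- function(v, u, a)
  v * cos(a) + .cross3(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))

## Build a gently kinked chain of `n` points with every consecutive
## distance exactly `L`: each step direction is the previous one rotated
## by a small random turn about a random perpendicular axis.
.kinked_chain <- function(n, L, origin, dir0, max_turn_deg = 15) {
  pts <- matrix(0, n, 3)
  pts[1, ] <- origin
  dir <- dir0 / sqrt(sum(dir0^2))
  for (k in 2:n) {
    pts[k, ] <- pts[k - 1, ] + dir * L
    ## random small turn keeps the chain non-collinear but bond-exact
    ax <- c(-dir[2], dir[1], 0)
    if (sum(ax^2) < 1e-12) ax <- c(1, 0, 0)
    ax <- ax / sqrt(sum(ax^2))
    ax <- .rotate_about(ax, dir, stats::runif(1, 0, 2 * pi))
    dir <- .rotate_about(dir, ax, stats::runif(1, 0.3, 1) *
                           max_turn_deg * pi / 180)
  }
  pts
}

#' Generate a toy molecule and its mapping-scheme stub
#'
#' Three fixture families mirror the geometries the toolkit targets:
#' `"three_wing_surfactant"` (default 3 x 19 = 57 beads: per wing a
#' 13-bead polar head and 6-bead apolar tail, joined at a central
#' triangular junction), `"rigid_core_drug"` (default 24 beads: a 15-bead
#' core chain carrying three 3-bead rings labelled 1-3), and
#' `"bead_chain"` (a plain chain).  Every bond is constructed at exactly
#' `bond_length`; the small chain kinks that keep angles/dihedrals
#' well-defined are drawn from the seeded stream.
#'
#' @param kind Fixture family.
#' @param n_beads Chain length for `"bead_chain"`.
#' @param wing_length Beads per wing for the surfactant (default 19).
#' @param bond_length Bond length in nm (default 0.47, the common CG
#'   bead spacing).
#' @param bead_mass Per-bead mass in amu (default 72, four heavy atoms).
#' @param seed Integer seed.
#' @return List with `frame` (a `cg_frame`), `scheme` (a `cg_scheme`
#'   stub whose beads each contain the single generated bead), and for
#'   the drug fixture `rings` (named list of ring member bead names).
#' @export
generate_molecule <- function(kind = c("three_wing_surfactant",
                                       "rigid_core_drug", "bead_chain"),
                              n_beads = 10, wing_length = 19,
                              bond_length = 0.47, bead_mass = 72,
                              seed = 1) {
  kind <- match.arg(kind)
  stopifnot(bond_length > 0, bead_mass > 0)
  .with_seed(seed, {
    L <- bond_length
    if (kind == "three_wing_surfactant") {
      stopifnot(wing_length >= 2)
      rad <- L / sqrt(3)                  # circumradius: triangle side L
      angs <- c(90, 210, 330) * pi / 180
      pos <- NULL; names <- NULL; types <- NULL
      bonds <- list(); angles <- list(); dihedrals <- list()
      base_idx <- integer(3)
      for (w in 1:3) {
        dir <- c(cos(angs[w]), sin(angs[w]), 0)
        pts <- .kinked_chain(wing_length, L, dir * rad, dir)
        off <- nrow(pos %||% matrix(0, 0, 3))
        base_idx[w] <- off + 1L
        pos <- rbind(pos, pts)
        names <- c(names, sprintf("W%dB%d", w, seq_len(wing_length)))
        nhead <- min(13L, wing_length)
        types <- c(types, c(rep("P1", nhead),
                            rep("C1", wing_length - nhead)))
        for (k in seq_len(wing_length - 1))
          bonds[[length(bonds) + 1L]] <- off + c(k, k + 1L)
        for (k in seq_len(max(0, wing_length - 2)))
          angles[[length(angles) + 1L]] <- off + c(k, k + 1L, k + 2L)
        for (k in seq_len(max(0, wing_length - 3)))
          dihedrals[[length(dihedrals) + 1L]] <- off + c(k, k + 1L,
                                                         k + 2L, k + 3L)
      }
      bonds <- c(bonds, list(base_idx[c(1, 2)], base_idx[c(2, 3)],
                             base_idx[c(3, 1)]))
      mol <- "SURF"
      rings <- NULL
    } else if (kind == "rigid_core_drug") {
      ncore <- 15L
      pts <- .kinked_chain(ncore, L, c(0, 0, 0), c(1, 0, 0))
      pos <- pts
      names <- sprintf("C%d", seq_len(ncore))
      types <- rep("Na", ncore)
      bonds <- lapply(seq_len(ncore - 1), function(k) c(k, k + 1L))
      angles <- lapply(seq_len(ncore - 2), function(k) c(k, k + 1L, k + 2L))
      dihedrals <- lapply(seq_len(ncore - 3), function(k)
        c(k, k + 1L, k + 2L, k + 3L))
      rings <- list()
      attach_at <- c(2L, 8L, 14L)
      for (r in 1:3) {
        ca <- attach_at[r]
        ## equilateral triangle of side L, first vertex one bond from
        ## the core attachment bead
        nrm <- .rotate_about(c(0, 0, 1), c(1, 0, 0),
                             stats::runif(1, 0, 2 * pi))
        e1 <- .cross3(nrm, c(1, 0, 0)); e1 <- e1 / sqrt(sum(e1^2))
        e2 <- .cross3(nrm, e1)
        v1 <- pts[ca, ] + e1 * L
        cc <- v1 + e1 * (L / sqrt(3))
        verts <- t(vapply(0:2, function(k)
          cc + .rotate_about(v1 - cc, nrm, 2 * pi * k / 3), numeric(3)))
        off <- nrow(pos)
        pos <- rbind(pos, verts)
        rn <- sprintf("R%dA%d", r, 1:3)
        names <- c(names, rn)
        types <- c(types, rep("SC4", 3))
        bonds <- c(bonds, list(off + c(1L, 2L), off + c(2L, 3L),
                               off + c(3L, 1L), c(ca, off + 1L)))
        rings[[as.character(r)]] <- rn
      }
      mol <- "DRUG"
    } else {
      stopifnot(n_beads >= 1)
      pos <- .kinked_chain(max(n_beads, 1L), L, c(0, 0, 0), c(1, 0, 0))
      names <- sprintf("B%d", seq_len(n_beads))
      types <- rep("C1", n_beads)
      bonds <- lapply(seq_len(max(0, n_beads - 1)), function(k) c(k, k + 1L))
      angles <- lapply(seq_len(max(0, n_beads - 2)), function(k)
        c(k, k + 1L, k + 2L))
      dihedrals <- lapply(seq_len(max(0, n_beads - 3)), function(k)
        c(k, k + 1L, k + 2L, k + 3L))
      mol <- "CHAIN"
      rings <- NULL
    }
    if (kind == "rigid_core_drug") { angles <- angles; dihedrals <- dihedrals }
    atoms <- data.frame(name = names, type = types, mass = bead_mass,
                        charge = 0, molecule_id = 1L, molecule_name = mol,
                        element = NA_character_, stringsAsFactors = FALSE)
    frame <- new_frame(atoms, pos)
    scheme <- new_scheme(stats::setNames(list(list(
      beads = lapply(seq_along(names), function(i)
        list(name = names[i], type = types[i], atoms = names[i], charge = 0)),
      bonds = bonds, angles = angles, dihedrals = dihedrals)), mol))
    out <- list(frame = frame, scheme = scheme)
    if (!is.null(rings)) out$rings <- rings
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a Boltzmann conformer ensemble from a chain topology
#'
#' Draws each internal coordinate independently from its Boltzmann
#' marginal - Gaussian for harmonic bonds/angles (variance
#' \eqn{k_B T / k}), Gaussian in \eqn{\cos\theta} for G96 angles, and
#' rejection sampling against \eqn{e^{-V(\phi)/k_B T}} for periodic
#' dihedrals - then rebuilds Cartesian coordinates by sequential (NeRF)
#' placement.  The first three particles are placed canonically (origin,
#' +x, xy-plane), removing rigid-body ambiguity.
#'
#' Requires a chain-structured topology: bond (k-1, k), angle
#' (k-2, k-1, k), dihedral (k-3, ..., k) for each successive bead.
#'
#' @param topology A `cg_topology`.
#' @param temperature_K Temperature in K.
#' @param n Number of conformers.
#' @param seed Integer seed.
#' @param molecule_ids Molecule ids assigned to the conformers (default
#'   `1:n`).
#' @return List of `cg_frame`s.
#' @export
sample_conformer_ensemble <- function(topology, temperature_K = 300, n = 1,
                                      seed = 1, molecule_ids = seq_len(n)) {
  stopifnot(inherits(topology, "cg_topology"), n >= 1)
  kB <- cg_constants$kB
  nb <- nrow(topology$beads)
  findb <- function(i, j) {
    r <- topology$bonds[topology$bonds$i == i & topology$bonds$j == j |
                        topology$bonds$i == j & topology$bonds$j == i, ]
    if (!nrow(r)) stop("chain topology required: missing bond ", i, "-", j)
    r[1, ]
  }
  finda <- function(i, j, k) {
    a <- topology$angles
    r <- a[(a$i == i & a$j == j & a$k == k) |
           (a$i == k & a$j == j & a$k == i), ]
    if (!nrow(r)) stop("chain topology required: missing angle ",
                       i, "-", j, "-", k)
    r[1, ]
  }
  findd <- function(i, j, k, l) {
    d <- topology$dihedrals
    r <- d[(d$i == i & d$j == j & d$k == k & d$l == l) |
           (d$i == l & d$j == k & d$k == j & d$l == i), ]
    if (!nrow(r)) stop("chain topology required: missing dihedral ",
                       paste(c(i, j, k, l), collapse = "-"))
    if (r$form[1] != "periodic")
      stop("only periodic dihedral sampling is supported")
    r[1, ]
  }
  sample_bond <- function(p) stats::rnorm(1, p$b0, sqrt(kB * temperature_K /
                                                        p$kb))
  sample_angle <- function(p) {
    sd_ <- sqrt(kB * temperature_K / p$ktheta)
    if (p$form == "g96") {
      repeat {
        c0 <- stats::rnorm(1, cos(p$theta0 * pi / 180), sd_)
        if (abs(c0) <= 1) return(acos(c0))
      }
    } else {
      stats::rnorm(1, p$theta0 * pi / 180, sd_)   # sd in radians
    }
  }
  sample_dihedral <- function(p) {
    k <- p$kphi; m <- p$mult; phi0 <- p$phi0 * pi / 180
    vmin <- 0                                     # min of k(1+cos) = 0
    repeat {
      phi <- stats::runif(1, -pi, pi)
      v <- k * (1 + cos(m * phi - phi0)) - vmin
      if (stats::runif(1) < exp(-v / (kB * temperature_K))) return(phi)
    }
  }
  .with_seed(seed, {
    lapply(seq_len(n), function(q) {
      x <- matrix(0, nb, 3)
      if (nb >= 2) {
        b <- sample_bond(findb(1, 2))
        x[2, ] <- c(b, 0, 0)
      }
      if (nb >= 3) {
        b <- sample_bond(findb(2, 3))
        th <- sample_angle(finda(1, 2, 3))
        x[3, ] <- x[2, ] + b * c(-cos(th), sin(th), 0)
      }
      if (nb >= 4) for (k in 4:nb) {
        b <- sample_bond(findb(k - 1, k))
        th <- sample_angle(finda(k - 2, k - 1, k))
        phi <- sample_dihedral(findd(k - 3, k - 2, k - 1, k))
        x[k, ] <- .nerf_place(x[k - 3, ], x[k - 2, ], x[k - 1, ], b, th, phi)
      }
      atoms <- data.frame(name = topology$beads$name,
                          type = topology$beads$type,
                          mass = ifelse(is.na(topology$beads$mass), 72,
                                        topology$beads$mass),
                          charge = topology$beads$charge,
                          molecule_id = molecule_ids[q],
                          molecule_name = topology$name,
                          element = NA_character_, stringsAsFactors = FALSE)
      new_frame(atoms, x)
    })
  })
}

## Natural-extension reference frame placement: D such that |CD| = R,
## angle(B,C,D) = theta, dihedral(A,B,C,D) = phi (radians).
.nerf_place <- function(A, B, C, R, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-R * cos(theta), R * sin(theta) * cos(phi),
          R * sin(theta) * sin(phi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Brownian dynamics fixture trajectory with known diffusion constant
#'
#' Independent Gaussian steps of per-axis variance \eqn{2 D \Delta t};
#' positions are wrapped into the periodic box while the unwrapped truth
#' is kept in `attr(, "unwrapped")` for validation.
#'
#' @param n_particles Number of particles.
#' @param d_cm2_s True diffusion constant, cm^2 s^-1.
#' @param dt_ns Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param box_nm Cubic box edge, nm.
#' @param seed Integer seed.
#' @param mass Particle mass, amu.
#' @return A `cg_traj`; frames carry the box, unwrapped coordinate list
#'   in the attribute.
#' @export
brownian_trajectory <- function(n_particles, d_cm2_s, dt_ns, n_frames,
                                box_nm, seed = 1, mass = 72) {
  stopifnot(n_particles >= 1, d_cm2_s >= 0, dt_ns > 0, n_frames >= 1,
            box_nm > 0)
  D <- d_cm2_s / cg_constants$nm2_ns_to_cm2_s   # nm^2 / ns
  sd_ <- sqrt(2 * D * dt_ns)
  .with_seed(seed, {
    atoms <- data.frame(name = sprintf("P%d", seq_len(n_particles)),
                        mass = mass, molecule_id = seq_len(n_particles),
                        molecule_name = "BRW", element = NA_character_,
                        stringsAsFactors = FALSE)
    x <- matrix(stats::runif(n_particles * 3, 0, box_nm), n_particles, 3)
    frames <- vector("list", n_frames)
    unwrapped <- vector("list", n_frames)
    cur <- x
    for (q in seq_len(n_frames)) {
      if (q > 1)
        cur <- cur + matrix(stats::rnorm(n_particles * 3, 0, sd_),
                            n_particles, 3)
      unwrapped[[q]] <- cur
      frames[[q]] <- new_frame(atoms, cur %% box_nm, rep(box_nm, 3))
    }
    traj <- new_trajectory(frames, times = (seq_len(n_frames) - 1) * dt_ns)
    attr(traj, "unwrapped") <- unwrapped
    traj
  })
}

#' Assemble sub-boxes or molecules into one simulation box
#'
#' `"diagonal"` places the sub-box frames corner-to-corner along the main
#' diagonal with a fixed inter-phase gap between faces (the mixing layout
#' used to initialise strongly contrasted multi-phase systems).
#' `"random"` inserts each frame at a random position and orientation in
#' a target box, rejecting any placement that brings two atoms closer
#' than `min_dist` (minimum image).
#'
#' @param frames List of `cg_frame`s.  Diagonal mode requires each to
#'   carry its own box.
#' @param arrangement `"diagonal"` or `"random"`.
#' @param gap Inter-phase gap in nm (diagonal mode).
#' @param box Target cubic edge or length-3 box (random mode).
#' @param min_dist Minimum allowed interatomic distance in nm (random
#'   mode).
#' @param seed Integer seed (random mode).
#' @param max_tries Placement attempts per frame before giving up.
#' @return A combined `cg_frame` with renumbered molecule ids.
#' @export
assemble_box <- function(frames, arrangement = c("diagonal", "random"),
                         gap = 0.1, box = NULL, min_dist = 0.2, seed = 1,
                         max_tries = 1000L) {
  arrangement <- match.arg(arrangement)
  stopifnot(length(frames) >= 1L, gap >= 0, min_dist >= 0)
  if (arrangement == "diagonal") {
    origin <- c(0, 0, 0)
    xyz <- NULL; atoms <- NULL
    for (f in frames) {
      if (is.null(f$box)) stop("diagonal assembly requires boxed sub-frames")
      shifted <- sweep(f$xyz, 2, origin, "+")
      xyz <- rbind(xyz, shifted)
      atoms <- rbind(atoms, f$atoms)
      origin <- origin + f$box + gap
    }
    total_box <- origin - gap
    atoms$molecule_id <- .renumber_molecules(frames)
    return(new_frame(atoms, xyz, total_box))
  }
  ## random insertion
  if (is.null(box)) stop("random assembly requires a target box")
  if (length(box) == 1L) box <- rep(box, 3)
  .with_seed(seed, {
    placed_xyz <- NULL; atoms <- NULL
    for (fi in seq_along(frames)) {
      f <- frames[[fi]]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- f$xyz
        cand <- sweep(cand, 2, colMeans(cand))
        ## random rotation
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- t(apply(cand, 1, .rotate_about, u = ax, a = ang))
        if (natoms(f) == 1L) cand <- matrix(cand, 1, 3)
        cand <- sweep(cand, 2, stats::runif(3, 0, box), "+") %% box
        if (is.null(placed_xyz)) { ok <- TRUE }
        else {
          dmin <- min(vapply(seq_len(nrow(cand)), function(i) {
            d <- .min_image(sweep(placed_xyz, 2, cand[i, ], "-"), box)
            min(rowSums(d^2))
          }, 0))
          ok <- dmin >= min_dist^2
        }
        if (ok) {
          placed_xyz <- rbind(placed_xyz, cand)
          atoms <- rbind(atoms, f$atoms)
          break
        }
      }
      if (!ok) {
        vol_frac <- nrow(placed_xyz %||% matrix(0, 0, 3)) *
          (4 / 3) * pi * (min_dist / 2)^3 / prod(box)
        stop("random insertion failed for frame ", fi, " after ",
             max_tries, " tries (approx packing fraction ",
             signif(vol_frac, 3), "); enlarge the box or reduce min_dist")
      }
    }
    atoms$molecule_id <- .renumber_molecules(frames)
    new_frame(atoms, placed_xyz, box)
  })
}

.renumber_molecules <- function(frames) {
  out <- integer(0); off <- 0L
  for (f in frames) {
    ids <- f$atoms$molecule_id
    out <- c(out, off + match(ids, unique(ids)))
    off <- off + length(unique(ids))
  }
  out
}
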