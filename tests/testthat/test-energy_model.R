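test_that("bonded term energies match their closed forms", {
  top <- chain_topology(2)
  f0 <- quick_frame(rbind(c(0, 0, 0), c(0.47, 0, 0)))
  expect_equal(evaluate_energy(f0, top)$bond, 0)

  f1 <- quick_frame(rbind(c(0, 0, 0), c(0.57, 0, 0)))
  expect_equal(evaluate_energy(f1, top)$bond, 0.5 * 1250 * 0.1^2,
               tolerance = 1e-9)

  # G96 angle at theta0 and RB with all Cn = 0 both vanish
  topg <- chain_topology(3, theta0 = 120, angle_form = "g96")
  th <- 120 * pi / 180
  f2 <- quick_frame(rbind(c(0.47, 0, 0), c(0, 0, 0),
                          0.47 * c(cos(th), sin(th), 0)))
  expect_equal(evaluate_energy(f2, topg)$angle, 0, tolerance = 1e-12)

  toprb <- chain_topology(4)
  toprb$dihedrals <- data.frame(i = 1, j = 2, k = 3, l = 4, form = "rb",
                                phi0 = NA_real_, kphi = NA_real_,
                                mult = NA_integer_, C0 = 0, C1 = 0, C2 = 0,
                                C3 = 0, C4 = 0, C5 = 0)
  f3 <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(evaluate_energy(f3, toprb)$dihedral, 0)

  # periodic dihedral extrema: k(1+cos(n*phi - phi0))
  topp <- chain_topology(4, kphi = 5, mult = 1L, phi0 = 0)
  ftrans <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0),
                              c(1, 2, 0)))
  expect_equal(evaluate_energy(ftrans, topp)$dihedral, 0, tolerance = 1e-9)
  fcis <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  expect_equal(evaluate_energy(fcis, topp)$dihedral, 10, tolerance = 1e-9)
})

test_that("total equals the sum of components", {
  set.seed(5)
  top <- chain_topology(5, charge = 0.1)
  nb <- new_nonbonded(data.frame(type = "C1", eps = 3.5, sigma = 0.47,
                                 charge = 0.1))
  f <- quick_frame(matrix(rnorm(15, 0, 0.4), 5, 3))
  e <- evaluate_energy(f, top, nb)
  expect_equal(e$total, e$bond + e$angle + e$dihedral + e$lj + e$coulomb +
                 e$restraint, tolerance = 1e-9)
})

test_that("analytic forces match central-difference gradients for every term", {
  set.seed(31)
  nb <- new_nonbonded(data.frame(type = "C1", eps = 3.5, sigma = 0.47,
                                 charge = 0.2), cutoff = 1.5)
  configs <- list(
    list(top = chain_topology(4, kb = 800), nb = NULL),
    list(top = chain_topology(4, ktheta = 40, angle_form = "harmonic"),
         nb = NULL),
    list(top = chain_topology(4, ktheta = 40, angle_form = "g96"),
         nb = NULL),
    list(top = chain_topology(5, kphi = 8, mult = 3L, phi0 = 45), nb = NULL),
    list(top = chain_topology(5, charge = 0.2), nb = nb))
  rbtop <- chain_topology(4)
  rbtop$dihedrals <- data.frame(i = 1, j = 2, k = 3, l = 4, form = "rb",
                                phi0 = NA_real_, kphi = NA_real_,
                                mult = NA_integer_, C0 = 9.28, C1 = 12.16,
                                C2 = -13.12, C3 = -3.06, C4 = 26.24,
                                C5 = -31.5)
  configs <- c(configs, list(list(top = rbtop, nb = NULL)))
  for (cfg in configs) {
    n <- nrow(cfg$top$beads)
    f <- quick_frame(matrix(rnorm(3 * n, 0, 0.35), n, 3))
    F <- evaluate_forces(f, cfg$top, cfg$nb)
    num <- matrix(0, n, 3); h <- 1e-6
    for (i in seq_len(n)) for (k in 1:3) {
      fp <- f; fp$xyz[i, k] <- fp$xyz[i, k] + h
      fm <- f; fm$xyz[i, k] <- fm$xyz[i, k] - h
      num[i, k] <- -(evaluate_energy(fp, cfg$top, cfg$nb)$total -
                       evaluate_energy(fm, cfg$top, cfg$nb)$total) / (2 * h)
    }
    expect_lt(max(abs(F - num)) / max(1, max(abs(num))), 1e-4)
  }
})

test_that("shifted LJ and Coulomb vanish continuously at the cutoff", {
  top <- new_topology("PAIR", data.frame(name = c("B1", "B2"), type = "C1",
                                         mass = 72, charge = 0.3))
  nb <- new_nonbonded(data.frame(type = "C1", eps = 3.5, sigma = 0.47,
                                 charge = 0.3), cutoff = 1.0, shift = TRUE)
  for (delta in c(1e-2, 1e-4, 1e-6)) {
    f <- quick_frame(rbind(c(0, 0, 0), c(1.0 - delta, 0, 0)),
                     molecule_name = "PAIR")
    e <- evaluate_energy(f, top, nb)
    expect_lt(abs(e$lj) + abs(e$coulomb), 50 * delta)
  }
  fout <- quick_frame(rbind(c(0, 0, 0), c(1.01, 0, 0)),
                      molecule_name = "PAIR")
  eo <- evaluate_energy(fout, top, nb)
  expect_equal(eo$lj + eo$coulomb, 0)
})

test_that("exclusion depth removes bonded neighbours from nonbonded sums", {
  top <- chain_topology(4, charge = 0.3)
  nb <- new_nonbonded(data.frame(type = "C1", eps = 3.5, sigma = 0.47,
                                 charge = 0.3), cutoff = 2.5)
  f <- quick_frame(rbind(c(0, 0, 0), c(0.47, 0, 0), c(0.94, 0, 0.2),
                         c(1.2, 0.3, 0.2)))
  e <- evaluate_energy(f, top, nb)
  # only the single 1-4 pair survives exclusion: compute it directly
  r <- sqrt(sum((f$xyz[4, ] - f$xyz[1, ])^2))
  sr6 <- (0.47 / r)^6; src6 <- (0.47 / 2.5)^6
  vlj <- 4 * 3.5 * (sr6^2 - sr6) - 4 * 3.5 * (src6^2 - src6)
  vq <- cg_constants$f_coulomb * 0.09 * (1 / r - 1 / 2.5)
  expect_equal(e$lj, vlj, tolerance = 1e-9)
  expect_equal(e$coulomb, vq, tolerance = 1e-9)
})

test_that("missing pair parameters name the offending type", {
  top <- chain_topology(2)
  nb <- new_nonbonded(data.frame(type = "P4", eps = 5, sigma = 0.47))
  f <- quick_frame(rbind(c(0, 0, 0), c(0.47, 0, 0)))
  expect_error(evaluate_energy(f, top, nb), "C1")
})

test_that("steepest descent finds the analytic single-bond minimum monotonically", {
  top <- chain_topology(2)
  f <- quick_frame(rbind(c(0, 0, 0), c(0.6, 0, 0)))
  m <- minimize(f, top, settings = minimizer_settings(fmax = 0.1))
  blen <- sqrt(sum((m$frame$xyz[2, ] - m$frame$xyz[1, ])^2))
  expect_lt(abs(blen - 0.47), 1e-4)
  expect_lt(m$energy$total, 1e-5)
  expect_true(m$converged)
  expect_true(all(diff(m$trace) <= 0))
})

test_that("an input below the force threshold is returned unchanged with 0 steps", {
  top <- chain_topology(2)
  f <- quick_frame(rbind(c(0, 0, 0), c(0.47005, 0, 0)))
  m <- minimize(f, top, settings = minimizer_settings(fmax = 100))
  expect_identical(m$frame$xyz, f$xyz)
  expect_equal(m$steps, 0L)
  expect_true(m$converged)
})

test_that("separable bond+angle system relaxes bonds without moving the angle", {
  top <- chain_topology(3, theta0 = 120, ktheta = 25)
  th <- 120 * pi / 180
  # bonds stretched 15% but angle exactly at equilibrium
  f <- quick_frame(rbind(0.54 * c(cos(th), sin(th), 0), c(0, 0, 0),
                         c(0.54, 0, 0)))
  m <- minimize(f, top, settings = minimizer_settings(fmax = 1e-3,
                                                      max_steps = 20000))
  r <- measure_internals(m$frame, chain_scheme(3))
  expect_lt(abs(r$value[r$kind == "angle"] - 120), 1e-3)
  expect_lt(m$energy$total, 1e-7)
})

test_that("relative conformation energies are gauge-free and match closed forms", {
  top <- chain_topology(4, kphi = 5, mult = 1L, phi0 = 180)  # minimum at 0
  f <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  res <- relative_conformation_energies(list(f, f, f), top,
                                        settings =
                                          minimizer_settings(max_steps = 1))
  expect_equal(res$dU, c(0, 0, 0))

  # gauge shift: adding a constant through an extra RB C0 term leaves dU
  top_shift <- top
  top_shift$dihedrals <- rbind(top_shift$dihedrals, data.frame(
    i = 1, j = 2, k = 3, l = 4, form = "rb", phi0 = NA_real_,
    kphi = NA_real_, mult = NA_integer_, C0 = 123.456, C1 = 0, C2 = 0,
    C3 = 0, C4 = 0, C5 = 0))
  set.seed(8)
  confs <- lapply(1:4, function(q)
    quick_frame(matrix(rnorm(12, 0, 0.4), 4, 3)))
  st <- minimizer_settings(fmax = 5, max_steps = 3000)
  r1 <- relative_conformation_energies(confs, top, settings = st)
  r2 <- relative_conformation_energies(confs, top_shift, settings = st)
  expect_equal(r2$U - r1$U, rep(123.456, 4), tolerance = 1e-6)
  expect_equal(r2$dU, r1$dU, tolerance = 1e-6)
  expect_equal(min(r1$dU), 0)
  expect_true(all(r1$dU >= 0))
})

test_that("a rotated-dihedral conformer pair yields the closed-form dU", {
  # stiff bonds/angles, single soft periodic dihedral (k=5, n=1, phi0=180):
  # conformer A at the 0-degree minimum, conformer B rotated to 60 degrees
  top <- chain_topology(4, kb = 1e5, ktheta = 1e4, kphi = 5, mult = 1L,
                        phi0 = 180)
  mk <- function(phi) {
    th <- 120 * pi / 180
    x3 <- c(0.47, 0, 0)
    x2 <- c(0, 0, 0)
    x4 <- x3 + 0.47 * c(cos(pi - th), sin(pi - th), 0)
    # place bead 1 by NeRF off the 4-3-2 frame at the requested dihedral
    x1 <- cgconform:::.nerf_place(x4, x3, x2, 0.47, th, phi * pi / 180)
    quick_frame(rbind(x1, x2, x3, x4))
  }
  # under the conventional fmax = 100 threshold the soft-dihedral forces
  # (~9 kJ/mol/nm) are already converged, so U is the as-built energy
  res <- relative_conformation_energies(list(mk(0), mk(60)), top)
  want <- 5 * (1 + cos(60 * pi / 180 - pi)) - 5 * (1 + cos(0 - pi))
  expect_equal(res$dU[2], want, tolerance = 1e-6)
})

test_that("minimized energy is invariant under rigid transforms of the conformer", {
  set.seed(14)
  top <- chain_topology(4)
  f <- quick_frame(matrix(rnorm(12, 0, 0.4), 4, 3))
  st <- minimizer_settings(fmax = 0.01, max_steps = 30000)
  u0 <- minimize(f, top, settings = st)$energy$total
  for (q in 1:5) {
    fr <- apply_rigid(f, rnorm(3), runif(1, 0, 2 * pi), rnorm(3))
    uq <- minimize(fr, top, settings = st)$energy$total
    expect_lt(abs(uq - u0), 1e-6)
  }
})

test_that("position restraints add the harmonic penalty and pin particles", {
  top <- chain_topology(2)
  f <- quick_frame(rbind(c(0, 0, 0), c(0.47, 0, 0)))
  pr <- position_restraints(f$xyz, k = 1000)
  expect_equal(evaluate_energy(f, top, restraints = pr)$restraint, 0)

  fd <- f; fd$xyz[1, ] <- fd$xyz[1, ] + c(0.1, 0, 0)
  e <- evaluate_energy(fd, top, restraints = pr)
  expect_equal(e$restraint, 0.5 * 1000 * 0.01, tolerance = 1e-12)

  # stiff restraint dominates the stretched bond
  fstretch <- quick_frame(rbind(c(0, 0, 0), c(0.6, 0, 0)))
  prs <- position_restraints(fstretch$xyz[1, , drop = FALSE], k = 1e6,
                             indices = 1L)
  m <- minimize(fstretch, top, restraints = prs,
                settings = minimizer_settings(fmax = 0.1,
                                              max_steps = 20000))
  expect_lt(sqrt(sum((m$frame$xyz[1, ] - fstretch$xyz[1, ])^2)), 0.01)

  expect_error(position_restraints(f$xyz, k = 10, indices = 1L),
               "does not match")
})

test_that("overlapping particles raise an actionable error", {
  top <- new_topology("PAIR", data.frame(name = c("B1", "B2"), type = "C1",
                                         mass = 72, charge = 0))
  nb <- new_nonbonded(data.frame(type = "C1", eps = 3.5, sigma = 0.47))
  f <- quick_frame(rbind(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2)),
                   molecule_name = "PAIR")
  expect_error(evaluate_energy(f, top, nb), "jitter|overlap")
})
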