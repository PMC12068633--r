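test_that("mapping puts beads at mass-weighted centres and conserves mass/COM", {
  sch <- new_scheme(list(DIMER = list(
    beads = list(list(name = "BD", type = "P1", atoms = c("A1", "A2"),
                      charge = 0)),
    bonds = list(), angles = list(), dihedrals = list())))
  f <- new_frame(data.frame(name = c("A1", "A2"), mass = c(12, 12),
                            molecule_name = "DIMER"),
                 rbind(c(0, 0, 0), c(0, 0, 1)))
  cg <- map_frame(f, sch)
  expect_equal(drop(cg$xyz), c(0, 0, 0.5))
  expect_equal(cg$atoms$mass, 24)

  # ethanol: 9 atoms to one bead, bead mass = molecular mass
  eth_names <- c("C1", "C2", "O1", paste0("H", 1:6))
  sch_e <- new_scheme(list(EOH = list(
    beads = list(list(name = "P2", type = "P2", atoms = eth_names,
                      charge = 0)))))
  set.seed(3)
  fe <- new_frame(data.frame(name = eth_names, molecule_name = "EOH"),
                  matrix(rnorm(27, 0, 0.05), 9, 3))
  cge <- map_frame(fe, sch_e)
  expect_equal(cge$atoms$mass, 46.069, tolerance = 1e-3)
  expect_equal(sum(cge$atoms$mass), sum(fe$atoms$mass))
  # nested weighted means: per-molecule COM preserved to 1e-9
  expect_lt(max(abs(center_of_mass(cge) - center_of_mass(fe))), 1e-9)
})

test_that("unmatched and doubly-claimed atoms are rejected with names", {
  f <- new_frame(data.frame(name = c("A1", "A2", "A3"), mass = 12,
                            molecule_name = "TRI"),
                 matrix(0:8 / 10, 3, 3))
  sch_missing <- new_scheme(list(TRI = list(
    beads = list(list(name = "B1", type = "P1", atoms = c("A1", "A2"),
                      charge = 0)))))
  expect_error(map_frame(f, sch_missing), "A3")
  sch_double <- new_scheme(list(TRI = list(
    beads = list(list(name = "B1", type = "P1", atoms = c("A1", "A2"),
                      charge = 0),
                 list(name = "B2", type = "P1", atoms = c("A2", "A3"),
                      charge = 0)))))
  expect_error(map_frame(f, sch_double), "claimed by two")
})

test_that("measured internal coordinates match forced geometries", {
  sch3 <- chain_scheme(3)
  fcol <- quick_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  rcol <- measure_internals(fcol, sch3)
  expect_equal(rcol$value[rcol$kind == "bond"], c(1, 1))
  expect_equal(rcol$value[rcol$kind == "angle"], 180)

  sch <- chain_scheme(4)

  f2 <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 1, 1)))
  r2 <- measure_internals(f2, sch)
  expect_equal(r2$value[r2$kind == "dihedral"], -90, tolerance = 1e-10)

  # planar cis quadruple (4th particle on the same side as the 1st)
  f3 <- quick_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  r3 <- measure_internals(f3, sch)
  expect_equal(r3$value[r3$kind == "dihedral"], 0, tolerance = 1e-10)
})

test_that("dihedrals agree with the rotation-construction oracle for 100 angles", {
  sch <- chain_scheme(4)
  set.seed(123)
  phis <- runif(100, -179.99, 180)
  for (phi in phis) {
    f <- quick_frame(dihedral_by_rotation(phi))
    r <- measure_internals(f, sch)
    got <- r$value[r$kind == "dihedral"]
    err <- abs(got - phi)
    expect_lt(min(err, 360 - err), 1e-9)
  }
})

test_that("internal coordinates are invariant under rigid transforms", {
  sch <- chain_scheme(5)
  set.seed(21)
  base <- quick_frame(matrix(rnorm(15, 0, 0.4), 5, 3))
  ref <- measure_internals(base, sch)
  for (q in 1:50) {
    fr <- apply_rigid(base, rnorm(3), runif(1, 0, 2 * pi), rnorm(3))
    got <- measure_internals(fr, sch)
    expect_lt(max(abs(got$value - ref$value)), 1e-9)
  }
})

test_that("minimum image is applied to bonds across the periodic boundary", {
  sch <- chain_scheme(2)
  f <- quick_frame(rbind(c(0.05, 0.5, 0.5), c(1.95, 0.5, 0.5)),
                   box = c(2, 2, 2))
  r <- measure_internals(f, sch)
  expect_equal(r$value, 0.1, tolerance = 1e-12)
})

test_that("topology derivation averages correctly and Boltzmann-inverts", {
  sch <- chain_scheme(2)
  recs <- data.frame(kind = "bond", i = 1L, j = 2L, k = NA, l = NA,
                     value = rep(0.47, 50), molecule_id = 1:50, time = NA)
  top <- derive_topology(recs, sch, mode = "fixed")
  expect_equal(top$bonds$b0, 0.47)
  expect_equal(top$bonds$kb, 1250)

  set.seed(77)
  recs2 <- recs[rep(1, 1e4), ]
  recs2$value <- rnorm(1e4, 0.47, 0.02)
  top2 <- derive_topology(recs2, sch, mode = "boltzmann", temperature = 300)
  k_expect <- cg_constants$kB * 300 / 0.02^2
  expect_lt(abs(top2$bonds$kb - k_expect) / k_expect, 0.10)

  recs3 <- recs
  expect_error(derive_topology(recs3, sch, mode = "boltzmann"),
               "zero variance")
})

test_that("dihedral equilibrium uses the circular mean across the wrap", {
  sch4 <- chain_scheme(4)
  recs <- rbind(
    data.frame(kind = "bond", i = 1:3, j = 2:4, k = NA, l = NA, value = 0.47,
               molecule_id = 1L, time = NA),
    data.frame(kind = "angle", i = 1:2, j = 2:3, k = 3:4, l = NA, value = 120,
               molecule_id = 1L, time = NA),
    data.frame(kind = "dihedral", i = 1L, j = 2L, k = 3L, l = 4L,
               value = c(179, -179), molecule_id = 1:2, time = NA))
  top <- derive_topology(recs, sch4, mode = "fixed")
  d <- top$dihedrals
  # minimum of k(1+cos(n phi - phi0)) must sit at the circular mean 180
  eq <- (d$phi0 - 180) / d$mult
  err <- abs((eq - 180) %% 360)
  expect_lt(min(err, 360 - err), 1e-9)
})

test_that("parameter recovery from a sampled Boltzmann ensemble", {
  top_true <- chain_topology(3, b0 = 0.47, kb = 1250, theta0 = 120,
                             ktheta = 60)
  ens <- sample_conformer_ensemble(top_true, 300, 800, seed = 42)
  sch <- chain_scheme(3)
  recs <- do.call(rbind, lapply(ens, measure_internals, scheme = sch))
  top <- derive_topology(recs, sch, mode = "boltzmann", temperature = 300)
  expect_lt(max(abs(top$bonds$b0 - 0.47)), 0.005)
  expect_lt(abs(top$angles$theta0 - 120), 2)
  expect_lt(abs(top$bonds$kb[1] - 1250) / 1250, 0.15)
  expect_lt(abs(top$angles$ktheta - 60) / 60, 0.15)
})

test_that("ITP round trip preserves parameters and distinguishes angle forms", {
  top <- new_topology(
    "TOY",
    data.frame(name = c("B1", "B2", "B3", "B4"), type = c("P1", "C1", "C1",
                                                          "Na"),
               mass = c(54.321123, 72, 72, 45.5), charge = c(0.1, 0, 0,
                                                             -0.1)),
    bonds = data.frame(i = 1:3, j = 2:4, b0 = c(0.47, 0.123456, 0.5),
                       kb = c(1250, 987.654, 10)),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, theta0 = c(120, 98.7654),
                        ktheta = c(25, 12.3456),
                        form = c("harmonic", "g96"), stringsAsFactors = FALSE),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, form = "periodic",
                           phi0 = 33.3333, kphi = 5.55555, mult = 2L,
                           C0 = NA_real_, C1 = NA_real_, C2 = NA_real_,
                           C3 = NA_real_, C4 = NA_real_, C5 = NA_real_))
  p <- withr::local_tempfile(fileext = ".itp")
  write_topology(top, p)
  lines <- readLines(p)
  expect_true(any(grepl("^\\s*1\\s+2\\s+1\\s+0\\.47\\s+1250", lines)))
  # harmonic and G96 angle lines carry distinct function tags
  atags <- sub("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+(\\d+).*$", "\\1",
               grep("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+1[02]", lines,
                    value = TRUE))
  rt <- read_topology(p)
  tol6 <- 1e-5  # 6 significant digits
  expect_equal(rt$angles$form, c("harmonic", "g96"))
  expect_equal(rt$bonds$b0, top$bonds$b0, tolerance = tol6)
  expect_equal(rt$bonds$kb, top$bonds$kb, tolerance = tol6)
  expect_equal(rt$angles$theta0, top$angles$theta0, tolerance = tol6)
  expect_equal(rt$dihedrals$phi0, top$dihedrals$phi0, tolerance = tol6)
  expect_equal(rt$dihedrals$kphi, top$dihedrals$kphi, tolerance = tol6)
  expect_equal(rt$dihedrals$mult, top$dihedrals$mult)
  expect_equal(rt$beads$mass, top$beads$mass, tolerance = tol6)

  # RB dihedral round trip
  top$dihedrals <- data.frame(i = 1, j = 2, k = 3, l = 4, form = "rb",
                              phi0 = NA_real_, kphi = NA_real_,
                              mult = NA_integer_, C0 = 1.1, C1 = -2.2,
                              C2 = 0.33, C3 = 1.234567, C4 = -0.3, C5 = 0.1)
  write_topology(top, p)
  rt2 <- read_topology(p)
  expect_equal(unlist(rt2$dihedrals[1, paste0("C", 0:5)]),
               unlist(top$dihedrals[1, paste0("C", 0:5)]), tolerance = 1e-5)
})

test_that("scheme YAML round trip preserves beads and connectivity", {
  sch <- chain_scheme(4)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(sch, p)
  rt <- read_scheme(p)
  expect_equal(rt$molecules$CHAIN$bonds, sch$molecules$CHAIN$bonds)
  expect_equal(rt$molecules$CHAIN$dihedrals, sch$molecules$CHAIN$dihedrals)
  expect_equal(vapply(rt$molecules$CHAIN$beads, `[[`, "", "name"),
               vapply(sch$molecules$CHAIN$beads, `[[`, "", "name"))
})
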