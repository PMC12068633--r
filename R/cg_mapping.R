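## Coarse-grained mapping: declarative bead schemes, AA -> CG projection,
## internal-coordinate measurement and bonded-topology derivation.

#' Construct or read a bead-mapping scheme
#'
#' A mapping scheme declares, per molecule name, an ordered set of beads
#' (each bead a group of atom names with a MARTINI-style type label and a
#' charge) and the CG connectivity (bond pairs, angle triples, dihedral
#' quadruples, 1-based bead indices).
#'
#' @param molecules Named list; each element a list with fields
#'   `beads` (list of `list(name=, type=, atoms=, charge=)`),
#'   and optionally `bonds`, `angles`, `dihedrals` (lists/matrices of bead
#'   index tuples).
#' @return An object of class `"cg_scheme"`.
#' @export
new_scheme <- function(molecules) {
  stopifnot(is.list(molecules), length(molecules) >= 1L,
            !is.null(names(molecules)))
  for (mn in names(molecules)) {
    mol <- molecules[[mn]]
    if (is.null(mol$beads) || !length(mol$beads))
      stop("molecule '", mn, "' declares no beads")
    bn <- vapply(mol$beads, function(b) as.character(b$name), "")
    if (anyDuplicated(bn))
      stop("duplicate bead name in molecule '", mn, "': ",
           bn[duplicated(bn)][1])
    for (b in mol$beads)
      if (!length(b$atoms)) stop("bead '", b$name, "' of '", mn,
                                 "' has no member atoms")
    nb <- length(mol$beads)
    for (kind in c("bonds", "angles", "dihedrals")) {
      tb <- .tuple_matrix(mol[[kind]], c(bonds = 2L, angles = 3L,
                                         dihedrals = 4L)[[kind]])
      if (length(tb) && (any(tb < 1L) || any(tb > nb)))
        stop(kind, " of molecule '", mn, "' reference bead index out of 1..",
             nb)
      molecules[[mn]][[kind]] <- tb
    }
  }
  structure(list(molecules = molecules), class = "cg_scheme")
}

.tuple_matrix <- function(x, width) {
  if (is.null(x) || !length(x)) return(matrix(integer(0), 0, width))
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.integer))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != width) stop("expected ", width, "-tuples, got ", ncol(x),
                             " columns")
  unname(x)
}

#' @rdname new_scheme
#' @param path YAML or JSON file with a top-level `molecules` mapping (or
#'   the molecule mapping directly).
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(raw$molecules)) raw <- raw$molecules
  raw <- lapply(raw, function(mol) {
    mol$beads <- lapply(mol$beads, function(b) {
      list(name = b$name, type = if (is.null(b$type)) "P1" else b$type,
           atoms = unlist(b$atoms, use.names = FALSE),
           charge = if (is.null(b$charge)) 0 else as.numeric(b$charge))
    })
    mol
  })
  new_scheme(raw)
}

#' @rdname new_scheme
#' @param scheme A `cg_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  out <- lapply(scheme$molecules, function(mol) {
    list(beads = lapply(mol$beads, function(b)
           list(name = b$name, type = b$type, atoms = as.list(b$atoms),
                charge = b$charge)),
         bonds = .tuples_to_list(mol$bonds),
         angles = .tuples_to_list(mol$angles),
         dihedrals = .tuples_to_list(mol$dihedrals))
  })
  yaml::write_yaml(list(molecules = out), path)
  invisible(path)
}

.tuples_to_list <- function(m)
  if (!nrow(m)) list() else lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))

#' Map an all-atom frame to a coarse-grained bead frame
#'
#' Each bead position is the mass-weighted mean of its member atoms
#' (\eqn{r_c = \sum m_i r_i / \sum m_i}); the bead mass is the summed
#' member mass, so total mass and every per-molecule centre of mass are
#' conserved exactly.
#'
#' @param frame An all-atom `cg_frame`.
#' @param scheme A `cg_scheme` covering every molecule name present in
#'   `frame` that is to be mapped.  Every atom of a mapped molecule must
#'   belong to exactly one bead.
#' @return A `cg_frame` of beads, with bead types in `atoms$type` and
#'   charges in `atoms$charge`.
#' @export
map_frame <- function(frame, scheme) {
  stopifnot(inherits(frame, "cg_frame"), inherits(scheme, "cg_scheme"))
  a <- frame$atoms
  mol_ids <- unique(a$molecule_id)
  rows <- list(); pos <- list()
  for (mid in mol_ids) {
    sel <- which(a$molecule_id == mid)
    mname <- a$molecule_name[sel[1]]
    mol <- scheme$molecules[[mname]]
    if (is.null(mol))
      stop("no mapping for molecule '", mname, "' (id ", mid, ")")
    claimed <- integer(0)
    for (bi in seq_along(mol$beads)) {
      b <- mol$beads[[bi]]
      idx <- sel[match(b$atoms, a$name[sel])]
      if (anyNA(idx))
        stop("molecule '", mname, "' (id ", mid, "): atom(s) ",
             paste(b$atoms[is.na(idx)], collapse = ", "),
             " of bead '", b$name, "' not found")
      dup <- intersect(idx, claimed)
      if (length(dup))
        stop("molecule '", mname, "' (id ", mid, "): atom '",
             a$name[dup[1]], "' claimed by two beads")
      claimed <- c(claimed, idx)
      m <- a$mass[idx]
      rows[[length(rows) + 1L]] <-
        data.frame(name = b$name, type = b$type, mass = sum(m),
                   charge = b$charge, molecule_id = mid,
                   molecule_name = mname, stringsAsFactors = FALSE)
      pos[[length(pos) + 1L]] <-
        drop(crossprod(frame$xyz[idx, , drop = FALSE], m)) / sum(m)
    }
    un <- setdiff(sel, claimed)
    if (length(un))
      stop("molecule '", mname, "' (id ", mid, "): atom(s) ",
           paste(unique(a$name[un]), collapse = ", "),
           " matched by no bead definition")
  }
  beads <- do.call(rbind, rows)
  beads$element <- NA_character_
  new_frame(beads, do.call(rbind, pos), frame$box)
}

## --------------------------------------------------------------------
## Internal-coordinate geometry.  Angles use the central-bead convention
## (180 deg for a straight chain); dihedrals the IUPAC atan2 form with
## 0 = cis, range (-180, 180].

.bond_length <- function(r1, r2, box = NULL)
  sqrt(sum(.min_image(r2 - r1, box)^2))

.bead_angle <- function(r1, r2, r3, box = NULL) {
  a <- .min_image(r1 - r2, box); b <- .min_image(r3 - r2, box)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length bond vector in angle")
  cth <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cth))) * 180 / pi
}

.dihedral <- function(r1, r2, r3, r4, box = NULL) {
  v1 <- .min_image(r2 - r1, box)
  v2 <- .min_image(r3 - r2, box)
  v3 <- .min_image(r4 - r3, box)
  n1 <- .cross3(v1, v2); n2 <- .cross3(v2, v3)
  if (sum(n1^2) == 0 || sum(n2^2) == 0)
    stop("collinear or zero-length bond vectors: dihedral undefined")
  phi <- atan2(sqrt(sum(v2^2)) * sum(v1 * n2), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Measure CG internal coordinates over a frame or trajectory
#'
#' Bonds are vector norms (nm); angles are measured at the central bead
#' between the two flanking beads, in degrees (180 for a straight chain);
#' dihedrals use the `atan2` convention with 0 = cis, range
#' (-180, 180].  The minimum-image convention is applied to every
#' displacement when the frame has a box.
#'
#' @param x A CG `cg_frame` or `cg_traj` (bead naming as produced by
#'   [map_frame()] or [generate_molecule()]).
#' @param scheme A `cg_scheme` providing the connectivity.
#' @return `data.frame` with columns `kind` ("bond"/"angle"/"dihedral"),
#'   `i,j,k,l` (bead indices within the molecule; unused trailing indices
#'   `NA`), `value` (nm or degrees), `molecule_id`, `time` (ns; `NA` for a
#'   bare frame).
#' @export
measure_internals <- function(x, scheme) {
  if (inherits(x, "cg_frame"))
    return(.measure_frame(x, scheme, NA_real_))
  stopifnot(inherits(x, "cg_traj"))
  do.call(rbind, lapply(seq_along(x$frames), function(i)
    .measure_frame(x$frames[[i]], scheme, x$times[i])))
}

.measure_frame <- function(frame, scheme, time) {
  a <- frame$atoms
  out <- list()
  for (mid in unique(a$molecule_id)) {
    sel <- which(a$molecule_id == mid)
    mol <- scheme$molecules[[a$molecule_name[sel[1]]]]
    if (is.null(mol)) next
    r <- function(b) frame$xyz[sel[b], ]
    bx <- frame$box
    bm <- mol$bonds
    if (nrow(bm)) out[[length(out) + 1L]] <- data.frame(
      kind = "bond", i = bm[, 1], j = bm[, 2], k = NA_integer_,
      l = NA_integer_,
      value = vapply(seq_len(nrow(bm)), function(q)
        .bond_length(r(bm[q, 1]), r(bm[q, 2]), bx), 0),
      molecule_id = mid, time = time, stringsAsFactors = FALSE)
    am <- mol$angles
    if (nrow(am)) out[[length(out) + 1L]] <- data.frame(
      kind = "angle", i = am[, 1], j = am[, 2], k = am[, 3],
      l = NA_integer_,
      value = vapply(seq_len(nrow(am)), function(q)
        .bead_angle(r(am[q, 1]), r(am[q, 2]), r(am[q, 3]), bx), 0),
      molecule_id = mid, time = time, stringsAsFactors = FALSE)
    dm <- mol$dihedrals
    if (nrow(dm)) out[[length(out) + 1L]] <- data.frame(
      kind = "dihedral", i = dm[, 1], j = dm[, 2], k = dm[, 3], l = dm[, 4],
      value = vapply(seq_len(nrow(dm)), function(q)
        .dihedral(r(dm[q, 1]), r(dm[q, 2]), r(dm[q, 3]), r(dm[q, 4]), bx), 0),
      molecule_id = mid, time = time, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no connectivity declared for any molecule present")
  do.call(rbind, out)
}

## Circular mean of angles in degrees, result in (-180, 180].
.circ_mean_deg <- function(x) {
  rad <- x * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (m <= -180) m + 360 else m
}

## Circular variance proxy: variance of wrapped deviations from the
## circular mean, in squared degrees.
.circ_var_deg2 <- function(x) {
  m <- .circ_mean_deg(x)
  d <- (x - m + 180) %% 360 - 180
  mean(d^2)
}

#' Derive a bonded CG topology from measured internal coordinates
#'
#' Equilibrium values are ensemble means over all molecules and frames
#' (arithmetic for bonds and angles, circular for dihedrals).  Force
#' constants are either fixed config defaults or obtained by Boltzmann
#' inversion, \eqn{k = k_B T / \mathrm{var}}, with bond variance in nm^2
#' and angle/dihedral variance in rad^2.  Periodic dihedral constants use
#' the small-oscillation correspondence \eqn{k_\phi = k_B T/(n^2
#' \mathrm{var})} with the phase set so the potential minimum sits at the
#' circular mean.
#'
#' @param records Output of [measure_internals()].
#' @param scheme The `cg_scheme` (for bead identities and types).
#' @param molecule Molecule name to parameterise (default: the single name
#'   present in `scheme`).
#' @param mode `"fixed"` or `"boltzmann"`.
#' @param temperature Kelvin; used by Boltzmann inversion.
#' @param defaults Fixed force constants: list with `k_bond`
#'   (kJ mol^-1 nm^-2), `k_angle` (kJ mol^-1), `k_dihedral` (kJ mol^-1),
#'   `dihedral_mult`.  MARTINI-typical magnitudes are the defaults.
#' @param angle_form `"harmonic"` or `"g96"` tag recorded on angle terms.
#' @param bead_masses Optional named numeric vector of per-bead masses;
#'   when absent, masses must be recoverable later from a mapped frame
#'   and are set to `NA`.
#' @return An object of class `"cg_topology"`: list with `name`, `beads`
#'   (`data.frame`: name, type, mass, charge), `bonds` (i, j, b0, kb),
#'   `angles` (i, j, k, theta0, ktheta, form), `dihedrals` (i, j, k, l,
#'   form, phi0, kphi, mult, C0..C5).
#' @export
derive_topology <- function(records, scheme,
                            molecule = names(scheme$molecules)[1],
                            mode = c("fixed", "boltzmann"),
                            temperature = 300,
                            defaults = list(k_bond = 1250, k_angle = 25,
                                            k_dihedral = 5, dihedral_mult = 1L),
                            angle_form = c("harmonic", "g96"),
                            bead_masses = NULL) {
  mode <- match.arg(mode); angle_form <- match.arg(angle_form)
  mol <- scheme$molecules[[molecule]]
  if (is.null(mol)) stop("molecule '", molecule, "' not in scheme")
  kB <- cg_constants$kB
  bn <- vapply(mol$beads, function(b) b$name, "")
  beads <- data.frame(
    name = bn,
    type = vapply(mol$beads, function(b) b$type, ""),
    mass = if (is.null(bead_masses)) NA_real_ else unname(bead_masses[bn]),
    charge = vapply(mol$beads, function(b) as.numeric(b$charge), 0),
    stringsAsFactors = FALSE)

  summarise <- function(kind, m, cols) {
    if (!nrow(m)) return(NULL)
    recs <- records[records$kind == kind, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(m)), function(q) {
      key <- m[q, ]
      hit <- rep(TRUE, nrow(recs))
      for (ci in seq_along(cols)) hit <- hit & recs[[cols[ci]]] == key[ci]
      v <- recs$value[hit]
      if (!length(v))
        stop("no ", kind, " records for term (",
             paste(key, collapse = ","), ")")
      if (kind == "dihedral") {
        mu <- .circ_mean_deg(v); va <- .circ_var_deg2(v) * (pi / 180)^2
      } else {
        mu <- mean(v); va <- stats::var(v) * (length(v) - 1) / length(v)
        if (kind == "angle") va <- va * (pi / 180)^2
      }
      if (mode == "boltzmann" && va == 0)
        stop("zero variance for ", kind, " term (",
             paste(key, collapse = ","),
             "); Boltzmann inversion undefined - use mode = 'fixed'")
      data.frame(t(stats::setNames(as.integer(key), cols)), mu = mu, va = va)
    }))
  }

  b <- summarise("bond", mol$bonds, c("i", "j"))
  bonds <- if (is.null(b)) data.frame() else data.frame(
    i = b$i, j = b$j, b0 = b$mu,
    kb = if (mode == "boltzmann") kB * temperature / b$va
         else defaults$k_bond)
  a <- summarise("angle", mol$angles, c("i", "j", "k"))
  angles <- if (is.null(a)) data.frame() else data.frame(
    i = a$i, j = a$j, k = a$k, theta0 = a$mu,
    ktheta = if (mode == "boltzmann") kB * temperature / a$va
             else defaults$k_angle,
    form = angle_form, stringsAsFactors = FALSE)
  d <- summarise("dihedral", mol$dihedrals, c("i", "j", "k", "l"))
  mult <- as.integer(defaults$dihedral_mult)
  dihedrals <- if (is.null(d)) data.frame() else data.frame(
    i = d$i, j = d$j, k = d$k, l = d$l, form = "periodic",
    ## minimum of k(1+cos(n phi - phi0)) at phi = (phi0 - 180)/n:
    ## place it at the circular mean
    phi0 = ((d$mu * mult + 180 + 180) %% 360) - 180,
    kphi = if (mode == "boltzmann") kB * temperature / (mult^2 * d$va)
           else defaults$k_dihedral,
    mult = mult, C0 = NA_real_, C1 = NA_real_, C2 = NA_real_,
    C3 = NA_real_, C4 = NA_real_, C5 = NA_real_, stringsAsFactors = FALSE)
  new_topology(molecule, beads, bonds, angles, dihedrals)
}

#' @rdname derive_topology
#' @param name Molecule name.
#' @param beads,bonds,angles,dihedrals Component tables, see above.
#' @export
new_topology <- function(name, beads, bonds = data.frame(),
                         angles = data.frame(), dihedrals = data.frame()) {
  nb <- nrow(beads)
  chk <- function(tb, cols) {
    if (!nrow(tb)) return()
    idx <- unlist(tb[cols])
    if (any(idx < 1L | idx > nb)) stop("bonded term references bead out of 1..",
                                       nb)
  }
  chk(bonds, c("i", "j")); chk(angles, c("i", "j", "k"))
  chk(dihedrals, c("i", "j", "k", "l"))
  if (nrow(bonds) && any(bonds$kb < 0)) stop("negative force constant")
  if (nrow(angles) && any(angles$ktheta < 0)) stop("negative force constant")
  structure(list(name = name, beads = beads, bonds = bonds, angles = angles,
                 dihedrals = dihedrals),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology '", x$name, "': ", nrow(x$beads), " beads, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, ",
      nrow(x$dihedrals), " dihedrals\n", sep = "")
  invisible(x)
}
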