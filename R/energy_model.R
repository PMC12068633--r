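## Potential-energy model: harmonic bonds, harmonic/G96 angles,
## periodic/Ryckaert-Bellemans dihedrals, shifted LJ + Coulomb, optional
## harmonic position restraints.  Degrees at the interfaces, radians
## internally.  Analytic gradients for every term (validated against
## central differences in the test suite).

#' Nonbonded parameter table
#'
#' @param types `data.frame` with columns `type`, `eps` (kJ mol^-1),
#'   `sigma` (nm), `charge` (e).
#' @param mixing `"geometric"` (\eqn{\epsilon_{ij}=\sqrt{\epsilon_i
#'   \epsilon_j}}, \eqn{\sigma_{ij}=\sqrt{\sigma_i\sigma_j}}) or
#'   `"lorentz_berthelot"` (arithmetic \eqn{\sigma}).
#' @param cutoff Cutoff radius r_c in nm for LJ and Coulomb.
#' @param shift Logical; subtract V(r_c) so the truncated potentials
#'   vanish continuously at the cutoff.
#' @param excl_depth Bonded separation up to which pairs are excluded
#'   from nonbonded interactions (2 = exclude 1-2 and 1-3 pairs).
#' @param fudge_lj,fudge_qq Scaling applied to pairs exactly one bond
#'   beyond the exclusion depth (the 1-4 pairs under the default depth).
#' @return An object of class `"cg_nonbonded"`.
#' @export
new_nonbonded <- function(types, mixing = c("geometric", "lorentz_berthelot"),
                          cutoff = 1.0, shift = TRUE, excl_depth = 2L,
                          fudge_lj = 1.0, fudge_qq = 1.0) {
  mixing <- match.arg(mixing)
  stopifnot(is.data.frame(types),
            all(c("type", "eps", "sigma") %in% names(types)),
            all(types$eps >= 0), all(types$sigma > 0), cutoff > 0)
  if (is.null(types$charge)) types$charge <- 0
  structure(list(types = types, mixing = mixing, cutoff = cutoff,
                 shift = isTRUE(shift), excl_depth = as.integer(excl_depth),
                 fudge_lj = fudge_lj, fudge_qq = fudge_qq),
            class = "cg_nonbonded")
}

#' @rdname new_nonbonded
#' @param path YAML file with fields `types` (list of type records),
#'   `mixing`, `cutoff`, `shift`, `excl_depth`, `fudge_lj`, `fudge_qq`.
#' @export
read_nonbonded <- function(path) {
  y <- yaml::read_yaml(path)
  types <- do.call(rbind, lapply(y$types, function(t)
    data.frame(type = t$type, eps = as.numeric(t$eps),
               sigma = as.numeric(t$sigma),
               charge = if (is.null(t$charge)) 0 else as.numeric(t$charge),
               stringsAsFactors = FALSE)))
  args <- list(types = types)
  for (f in c("mixing", "cutoff", "shift", "excl_depth", "fudge_lj",
              "fudge_qq"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(new_nonbonded, args)
}

#' Harmonic position restraints
#'
#' Adds \eqn{\frac{1}{2} k_{pr} \lVert r - r_{ref}\rVert^2} per restrained
#' particle to [evaluate_energy()] / [minimize()].
#'
#' @param reference Reference positions: a `cg_frame` or an n x 3 matrix
#'   (nm) matching the restrained selection.
#' @param k Force constant, kJ mol^-1 nm^-2.
#' @param indices Restrained atom indices (default: all reference rows,
#'   assumed to be the first atoms of the frame in order).
#' @return An object of class `"cg_restraints"`.
#' @export
position_restraints <- function(reference, k, indices = NULL) {
  ref <- if (inherits(reference, "cg_frame")) reference$xyz
         else as.matrix(reference)
  if (is.null(indices)) indices <- seq_len(nrow(ref))
  if (length(indices) != nrow(ref))
    stop("restrained selection (", length(indices),
         ") does not match reference count (", nrow(ref), ")")
  stopifnot(k >= 0)
  structure(list(ref = unname(ref), k = k, indices = as.integer(indices)),
            class = "cg_restraints")
}

## ------------------------------------------------------------------
## System assembly: replicate per-molecule bonded terms across all
## matching molecule instances; build nonbonded pair list + exclusions.

.build_system <- function(frame, topology, nonbonded = NULL) {
  a <- frame$atoms
  n <- natoms(frame)
  bonds <- angles <- dihedrals <- NULL
  for (mid in unique(a$molecule_id)) {
    sel <- which(a$molecule_id == mid)
    if (a$molecule_name[sel[1]] != topology$name) next
    if (length(sel) != nrow(topology$beads))
      stop("molecule id ", mid, " has ", length(sel),
           " particles; topology '", topology$name, "' declares ",
           nrow(topology$beads))
    off <- function(v) sel[v]
    tb <- topology$bonds
    if (nrow(tb)) bonds <- rbind(bonds, data.frame(
      i = off(tb$i), j = off(tb$j), b0 = tb$b0, kb = tb$kb))
    ta <- topology$angles
    if (nrow(ta)) angles <- rbind(angles, data.frame(
      i = off(ta$i), j = off(ta$j), k = off(ta$k), theta0 = ta$theta0,
      ktheta = ta$ktheta, form = ta$form, stringsAsFactors = FALSE))
    td <- topology$dihedrals
    if (nrow(td)) {
      td2 <- td
      td2$i <- off(td$i); td2$j <- off(td$j)
      td2$k <- off(td$k); td2$l <- off(td$l)
      dihedrals <- rbind(dihedrals, td2)
    }
  }
  sys <- list(bonds = bonds, angles = angles, dihedrals = dihedrals,
              n = n, box = frame$box, nb = NULL, restr = NULL)
  if (!is.null(nonbonded)) {
    typ <- if (!is.null(a$type)) a$type else a$name
    row <- match(typ, nonbonded$types$type)
    if (anyNA(row))
      stop("missing nonbonded parameters for type(s): ",
           paste(unique(typ[is.na(row)]), collapse = ", "))
    eps <- nonbonded$types$eps[row]
    sig <- nonbonded$types$sigma[row]
    q <- if (!is.null(a$charge)) a$charge else nonbonded$types$charge[row]
    ## bonded-graph distances for exclusions (within molecules only)
    dist <- .graph_depths(n, bonds, nonbonded$excl_depth + 1L)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    key <- (i - 1) * n + j
    dep <- dist[key]
    keep <- is.na(dep) | dep > nonbonded$excl_depth
    i <- i[keep]; j <- j[keep]; dep <- dep[keep]
    scale14 <- !is.na(dep) & dep == nonbonded$excl_depth + 1L
    epsij <- sqrt(eps[i] * eps[j])
    sigij <- if (nonbonded$mixing == "geometric") sqrt(sig[i] * sig[j])
             else (sig[i] + sig[j]) / 2
    sys$nb <- list(i = i, j = j, eps = epsij, sigma = sigij,
                   qq = q[i] * q[j] * cg_constants$f_coulomb,
                   flj = ifelse(scale14, nonbonded$fudge_lj, 1.0),
                   fqq = ifelse(scale14, nonbonded$fudge_qq, 1.0),
                   rc = nonbonded$cutoff, shift = nonbonded$shift)
  }
  sys
}

## Named vector of graph distances (1..maxd) for atom pairs connected
## through <= maxd bonds; index (i-1)*n + j with i < j.
.graph_depths <- function(n, bonds, maxd) {
  out <- rep(NA_integer_, n * n)
  if (is.null(bonds) || !nrow(bonds)) return(out)
  adj <- vector("list", n)
  for (q in seq_len(nrow(bonds))) {
    i <- bonds$i[q]; j <- bonds$j[q]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    depth <- rep(NA_integer_, n); depth[s] <- 0L
    frontier <- s
    for (d in seq_len(maxd)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(depth[nxt])]
      if (!length(nxt)) break
      depth[nxt] <- d
      frontier <- nxt
    }
    hit <- which(!is.na(depth) & depth > 0L & seq_len(n) > s)
    out[(s - 1) * n + hit] <- depth[hit]
  }
  out
}

## ------------------------------------------------------------------
## Energy + gradient of the full system at coordinates x (n x 3 matrix).
## Returns list(e = named components, g = gradient matrix).

.energy_gradient <- function(x, sys, restraints = NULL, gradient = TRUE) {
  n <- nrow(x)
  g <- if (gradient) matrix(0, n, 3) else NULL
  box <- sys$box
  e <- c(bond = 0, angle = 0, dihedral = 0, lj = 0, coulomb = 0,
         restraint = 0)

  b <- sys$bonds
  if (!is.null(b) && nrow(b)) {
    d <- .min_image(x[b$j, , drop = FALSE] - x[b$i, , drop = FALSE], box)
    r <- sqrt(rowSums(d^2))
    e[["bond"]] <- sum(0.5 * b$kb * (r - b$b0)^2)
    if (gradient) {
      coef <- b$kb * (r - b$b0) / r
      gd <- d * coef
      for (q in seq_len(nrow(b))) {
        g[b$i[q], ] <- g[b$i[q], ] - gd[q, ]
        g[b$j[q], ] <- g[b$j[q], ] + gd[q, ]
      }
    }
  }

  an <- sys$angles
  if (!is.null(an) && nrow(an)) {
    for (q in seq_len(nrow(an))) {
      i <- an$i[q]; j <- an$j[q]; k <- an$k[q]
      va <- .min_image(x[i, ] - x[j, ], box)
      vb <- .min_image(x[k, ] - x[j, ], box)
      na_ <- sqrt(sum(va^2)); nb_ <- sqrt(sum(vb^2))
      cth <- min(1, max(-1, sum(va * vb) / (na_ * nb_)))
      th <- acos(cth)
      th0 <- an$theta0[q] * pi / 180
      if (an$form[q] == "g96") {
        e[["angle"]] <- e[["angle"]] + 0.5 * an$ktheta[q] * (cth - cos(th0))^2
        dVdc <- an$ktheta[q] * (cth - cos(th0))
      } else {
        e[["angle"]] <- e[["angle"]] + 0.5 * an$ktheta[q] * (th - th0)^2
        sth <- max(sin(th), 1e-8)
        dVdc <- -an$ktheta[q] * (th - th0) / sth
      }
      if (gradient) {
        dca <- vb / (na_ * nb_) - cth * va / na_^2
        dcb <- va / (na_ * nb_) - cth * vb / nb_^2
        g[i, ] <- g[i, ] + dVdc * dca
        g[k, ] <- g[k, ] + dVdc * dcb
        g[j, ] <- g[j, ] - dVdc * (dca + dcb)
      }
    }
  }

  dh <- sys$dihedrals
  if (!is.null(dh) && nrow(dh)) {
    for (q in seq_len(nrow(dh))) {
      i <- dh$i[q]; j <- dh$j[q]; k <- dh$k[q]; l <- dh$l[q]
      b1 <- .min_image(x[j, ] - x[i, ], box)
      b2 <- .min_image(x[k, ] - x[j, ], box)
      b3 <- .min_image(x[l, ] - x[k, ], box)
      n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
      n1sq <- sum(n1^2); n2sq <- sum(n2^2)
      if (n1sq == 0 || n2sq == 0)
        stop("degenerate dihedral geometry (collinear beads)")
      nb2 <- sqrt(sum(b2^2))
      phi <- atan2(nb2 * sum(b1 * n2), sum(n1 * n2))
      if (dh$form[q] == "rb") {
        psi <- phi - pi
        cp <- cos(psi)
        Cs <- as.numeric(dh[q, paste0("C", 0:5)])
        e[["dihedral"]] <- e[["dihedral"]] + sum(Cs * cp^(0:5))
        dVdphi <- -sin(psi) * sum((1:5) * Cs[2:6] * cp^(0:4))
      } else {
        phi0 <- dh$phi0[q] * pi / 180
        m <- dh$mult[q]
        e[["dihedral"]] <- e[["dihedral"]] +
          dh$kphi[q] * (1 + cos(m * phi - phi0))
        dVdphi <- -dh$kphi[q] * m * sin(m * phi - phi0)
      }
      if (gradient) {
        dpdri <- -(nb2 / n1sq) * n1
        dpdrl <- (nb2 / n2sq) * n2
        p <- sum(b1 * b2) / nb2^2
        s <- sum(b3 * b2) / nb2^2
        dpdrj <- -(1 + p) * dpdri + s * dpdrl
        dpdrk <- p * dpdri - (1 + s) * dpdrl
        g[i, ] <- g[i, ] + dVdphi * dpdri
        g[j, ] <- g[j, ] + dVdphi * dpdrj
        g[k, ] <- g[k, ] + dVdphi * dpdrk
        g[l, ] <- g[l, ] + dVdphi * dpdrl
      }
    }
  }

  nb <- sys$nb
  if (!is.null(nb) && length(nb$i)) {
    d <- .min_image(x[nb$j, , drop = FALSE] - x[nb$i, , drop = FALSE], box)
    r2 <- rowSums(d^2)
    r <- sqrt(r2)
    inside <- r <= nb$rc & r > 0
    if (any(r == 0)) stop("overlapping particles (zero distance); ",
                          "jitter or pre-separate the input")
    if (any(inside)) {
      ii <- which(inside)
      sr6 <- (nb$sigma[ii] / r[ii])^6
      vlj <- 4 * nb$eps[ii] * (sr6^2 - sr6)
      vq <- nb$qq[ii] / r[ii]
      if (nb$shift) {
        src6 <- (nb$sigma[ii] / nb$rc)^6
        vlj <- vlj - 4 * nb$eps[ii] * (src6^2 - src6)
        vq <- vq - nb$qq[ii] / nb$rc
      }
      e[["lj"]] <- sum(nb$flj[ii] * vlj)
      e[["coulomb"]] <- sum(nb$fqq[ii] * vq)
      if (gradient) {
        ## dV/dr
        dvlj <- -24 * nb$eps[ii] * (2 * sr6^2 - sr6) / r[ii]
        dvq <- -nb$qq[ii] / r2[ii]
        coef <- (nb$flj[ii] * dvlj + nb$fqq[ii] * dvq) / r[ii]
        gd <- d[ii, , drop = FALSE] * coef
        for (w in seq_along(ii)) {
          q <- ii[w]
          g[nb$i[q], ] <- g[nb$i[q], ] - gd[w, ]
          g[nb$j[q], ] <- g[nb$j[q], ] + gd[w, ]
        }
      }
    }
  }

  if (!is.null(restraints)) {
    dr <- x[restraints$indices, , drop = FALSE] - restraints$ref
    e[["restraint"]] <- 0.5 * restraints$k * sum(dr^2)
    if (gradient)
      g[restraints$indices, ] <- g[restraints$indices, ] + restraints$k * dr
  }

  list(e = e, g = g)
}

#' Evaluate the potential energy of a configuration
#'
#' Computes the bonded terms declared by `topology` for every matching
#' molecule in `frame`, plus (when a [new_nonbonded()] table is supplied)
#' cutoff LJ and Coulomb interactions with optional potential shift so
#' V(r_c) = 0.  Pairs within `excl_depth` bonds are excluded; pairs one
#' bond beyond are scaled by the fudge factors.
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology` (its molecule name is matched against
#'   `frame$atoms$molecule_name`).
#' @param nonbonded Optional `cg_nonbonded` table; `NULL` = bonded terms
#'   only.
#' @param restraints Optional [position_restraints()] term.
#' @return Object of class `"energy_breakdown"`: named list with
#'   `bond`, `angle`, `dihedral`, `lj`, `coulomb`, `restraint`, `total`
#'   (kJ mol^-1).
#' @examples
#' top <- new_topology("DI", data.frame(name = c("B1", "B2"),
#'                     type = "P1", mass = 72, charge = 0),
#'                     bonds = data.frame(i = 1, j = 2, b0 = 0.47, kb = 1250))
#' f <- new_frame(data.frame(name = c("B1", "B2"), mass = 72,
#'                           molecule_name = "DI"),
#'                rbind(c(0, 0, 0), c(0.57, 0, 0)))
#' evaluate_energy(f, top)$bond  # 0.5 * 1250 * 0.1^2 = 6.25
#' @export
evaluate_energy <- function(frame, topology, nonbonded = NULL,
                            restraints = NULL) {
  sys <- .build_system(frame, topology, nonbonded)
  e <- .energy_gradient(frame$xyz, sys, restraints, gradient = FALSE)$e
  structure(c(as.list(e), list(total = sum(e))), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy (kJ/mol):",
      paste(sprintf("%s=%.4f", names(x), unlist(x)), collapse = "  "), "\n")
  invisible(x)
}

#' Forces on every particle
#'
#' Negative gradient of [evaluate_energy()]; mainly exposed for testing
#' and convergence reporting.
#'
#' @inheritParams evaluate_energy
#' @return n x 3 matrix of forces, kJ mol^-1 nm^-1.
#' @export
evaluate_forces <- function(frame, topology, nonbonded = NULL,
                            restraints = NULL) {
  sys <- .build_system(frame, topology, nonbonded)
  -.energy_gradient(frame$xyz, sys, restraints)$g
}

#' Steepest-descent minimizer settings
#'
#' @param fmax Convergence threshold on the maximum per-particle force,
#'   kJ mol^-1 nm^-1 (default 100, the conventional MD pre-equilibration
#'   target).
#' @param max_steps Maximum accepted+rejected step attempts.
#' @param step0 Initial displacement of the largest-force particle, nm.
#' @param grow,shrink Step-size multipliers after an accepted / rejected
#'   step.
#' @param min_step Abandon when the step size underflows this value.
#' @return List of class `"minimizer_settings"`.
#' @export
minimizer_settings <- function(fmax = 100, max_steps = 5000, step0 = 0.01,
                               grow = 1.2, shrink = 0.5, min_step = 1e-10) {
  stopifnot(fmax > 0, max_steps >= 1)
  structure(list(fmax = fmax, max_steps = max_steps, step0 = step0,
                 grow = grow, shrink = shrink, min_step = min_step),
            class = "minimizer_settings")
}

#' Energy minimization by adaptive steepest descent
#'
#' Moves particles along the force direction with an adaptive step
#' (accepted downhill steps grow the step size, uphill trials are
#' rejected and shrink it); terminates once the maximum per-particle
#' force drops below `fmax` or `max_steps` is reached.  Energies over
#' accepted steps are non-increasing by construction.
#'
#' @inheritParams evaluate_energy
#' @param settings A [minimizer_settings()] list.
#' @return List with `frame` (minimized), `energy` (final
#'   `energy_breakdown`), `converged`, `steps` (accepted steps), `fmax`
#'   (final max force), `trace` (accepted-step energies).
#' @export
minimize <- function(frame, topology, nonbonded = NULL, restraints = NULL,
                     settings = minimizer_settings()) {
  sys <- .build_system(frame, topology, nonbonded)
  x <- frame$xyz
  eg <- .energy_gradient(x, sys, restraints)
  if (!all(is.finite(eg$g)) || !all(is.finite(eg$e)))
    stop("non-finite initial energy/force (overlapping particles?); ",
         "jitter or pre-separate the input")
  E <- sum(eg$e)
  fmat <- -eg$g
  fnorm <- sqrt(rowSums(fmat^2))
  step <- settings$step0
  trace <- E
  accepted <- 0L
  attempts <- 0L
  while (max(fnorm) >= settings$fmax && attempts < settings$max_steps &&
         step > settings$min_step) {
    attempts <- attempts + 1L
    xt <- x + fmat * (step / max(fnorm))
    egt <- .energy_gradient(xt, sys, restraints)
    Et <- sum(egt$e)
    if (is.finite(Et) && Et < E) {
      x <- xt; E <- Et
      fmat <- -egt$g
      fnorm <- sqrt(rowSums(fmat^2))
      step <- step * settings$grow
      accepted <- accepted + 1L
      trace <- c(trace, E)
    } else {
      step <- step * settings$shrink
    }
  }
  out <- frame
  out$xyz <- x
  efin <- .energy_gradient(x, sys, restraints, gradient = FALSE)$e
  list(frame = out,
       energy = structure(c(as.list(efin), list(total = sum(efin))),
                          class = "energy_breakdown"),
       converged = max(fnorm) < settings$fmax,
       steps = accepted, fmax = max(fnorm), trace = trace)
}

#' Relative conformation energies over an ensemble
#'
#' Each conformer (one molecule per frame, identical topology) is centred
#' in the stated box, minimized in isolation with intramolecular terms
#' only, and its minimized potential energy U recorded.  Because the
#' potential energy is gauge dependent, the reported quantity is the
#' relative energy \eqn{\Delta U = U - U^{ref}} with \eqn{U^{ref} =
#' \min_j U_j}, which is invariant under any constant shift of the
#' per-term energies.
#'
#' @param conformers List of `cg_frame`s or a `cg_traj` (one conformer
#'   per frame).
#' @param topology,nonbonded,settings As in [minimize()].
#' @param box Optional cubic box edge (single number) or length-3 vector
#'   used to centre each conformer; `NULL` keeps each conformer's own
#'   placement.
#' @return `data.frame` of class `"conformer_energies"` with columns
#'   `molecule_id`, `U`, `dU`, `converged`, `steps`; minimized frames in
#'   `attr(, "frames")`.
#' @export
relative_conformation_energies <- function(conformers, topology,
                                           nonbonded = NULL,
                                           settings = minimizer_settings(),
                                           box = NULL) {
  if (inherits(conformers, "cg_traj")) conformers <- conformers$frames
  stopifnot(length(conformers) >= 1L)
  if (!is.null(box) && length(box) == 1L) box <- rep(box, 3)
  res <- vector("list", length(conformers))
  frames <- vector("list", length(conformers))
  for (q in seq_along(conformers)) {
    f <- conformers[[q]]
    if (!is.null(box)) {
      f$xyz <- f$xyz + matrix(box / 2 - center_of_mass(f),
                              natoms(f), 3, byrow = TRUE)
      f$box <- box
    }
    m <- minimize(f, topology, nonbonded, settings = settings)
    frames[[q]] <- m$frame
    res[[q]] <- data.frame(molecule_id = f$atoms$molecule_id[1],
                           U = m$energy$total, converged = m$converged,
                           steps = m$steps)
  }
  out <- do.call(rbind, res)
  out$dU <- out$U - min(out$U)
  out <- out[, c("molecule_id", "U", "dU", "converged", "steps")]
  attr(out, "frames") <- frames
  class(out) <- c("conformer_energies", class(out))
  out
}
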