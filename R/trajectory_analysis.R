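## Spatial and dynamic structure analyses over trajectories.

#' Partial (slab) density profile along a box axis
#'
#' Slices the box into `nbins` slabs perpendicular to `axis`, sums the
#' selected atoms' mass per slab, divides by the slab volume and averages
#' over frames.  The identity
#' `sum(value_i * slab_volume)` = frame-average selected mass holds
#' exactly.
#'
#' @param traj A `cg_traj`; every frame must carry a box.
#' @param selection Atom indices (default: all atoms).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param nbins Number of slabs.
#' @return `data.frame` of class `"profile1d"`: `r` (bin centres, nm),
#'   `value` (kg m^-3), with the axis and bin width in attributes.
#' @export
partial_density <- function(traj, selection = NULL, axis = c("x", "y", "z"),
                            nbins = 50) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  stopifnot(inherits(traj, "cg_traj"), nbins >= 1)
  if (is.null(selection)) selection <- seq_len(natoms(traj$frames[[1]]))
  acc <- numeric(nbins)
  L <- NULL
  for (f in traj$frames) {
    if (is.null(f$box)) stop("partial_density requires a box in every frame")
    L <- f$box
    w <- L[ax] / nbins
    pos <- f$xyz[selection, ax] %% L[ax]
    bin <- pmin(floor(pos / w) + 1L, nbins)
    slabvol <- w * prod(L[-ax])                       # nm^3
    dens <- tapply(f$atoms$mass[selection], factor(bin, levels = 1:nbins),
                   sum, default = 0) / slabvol        # amu / nm^3
    acc <- acc + as.numeric(dens)
  }
  acc <- acc / length(traj$frames) * cg_constants$amu_per_nm3_to_kg_m3
  out <- data.frame(r = (seq_len(nbins) - 0.5) * L[ax] / nbins, value = acc)
  attr(out, "axis") <- axis
  attr(out, "bin_width") <- L[ax] / nbins
  class(out) <- c("profile1d", class(out))
  out
}

#' Radial distribution function g(r)
#'
#' Standard pair-correlation function between two selections under the
#' minimum-image convention, normalized per frame by the spherical-shell
#' volume and the instantaneous partner density, so a uniform fluid gives
#' g(r) = 1.  Self-pairs are excluded where the selections overlap.
#'
#' @param traj A `cg_traj` with periodic boxes.
#' @param selection_a,selection_b Atom index vectors (defaults: all).
#' @param r_max Maximum distance, nm; must not exceed half the smallest
#'   box edge.
#' @param dr Bin width, nm.
#' @return `data.frame` of class `"profile1d"`: `r` (bin centres), `value`
#'   (g(r), unitless).
#' @export
rdf <- function(traj, selection_a = NULL, selection_b = NULL,
                r_max = NULL, dr = 0.02) {
  stopifnot(inherits(traj, "cg_traj"), dr > 0)
  n <- natoms(traj$frames[[1]])
  if (is.null(selection_a)) selection_a <- seq_len(n)
  if (is.null(selection_b)) selection_b <- seq_len(n)
  boxes <- lapply(traj$frames, `[[`, "box")
  if (any(vapply(boxes, is.null, TRUE)))
    stop("rdf requires a periodic box in every frame")
  halfmin <- min(vapply(boxes, min, 0)) / 2
  if (is.null(r_max)) r_max <- halfmin
  if (r_max > halfmin + 1e-9)
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge (",
         signif(halfmin, 6), " nm)")
  nbins <- ceiling(r_max / dr)
  gacc <- numeric(nbins)
  shellvol <- 4 / 3 * pi * ((dr * seq_len(nbins))^3 -
                            (dr * (seq_len(nbins) - 1))^3)
  for (f in traj$frames) {
    box <- f$box
    xa <- f$xyz[selection_a, , drop = FALSE]
    xb <- f$xyz[selection_b, , drop = FALSE]
    cnt <- numeric(nbins)
    for (ia in seq_along(selection_a)) {
      d <- .min_image(sweep(xb, 2, xa[ia, ], "-"), box)
      r <- sqrt(rowSums(d^2))
      r <- r[selection_b != selection_a[ia]]       # drop self pairs
      r <- r[r < r_max]
      if (length(r))
        cnt <- cnt + tabulate(pmin(floor(r / dr) + 1L, nbins), nbins)
    }
    V <- prod(box)
    rho_b <- length(selection_b) / V
    gacc <- gacc + cnt / (length(selection_a) * rho_b * shellvol)
  }
  out <- data.frame(r = (seq_len(nbins) - 0.5) * dr,
                    value = gacc / length(traj$frames))
  attr(out, "dr") <- dr
  class(out) <- c("profile1d", class(out))
  out
}

## Unwrap periodic coordinates: per particle, accumulate minimum-image
## displacements between consecutive frames so tracks are continuous.
.unwrap_positions <- function(traj, selection) {
  nf <- length(traj$frames)
  prev <- traj$frames[[1]]$xyz[selection, , drop = FALSE]
  out <- vector("list", nf)
  out[[1]] <- prev
  cur <- prev
  for (q in 2:nf) {
    nxt <- traj$frames[[q]]$xyz[selection, , drop = FALSE]
    step <- .min_image(nxt - prev, traj$frames[[q]]$box)
    cur <- cur + step
    out[[q]] <- cur
    prev <- nxt
  }
  out
}

#' Mean-square displacement and windowed diffusion fits
#'
#' Computes MSD(tau) averaged over the selected particles and all time
#' origins inside each analysis window, after unwrapping coordinates
#' across periodic boundaries.  A least-squares line is fitted through
#' MSD(tau) per window; the diffusion constant is the slope
#' (`convention = "raw_slope"`, the literal `D*t + c` fit) or slope/6
#' (`"einstein_3d"`, the 3-D Einstein relation).
#'
#' @param traj A `cg_traj` with uniform time spacing.
#' @param selection Atom indices (default: all).
#' @param window_ns Window length in ns (default: the whole trajectory,
#'   one window).
#' @param convention `"einstein_3d"` (default) or `"raw_slope"`.
#' @return List with `msd` (`profile1d`: tau in ns vs nm^2, computed over
#'   the first window length of lags using all origins) and `fits`
#'   (`data.frame`: `t_start`, `t_end` ns, `slope` nm^2/ns, `intercept`,
#'   `D_cm2_s`, `r_squared`).
#' @export
msd_diffusion <- function(traj, selection = NULL, window_ns = NULL,
                          convention = c("einstein_3d", "raw_slope")) {
  convention <- match.arg(convention)
  stopifnot(inherits(traj, "cg_traj"))
  nf <- length(traj$frames)
  if (nf < 3L) stop("need at least 3 frames")
  if (is.null(selection)) selection <- seq_len(natoms(traj$frames[[1]]))
  tt <- traj$times
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt))
    stop("msd_diffusion requires uniform frame spacing")
  dt <- dt[1]
  total <- tt[nf] - tt[1]
  if (is.null(window_ns)) window_ns <- total
  if (window_ns > total + 1e-9)
    stop("window (", window_ns, " ns) longer than trajectory (",
         total, " ns)")
  wlen <- max(2L, round(window_ns / dt))      # frames per window lag span
  un <- .unwrap_positions(traj, selection)

  msd_over <- function(frames_idx, nlag) {
    m <- numeric(nlag + 1L)
    cnt <- integer(nlag + 1L)
    for (lag in 0:nlag) {
      orig <- frames_idx[seq_len(length(frames_idx) - lag)]
      if (!length(orig)) next
      s <- 0
      for (o in orig)
        s <- s + mean(rowSums((un[[o + lag]] - un[[o]])^2))
      m[lag + 1L] <- s / length(orig)
      cnt[lag + 1L] <- length(orig)
    }
    m
  }

  ## global MSD curve over the first window span of lags, all origins
  nlag <- min(wlen, nf - 1L)
  mall <- msd_over(seq_len(nf), nlag)
  msd <- data.frame(r = (0:nlag) * dt, value = mall)
  class(msd) <- c("profile1d", class(msd))

  starts <- seq(1L, max(1L, nf - wlen), by = wlen)
  fits <- do.call(rbind, lapply(starts, function(s) {
    e <- min(nf, s + wlen)
    idx <- s:e
    nl <- length(idx) - 1L
    m <- msd_over(idx, nl)
    tau <- (0:nl) * dt
    fit <- stats::lm.fit(cbind(1, tau), m)
    slope <- fit$coefficients[2]
    ssr <- sum(fit$residuals^2)
    sst <- sum((m - mean(m))^2)
    data.frame(t_start = tt[s], t_end = tt[e], slope = slope,
               intercept = fit$coefficients[1],
               D_cm2_s = slope * cg_constants$nm2_ns_to_cm2_s /
                 (if (convention == "einstein_3d") 6 else 1),
               r_squared = if (sst > 0) 1 - ssr / sst else 1)
  }))
  rownames(fits) <- NULL
  list(msd = msd, fits = fits, convention = convention)
}

#' Aggregate volume and expansion arithmetic
#'
#' `aggregate_volume()` estimates the volume occupied by an aggregate as
#' the equilibrium ternary-system box volume minus the equilibrium
#' binary-system (aggregate removed) box volume.  `aggregate_expansion()`
#' is the difference between that MD-derived aggregate volume and the
#' ideal molar volume of the same number of molecules, i.e. the swelling
#' of the aggregate relative to the neat liquid.
#'
#' @param v_ternary_nm3,v_binary_nm3 Equilibrium box volumes, nm^3.
#' @param v_aggregate_nm3 Aggregate volume from MD, nm^3.
#' @param v_molar_nm3 Ideal molar volume of the aggregate's molecules,
#'   nm^3 (see [molar_volume()]).
#' @return Volume in nm^3.
#' @examples
#' aggregate_expansion(856.155, 765.447)  # 90.708
#' @export
aggregate_expansion <- function(v_aggregate_nm3, v_molar_nm3) {
  stopifnot(v_aggregate_nm3 >= 0, v_molar_nm3 >= 0)
  v_aggregate_nm3 - v_molar_nm3
}

#' @rdname aggregate_expansion
#' @export
aggregate_volume <- function(v_ternary_nm3, v_binary_nm3) {
  stopifnot(v_ternary_nm3 >= 0, v_binary_nm3 >= 0)
  v_ternary_nm3 - v_binary_nm3
}
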