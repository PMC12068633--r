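## Shape descriptors and ensemble statistics for conformers.

#' Ring centroid distances and conformation radius
#'
#' Reports the distances between mass-weighted centroids of labelled
#' rings (e.g. the two side-chain phenyl rings and the terminus ring of
#' paclitaxel) and the conformation radius R_C, i.e. the per-molecule
#' mass-weighted radius of gyration about the molecule's centre of mass.
#' All outputs in Angstrom, the customary unit for intramolecular
#' distances.
#'
#' @param frame A `cg_frame`.
#' @param molecule_id Molecule to analyse (default: first present).
#' @param rings Named list of character vectors: ring label (e.g. `"1"`,
#'   `"2"`, `"3"`) to member atom/bead names, each with >= 3 members.
#' @param weighting `"mass"` (default) or `"geometric"` centroids.
#' @return `data.frame` with one row: `molecule_id`, one `L<ij>` column
#'   (Angstrom) per ring pair, and `RC` (Angstrom).
#' @export
shape_descriptors <- function(frame, rings,
                              molecule_id = frame$atoms$molecule_id[1],
                              weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  sel <- which(frame$atoms$molecule_id == molecule_id)
  if (!length(sel)) stop("molecule id ", molecule_id, " not present")
  cent <- lapply(names(rings), function(lab) {
    mem <- rings[[lab]]
    if (length(mem) < 3L) stop("ring '", lab, "' has fewer than 3 members")
    idx <- sel[match(mem, frame$atoms$name[sel])]
    if (anyNA(idx))
      stop("ring '", lab, "': member(s) ",
           paste(mem[is.na(idx)], collapse = ", "), " not found")
    w <- if (weighting == "mass") frame$atoms$mass[idx]
         else rep(1, length(idx))
    drop(crossprod(frame$xyz[idx, , drop = FALSE], w)) / sum(w)
  })
  names(cent) <- names(rings)
  out <- data.frame(molecule_id = molecule_id)
  labs <- names(rings)
  if (length(labs) >= 2) {
    for (a in seq_len(length(labs) - 1)) for (b in (a + 1):length(labs)) {
      out[[paste0("L", labs[a], labs[b])]] <-
        sqrt(sum((cent[[a]] - cent[[b]])^2)) * 10  # nm -> Angstrom
    }
  }
  out$RC <- radius_of_gyration(frame, sel) * 10
  out
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i \lVert r_i - c\rVert^2 / \sum_i m_i}} over a
#' group of particles.  The centre `c` is either the plain group centre
#' of mass or, for aggregates of many molecules, the mean of the
#' per-molecule centres of mass (each molecule contributing equally to
#' the group centre), reproducing the grouped-aggregate convention.
#'
#' @param frame A `cg_frame`.
#' @param group Atom indices (default: all atoms).
#' @param center_mode `"group_com"` or `"mean_of_molecule_coms"`.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, group = seq_len(natoms(frame)),
                               center_mode = c("group_com",
                                               "mean_of_molecule_coms")) {
  center_mode <- match.arg(center_mode)
  if (!length(group)) stop("empty group")
  m <- frame$atoms$mass[group]
  x <- frame$xyz[group, , drop = FALSE]
  cen <- if (center_mode == "group_com") {
    drop(crossprod(x, m)) / sum(m)
  } else {
    mids <- unique(frame$atoms$molecule_id[group])
    coms <- vapply(mids, function(mid)
      center_of_mass(frame, group[frame$atoms$molecule_id[group] == mid]),
      numeric(3))
    rowMeans(coms)
  }
  dx <- sweep(x, 2, cen)
  sqrt(sum(m * rowSums(dx^2)) / sum(m))
}

#' Summary statistics and frequency histogram of an ensemble of values
#'
#' Returns mean, median (mean of the middle two for even n), population
#' standard deviation (divisor n), and a frequency histogram over
#' half-open bins `[origin + k*width, origin + (k+1)*width)`.
#'
#' @param values Numeric vector, n >= 1.
#' @param bin_width Histogram bin width (default 10, suited to relative
#'   conformation energies in kJ mol^-1).
#' @param bin_origin Left edge of the first bin (default 0).
#' @return List of class `"ensemble_stats"`: `n`, `mean`, `median`, `sd`
#'   (population), `breaks`, `counts`.
#' @examples
#' s <- ensemble_statistics(c(1, 2, 3, 4), bin_width = 2)
#' s$mean; s$sd
#' @export
ensemble_statistics <- function(values, bin_width = 10, bin_origin = 0) {
  stopifnot(length(values) >= 1L, bin_width > 0, all(is.finite(values)))
  mu <- mean(values)
  sdev <- sqrt(mean((values - mu)^2))
  lo <- floor((min(values) - bin_origin) / bin_width)
  hi <- floor((max(values) - bin_origin) / bin_width)
  breaks <- bin_origin + (lo:(hi + 1)) * bin_width
  idx <- floor((values - bin_origin) / bin_width) - lo + 1
  counts <- tabulate(idx, nbins = hi - lo + 1)
  structure(list(n = length(values), mean = mu,
                 median = stats::median(values), sd = sdev,
                 breaks = breaks, counts = counts),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.4f  median = %.4f  sd(pop) = %.4f\n",
              x$n, x$mean, x$median, x$sd))
  invisible(x)
}

#' Pearson and Spearman correlation coefficients
#'
#' Product-moment correlation plus rank correlation with midranks for
#' ties, as used to track the co-evolution of structural observables
#' (e.g. RMSD time series of different species).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Named numeric vector `c(pearson = , spearman = )`.
#' @export
correlations <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  c(pearson = stats::cor(x, y, method = "pearson"),
    spearman = stats::cor(x, y, method = "spearman"))
}

#' Root-mean-square deviation between two frames
#'
#' \eqn{\sqrt{\mathrm{mean}_i \lVert r^a_i - r^b_i \rVert^2}} over a
#' selection, optionally after removing the centre-of-mass offset.  No
#' rotational superposition is performed: the intended use is tracking
#' configurational drift against a fixed reference in one box.
#'
#' @param frame_a,frame_b Frames with matching selections.
#' @param selection Atom indices (default: all).
#' @param remove_com Subtract each selection's centre of mass first.
#' @return RMSD in nm.
#' @export
rmsd <- function(frame_a, frame_b, selection = seq_len(natoms(frame_a)),
                 remove_com = FALSE) {
  if (length(selection) && (max(selection) > natoms(frame_a) ||
                            max(selection) > natoms(frame_b)))
    stop("selection length mismatch between frames")
  xa <- frame_a$xyz[selection, , drop = FALSE]
  xb <- frame_b$xyz[selection, , drop = FALSE]
  if (remove_com) {
    ma <- frame_a$atoms$mass[selection]; mb <- frame_b$atoms$mass[selection]
    xa <- sweep(xa, 2, drop(crossprod(xa, ma)) / sum(ma))
    xb <- sweep(xb, 2, drop(crossprod(xb, mb)) / sum(mb))
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}
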