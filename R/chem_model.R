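## Core structural containers: frame (single configuration) and
## trajectory (ordered frames with times).  Units: nm, amu, ns.

#' Construct a molecular frame
#'
#' A frame is the package's basic structural container: a table of atom
#' (or bead) identities plus an n x 3 coordinate matrix in nm and an
#' optional orthorhombic box.
#'
#' @param atoms `data.frame` with columns `name` (character), `mass` (amu),
#'   and optionally `element`, `molecule_id` (integer), `molecule_name`.
#'   Missing optional columns are filled (single molecule "MOL", element
#'   guessed from the atom name).
#' @param xyz Numeric matrix, `nrow(atoms)` rows and 3 columns, positions
#'   in nm.
#' @param box Optional numeric length-3 vector of orthorhombic box edge
#'   lengths in nm, or `NULL`.
#' @param masses Mass lookup used when `atoms$mass` is absent; see
#'   [mass_table()].
#' @return An object of class `"cg_frame"`.
#' @examples
#' f <- new_frame(data.frame(name = c("C1", "O1")),
#'                rbind(c(0, 0, 0), c(0.15, 0, 0)))
#' natoms(f)
#' @export
new_frame <- function(atoms, xyz, box = NULL, masses = mass_table()) {
  stopifnot(is.data.frame(atoms), "name" %in% names(atoms))
  atoms$name <- as.character(atoms$name)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (is.null(dim(xyz)) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix")
  if (nrow(xyz) != nrow(atoms))
    stop("positions count (", nrow(xyz), ") != atom count (", nrow(atoms), ")")
  if (is.null(atoms$element))
    atoms$element <- .guess_element(atoms$name, masses)
  if (is.null(atoms$mass)) {
    if (anyNA(atoms$element))
      stop("unknown element for atom(s) ",
           paste(unique(atoms$name[is.na(atoms$element)]), collapse = ", "),
           "; supply atoms$mass or a mass override")
    atoms$mass <- unname(masses[atoms$element])
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be finite and > 0")
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- 1L
  if (is.null(atoms$molecule_name)) atoms$molecule_name <- "MOL"
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive orthorhombic edge lengths (nm)")
  }
  structure(list(atoms = atoms, xyz = unname(xyz), box = box),
            class = "cg_frame")
}

#' @rdname new_frame
#' @param x A `cg_frame`.
#' @export
natoms <- function(x) nrow(x$atoms)

#' @export
print.cg_frame <- function(x, ...) {
  cat("cg_frame:", natoms(x), "atoms,",
      length(unique(x$atoms$molecule_id)), "molecule(s)")
  if (!is.null(x$box))
    cat(", box", paste(sprintf("%.3f", x$box), collapse = " x "), "nm")
  cat("\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames List of [new_frame()] objects with a constant atom count.
#' @param times Numeric vector of frame times in ns, strictly increasing.
#'   Defaults to `0, stride, 2*stride, ...`.
#' @param stride Frame spacing in ns used when `times` is missing.
#' @return An object of class `"cg_traj"`.
#' @export
new_trajectory <- function(frames, times = NULL, stride = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- vapply(frames, natoms, integer(1))
  if (length(unique(n)) != 1L)
    stop("frame ", which(n != n[1])[1], " has ", n[n != n[1]][1],
         " atoms; expected ", n[1], " (constant atom count required)")
  if (is.null(times)) times <- (seq_along(frames) - 1) * stride
  times <- as.numeric(times)
  if (length(times) != length(frames))
    stop("times length != number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = times), class = "cg_traj")
}

#' @export
print.cg_traj <- function(x, ...) {
  cat("cg_traj:", length(x$frames), "frames,", natoms(x$frames[[1]]),
      "atoms, t =", x$times[1], "..", x$times[length(x$times)], "ns\n")
  invisible(x)
}

#' @export
length.cg_traj <- function(x) length(x$frames)

#' Mass-weighted centre of mass
#'
#' Computes \eqn{\sum m_i r_i / \sum m_i} over a selection of atoms.
#'
#' @param frame A `cg_frame`.
#' @param atom_indices Integer indices of the atoms to include (1-based);
#'   defaults to all atoms.
#' @return Numeric length-3 position in nm.
#' @examples
#' f <- new_frame(data.frame(name = c("C", "C"), mass = c(12, 12)),
#'                rbind(c(0, 0, 0), c(0, 0, 1)))
#' center_of_mass(f)  # (0, 0, 0.5)
#' @export
center_of_mass <- function(frame, atom_indices = seq_len(natoms(frame))) {
  if (length(atom_indices) == 0L) stop("empty selection")
  m <- frame$atoms$mass[atom_indices]
  drop(crossprod(frame$xyz[atom_indices, , drop = FALSE], m)) / sum(m)
}

## --------------------------------------------------------------------
## GRO format (fixed width, nm):
##   title / natoms / "%5d%-5s%5s%5d%8.3f%8.3f%8.3f" / box line

.parse_gro_frame <- function(lines, offset, masses, path) {
  nat <- suppressWarnings(as.integer(trimws(lines[offset + 1L])))
  if (is.na(nat) || nat < 1L)
    stop("GRO parse error at line ", offset + 1L, " of ", path,
         ": invalid atom count '", trimws(lines[offset + 1L]), "'")
  need <- offset + 2L + nat
  if (length(lines) < need)
    stop("GRO parse error in ", path, ": truncated frame starting line ",
         offset)
  al <- lines[offset + 1L + seq_len(nat)]
  bad <- which(nchar(al) < 44)
  if (length(bad))
    stop("GRO parse error at line ", offset + 1L + bad[1], " of ", path,
         ": record shorter than fixed-width 44 characters")
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  atname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("GRO parse error at line ",
         offset + 1L + which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1],
         " of ", path, ": non-numeric field")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[need]), "\\s+")[[1]]))
  if (anyNA(boxv) || !(length(boxv) %in% c(3L, 9L)))
    stop("GRO parse error at line ", need, " of ", path, ": bad box line")
  if (length(boxv) == 9L) {
    if (any(boxv[4:9] != 0))
      stop("triclinic box in ", path, " not supported (orthorhombic only)")
    boxv <- boxv[1:3]
  }
  box <- if (all(boxv > 0)) boxv else NULL
  atoms <- data.frame(name = atname, molecule_id = resid,
                      molecule_name = resname, stringsAsFactors = FALSE)
  list(frame = new_frame(atoms, cbind(x, y, z), box, masses),
       next_offset = need + 1L,
       title = lines[offset])
}

#' Read a structure file (GRO or PDB)
#'
#' Positions are returned in nm: GRO files are already in nm, PDB
#' coordinates are converted from Angstrom.  Molecule ids come from the
#' residue numbering of the file.
#'
#' @param path Path to the file.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @param masses Mass lookup, see [mass_table()].  Elements are inferred
#'   from atom names; an unknown element is an error unless its mass is
#'   supplied here.
#' @return A `cg_frame`.
#' @seealso [write_structure()], [read_trajectory()]
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"),
                           masses = mass_table()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gro") {
    .parse_gro_frame(lines, 1L, masses, path)$frame
  } else {
    rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
    if (!length(rec)) stop("no ATOM/HETATM records in ", path)
    atname <- trimws(substr(rec, 13, 16))
    resname <- trimws(substr(rec, 18, 20))
    resid <- as.integer(substr(rec, 23, 26))
    x <- as.numeric(substr(rec, 31, 38))
    y <- as.numeric(substr(rec, 39, 46))
    z <- as.numeric(substr(rec, 47, 54))
    if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid))
      stop("PDB parse error in ", path, " at record ",
           which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))[1])
    elcol <- trimws(substr(rec, 77, 78))
    atoms <- data.frame(name = atname, molecule_id = resid,
                        molecule_name = resname, stringsAsFactors = FALSE)
    if (any(nzchar(elcol))) {
      el <- ifelse(nzchar(elcol),
                   paste0(toupper(substr(elcol, 1, 1)),
                          tolower(substr(elcol, 2, 2))),
                   NA_character_)
      guess <- .guess_element(atname, masses)
      atoms$element <- ifelse(is.na(el), guess, el)
      if (anyNA(atoms$element) || !all(atoms$element %in% names(masses)))
        stop("unknown element in ", path, ": ",
             paste(unique(atoms$element[!(atoms$element %in% names(masses))]),
                   collapse = ", "))
    }
    ## PDB is the package's only Angstrom boundary
    new_frame(atoms, cbind(x, y, z) / 10, box = NULL, masses = masses)
  }
}

#' Write a structure file (GRO or PDB)
#'
#' @param frame A `cg_frame`.
#' @param path Output path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, format = c("auto", "gro", "pdb"),
                            title = "written by cgconform") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  a <- frame$atoms
  n <- natoms(frame)
  if (format == "gro") {
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    a$molecule_id %% 100000L, substr(a$molecule_name, 1, 5),
                    substr(a$name, 1, 5), seq_len(n) %% 100000L,
                    frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3])
    box <- if (is.null(frame$box)) c(0, 0, 0) else frame$box
    writeLines(c(title, sprintf("%5d", n), body,
                 sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  } else {
    el <- if (!is.null(a$element)) a$element else .guess_element(a$name)
    body <- sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                    seq_len(n) %% 100000L, substr(a$name, 1, 4),
                    substr(a$molecule_name, 1, 3), a$molecule_id %% 10000L,
                    frame$xyz[, 1] * 10, frame$xyz[, 2] * 10,
                    frame$xyz[, 3] * 10, toupper(el))
    writeLines(c(paste("REMARK   ", title), body, "END"), path)
  }
  invisible(path)
}

## --------------------------------------------------------------------
## Multi-frame formats.  XYZ dialect used here is bead-name + x y z in nm
## (internal convention; GRO is the interchange format), with comment
## lines carrying "t= <ns>".

#' Read a multi-frame trajectory (XYZ or GRO)
#'
#' The XYZ dialect stores coordinates in nm with a `t= <ns>` stamp on the
#' comment line.  Frame times are taken from those stamps when present on
#' every frame, otherwise from `stride`.
#'
#' @param path Path to the file.
#' @param format `"xyz"` or `"gro"`; default guessed from the extension.
#' @param stride Frame spacing in ns used when the file carries no times.
#' @param masses,template For XYZ, atom masses are resolved from bead/atom
#'   names via `masses` unless a template `cg_frame` with matching atom
#'   count supplies the identities.
#' @return A `cg_traj`.
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "gro"),
                            stride = 1, masses = mass_table(),
                            template = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); off <- 1L
  if (format == "gro") {
    while (off <= length(lines) && nzchar(trimws(lines[off]))) {
      p <- .parse_gro_frame(lines, off, masses, path)
      frames[[length(frames) + 1L]] <- p$frame
      times <- c(times, .time_from_comment(p$title))
      off <- p$next_offset
    }
  } else {
    while (off <= length(lines) && nzchar(trimws(lines[off]))) {
      nat <- suppressWarnings(as.integer(trimws(lines[off])))
      if (is.na(nat) || nat < 1L)
        stop("XYZ parse error at line ", off, " of ", path)
      if (length(lines) < off + 1L + nat)
        stop("XYZ parse error in ", path, ": truncated frame at line ", off)
      al <- strsplit(trimws(lines[off + 1L + seq_len(nat)]), "\\s+")
      if (any(lengths(al) < 4L))
        stop("XYZ parse error at line ",
             off + 1L + which(lengths(al) < 4L)[1], " of ", path)
      nm <- vapply(al, `[[`, "", 1L)
      xyz <- t(vapply(al, function(v) as.numeric(v[2:4]), numeric(3)))
      if (anyNA(xyz))
        stop("XYZ parse error in ", path, ": non-numeric coordinate near line ",
             off + 2L)
      fr <- if (!is.null(template) && natoms(template) == nat) {
        new_frame(template$atoms, xyz, template$box, masses)
      } else {
        new_frame(data.frame(name = nm, stringsAsFactors = FALSE), xyz,
                  masses = masses)
      }
      frames[[length(frames) + 1L]] <- fr
      times <- c(times, .time_from_comment(lines[off + 1L]))
      off <- off + 2L + nat
    }
  }
  if (!length(frames)) stop("no frames found in ", path)
  nat <- vapply(frames, natoms, integer(1))
  if (length(unique(nat)) != 1L)
    stop("frame ", which(nat != nat[1])[1], " of ", path,
         " has a deviating atom count")
  if (anyNA(times)) times <- NULL
  new_trajectory(frames, times = times, stride = stride)
}

.time_from_comment <- function(line) {
  m <- regmatches(line, regexpr("t\\s*=\\s*[-0-9.eE+]+", line))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("t\\s*=\\s*", "", m))
}

#' Write a multi-frame XYZ trajectory (nm units, t= stamps)
#'
#' @param traj A `cg_traj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c(sprintf("%d", natoms(f)),
                 sprintf("frame %d t= %.6f", i, traj$times[i]),
                 sprintf("%-6s %12.6f %12.6f %12.6f", f$atoms$name,
                         f$xyz[, 1], f$xyz[, 2], f$xyz[, 3])), con)
  }
  invisible(path)
}

## Minimum-image displacement(s) r2 - r1 under an orthorhombic box.
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}
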