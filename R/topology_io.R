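## GROMACS ITP dialect for derived CG topologies.
## Function tags follow the GROMACS convention: bonds 1 = harmonic;
## angles 1 = harmonic, 2 = G96 cosine-based; dihedrals 1 = periodic
## proper, 3 = Ryckaert-Bellemans.

#' Write a CG topology as a GROMACS-style ITP file
#'
#' Emits `[moleculetype]`, `[atoms]`, `[bonds]`, `[angles]` and
#' `[dihedrals]` sections.  Angle and dihedral functional forms are
#' distinguished by the standard integer tags (harmonic angle 1, G96
#' angle 2; periodic dihedral 1, Ryckaert-Bellemans 3).
#'
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_topology()]
#' @export
write_topology <- function(topology, path) {
  t <- topology
  ln <- c("; generated by cgconform",
          "[ moleculetype ]",
          "; name  nrexcl",
          sprintf("%s  3", t$name),
          "",
          "[ atoms ]",
          "; nr type resnr residue atom cgnr charge mass")
  b <- t$beads
  ln <- c(ln, sprintf("%5d %6s %5d %6s %6s %5d %10.4f %12.6g",
                      seq_len(nrow(b)), b$type, 1L, t$name, b$name,
                      seq_len(nrow(b)), b$charge,
                      ifelse(is.na(b$mass), 72, b$mass)))
  if (nrow(t$bonds)) {
    ln <- c(ln, "", "[ bonds ]", ";  i   j funct    b0(nm)      kb")
    ln <- c(ln, sprintf("%4d %4d %2d %10.6g %12.6g",
                        t$bonds$i, t$bonds$j, 1L, t$bonds$b0, t$bonds$kb))
  }
  if (nrow(t$angles)) {
    ln <- c(ln, "", "[ angles ]", ";  i   j   k funct theta0(deg)  ktheta")
    fn <- ifelse(t$angles$form == "g96", 2L, 1L)
    ln <- c(ln, sprintf("%4d %4d %4d %2d %10.6g %12.6g",
                        t$angles$i, t$angles$j, t$angles$k, fn,
                        t$angles$theta0, t$angles$ktheta))
  }
  if (nrow(t$dihedrals)) {
    ln <- c(ln, "", "[ dihedrals ]",
            ";  i   j   k   l funct  params")
    d <- t$dihedrals
    for (q in seq_len(nrow(d))) {
      ln <- c(ln, if (d$form[q] == "rb")
        sprintf("%4d %4d %4d %4d %2d %s", d$i[q], d$j[q], d$k[q], d$l[q], 3L,
                paste(sprintf("%.6g", unlist(d[q, paste0("C", 0:5)])),
                      collapse = " "))
      else
        sprintf("%4d %4d %4d %4d %2d %10.6g %12.6g %3d",
                d$i[q], d$j[q], d$k[q], d$l[q], 1L, d$phi0[q], d$kphi[q],
                d$mult[q]))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a CG topology from an ITP file written by [write_topology()]
#'
#' @param path Path to the ITP file.
#' @return A `cg_topology`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- ""
  name <- NULL
  beads <- list(); bonds <- list(); angles <- list(); dihedrals <- list()
  for (l in lines) {
    if (grepl("^\\[", l)) {
      sec <- tolower(gsub("[][ ]", "", l)); next
    }
    f <- strsplit(l, "\\s+")[[1]]
    if (sec == "moleculetype") {
      name <- f[1]
    } else if (sec == "atoms") {
      beads[[length(beads) + 1L]] <- data.frame(
        name = f[5], type = f[2], mass = as.numeric(f[8]),
        charge = as.numeric(f[7]), stringsAsFactors = FALSE)
    } else if (sec == "bonds") {
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        b0 = as.numeric(f[4]), kb = as.numeric(f[5]))
    } else if (sec == "angles") {
      angles[[length(angles) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        theta0 = as.numeric(f[5]), ktheta = as.numeric(f[6]),
        form = if (as.integer(f[4]) == 2L) "g96" else "harmonic",
        stringsAsFactors = FALSE)
    } else if (sec == "dihedrals") {
      fn <- as.integer(f[5])
      dihedrals[[length(dihedrals) + 1L]] <- if (fn == 3L) data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        l = as.integer(f[4]), form = "rb", phi0 = NA_real_, kphi = NA_real_,
        mult = NA_integer_, C0 = as.numeric(f[6]), C1 = as.numeric(f[7]),
        C2 = as.numeric(f[8]), C3 = as.numeric(f[9]), C4 = as.numeric(f[10]),
        C5 = as.numeric(f[11]), stringsAsFactors = FALSE)
      else data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        l = as.integer(f[4]), form = "periodic", phi0 = as.numeric(f[6]),
        kphi = as.numeric(f[7]), mult = as.integer(f[8]), C0 = NA_real_,
        C1 = NA_real_, C2 = NA_real_, C3 = NA_real_, C4 = NA_real_,
        C5 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (is.null(name)) stop("no [moleculetype] section in ", path)
  new_topology(name, do.call(rbind, beads),
               if (length(bonds)) do.call(rbind, bonds) else data.frame(),
               if (length(angles)) do.call(rbind, angles) else data.frame(),
               if (length(dihedrals)) do.call(rbind, dihedrals)
               else data.frame())
}
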