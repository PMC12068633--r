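## Physical constants (GROMACS unit system: nm, amu, kJ/mol, e, ns)

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ mol^-1 K^-1.}
#'   \item{N_A}{Avogadro constant, mol^-1.}
#'   \item{f_coulomb}{Electric conversion factor \eqn{1/(4\pi\epsilon_0)},
#'     kJ mol^-1 nm e^-2.}
#'   \item{amu_per_nm3_to_kg_m3}{Density conversion: 1 amu nm^-3 in kg m^-3.}
#'   \item{nm2_ns_to_cm2_s}{Diffusion conversion: 1 nm^2 ns^-1 in cm^2 s^-1.}
#' }
#' @export
cg_constants <- list(
  kB                   = 0.0083144621,
  N_A                  = 6.02214076e23,
  f_coulomb            = 138.935458,
  amu_per_nm3_to_kg_m3 = 1.66053907,
  nm2_ns_to_cm2_s      = 1e-5
)

## IUPAC 2021 standard atomic weights, 5 significant figures.
.default_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ar = 39.95, Ca = 40.078,
  Fe = 55.845, Zn = 65.38, Br = 79.904, I = 126.90
)

#' Table of atomic masses
#'
#' Returns the built-in element-to-mass lookup (IUPAC standard atomic
#' weights, amu), optionally extended or overridden.
#'
#' @param overrides Named numeric vector of element masses that extend or
#'   replace the defaults (e.g. `c(D = 2.014)`).
#' @return Named numeric vector, element symbol to mass in amu.
#' @examples
#' mass_table()[["C"]]
#' mass_table(c(X = 72))[["X"]]
#' @export
mass_table <- function(overrides = NULL) {
  m <- .default_masses
  if (length(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)),
              all(overrides > 0))
    m[names(overrides)] <- overrides
  }
  m
}

## Infer an element symbol from an atom name ("CA1" -> "C", "Cl2" -> "Cl").
## GRO files carry no element column; convention: leading alphabetic
## characters, two-letter symbols honoured only when typed in title case
## (so "CA" is a carbon, "Ca" a calcium).
.guess_element <- function(name, masses = mass_table()) {
  lead <- sub("^([A-Za-z]+).*$", "\\1", name)
  out <- character(length(name))
  for (i in seq_along(name)) {
    s <- lead[i]
    two <- if (nchar(s) >= 2) substr(s, 1, 2) else ""
    one <- toupper(substr(s, 1, 1))
    if (nchar(two) == 2 && grepl("^[A-Z][a-z]$", two) && two %in% names(masses))
      out[i] <- two
    else if (one %in% names(masses))
      out[i] <- one
    else
      out[i] <- NA_character_
  }
  out
}
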