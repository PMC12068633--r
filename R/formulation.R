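## Formulation arithmetic: molecular weights, mole counts, molar and
## sphere volumes.

#' Molecular weight from a chemical formula
#'
#' @param formula Either a formula string such as `"C47H51NO14"` or a
#'   named integer vector/list of element counts.
#' @param masses Mass lookup, see [mass_table()].
#' @return Molecular weight in g mol^-1.
#' @examples
#' molecular_weight("H2O")        # 18.015
#' molecular_weight("C47H51NO14") # paclitaxel, ~853.9
#' @export
molecular_weight <- function(formula, masses = mass_table()) {
  counts <- if (is.character(formula)) .parse_formula(formula) else
    stats::setNames(as.numeric(formula), names(formula))
  if (any(counts < 1)) stop("element counts must be >= 1")
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(counts * masses[names(counts)])
}

.parse_formula <- function(s) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
  parts <- regmatches(s, m)[[1]]
  if (!length(parts) || sum(attr(m[[1]], "match.length")) != nchar(s))
    stop("cannot parse formula: ", s)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(ifelse(grepl("[0-9]$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)
}

#' Formulation component
#'
#' One chemical component of a recipe, specified by a formula and either
#' a mass or a volume plus density.
#'
#' @param name Component name.
#' @param formula Formula string or named count vector.
#' @param mass_g Mass in grams (exclusive with `volume_ml`).
#' @param volume_ml,density_g_cm3 Volumetric amount: millilitres and
#'   g cm^-3.
#' @return List of class `"component_spec"`.
#' @export
component_spec <- function(name, formula, mass_g = NULL, volume_ml = NULL,
                           density_g_cm3 = NULL) {
  if (is.null(mass_g) == is.null(volume_ml))
    stop("specify exactly one of mass_g or volume_ml for '", name, "'")
  if (!is.null(volume_ml)) {
    if (is.null(density_g_cm3) || density_g_cm3 <= 0)
      stop("volumetric amount for '", name,
           "' needs a positive density_g_cm3")
    mass_g <- volume_ml * density_g_cm3
  }
  if (mass_g < 0) stop("negative mass for '", name, "'")
  structure(list(name = name, formula = formula, mass_g = mass_g),
            class = "component_spec")
}

#' Convert a recipe to moles and molecule counts
#'
#' For each component: mass (from volume x density when volumetric),
#' moles = mass / MW, molecule count = moles x N_A.  Reported moles are
#' additionally rounded to the nearest `rounding` mol (default 1e-6,
#' micro-mole presentation); raw values are always retained.
#'
#' @param components List of [component_spec()] objects.
#' @param rounding Mole-rounding quantum (default 1e-6 mol); `NA`
#'   disables rounding.
#' @param masses Mass lookup.
#' @return `data.frame`: `name`, `MW_g_mol`, `mass_g`, `moles`,
#'   `moles_rounded`, `molecules`.
#' @examples
#' ptx <- component_spec("PTX", "C47H51NO14", mass_g = 0.006)
#' composition_to_moles(list(ptx))$moles_rounded  # 7e-06
#' @export
composition_to_moles <- function(components, rounding = 1e-6,
                                 masses = mass_table()) {
  stopifnot(length(components) >= 1L)
  do.call(rbind, lapply(components, function(cs) {
    stopifnot(inherits(cs, "component_spec"))
    mw <- molecular_weight(cs$formula, masses)
    mol <- cs$mass_g / mw
    data.frame(name = cs$name, MW_g_mol = mw, mass_g = cs$mass_g,
               moles = mol,
               moles_rounded = if (is.na(rounding)) mol
                               else round(mol / rounding) * rounding,
               molecules = mol * cg_constants$N_A,
               stringsAsFactors = FALSE)
  }))
}

#' Ideal molar volume of n molecules
#'
#' \eqn{V = n \cdot MW / (N_A \rho)}, converted to nm^3: the volume the
#' molecules would occupy as a neat liquid of the stated density.
#'
#' @param n_molecules Number of molecules.
#' @param formula Formula string or named count vector.
#' @param density_g_cm3 Liquid density, g cm^-3.
#' @param masses Mass lookup.
#' @return Volume in nm^3.
#' @examples
#' molar_volume(200, "C126H242O45", 1.05)  # ~783.5 nm^3
#' @export
molar_volume <- function(n_molecules, formula, density_g_cm3,
                         masses = mass_table()) {
  stopifnot(density_g_cm3 > 0, n_molecules >= 0)
  mw <- molecular_weight(formula, masses)
  ## g/mol / (1/mol * g/cm^3) = cm^3; 1 cm^3 = 1e21 nm^3
  n_molecules * mw / (cg_constants$N_A * density_g_cm3) * 1e21
}

#' Sphere volume
#'
#' \eqn{(4/3)\pi R^3}; used e.g. to convert an experimentally measured
#' micelle radius into a volume for comparison with simulated aggregate
#' volumes.
#'
#' @param radius_nm Radius in nm, >= 0.
#' @return Volume in nm^3.
#' @examples
#' sphere_volume(6.5)  # ~1150
#' @export
sphere_volume <- function(radius_nm) {
  stopifnot(radius_nm >= 0)
  4 / 3 * pi * radius_nm^3
}
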