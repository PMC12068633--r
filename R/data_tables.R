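## Bundled reference tables (plain CSV under inst/extdata).

#' Bundled per-conformer table for the 32 drug molecules
#'
#' Relative conformation energies (kJ mol^-1) and shape descriptors
#' (ring-centroid distances L12/L13 and conformation radius R_C, in
#' Angstrom) for 32 paclitaxel conformers extracted from the
#' high-concentration Taxol micelle, in both all-atom (`model == "AA"`)
#' and coarse-grained (`model == "CG"`) representations.  Used as a
#' regression fixture for the statistics engine and as example input for
#' the descriptor-table workflow.
#'
#' @param path CSV path; defaults to the copy installed with the package.
#' @return `data.frame` with columns `molecule`, `model`, `dU_kJmol`,
#'   `L12_A`, `L13_A`, `RC_A`.
#' @export
ptx_conformer_table <- function(path = system.file("extdata",
                                                   "ptx_conformers.csv",
                                                   package = "cgconform")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled surfactant-aggregation volumes and radii
#'
#' Equilibrium aggregate volumes (nm^3) and radii of gyration (nm) of the
#' 200-molecule surfactant aggregate in the standard- (`SC`) and
#' high-concentration (`HC`) micelle systems, with and without a
#' surrounding water bath, at three late simulation times.
#'
#' @param path CSV path; defaults to the installed copy.
#' @return `data.frame` with columns `system`, `t_ns`, `V_nm3`, `Rg_nm`,
#'   `Rg_in_water_nm`.
#' @export
crel_aggregation_table <- function(path = system.file("extdata",
                                                      "crel_aggregation.csv",
                                                      package = "cgconform")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
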