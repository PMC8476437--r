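#' Conversion constants for cell- and ATP-based biomass carbon
#'
#' Bundles the two conversion factors used throughout the biomass accounting:
#' the organic carbon content of a single cell and the number of cells per
#' gram of ATP. The ATP conversion depends strongly on how biomass is
#' detached from the medium before measurement, so named scenarios are
#' provided via [atp_scenarios()].
#'
#' @param carbon_per_cell Carbon content of one cell, gTOC/cell. Default
#'   `2e-14`, a standard assumption for heterotrophic cells in drinking-water
#'   biofilters.
#' @param cells_per_gATP Cells per gram of ATP. Default `1.1e14`
#'   (sonication-detached biomass, the main case).
#' @return An object of class `conversion_constants`.
#' @seealso [atp_scenarios()], [qe_scenarios()]
#' @export
#' @examples
#' conversion_constants()
#' conversion_constants(cells_per_gATP = atp_scenarios()[["shaking"]])
conversion_constants <- function(carbon_per_cell = 2e-14,
                                 cells_per_gATP = 1.1e14) {
  stopifnot(is.numeric(carbon_per_cell), length(carbon_per_cell) == 1L,
            is.finite(carbon_per_cell), carbon_per_cell > 0,
            is.numeric(cells_per_gATP), length(cells_per_gATP) == 1L,
            is.finite(cells_per_gATP), cells_per_gATP > 0)
  structure(list(carbon_per_cell = carbon_per_cell,
                 cells_per_gATP = cells_per_gATP),
            class = "conversion_constants")
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat("Conversion constants:\n")
  cat(sprintf("  carbon per cell : %.3g gTOC/cell\n", x$carbon_per_cell))
  cat(sprintf("  cells per g ATP : %.3g cells/gATP\n", x$cells_per_gATP))
  invisible(x)
}

#' Named ATP-to-cell conversion scenarios
#'
#' Cells-per-gram-ATP values for the three detachment/quantification
#' scenarios used in the mass-balance sensitivity analysis: biomass detached
#' by sonication (main case), biomass detached by manual shaking, and a
#' literature value determined for a drinking-water BAC filter.
#'
#' @return Named numeric vector (cells/gATP).
#' @export
#' @examples
#' atp_scenarios()
atp_scenarios <- function() {
  c(sonication = 1.1e14, shaking = 4.8e13, literature = 3e15)
}

#' Named equilibrium-loading (q_e) scenarios
#'
#' Equilibrium sorption loadings (mgTOC/gGAC) spanning the assumptions about
#' how much of the TOC removed in the top filter segment before sorption
#' equilibrium was reached is attributable to adsorption: the main case
#' (65 % sorption / 35 % biodegradation until equilibrium), the upper bound
#' (all removal by sorption) and the lower bound (medium already exhausted
#' before the high-concentration influent peak).
#'
#' @return Named numeric vector (mgTOC/gGAC).
#' @export
#' @examples
#' qe_scenarios()
qe_scenarios <- function() {
  c(base = 25.6, all_sorption = 31.5, exhausted_before_peak = 14.7)
}
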