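#' Estimate the equilibrium sorption loading q_e
#'
#' Integral mass-balance estimate of the equilibrium loading from the TOC
#' load removed in the top filter segment up to the day equilibrium is
#' reached (after the desorption phase that follows a high-concentration
#' influent peak), under an assumed split of that early removal between
#' sorption and biodegradation:
#' `q_e = sorbed_fraction * removed_g / segment_gac_kg` (mgTOC/gGAC, with
#' the removed load in g and the segment GAC mass in kg).
#'
#' @param removed_g TOC load removed in the top segment over the
#'   equilibration window, g.
#' @param sorbed_fraction Fraction of that removal attributed to sorption
#'   (in `[0, 1]`; the main case assumes 0.65).
#' @param segment_gac_kg GAC mass in the top segment, kg (> 0).
#' @return q_e, mgTOC/gGAC.
#' @export
#' @examples
#' estimate_qe(78.77, 0.65, 2.0)  # 25.6 mg/g
estimate_qe <- function(removed_g, sorbed_fraction, segment_gac_kg) {
  if (segment_gac_kg <= 0) stop("segment GAC mass must be positive")
  stopifnot(sorbed_fraction >= 0, sorbed_fraction <= 1)
  sorbed_fraction * removed_g / segment_gac_kg
}

#' TOC mass sorbed at equilibrium loading
#'
#' @param qe Equilibrium loading, mgTOC/gGAC.
#' @param gac_mass_kg GAC mass carrying that loading, kg.
#' @return Sorbed TOC, g (mg/g x kg = g).
#' @export
#' @examples
#' sorbed_mass(25.6, 20)  # 512 g
sorbed_mass <- function(qe, gac_mass_kg) {
  stopifnot(qe >= 0, gac_mass_kg >= 0)
  qe * gac_mass_kg
}

#' Biomass carbon accumulated in the filter from the ATP inventory
#'
#' @param atp_g Total ATP inventory on the GAC, g.
#' @param const [conversion_constants()].
#' @return Accumulated biomass carbon, g.
#' @export
#' @examples
#' biomass_accumulated(0.0686)  # 0.151 g with the sonication conversion
biomass_accumulated <- function(atp_g, const = conversion_constants()) {
  stopifnot(atp_g >= 0)
  atp_g * const$cells_per_gATP * const$carbon_per_cell
}

#' Biomass carbon washed out with the treated water
#'
#' The excess of effluent over influent cell concentration, times the treated
#' volume and the carbon content per cell. A negative difference (fewer cells
#' leaving than entering) is reported as a negative load with a warning,
#' never clipped.
#'
#' @param tcc_in,tcc_out Mean influent / effluent TCC, cells/mL.
#' @param volume_L Treated volume, L.
#' @param const [conversion_constants()].
#' @return Washed-out biomass carbon, g.
#' @export
#' @examples
#' biomass_washedout(3.3e5, 8.6e5, 330 * 912)  # 3.19 g
biomass_washedout <- function(tcc_in, tcc_out, volume_L,
                              const = conversion_constants()) {
  stopifnot(volume_L >= 0)
  out <- (tcc_out - tcc_in) * 1000 * volume_L * const$carbon_per_cell
  if (out < 0)
    warning("effluent TCC below influent TCC: negative washed-out load reported")
  out
}

#' Biomass carbon removed by a backwash event
#'
#' Sum over the minute-resolved backwash samples of TCC x flow x 1 min,
#' converted to carbon. Background (tap-water) cells can be subtracted.
#'
#' @param record A `backwash_record` (or data.frame with `tcc_cells_mL`).
#' @param flow_L_min Backwash flow; defaults to the record's attribute.
#' @param const [conversion_constants()].
#' @param subtract_background Subtract the record's tap-water background TCC
#'   if available.
#' @return Backwashed biomass carbon, g.
#' @export
biomass_backwash <- function(record, flow_L_min = NULL,
                             const = conversion_constants(),
                             subtract_background = TRUE) {
  if (is.null(flow_L_min)) flow_L_min <- attr(record, "flow_L_min")
  if (is.null(flow_L_min) || flow_L_min <= 0)
    stop("backwash flow must be positive")
  if (nrow(record) < 1) stop("backwash record has no samples")
  tcc <- record$tcc_cells_mL
  bg <- attr(record, "background_tcc")
  if (subtract_background && !is.null(bg)) tcc <- pmax(0, tcc - bg)
  sum(tcc) * flow_L_min * 1000 * const$carbon_per_cell
}

#' Partition removed TOC into its fates (the carbon mass balance)
#'
#' Applies the three balance identities: biodegraded = removed - sorbed;
#' CO2 = biodegraded - assimilated; assimilated = accumulated + washed out +
#' backwashed. The identities hold exactly on the result. If the sorption
#' scenario exceeds the removed load, the biodegraded (and CO2) loads are
#' negative and the result carries a prominent `infeasible` flag; nothing is
#' clipped.
#'
#' @param removed_g Removed TOC, g (>= 0).
#' @param sorbed_g Sorbed TOC, g.
#' @param accumulated_g,washedout_g,backwash_g Assimilated-biomass carbon
#'   components, g.
#' @return Object of class `mass_balance` with the five loads, the three
#'   assimilation components and derived fractions (full precision; use
#'   [fractions_pct()] or `print()` for the rounded report).
#' @export
#' @examples
#' mass_balance(1024, 512, 0.151, 3.19, 0.02)
mass_balance <- function(removed_g, sorbed_g, accumulated_g = 0,
                         washedout_g = 0, backwash_g = 0) {
  stopifnot(removed_g >= 0)
  biodeg <- removed_g - sorbed_g
  assim <- accumulated_g + washedout_g + backwash_g
  co2 <- biodeg - assim
  structure(list(
    removed_g = removed_g, sorbed_g = sorbed_g, biodegraded_g = biodeg,
    co2_g = co2, assimilated_g = assim,
    accumulated_g = accumulated_g, washedout_g = washedout_g,
    backwash_g = backwash_g,
    sorption_share = sorbed_g / removed_g,
    biodeg_share = biodeg / removed_g,
    assimilated_share_of_biodeg = if (biodeg != 0) assim / biodeg else NA_real_,
    co2_share_of_biodeg = if (biodeg != 0) co2 / biodeg else NA_real_,
    accumulated_share_of_assim = if (assim > 0) accumulated_g / assim else NA_real_,
    washedout_share_of_assim = if (assim > 0) washedout_g / assim else NA_real_,
    backwash_share_of_assim = if (assim > 0) backwash_g / assim else NA_real_,
    infeasible = biodeg < 0), class = "mass_balance")
}

#' Report fractions of a mass balance rounded to whole percent
#'
#' @param x A [mass_balance()].
#' @param digits Decimal places of the percent values (default 0, matching
#'   report tables).
#' @return Named numeric vector of percentages.
#' @export
fractions_pct <- function(x, digits = 0) {
  stopifnot(inherits(x, "mass_balance"))
  round(100 * c(sorption_of_removed = x$sorption_share,
                biodegradation_of_removed = x$biodeg_share,
                assimilated_of_biodegraded = x$assimilated_share_of_biodeg,
                co2_of_biodegraded = x$co2_share_of_biodeg,
                accumulated_of_assimilated = x$accumulated_share_of_assim,
                washedout_of_assimilated = x$washedout_share_of_assim,
                backwash_of_assimilated = x$backwash_share_of_assim),
        digits)
}

#' @export
print.mass_balance <- function(x, ...) {
  cat("TOC mass balance (g):\n")
  cat(sprintf("  removed %.4g = sorbed %.4g + biodegraded %.4g\n",
              x$removed_g, x$sorbed_g, x$biodegraded_g))
  cat(sprintf("  biodegraded %.4g = CO2 %.4g + assimilated %.4g\n",
              x$biodegraded_g, x$co2_g, x$assimilated_g))
  cat(sprintf("  assimilated %.4g = accumulated %.4g + washed out %.4g + backwash %.4g\n",
              x$assimilated_g, x$accumulated_g, x$washedout_g, x$backwash_g))
  f <- fractions_pct(x)
  cat(sprintf("  shares: sorption %.0f%%, biodegradation %.0f%%; of biodegraded: assimilated %.0f%%, CO2 %.0f%%\n",
              f[1], f[2], f[3], f[4]))
  cat(sprintf("  of assimilated: accumulated %.0f%%, washed out %.0f%%, backwash %.0f%%\n",
              f[5], f[6], f[7]))
  if (x$infeasible)
    cat("  ** INFEASIBLE: sorption scenario exceeds removed load (negative biodegradation) **\n")
  invisible(x)
}

#' Scenario sweep over the mass-balance assumptions
#'
#' Recomputes the mass balance over every combination of: equilibrium
#' loading q_e, ATP-to-cell conversion, effluent TCC source (measured cell
#' counts vs the turbidity-derived estimate) and treated-volume method
#' (integrated 1-minute flow vs mean daily flow x days).
#'
#' @param removed_g Whole-filter removed TOC, g.
#' @param gac_mass_kg Total GAC mass, kg.
#' @param atp_g ATP inventory, g.
#' @param tcc_in Mean influent TCC, cells/mL.
#' @param tcc_out_measured,tcc_out_turbidity Effluent TCC estimates, cells/mL.
#' @param volume_integrated_L,volume_meanflow_L Treated volumes, L.
#' @param backwash_cells Total cells removed by the backwash.
#' @param qe Named vector of q_e scenarios (mg/g).
#' @param cells_per_gATP Named vector of ATP conversion scenarios.
#' @param effluent_tcc_source Subset of `c("measured", "turbidity")`.
#' @param volume_method Subset of `c("integrated", "meanflow")`.
#' @param carbon_per_cell gTOC/cell.
#' @return data.frame with one row per scenario combination: the scenario
#'   axes, all loads (g) and the report fractions in percent. Attribute
#'   `balances` holds the full [mass_balance()] objects.
#' @export
scenario_sweep <- function(removed_g, gac_mass_kg, atp_g,
                           tcc_in, tcc_out_measured, tcc_out_turbidity,
                           volume_integrated_L, volume_meanflow_L = NULL,
                           backwash_cells,
                           qe = qe_scenarios(),
                           cells_per_gATP = atp_scenarios(),
                           effluent_tcc_source = c("measured", "turbidity"),
                           volume_method = "integrated",
                           carbon_per_cell = 2e-14) {
  if (length(qe) == 0 || length(cells_per_gATP) == 0 ||
      length(effluent_tcc_source) == 0 || length(volume_method) == 0)
    stop("every scenario axis needs at least one value")
  effluent_tcc_source <- match.arg(effluent_tcc_source,
                                   c("measured", "turbidity"), several.ok = TRUE)
  volume_method <- match.arg(volume_method, c("integrated", "meanflow"),
                             several.ok = TRUE)
  if ("meanflow" %in% volume_method && is.null(volume_meanflow_L))
    stop("volume_meanflow_L required for the meanflow method")
  if (is.null(names(qe))) names(qe) <- paste0("qe", seq_along(qe))
  grid <- expand.grid(qe = names(qe), atp = names(cells_per_gATP),
                      tcc_source = effluent_tcc_source,
                      volume = volume_method,
                      stringsAsFactors = FALSE)
  balances <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    const <- conversion_constants(carbon_per_cell, cells_per_gATP[[g$atp]])
    vol <- if (g$volume == "integrated") volume_integrated_L else volume_meanflow_L
    tcc_out <- if (g$tcc_source == "measured") tcc_out_measured else tcc_out_turbidity
    mb <- mass_balance(
      removed_g,
      sorbed_mass(qe[[g$qe]], gac_mass_kg),
      biomass_accumulated(atp_g, const),
      biomass_washedout(tcc_in, tcc_out, vol, const),
      backwash_cells * carbon_per_cell)
    balances[[i]] <<- mb
    data.frame(g, qe_mg_g = qe[[g$qe]],
               removed_g = mb$removed_g, sorbed_g = mb$sorbed_g,
               biodegraded_g = mb$biodegraded_g, co2_g = mb$co2_g,
               assimilated_g = mb$assimilated_g,
               infeasible = mb$infeasible,
               t(fractions_pct(mb)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "balances") <- balances
  out
}
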