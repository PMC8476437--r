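#' Geometry and medium inventory of a fixed-bed BAC filter
#'
#' Describes the column: inner diameter, bed depth, depths of the
#' intermediate sampling ports (measured from the top of the bed), total
#' granular activated carbon (GAC) mass and bed porosity. Segment boundaries
#' are the bed top, the ports and the bed bottom; GAC mass is allocated to
#' segments proportionally to segment depth.
#'
#' @param inner_diameter Column inner diameter, m.
#' @param bed_depth Bed depth, m.
#' @param port_depths Port depths from bed top, m, strictly increasing and
#'   inside `(0, bed_depth)`.
#' @param gac_mass Total GAC mass, kg.
#' @param bed_porosity Bed porosity (water-filled fraction of bed volume).
#' @return Object of class `filter_spec` with derived fields:
#'   `area_m2`, `bed_volume_L` (empty-bed), `segment_bounds_m`,
#'   `segment_gac_kg`, `segment_water_L`.
#' @export
#' @examples
#' filter_spec()  # 0.3 m diameter, 0.52 m bed, ports at 7/22/37 cm, 20 kg GAC
filter_spec <- function(inner_diameter = 0.3, bed_depth = 0.52,
                        port_depths = c(0.07, 0.22, 0.37),
                        gac_mass = 20, bed_porosity = 0.4) {
  stopifnot(is.numeric(inner_diameter), length(inner_diameter) == 1L,
            is.finite(inner_diameter), inner_diameter > 0,
            is.numeric(bed_depth), is.finite(bed_depth), bed_depth > 0,
            is.numeric(gac_mass), is.finite(gac_mass), gac_mass > 0,
            is.numeric(bed_porosity), is.finite(bed_porosity),
            bed_porosity > 0, bed_porosity < 1,
            is.numeric(port_depths), length(port_depths) >= 1L,
            all(is.finite(port_depths)))
  if (any(port_depths <= 0) || any(port_depths >= bed_depth))
    stop("port depths must lie strictly inside (0, bed_depth)")
  if (is.unsorted(port_depths, strictly = TRUE))
    stop("port depths must be strictly increasing")
  area <- pi * (inner_diameter / 2)^2
  bounds <- c(0, port_depths, bed_depth)
  seg_len <- diff(bounds)
  structure(list(
    inner_diameter = inner_diameter,
    bed_depth = bed_depth,
    port_depths = port_depths,
    gac_mass = gac_mass,
    bed_porosity = bed_porosity,
    area_m2 = area,
    bed_volume_L = area * bed_depth * 1000,
    segment_bounds_m = bounds,
    segment_gac_kg = gac_mass * seg_len / bed_depth,
    segment_water_L = bed_porosity * area * seg_len * 1000
  ), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("BAC filter: d = %.2f m, bed %.2f m, %.1f kg GAC, porosity %.2f\n",
              x$inner_diameter, x$bed_depth, x$gac_mass, x$bed_porosity))
  cat(sprintf("  empty-bed volume %.1f L, ports at %s cm\n",
              x$bed_volume_L, paste(round(x$port_depths * 100), collapse = "/")))
  invisible(x)
}

#' Kinetic parameters of the mechanistic column model
#'
#' Parameters of the tanks-in-series column used by [simulate_column()].
#' Sorption follows a linear-driving-force law, `dq/dt = k_sorb (q*(C) - q)`
#' with a Langmuir-shaped equilibrium `q*(C) = q_max C / (c_half + C)`; the
#' reverse (desorption) branch uses the same rate constant, which reproduces
#' the desorption transient after a high-concentration influent peak.
#' Biodegradation acts only on a labile fraction of the influent TOC,
#' first-order in concentration and proportional to local attached biomass.
#' A fraction `yield_Y` of biodegraded carbon is assimilated into biomass,
#' of which `detach_fraction` detaches continuously and leaves with the
#' treated water; the rest accumulates as biofilm. The top cell stands in
#' for the Schmutzdecke and starts with elevated biomass.
#'
#' @param q_max Sorption capacity, mgTOC/gGAC.
#' @param k_sorb Linear-driving-force rate constant, 1/h.
#' @param c_half Half-saturation concentration of the sorption equilibrium,
#'   mg/L.
#' @param labile_fraction Fraction of influent TOC that is biodegradable.
#' @param k_bio Biodegradation rate, L/(gC h): first-order rate per unit
#'   attached biomass carbon per unit cell water volume.
#' @param yield_Y gTOC assimilated per gTOC biodegraded.
#' @param detach_fraction Fraction of produced biomass that detaches
#'   continuously and is washed out.
#' @param n_cells Number of well-mixed cells in series; must be a multiple of
#'   the number of bed segments (ports + 1) so that every port coincides with
#'   a cell interface, and at least ports + 1.
#' @param x0_total Initial attached biomass carbon in the column, g C.
#' @param x0_length_scale Depth scale of the initial biomass profile, m
#'   (biomass decays as `exp(-z / scale)`).
#' @param schmutzdecke_boost Multiplier on the top cell's initial biomass.
#' @return Object of class `column_kinetics`.
#' @export
column_kinetics <- function(q_max = 30, k_sorb = 3, c_half = 1,
                            labile_fraction = 0.6, k_bio = 110,
                            yield_Y = 0.01, detach_fraction = 0.94,
                            n_cells = 8, x0_total = 0.12,
                            x0_length_scale = 0.08, schmutzdecke_boost = 5) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  stopifnot(num1(q_max), q_max >= 0, num1(k_sorb), k_sorb >= 0,
            num1(c_half), c_half > 0, num1(k_bio), k_bio >= 0,
            num1(labile_fraction), labile_fraction >= 0, labile_fraction <= 1,
            num1(yield_Y), yield_Y >= 0, yield_Y <= 1,
            num1(detach_fraction), detach_fraction >= 0, detach_fraction <= 1,
            num1(x0_total), x0_total >= 0,
            num1(x0_length_scale), x0_length_scale > 0,
            num1(schmutzdecke_boost), schmutzdecke_boost > 0,
            num1(n_cells), n_cells == round(n_cells))
  structure(list(q_max = q_max, k_sorb = k_sorb, c_half = c_half,
                 labile_fraction = labile_fraction, k_bio = k_bio,
                 yield_Y = yield_Y, detach_fraction = detach_fraction,
                 n_cells = as.integer(n_cells), x0_total = x0_total,
                 x0_length_scale = x0_length_scale,
                 schmutzdecke_boost = schmutzdecke_boost),
            class = "column_kinetics")
}

#' @export
print.column_kinetics <- function(x, ...) {
  cat(sprintf("Column kinetics: q_max %.1f mg/g, k_sorb %.2g 1/h, c_half %.2g mg/L\n",
              x$q_max, x$k_sorb, x$c_half))
  cat(sprintf("  labile %.2f, k_bio %.2g L/(gC h), Y %.3f, detach %.2f, %d cells, X0 %.3f gC\n",
              x$labile_fraction, x$k_bio, x$yield_Y, x$detach_fraction,
              x$n_cells, x$x0_total))
  invisible(x)
}

#' Stochastic description of intermittent filter operation
#'
#' Describes the operating regime the synthetic generator emulates:
#' intermittent gravity-driven flow arriving in a few bursts per day, a
#' lognormal influent TOC, an optional extreme influent peak and an optional
#' single backwash event.
#'
#' @param duration_days Length of the operating record, days.
#' @param mean_daily_volume Long-run mean treated volume, L/d.
#' @param max_daily_volume Maximum treated volume on any day, L/d.
#' @param bursts_per_day Mean number of flow bursts per day (the per-day
#'   count is `1 + Poisson(bursts_per_day - 1)`).
#' @param flow_fraction_range Range of the fraction of each day with flow;
#'   together with the daily volume this sets the in-burst flow rate.
#' @param influent_toc_log_mean,influent_toc_log_sd Lognormal parameters of
#'   the influent TOC (mg/L); defaults give median 4.8 mg/L with a central
#'   range of roughly 1.9-19 mg/L.
#' @param peak_day Day index of an extreme influent peak, or `NA` for none.
#' @param peak_concentration Peak influent TOC, mg/L.
#' @param backwash_day Day index of the single backwash event, or `NA`.
#' @param seed Integer seed; mandatory so that every generated record is
#'   reproducible.
#' @return Object of class `operation_pattern`.
#' @export
#' @examples
#' operation_pattern(duration_days = 30, seed = 1)
operation_pattern <- function(duration_days = 912, mean_daily_volume = 330,
                              max_daily_volume = 1155, bursts_per_day = 3,
                              flow_fraction_range = c(0.3, 0.7),
                              influent_toc_log_mean = log(4.8),
                              influent_toc_log_sd = 0.5,
                              peak_day = 67, peak_concentration = 131,
                              backwash_day = 836, seed) {
  if (missing(seed) || is.null(seed))
    stop("operation_pattern(): 'seed' is mandatory")
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(duration_days) || duration_days <= 0)
    stop("duration_days must be a positive number (empty series otherwise)")
  if (!num1(mean_daily_volume) || mean_daily_volume < 0 ||
      !num1(max_daily_volume) || max_daily_volume < 0 ||
      !num1(influent_toc_log_mean) || !num1(influent_toc_log_sd) ||
      influent_toc_log_sd < 0 || !num1(bursts_per_day) || bursts_per_day < 1)
    stop("non-finite or out-of-range operation pattern parameter")
  if (mean_daily_volume > max_daily_volume)
    stop("mean_daily_volume must not exceed max_daily_volume")
  stopifnot(length(flow_fraction_range) == 2L,
            all(flow_fraction_range > 0), all(flow_fraction_range <= 1),
            flow_fraction_range[1] <= flow_fraction_range[2])
  chk_day <- function(d, nm) {
    if (!is.na(d) && (d < 0 || d > duration_days))
      stop(sprintf("%s must lie within [0, duration_days]", nm))
  }
  peak_day <- if (is.null(peak_day)) NA_real_ else peak_day
  backwash_day <- if (is.null(backwash_day)) NA_real_ else backwash_day
  chk_day(peak_day, "peak_day"); chk_day(backwash_day, "backwash_day")
  structure(list(duration_days = as.integer(duration_days),
                 mean_daily_volume = mean_daily_volume,
                 max_daily_volume = max_daily_volume,
                 bursts_per_day = bursts_per_day,
                 flow_fraction_range = flow_fraction_range,
                 influent_toc_log_mean = influent_toc_log_mean,
                 influent_toc_log_sd = influent_toc_log_sd,
                 peak_day = peak_day, peak_concentration = peak_concentration,
                 backwash_day = backwash_day, seed = as.integer(seed)),
            class = "operation_pattern")
}

#' @export
print.operation_pattern <- function(x, ...) {
  cat(sprintf("Operation pattern: %d d, %.0f L/d mean (max %.0f), seed %d\n",
              x$duration_days, x$mean_daily_volume, x$max_daily_volume, x$seed))
  cat(sprintf("  influent TOC lognormal(median %.2g mg/L, sdlog %.2g); peak day %s; backwash day %s\n",
              exp(x$influent_toc_log_mean), x$influent_toc_log_sd,
              ifelse(is.na(x$peak_day), "none", x$peak_day),
              ifelse(is.na(x$backwash_day), "none", x$backwash_day)))
  invisible(x)
}

# shared clock origin for all generated series
.sim_origin <- function() as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
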