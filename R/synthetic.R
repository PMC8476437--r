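#' Generate an intermittent-flow operating record
#'
#' Draws a 1-minute flow series and a matching influent TOC series from an
#' [operation_pattern()]. Each day's treated volume is gamma-distributed
#' (shape 2), resampled above `max_daily_volume`, with the raw mean adjusted
#' so that the truncated long-run mean equals `mean_daily_volume`. The volume
#' arrives in a small number of bursts at a constant in-burst flow rate set
#' by the day's flowing fraction; the remaining minutes are stagnant (zero
#' flow). Influent TOC is drawn per burst from a lognormal distribution and
#' held between bursts; the configured extreme peak replaces the first burst
#' concentration of `peak_day`.
#'
#' @param pattern An [operation_pattern()].
#' @return List with elements `flow` (data.frame `time`, `flow_L_min`) and
#'   `influent` (data.frame `time`, `toc_mg_L`), both on the same 1-minute
#'   grid, plus `pattern`.
#' @export
#' @examples
#' op <- generate_operation_series(operation_pattern(duration_days = 5, seed = 1))
#' sum(op$flow$flow_L_min)  # total volume, L
generate_operation_series <- function(pattern) {
  stopifnot(inherits(pattern, "operation_pattern"))
  set.seed(pattern$seed)
  nd <- pattern$duration_days
  n_min <- nd * 1440L
  times <- .sim_origin() + 60 * (seq_len(n_min) - 1)
  flow <- numeric(n_min)
  toc <- numeric(n_min)

  mu <- pattern$mean_daily_volume
  vmax <- pattern$max_daily_volume
  if (mu > 0) {
    # raw gamma mean such that the mean after truncation at vmax hits mu
    trunc_mean <- function(m) {
      sc <- m / 2
      m * pgamma(vmax, 3, scale = sc) / pgamma(vmax, 2, scale = sc)
    }
    mu_raw <- if (is.finite(vmax) && trunc_mean(mu * 3) > mu) {
      uniroot(function(m) trunc_mean(m) - mu, c(mu, mu * 3))$root
    } else mu
    vday <- rgamma(nd, shape = 2, scale = mu_raw / 2)
    for (k in 1:20) {
      over <- vday > vmax
      if (!any(over)) break
      vday[over] <- rgamma(sum(over), shape = 2, scale = mu_raw / 2)
    }
    vday[vday > vmax] <- vmax
  } else {
    vday <- numeric(nd)
  }

  # influent TOC: day-scale AR(1) on the log scale with the configured
  # lognormal marginal, plus small within-day burst-to-burst jitter --
  # greywater quality after the upstream treatment drifts over days, it does
  # not resample independently at every flow burst
  rho <- 0.7
  z <- numeric(nd)
  z[1] <- rnorm(1)
  if (nd > 1)
    for (d in 2:nd) z[d] <- rho * z[d - 1] + sqrt(1 - rho^2) * rnorm(1)
  c_day <- exp(pattern$influent_toc_log_mean + pattern$influent_toc_log_sd * z)

  fr <- pattern$flow_fraction_range
  last_conc <- c_day[1]
  for (d in seq_len(nd)) {
    off <- (d - 1L) * 1440L
    v <- vday[d]
    if (v > 0) {
      n_b <- 1L + rpois(1, max(0, pattern$bursts_per_day - 1))
      f_t <- runif(1, fr[1], fr[2])
      q_b <- v / (f_t * 1440)
      q_b <- min(max(q_b, 0.2), 2.45)
      m_tot <- max(1L, round(v / q_b))
      if (m_tot > 1435L) m_tot <- 1435L
      q_b <- v / m_tot
      # burst lengths: split m_tot minutes into n_b positive parts
      n_b <- min(n_b, m_tot)
      cuts <- if (n_b > 1) sort(sample.int(m_tot - 1L, n_b - 1L)) else integer(0)
      lens <- diff(c(0L, cuts, m_tot))
      # gaps before each burst (stick-breaking over the idle minutes)
      idle <- 1440L - m_tot
      w <- runif(n_b + 1L)
      gaps <- floor(idle * w / sum(w))
      pos <- 0L
      concs <- c_day[d] * exp(0.1 * rnorm(n_b) - 0.005)
      if (!is.na(pattern$peak_day) && d == pattern$peak_day)
        concs[] <- pattern$peak_concentration   # day-scale excursion
      for (b in seq_len(n_b)) {
        pos <- pos + gaps[b]
        idx <- off + pos + seq_len(lens[b])
        flow[idx] <- q_b
        # concentration holds from burst start until the next burst starts
        toc_start <- off + pos + 1L
        toc[toc_start:n_min] <- concs[b]
        pos <- pos + lens[b]
      }
      last_conc <- concs[n_b]
    }
    if (d == 1L && all(toc[seq_len(min(10L, n_min))] == 0))
      toc[toc == 0] <- last_conc
  }
  toc[toc <= 0] <- last_conc
  if (!is.na(pattern$peak_day) && vday[max(1, pattern$peak_day)] == 0 &&
      pattern$duration_days >= pattern$peak_day && pattern$peak_day >= 1) {
    idx <- (pattern$peak_day - 1L) * 1440L + seq_len(1440L)
    toc[idx] <- pattern$peak_concentration
  }
  list(flow = data.frame(time = times, flow_L_min = flow),
       influent = data.frame(time = times, toc_mg_L = toc),
       pattern = pattern)
}

#' Simulate a BAC column run with known ground truth
#'
#' Runs the mechanistic tanks-in-series column (see [column_kinetics()] for
#' the process laws) over a 1-minute flow and influent TOC record and returns
#' depth-resolved TOC series at every sampling port plus a mass-conserving
#' `SimulationTruth` ledger: per-segment sorbed and biodegraded mass and the
#' fate of produced biomass (accumulated / washed out / backwashed / CO2).
#'
#' @param spec A [filter_spec()].
#' @param kinetics A [column_kinetics()]; `n_cells` must be a multiple of the
#'   number of bed segments.
#' @param flow data.frame `time`, `flow_L_min` on a 1-minute grid.
#' @param influent data.frame `time`, `toc_mg_L` on the same grid.
#' @param backwash_day Day index of the single backwash (`NA` for none).
#' @param backwash_fraction Fraction of attached biomass removed by the
#'   backwash.
#' @return Object of class `bac_simulation` with elements `port_toc`
#'   (data.frame: time, influent, sub_schmutzdecke, port concentrations and
#'   effluent, mg/L), `truth` (list: `sorbed_seg_g`, `biodeg_seg_g`, `co2_g`,
#'   `produced_g`, `accumulated_g`, `washed_g`, `backwashed_g`,
#'   `influent_g`, `effluent_g`, `holdup_g`), `daily` (per-day snapshots),
#'   `cells` (geometry), and the inputs.
#' @export
simulate_column <- function(spec, kinetics, flow, influent,
                            backwash_day = NA, backwash_fraction = 0.15) {
  stopifnot(inherits(spec, "filter_spec"), inherits(kinetics, "column_kinetics"))
  if (nrow(flow) != nrow(influent) || !isTRUE(all.equal(
        as.numeric(flow$time), as.numeric(influent$time))))
    stop("flow and influent series must share the same 1-minute grid")
  if (any(flow$flow_L_min < 0)) stop("negative flow")
  nseg <- length(spec$port_depths) + 1L
  n <- kinetics$n_cells
  if (n < length(spec$port_depths) + 1L)
    stop("n_cells must be at least number of ports + 1")
  if (n %% nseg != 0L)
    stop(sprintf("n_cells must be a multiple of %d so ports fall on cell interfaces", nseg))
  k <- n %/% nseg
  bounds <- spec$segment_bounds_m
  # per-cell geometry: k equal cells inside every segment
  z0 <- rep(bounds[-length(bounds)], each = k) +
    rep(diff(bounds), each = k) * (rep(seq_len(k), nseg) - 1L) / k
  dz <- rep(diff(bounds) / k, each = k)
  zmid <- z0 + dz / 2
  V <- spec$bed_porosity * spec$area_m2 * dz * 1000       # L
  m_g <- spec$gac_mass * 1000 * dz / spec$bed_depth       # g GAC
  seg <- rep(seq_len(nseg), each = k)
  w <- m_g * exp(-zmid / kinetics$x0_length_scale)
  w[1] <- w[1] * kinetics$schmutzdecke_boost
  X0 <- kinetics$x0_total * w / sum(w)
  record <- c(1L, seq_len(nseg) * k)                      # sub-Schmutzdecke + ports
  bw_min <- if (is.na(backwash_day)) -1L else as.integer(round((backwash_day - 0.5) * 1440))

  res <- sim_core(flow$flow_L_min, influent$toc_mg_L, kinetics$labile_fraction,
                  V, m_g, X0, as.integer(seg), record,
                  kinetics$q_max, kinetics$k_sorb, kinetics$c_half,
                  kinetics$k_bio, kinetics$yield_Y, kinetics$detach_fraction,
                  bw_min, if (is.na(backwash_day)) 0 else backwash_fraction)
  if (isTRUE(res$negative_error))
    stop("integrator produced a negative concentration; reduce the step size")

  port_labels <- c("sub_schmutzdecke",
                   paste0("d", round(spec$port_depths * 100), "cm"), "effluent")
  port <- as.data.frame(res$port)
  names(port) <- port_labels
  port_toc <- cbind(data.frame(time = flow$time, influent = influent$toc_mg_L), port)

  accumulated <- res$produced_g - res$washed_g - res$backwashed_g
  truth <- list(
    sorbed_seg_g = as.numeric(res$sorbed_seg_g),
    biodeg_seg_g = as.numeric(res$biodeg_seg_g),
    sorbed_g = sum(res$sorbed_seg_g),
    biodeg_g = sum(res$biodeg_seg_g),
    co2_g = res$co2_g, produced_g = res$produced_g,
    accumulated_g = accumulated, washed_g = res$washed_g,
    backwashed_g = res$backwashed_g,
    influent_g = res$influent_g, effluent_g = res$effluent_g,
    holdup_g = res$holdup_g,
    removed_g = res$influent_g - res$effluent_g)
  nd <- length(res$daily_washed)
  daily <- data.frame(day = seq_len(nd),
                      res$daily_sorbed, res$daily_biodeg,
                      washed_g = as.numeric(res$daily_washed),
                      x_total_g = as.numeric(res$daily_x),
                      influent_g = as.numeric(res$daily_influent),
                      effluent_g = as.numeric(res$daily_effluent))
  names(daily)[2:(1 + nseg)] <- paste0("sorbed_seg", seq_len(nseg), "_g")
  names(daily)[(2 + nseg):(1 + 2 * nseg)] <- paste0("biodeg_seg", seq_len(nseg), "_g")

  structure(list(spec = spec, kinetics = kinetics,
                 flow = flow, influent = influent,
                 port_toc = port_toc, truth = truth, daily = daily,
                 cells = list(V_L = V, gac_g = m_g, z_mid_m = zmid, segment = seg,
                              q_final = as.numeric(res$q_final),
                              x_final = as.numeric(res$x_final)),
                 backwash_day = backwash_day,
                 backwash_fraction = if (is.na(backwash_day)) 0 else backwash_fraction,
                 x0_total = kinetics$x0_total),
            class = "bac_simulation")
}

#' @export
print.bac_simulation <- function(x, ...) {
  tr <- x$truth
  nd <- nrow(x$daily)
  cat(sprintf("BAC column simulation: %d days, %.0f L treated\n",
              nd, sum(x$flow$flow_L_min)))
  cat(sprintf("  influent %.1f g TOC, effluent %.1f g, removed %.1f g (%.0f%%)\n",
              tr$influent_g, tr$effluent_g, tr$removed_g,
              100 * tr$removed_g / max(tr$influent_g, 1e-12)))
  cat(sprintf("  truth: sorbed %.1f g, biodegraded %.1f g (sorption share %.0f%%)\n",
              tr$sorbed_g, tr$biodeg_g,
              100 * tr$sorbed_g / max(tr$removed_g, 1e-12)))
  cat(sprintf("  biomass: produced %.3f gC = accumulated %.3f + washed out %.3f + backwashed %.3f\n",
              tr$produced_g, tr$accumulated_g, tr$washed_g, tr$backwashed_g))
  invisible(x)
}

#' @export
summary.bac_simulation <- function(object, ...) {
  tr <- object$truth
  closure <- abs(tr$influent_g - (tr$effluent_g + tr$sorbed_g + tr$biodeg_g +
                                    tr$holdup_g)) / max(tr$influent_g, 1e-12)
  out <- list(truth = tr, carbon_closure_rel = closure,
              sorption_share = tr$sorbed_g / max(tr$removed_g, 1e-12),
              days = nrow(object$daily))
  class(out) <- "summary.bac_simulation"
  out
}

#' @export
print.summary.bac_simulation <- function(x, ...) {
  cat(sprintf("Carbon closure |in - (out + sorbed + biodegraded + holdup)| / in = %.2e\n",
              x$carbon_closure_rel))
  cat(sprintf("True sorption share of removed: %.1f%%\n", 100 * x$sorption_share))
  invisible(x)
}

#' @export
plot.bac_simulation <- function(x, every = 1440L, ...) {
  idx <- seq(1L, nrow(x$port_toc), by = every)
  pt <- x$port_toc[idx, ]
  days <- as.numeric(difftime(pt$time, .sim_origin(), units = "days"))
  cols <- c("grey40", "tan4", "orange3", "red3", "purple3", "blue3")
  ylim <- c(0, max(pt$influent, na.rm = TRUE))
  plot(days, pt$influent, type = "l", col = cols[1], ylim = ylim,
       xlab = "day of operation", ylab = "TOC (mg/L)", ...)
  series <- setdiff(names(pt), c("time", "influent"))
  for (j in seq_along(series))
    lines(days, pt[[series[j]]], col = cols[j + 1])
  legend("topright", legend = c("influent", series), col = cols, lty = 1, cex = 0.7)
  invisible(x)
}

#' Draw grab samples from a simulated column run
#'
#' Emulates the sampling campaign: TOC grab samples taken a fixed number of
#' times per week, only at minutes with flow, at the influent, the sampling
#' ports and the effluent, with multiplicative measurement noise.
#'
#' @param sim A [simulate_column()] result.
#' @param per_week Samples per week (default 2).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (default 0.01; the TOC analyser's repeatability).
#' @param at Optional explicit sample times (POSIXct); these must fall on
#'   minutes with nonzero flow, otherwise an error is raised.
#' @param locations Locations to sample.
#' @param seed Optional seed for the noise draw.
#' @return data.frame `time`, `location`, `toc_mg_L`.
#' @export
generate_grab_samples <- function(sim, per_week = 2, noise_cv = 0.01,
                                  at = NULL,
                                  locations = c("influent", "7cm", "22cm",
                                                "37cm", "effluent"),
                                  seed = NULL) {
  stopifnot(inherits(sim, "bac_simulation"))
  if (!is.null(seed)) set.seed(seed)
  n_min <- nrow(sim$flow)
  flowing <- which(sim$flow$flow_L_min > 0)
  if (!length(flowing)) stop("no flowing minutes in simulation")
  if (is.null(at)) {
    nd <- n_min / 1440
    targets <- round(seq(0.5, nd - 0.5, by = 7 / per_week) * 1440)
    # intensified sampling around an extreme influent event (the campaign
    # followed the peak and the desorption transient on consecutive days)
    infl <- sim$influent$toc_mg_L
    if (max(infl) > 5 * median(infl)) {
      peak_day <- ceiling(which.max(infl) / 1440)
      extra_days <- peak_day + c(-2, -1, 2:7, 9, 11, 13, 17, 21, 28)
      extra_days <- extra_days[extra_days >= 1 & extra_days <= nd]
      targets <- c(targets, round((extra_days - 0.5) * 1440))
      # during the excursion itself (peak day +/- 1), every flow burst is
      # sampled at its midpoint to resolve the breakthrough at the ports
      win <- ((max(1, peak_day - 2)) * 1440 + 1):min(n_min, (peak_day + 1) * 1440)
      fw <- sim$flow$flow_L_min[win] > 0
      runs <- rle(fw)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      mids <- win[1] - 1L + (starts + ends) %/% 2
      targets <- c(targets, mids[runs$values])
    }
    targets <- sort(unique(targets[targets >= 1 & targets <= n_min]))
    # sample in the middle of the flow burst nearest to each target time
    # (sampling happens while flow is running, not at the first-flush minute)
    fw <- sim$flow$flow_L_min > 0
    runs <- rle(fw)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bs <- starts[runs$values]; be <- ends[runs$values]
    bmid <- (bs + be) %/% 2L
    near <- function(tg) {
      d <- pmax(bs - tg, 0L) + pmax(tg - be, 0L)
      bmid[which.min(d)]
    }
    idx <- unique(vapply(targets, near, integer(1)))
  } else {
    if (min(at) < sim$flow$time[1] || max(at) > sim$flow$time[n_min])
      stop("requested sample time outside the simulation window")
    idx <- match(as.numeric(at), as.numeric(sim$flow$time))
    if (anyNA(idx)) stop("sample times must fall on the 1-minute grid")
    if (any(sim$flow$flow_L_min[idx] == 0))
      stop("grab samples can only be taken at minutes with flow")
  }
  port_map <- c(influent = "influent",
                "sub-schmutzdecke" = "sub_schmutzdecke",
                "7cm" = "d7cm", "22cm" = "d22cm", "37cm" = "d37cm",
                effluent = "effluent")
  locations <- match.arg(locations, names(port_map), several.ok = TRUE)
  out <- do.call(rbind, lapply(locations, function(loc) {
    val <- sim$port_toc[[port_map[[loc]]]][idx]
    data.frame(time = sim$flow$time[idx], location = loc, toc_mg_L = val)
  }))
  if (noise_cv > 0)
    out$toc_mg_L <- pmax(0, out$toc_mg_L * (1 + noise_cv * rnorm(nrow(out))))
  rownames(out) <- NULL
  out
}

#' Sparse total-cell-count samples from a simulated run
#'
#' TCC is measured infrequently. Influent TCC is a constant background with
#' measurement noise; effluent TCC is the background plus the cells detached
#' from the filter, computed from the day's washed-out biomass carbon and
#' treated volume via the carbon-per-cell constant.
#'
#' @param sim A [simulate_column()] result.
#' @param const [conversion_constants()].
#' @param tcc_influent Mean influent TCC, cells/mL.
#' @param n_influent,n_effluent Number of samples per location.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Optional seed.
#' @return data.frame `time`, `location`, `tcc_cells_mL`.
#' @export
generate_tcc_samples <- function(sim, const = conversion_constants(),
                                 tcc_influent = 3.3e5,
                                 n_influent = 99, n_effluent = 82,
                                 noise_cv = 0.1, seed = NULL) {
  stopifnot(inherits(sim, "bac_simulation"))
  if (!is.null(seed)) set.seed(seed)
  daily <- sim$daily
  vol_day <- tapply(sim$flow$flow_L_min, (seq_len(nrow(sim$flow)) - 1L) %/% 1440L, sum)
  washed_inc <- diff(c(0, daily$washed_g))
  extra <- ifelse(vol_day > 0, washed_inc / (vol_day * 1000) / const$carbon_per_cell, 0)
  flow_days <- which(vol_day > 0)
  pick <- function(nn) sort(sample(flow_days, min(nn, length(flow_days))))
  d_in <- pick(n_influent); d_out <- pick(n_effluent)
  mk <- function(days, loc, base) {
    val <- base * (1 + noise_cv * rnorm(length(days)))
    data.frame(time = .sim_origin() + (days - 0.5) * 86400,
               location = loc, tcc_cells_mL = pmax(0, val))
  }
  rbind(mk(d_in, "influent", tcc_influent),
        mk(d_out, "effluent", tcc_influent + extra[d_out]))
}

#' ATP inventory on the GAC from a simulated run
#'
#' Converts the attached biomass carbon per cell of the simulated column into
#' an ATP inventory via the carbon-per-cell and cells-per-gram-ATP constants,
#' reported per gram of GAC at each port depth and as a column total.
#'
#' @param sim A [simulate_column()] result.
#' @param const [conversion_constants()].
#' @return List with `table` (data.frame `depth_cm`, `atp_g_per_gGAC`) and
#'   `total_g_atp`.
#' @export
atp_inventory <- function(sim, const = conversion_constants()) {
  stopifnot(inherits(sim, "bac_simulation"))
  cells <- sim$cells
  to_atp <- function(xc) xc / const$carbon_per_cell / const$cells_per_gATP
  # per-gGAC value at each port: the cell just above the port interface
  nseg <- max(cells$segment)
  k <- length(cells$V_L) / nseg
  port_cells <- seq_len(nseg - 1) * k
  tab <- data.frame(
    depth_cm = round(sim$spec$port_depths * 100),
    atp_g_per_gGAC = to_atp(cells$x_final[port_cells]) / cells$gac_g[port_cells])
  list(table = tab, total_g_atp = to_atp(sum(cells$x_final)))
}

#' Generate a backwash event record from a simulated column
#'
#' Builds the minute-resolved backwash sampling record for the single
#' backwash of a run. The cells removed by the backwash (known exactly from
#' the simulation truth) are distributed over the sampled minutes with an
#' exponentially decaying profile on top of the tap-water background;
#' backwash TOC is the cell carbon plus a configurable load of GAC fines,
#' and TSS tracks the solids.
#'
#' @param sim A [simulate_column()] result that was run with a backwash day.
#' @param flow_L_min Backwash flow (must be > 0).
#' @param duration_min Backwash duration in minutes (one sample per minute).
#' @param const [conversion_constants()].
#' @param fines_toc_g TOC attributable to GAC fines and dust in the backwash
#'   water, g (not biomass; reported but excluded from the carbon balance by
#'   default).
#' @param background_tcc Tap-water background TCC, cells/mL.
#' @param bed_expansion Maximum bed expansion during the backwash (fraction).
#' @return Object of class `backwash_record`: data.frame `minute`,
#'   `toc_mg_L`, `tcc_cells_mL`, `atp_g_L`, `tss_mg_L` plus attributes
#'   `flow_L_min`, `event_day`, `bed_expansion`, `removed_biomass_g`.
#' @export
generate_backwash_event <- function(sim, flow_L_min = 20, duration_min = 11,
                                    const = conversion_constants(),
                                    fines_toc_g = 3.38, background_tcc = 5e4,
                                    bed_expansion = 0.14) {
  stopifnot(inherits(sim, "bac_simulation"))
  if (flow_L_min <= 0 || duration_min <= 0)
    stop("backwash flow and duration must be positive")
  if (is.na(sim$backwash_day))
    stop("simulation was run without a backwash event")
  removed_g <- sim$truth$backwashed_g
  vol_L <- flow_L_min * duration_min
  w <- exp(-0.4 * (seq_len(duration_min) - 1))
  w <- w / sum(w)
  cells_total <- removed_g / const$carbon_per_cell
  # concentration in each 1-minute sample (flow_L_min L per minute, in mL)
  tcc <- background_tcc + cells_total * w / (flow_L_min * 1000)
  cell_toc <- (tcc - background_tcc) * const$carbon_per_cell * 1000  # mg/L
  fines <- fines_toc_g * 1000 * w / flow_L_min                       # mg/L
  rec <- data.frame(minute = seq_len(duration_min),
                    toc_mg_L = cell_toc + fines,
                    tcc_cells_mL = tcc,
                    atp_g_L = tcc * 1000 / const$cells_per_gATP,
                    tss_mg_L = 1.8 * (cell_toc + fines))
  structure(rec, class = c("backwash_record", "data.frame"),
            flow_L_min = flow_L_min, event_day = sim$backwash_day,
            bed_expansion = bed_expansion, removed_biomass_g = removed_g,
            background_tcc = background_tcc)
}

#' Synthetic pressure-loss series over the filter bed
#'
#' Daily pressure loss across the bed, rising with accumulated biomass and
#' reset toward its initial value by the backwash; clipped at the operating
#' cap because the inflow is stopped when the cap is reached.
#'
#' @param sim A [simulate_column()] result.
#' @param base_mbar Clean-bed pressure loss, mbar.
#' @param mbar_per_gC Pressure-loss increase per gram of accumulated biomass
#'   carbon, mbar/gC.
#' @param cap_mbar Operating cap (inflow stops above it), mbar.
#' @return data.frame `day`, `loss_mbar`.
#' @export
pressure_loss_series <- function(sim, base_mbar = 4, mbar_per_gC = 120,
                                 cap_mbar = 22) {
  stopifnot(inherits(sim, "bac_simulation"))
  # growth of attached biomass relative to start drives the ramp
  growth <- pmax(0, sim$daily$x_total_g - sim$daily$x_total_g[1])
  loss <- pmin(base_mbar + mbar_per_gC * growth, cap_mbar)
  data.frame(day = sim$daily$day, loss_mbar = loss)
}
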