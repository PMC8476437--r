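#' Loads removed by a backwash event
#'
#' Integrates the minute-resolved backwash samples into the total TOC load,
#' the total cells and the cell-bound carbon removed by the event. The TOC
#' load and the cell carbon are reported side by side with their ratio: a
#' TOC load far above the cell carbon indicates non-biomass solids (fine GAC
#' particles and dust), which are excluded from the carbon balance unless
#' explicitly requested.
#'
#' @param record `backwash_record` (or data.frame with `toc_mg_L`,
#'   `tcc_cells_mL`).
#' @param flow_L_min Backwash flow; defaults to the record's attribute.
#' @param const [conversion_constants()].
#' @return List `toc_g`, `cells`, `cell_carbon_g`, `toc_to_cell_carbon`.
#' @export
backwash_loads <- function(record, flow_L_min = NULL,
                           const = conversion_constants()) {
  if (is.null(flow_L_min)) flow_L_min <- attr(record, "flow_L_min")
  if (is.null(flow_L_min) || flow_L_min <= 0)
    stop("backwash flow must be positive")
  if (nrow(record) < 1) stop("backwash record has no samples")
  toc_g <- sum(record$toc_mg_L) * flow_L_min / 1000
  cells <- sum(record$tcc_cells_mL) * flow_L_min * 1000
  cc <- cells * const$carbon_per_cell
  list(toc_g = toc_g, cells = cells, cell_carbon_g = cc,
       toc_to_cell_carbon = if (cc > 0) toc_g / cc else NA_real_)
}

#' Compare an effluent quality series before and after an event
#'
#' Mean and sample standard deviation in a window on each side of the event,
#' plus a Welch two-sample comparison (descriptive: the before/after contrast
#' is observational).
#'
#' @param series data.frame `time`, value column (second column).
#' @param event_time POSIXct (or numeric, same clock as `series$time`).
#' @param window_days Window length on each side, days (default 30).
#' @return List `before` and `after` (each `n`, `mean`, `sd`), `welch`
#'   (htest) and `window_days`.
#' @export
before_after_summary <- function(series, event_time, window_days = 30) {
  tt <- as.numeric(series$time)
  et <- as.numeric(event_time)
  v <- series[[2]]
  w <- window_days * 86400
  pre <- v[tt >= et - w & tt < et]
  post <- v[tt > et & tt <= et + w]
  if (length(pre) < 2 || length(post) < 2)
    stop("need at least 2 observations on each side of the event")
  welch <- if (sd(pre) == 0 && sd(post) == 0) NULL else
    t.test(pre, post)
  list(before = list(n = length(pre), mean = mean(pre), sd = sd(pre)),
       after = list(n = length(post), mean = mean(post), sd = sd(post)),
       welch = welch, window_days = window_days)
}

#' Summarise pressure loss around maintenance events
#'
#' Per event, the drop in pressure loss across the event (level just before
#' minus level just after), and flags for excursions above the operating cap
#' at which the inflow is stopped.
#'
#' @param series data.frame `day`, `loss_mbar` (any time resolution; `day`
#'   numeric).
#' @param events Numeric vector of event days.
#' @param cap_mbar Operating cap (default 22 mbar).
#' @param margin_days Levels are averaged over this many days on each side.
#' @return List `events` (data.frame `day`, `pre_mbar`, `post_mbar`,
#'   `drop_mbar`) and `exceedances` (days with loss above the cap).
#' @export
pressure_loss_summary <- function(series, events, cap_mbar = 22,
                                  margin_days = 3) {
  stopifnot(all(c("day", "loss_mbar") %in% names(series)))
  ev <- vapply(events, function(e) {
    pre <- series$loss_mbar[series$day < e & series$day >= e - margin_days]
    post <- series$loss_mbar[series$day > e & series$day <= e + margin_days]
    if (!length(pre) || !length(post)) return(c(NA, NA, NA))
    c(mean(pre), mean(post), mean(pre) - mean(post))
  }, numeric(3))
  list(events = data.frame(day = events, pre_mbar = ev[1, ],
                           post_mbar = ev[2, ], drop_mbar = ev[3, ]),
       exceedances = series$day[series$loss_mbar > cap_mbar])
}
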