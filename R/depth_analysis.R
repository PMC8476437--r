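#' Build removal-ratio observations for one depth
#'
#' Pairs every TOC grab sample at a depth with the nearest-in-time influent
#' sample (the same nearest rule used for load integration) and attaches the
#' per-observation empty bed contact time (EBCT): the empty-bed volume above
#' the port divided by the flow averaged over the contiguous flowing interval
#' ending at the sample minute. Stagnant minutes are excluded from the flow
#' average because samples are only taken at times with flow.
#'
#' @param samples Grab-sample data.frame (`time`, `location`, `toc_mg_L`).
#' @param flow data.frame `time`, `flow_L_min` (1-minute grid).
#' @param depth Location label of the sampled depth (e.g. `"22cm"`,
#'   `"effluent"`).
#' @param spec [filter_spec()] providing the geometry for the EBCT.
#' @return data.frame `day`, `ratio` (TOC_out/TOC_in), `toc_in` (mg/L),
#'   `ebct` (min).
#' @export
ratio_observations <- function(samples, flow, depth, spec = filter_spec()) {
  s <- samples[samples$location == depth & !is.na(samples$toc_mg_L), ]
  if (!nrow(s)) stop(sprintf("no samples at depth '%s'", depth))
  toc_in <- pair_nearest(data.frame(time = s$time, flow_L_min = 0),
                         samples, "influent")
  depth_m <- if (depth == "effluent") spec$bed_depth else
    as.numeric(sub("cm$", "", depth)) / 100
  vol_L <- spec$area_m2 * depth_m * 1000
  fl <- flow$flow_L_min
  run_id <- cumsum(c(TRUE, diff(fl > 0) != 0))          # contiguous runs
  run_mean <- tapply(fl, run_id, mean)
  idx <- findInterval(as.numeric(s$time), as.numeric(flow$time))
  idx[idx < 1] <- 1L
  ebct <- vapply(idx, function(i) {
    j <- i
    while (j > 1 && fl[j] == 0) j <- j - 1          # nearest flowing run
    q <- run_mean[[as.character(run_id[j])]]
    if (q > 0) vol_L / q else NA_real_
  }, numeric(1))
  day <- as.numeric(difftime(s$time, flow$time[1], units = "days")) + 1
  data.frame(day = day, ratio = s$toc_mg_L / toc_in, toc_in = toc_in,
             ebct = ebct)
}

#' Fit the linear removal-ratio model for one depth
#'
#' Ordinary least squares of the removal ratio on operating time, influent
#' TOC and EBCT:
#' `TOC_out/TOC_in = b0 + b1 * time + b2 * TOC_in + b3 * EBCT`,
#' with time in years (so `b1` has units 1/y), `TOC_in` in mg/L and EBCT in
#' minutes. Only observations from `start_day` on are used: the breakthrough
#' and desorption transient after an extreme influent peak violates the
#' linear structure and is excluded.
#'
#' @param obs data.frame with columns `ratio`, `day`, `toc_in`, `ebct`
#'   (see [ratio_observations()]).
#' @param start_day First day of operation included (inclusive; default 140).
#' @param depth Optional depth label carried into the result.
#' @return Object of class `bac_removal_lm`: the coefficients `b0..b3`,
#'   two-sided coefficient p-values, `n`, the fit window and the underlying
#'   `lm` fit (`$fit`). Supports `print`, `summary`, `coef`, `predict` and
#'   `residuals`.
#' @export
#' @examples
#' d <- data.frame(day = seq(150, 900, length.out = 40),
#'                 toc_in = rep(c(2, 5, 9, 16), 10),
#'                 ebct = rep(c(30, 78, 120, 160), each = 10))
#' d$ratio <- 0.23 + 0.080 * d$day / 365 - 0.019 * d$toc_in - 4.83e-6 * d$ebct
#' coef(fit_removal_model(d))
fit_removal_model <- function(obs, start_day = 140, depth = NULL) {
  need <- c("ratio", "day", "toc_in", "ebct")
  stopifnot(all(need %in% names(obs)))
  obs <- obs[complete.cases(obs[need]), ]
  obs <- obs[obs$day >= start_day, ]
  if (nrow(obs) < 10)
    stop("need at least 10 observations after start_day")
  obs$years <- obs$day / 365
  fit <- lm(ratio ~ years + toc_in + ebct, data = obs)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop(sprintf("singular design: column '%s' is collinear or constant",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  out <- list(depth = depth,
              coefficients = setNames(as.numeric(cf),
                                      c("b0", "b1_per_year", "b2_L_per_mg",
                                        "b3_per_min")),
              p_values = setNames(sm$coefficients[, 4],
                                  c("b0", "b1_per_year", "b2_L_per_mg",
                                    "b3_per_min")),
              n = nrow(obs),
              window_days = range(obs$day),
              sigma = sm$sigma, r_squared = sm$r.squared,
              fit = fit)
  class(out) <- "bac_removal_lm"
  out
}

#' @export
print.bac_removal_lm <- function(x, ...) {
  cat(sprintf("Removal-ratio model%s: n = %d, days %.0f-%.0f, R^2 = %.2f\n",
              if (is.null(x$depth)) "" else paste0(" [", x$depth, "]"),
              x$n, x$window_days[1], x$window_days[2], x$r_squared))
  cf <- x$coefficients
  star <- ifelse(x$p_values > 0.05, " *", "")
  cat(sprintf("  b0 = %.3g%s\n  b1 = %.3g 1/y%s\n  b2 = %.3g L/mg%s\n  b3 = %.3g 1/min%s\n",
              cf[1], star[1], cf[2], star[2], cf[3], star[3], cf[4], star[4]))
  cat("  (* not significantly different from 0 at p > 0.05)\n")
  invisible(x)
}

#' @export
coef.bac_removal_lm <- function(object, ...) object$coefficients

#' @export
summary.bac_removal_lm <- function(object, ...) summary(object$fit, ...)

#' @export
predict.bac_removal_lm <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata) && !"years" %in% names(newdata))
    newdata$years <- newdata$day / 365
  predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.bac_removal_lm <- function(object, ...) residuals(object$fit, ...)

#' Change in removal ratio implied by a fitted coefficient
#'
#' Multiplies one coefficient of a [fit_removal_model()] fit by a finite
#' change of its regressor: `days` (converted to years for `b1`), `toc_in`
#' (mg/L) or `ebct` (min). Exactly one delta must be given.
#'
#' @param fit A `bac_removal_lm` (or a named coefficient vector `b0..b3`).
#' @param days,toc_in,ebct The change along one axis.
#' @return Change in TOC_out/TOC_in.
#' @export
#' @examples
#' f <- list(coefficients = c(b0 = 0.31, b1_per_year = 0.182,
#'                            b2_L_per_mg = -0.019, b3_per_min = -0.00096))
#' class(f) <- "bac_removal_lm"
#' effect_size(f, days = 770)        # 0.38
#' effect_size(f, toc_in = 19.1 - 1.9)
effect_size <- function(fit, days = NULL, toc_in = NULL, ebct = NULL) {
  cf <- if (inherits(fit, "bac_removal_lm")) fit$coefficients else fit
  given <- !c(is.null(days), is.null(toc_in), is.null(ebct))
  if (sum(given) != 1)
    stop("give exactly one of days, toc_in, ebct")
  if (!is.null(days)) {
    stopifnot(is.finite(days)); return(cf[["b1_per_year"]] * days / 365)
  }
  if (!is.null(toc_in)) {
    stopifnot(is.finite(toc_in)); return(cf[["b2_L_per_mg"]] * toc_in)
  }
  stopifnot(is.finite(ebct))
  cf[["b3_per_min"]] * ebct
}

#' Table of removal-model fits across depths
#'
#' Lays out several [fit_removal_model()] fits as one table (depth columns,
#' coefficient rows) with an asterisk marking coefficients not significantly
#' different from zero (p > 0.05).
#'
#' @param fits Named list of `bac_removal_lm` objects.
#' @return data.frame of formatted coefficients.
#' @export
removal_fit_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  cols <- lapply(fits, function(f) {
    star <- ifelse(f$p_values > 0.05, " *", "")
    paste0(signif(f$coefficients, 3), star)
  })
  out <- as.data.frame(cols, check.names = FALSE)
  rownames(out) <- c("b0", "b1 (1/y)", "b2 (L/mg)", "b3 (1/min)")
  out
}

#' Per-segment removal profile from boundary load ledgers
#'
#' The removed load in each bed segment is the difference between adjacent
#' boundary ledgers (influent, the ports, effluent); the segment shares of
#' whole-filter removal telescope exactly. Segment GAC mass is allocated
#' proportionally to segment depth.
#'
#' @param ledgers List of [load_ledger()] objects ordered from influent to
#'   effluent (influent first), all on the same window and volume; or a
#'   numeric vector of cumulative removed loads at the boundaries
#'   (first element 0 for the influent).
#' @param spec [filter_spec()] for geometry and GAC masses.
#' @return Object of class `segment_profile`: data.frame `segment`, `top_cm`,
#'   `bottom_cm`, `gac_kg`, `removed_g`, `share`.
#' @export
segment_removal <- function(ledgers, spec = filter_spec()) {
  if (is.list(ledgers) && all(vapply(ledgers, inherits, TRUE, "load_ledger"))) {
    wins <- vapply(ledgers, function(l) l$window, numeric(2))
    if (max(wins[1, ]) - min(wins[1, ]) > 1e-9 ||
        max(wins[2, ]) - min(wins[2, ]) > 1e-9)
      stop("ledgers cover inconsistent windows")
    cumrem <- vapply(ledgers, function(l) ledgers[[1]]$ftoc_g - l$ftoc_g,
                     numeric(1))
  } else {
    cumrem <- as.numeric(ledgers)
  }
  nseg <- length(cumrem) - 1L
  if (nseg != length(spec$segment_gac_kg))
    stop("number of boundaries does not match the filter's segments")
  removed <- diff(cumrem)
  total <- cumrem[length(cumrem)]
  bounds_cm <- spec$segment_bounds_m * 100
  out <- data.frame(segment = seq_len(nseg),
                    top_cm = bounds_cm[-length(bounds_cm)],
                    bottom_cm = bounds_cm[-1],
                    gac_kg = spec$segment_gac_kg,
                    removed_g = removed,
                    share = if (total != 0) removed / total else removed * 0)
  structure(out, class = c("segment_profile", "data.frame"),
            total_removed_g = total)
}

#' Split per-segment removal into sorption and biodegradation
#'
#' Per segment, sorption is capped at the segment's equilibrium capacity:
#' `sorption = min(q_e x segment GAC mass, removed)`; the remainder is
#' biodegradation. In deep segments with removal below capacity, up to 100 %
#' of the removal can be sorption. The attribute `capacity_totals` reports
#' both the sum of capped per-segment sorption and the whole-filter
#' `q_e x M_GAC`, which the cap makes differ; the report prints both.
#'
#' @param profile A [segment_removal()] profile.
#' @param qe Equilibrium loading, mgTOC/gGAC.
#' @return The profile with columns `sorption_g`, `biodegradation_g`,
#'   `biodeg_share` added.
#' @export
#' @examples
#' prof <- segment_removal(c(0, 604.2, 850, 973, 1024))
#' segment_sorption_split(prof, 25.6)
segment_sorption_split <- function(profile, qe) {
  stopifnot(inherits(profile, "segment_profile"), qe >= 0)
  cap <- qe * profile$gac_kg
  profile$sorption_g <- pmin(cap, pmax(profile$removed_g, 0))
  profile$biodegradation_g <- profile$removed_g - profile$sorption_g
  profile$biodeg_share <- ifelse(profile$removed_g > 0,
                                 profile$biodegradation_g / profile$removed_g, 0)
  attr(profile, "capacity_totals") <-
    c(sum_capped_sorption_g = sum(profile$sorption_g),
      qe_times_total_mass_g = qe * sum(profile$gac_kg))
  profile
}

#' Removal vs influent concentration and the upper-envelope slope
#'
#' Pairs of same-timestamp influent TOC and concentration drop across a
#' segment, plus the slope of the upper envelope line through the origin,
#' estimated by quantile regression through the origin: for the model
#' `removed = b * toc_in`, the pinball-loss minimiser at quantile `tau` is
#' the `tau`-weighted quantile of the ratios `removed/toc_in` with weights
#' `toc_in`, computed exactly.
#'
#' @param pairs data.frame `toc_in`, `removed` (both mg/L); at least 20 rows.
#' @param tau Envelope quantile (default 0.95).
#' @return List with `pairs`, `tau` and `slope` (mgTOC removed per mgTOC in).
#' @export
removal_vs_influent <- function(pairs, tau = 0.95) {
  stopifnot(all(c("toc_in", "removed") %in% names(pairs)),
            tau > 0, tau < 1)
  pairs <- pairs[complete.cases(pairs[c("toc_in", "removed")]) &
                   pairs$toc_in > 0, ]
  if (nrow(pairs) < 20)
    stop("need at least 20 paired observations")
  r <- pairs$removed / pairs$toc_in
  w <- pairs$toc_in
  o <- order(r)
  cw <- cumsum(w[o])
  slope <- r[o][which(cw >= tau * sum(w))[1]]
  list(pairs = pairs, tau = tau, slope = slope)
}
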