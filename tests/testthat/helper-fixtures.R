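# shared fixture builders; everything is generated in code at test time

minute_flow <- function(n, flow = 1, start = as.POSIXct("2020-01-01", tz = "UTC")) {
  data.frame(time = start + 60 * (seq_len(n) - 1), flow_L_min = flow)
}

grab <- function(times, location, toc) {
  data.frame(time = times, location = location, toc_mg_L = toc)
}

# a small simulated run reused by several tests (memoised per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      op <- generate_operation_series(operation_pattern(
        duration_days = 100, peak_day = 67, backwash_day = 90, seed = 301))
      cache <<- simulate_column(filter_spec(), column_kinetics(),
                                op$flow, op$influent, backwash_day = 90)
    }
    cache
  }
})

# a bare backwash record (no background attribute) for cross-module identities
plain_backwash_record <- function(tcc = rep(4.5e6, 11), toc = rep(15.45, 11),
                                  flow = 20) {
  structure(data.frame(minute = seq_along(tcc), toc_mg_L = toc,
                       tcc_cells_mL = tcc),
            class = c("backwash_record", "data.frame"), flow_L_min = flow)
}
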