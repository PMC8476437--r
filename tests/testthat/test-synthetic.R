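test_that("generated flow matches the configured operating regime", {
  pat <- operation_pattern(duration_days = 912, seed = 101)
  op <- generate_operation_series(pat)
  expect_equal(nrow(op$flow), 912 * 1440)
  expect_true(all(op$flow$flow_L_min >= 0))
  # long-run volume within 5% of 330 L/d
  expect_lt(abs(sum(op$flow$flow_L_min) - 330 * 912) / (330 * 912), 0.05)
  daily <- tapply(op$flow$flow_L_min, (seq_len(nrow(op$flow)) - 1L) %/% 1440L, sum)
  expect_true(all(daily <= pat$max_daily_volume + 1e-9))
  # influent TOC positive with the configured extreme peak present
  expect_true(all(op$influent$toc_mg_L > 0))
  expect_equal(max(op$influent$toc_mg_L), 131)
  # the peak spans day 67; the last burst value holds into the following
  # stagnation, so no peak water appears before day 67
  peak_minutes <- which(op$influent$toc_mg_L == 131)
  expect_true(all(peak_minutes > 66 * 1440))
  expect_true(any(ceiling(peak_minutes / 1440) == 67))
  # lognormal marginal: series median near 4.8 mg/L
  expect_lt(abs(median(op$influent$toc_mg_L) - 4.8) / 4.8, 0.10)
})

test_that("degenerate and invalid operation patterns are handled", {
  op0 <- generate_operation_series(operation_pattern(
    duration_days = 5, mean_daily_volume = 0, max_daily_volume = 0,
    peak_day = NA, backwash_day = NA, seed = 1))
  expect_true(all(op0$flow$flow_L_min == 0))
  expect_error(operation_pattern(duration_days = 0, seed = 1), "positive")
  expect_error(operation_pattern(duration_days = 10, mean_daily_volume = NaN,
                                 seed = 1), "non-finite|out-of-range")
  expect_error(operation_pattern(duration_days = 10, peak_day = 99, seed = 1),
               "within")
  expect_error(operation_pattern(duration_days = 10, seed = NULL), "seed")
})

test_that("two runs with the same seed are identical", {
  pat <- function() operation_pattern(duration_days = 30, peak_day = 20,
                                      backwash_day = NA, seed = 7)
  a <- generate_operation_series(pat())
  b <- generate_operation_series(pat())
  expect_identical(a$flow, b$flow)
  expect_identical(a$influent, b$influent)
  sa <- simulate_column(filter_spec(), column_kinetics(), a$flow, a$influent)
  sb <- simulate_column(filter_spec(), column_kinetics(), b$flow, b$influent)
  expect_identical(sa$port_toc, sb$port_toc)
  expect_identical(sa$truth, sb$truth)
})

test_that("inert column passes influent through unchanged", {
  op <- generate_operation_series(operation_pattern(
    duration_days = 20, peak_day = NA, backwash_day = NA, seed = 5))
  sim <- simulate_column(filter_spec(),
                         column_kinetics(q_max = 0, k_bio = 0),
                         op$flow, op$influent)
  tr <- sim$truth
  expect_equal(tr$sorbed_g, 0)
  expect_equal(tr$biodeg_g, 0)
  # influent = effluent + holdup within 0.1% of influent
  expect_lt(abs(tr$influent_g - tr$effluent_g - tr$holdup_g) / tr$influent_g,
            1e-3)
})

test_that("an unexhaustible adsorber captures the whole influent load", {
  op <- generate_operation_series(operation_pattern(
    duration_days = 5, peak_day = NA, backwash_day = NA, seed = 5))
  sim <- simulate_column(filter_spec(),
                         column_kinetics(q_max = 1e6, c_half = 1e-3, k_bio = 0),
                         op$flow, op$influent)
  expect_lt(sim$truth$effluent_g, 1e-3 * sim$truth$influent_g)
  expect_equal(sim$truth$sorbed_g,
               sim$truth$influent_g - sim$truth$effluent_g - sim$truth$holdup_g,
               tolerance = 1e-6)
})

test_that("the simulator conserves carbon under varied kinetics", {
  for (seed in 1:3) {
    set.seed(seed)
    kin <- column_kinetics(q_max = runif(1, 1, 40), k_sorb = runif(1, 0.5, 5),
                           c_half = runif(1, 0.5, 3), k_bio = runif(1, 0, 150),
                           labile_fraction = runif(1, 0.3, 0.9))
    op <- generate_operation_series(operation_pattern(
      duration_days = 15, peak_day = 8, backwash_day = 12, seed = seed + 50))
    sim <- simulate_column(filter_spec(), kin, op$flow, op$influent,
                           backwash_day = 12)
    tr <- sim$truth
    closure <- abs(tr$influent_g -
                     (tr$effluent_g + tr$sorbed_g + tr$biodeg_g + tr$holdup_g))
    expect_lt(closure, 1e-3 * tr$influent_g)
    # biomass fate identity holds exactly (same accumulators)
    expect_equal(tr$produced_g,
                 tr$accumulated_g + tr$washed_g + tr$backwashed_g,
                 tolerance = 1e-12)
  }
})

test_that("TOC is non-increasing with depth when the column only removes", {
  # constant influent means the equilibrium loading is never overshot, so
  # no desorption occurs and every cell is removal-only
  op <- generate_operation_series(operation_pattern(
    duration_days = 12, peak_day = NA, backwash_day = NA, seed = 71))
  infl <- op$influent
  infl$toc_mg_L <- 8
  sim <- simulate_column(filter_spec(), column_kinetics(), op$flow, infl)
  flowing <- sim$flow$flow_L_min > 0
  pt <- sim$port_toc
  expect_true(all(pt$d7cm[flowing] >= pt$d22cm[flowing] - 1e-9))
  expect_true(all(pt$d22cm[flowing] >= pt$d37cm[flowing] - 1e-9))
  expect_true(all(pt$d37cm[flowing] >= pt$effluent[flowing] - 1e-9))
})

test_that("full detachment leaves no accumulated biomass", {
  op <- generate_operation_series(operation_pattern(
    duration_days = 10, peak_day = NA, backwash_day = NA, seed = 9))
  sim <- simulate_column(filter_spec(), column_kinetics(detach_fraction = 1),
                         op$flow, op$influent)
  expect_equal(sim$truth$accumulated_g, 0, tolerance = 1e-12)
})

test_that("column simulation agrees with an independent stiff-ODE reference", {
  skip_if_not_installed("deSolve")
  spec <- filter_spec()
  kin <- column_kinetics(q_max = 0.3, c_half = 2, k_sorb = 2, k_bio = 60)
  hours <- 48
  nmin <- hours * 60
  cin <- function(t) ifelse(t >= 20 * 60 & t < 24 * 60, 131, 10)
  flow <- minute_flow(nmin, 0.5)
  infl <- data.frame(time = flow$time, toc_mg_L = cin(0:(nmin - 1)))
  sim <- simulate_column(spec, kin, flow, infl)
  ref <- ref_column(spec, kin, 0.5, cin, hours)
  expect_lt(abs(sim$truth$effluent_g - ref$effluent_g) / ref$effluent_g, 0.01)
  expect_lt(abs(sim$truth$sorbed_g - ref$sorbed_g) / ref$sorbed_g, 0.01)
  expect_lt(abs(sim$truth$biodeg_g - ref$biodeg_g) / ref$biodeg_g, 0.05)
  expect_lt(max(abs(sim$cells$q_final - ref$q) / ref$q), 0.02)
})

test_that("remaining capacity at the bottom buffers an extreme influent peak", {
  sim <- small_sim()   # default kinetics, 131 mg/L peak on day 67
  pt <- sim$port_toc
  flowing <- sim$flow$flow_L_min > 0
  day <- rep(seq_len(nrow(sim$daily)), each = 1440)[seq_len(nrow(pt))]
  # effluent stays below 5% of the peak while it passes
  expect_lt(max(pt$effluent[day == 67]), 0.05 * 131)
  # the exhausted top segment desorbs afterwards: elevated 7 cm TOC decaying
  pre <- quantile(pt$d7cm[day %in% 55:65 & flowing], 0.95)
  post <- max(pt$d7cm[day %in% 68:75 & flowing])
  late <- max(pt$d7cm[day %in% 85:95 & flowing])
  expect_gt(post, 2 * pre)
  expect_lt(late, post)
})

test_that("grab samples reproduce the simulated record", {
  sim <- small_sim()
  s0 <- generate_grab_samples(sim, noise_cv = 0)
  # noise-free samples equal the simulated concentration exactly
  idx <- match(as.numeric(s0$time[s0$location == "effluent"]),
               as.numeric(sim$flow$time))
  expect_equal(s0$toc_mg_L[s0$location == "effluent"],
               sim$port_toc$effluent[idx])
  # all samples taken at flowing minutes
  expect_true(all(sim$flow$flow_L_min[match(as.numeric(unique(s0$time)),
                                            as.numeric(sim$flow$time))] > 0))
  # twice-weekly schedule: about 2/7 samples per location-day
  n_eff <- sum(s0$location == "effluent")
  expect_gt(n_eff, 100 * 2 / 7 * 0.8)
  expect_lt(n_eff, 100 * 2 / 7 * 2.2)  # event window adds extra samples
  # explicit request at a stagnant minute errors
  stag <- sim$flow$time[which(sim$flow$flow_L_min == 0)[10]]
  expect_error(generate_grab_samples(sim, at = stag), "flow")
  expect_error(generate_grab_samples(
    sim, at = sim$flow$time[1] - 3600), "window")
})

test_that("912-day campaign yields about 260 samples per location", {
  op <- generate_operation_series(operation_pattern(duration_days = 912, seed = 61))
  sim <- simulate_column(filter_spec(), column_kinetics(), op$flow, op$influent,
                         backwash_day = 836)
  s <- generate_grab_samples(sim, seed = 62)
  n <- sum(s$location == "influent")
  # 912 / 7 * 2 = 260 scheduled, plus the event-window extras
  expect_gt(n, 240)
  expect_lt(n, 320)
})

test_that("backwash event record conserves the removed biomass", {
  sim <- small_sim()
  rec <- generate_backwash_event(sim)
  expect_equal(nrow(rec), 11)
  expect_equal(attr(rec, "flow_L_min"), 20)
  carbon <- biomass_backwash(rec)
  expect_equal(carbon, sim$truth$backwashed_g, tolerance = 1e-9)
  expect_equal(attr(rec, "removed_biomass_g"), sim$truth$backwashed_g)
  expect_error(generate_backwash_event(sim, flow_L_min = 0), "positive")
  # no backwash configured -> no record
  op <- generate_operation_series(operation_pattern(
    duration_days = 5, peak_day = NA, backwash_day = NA, seed = 3))
  sim2 <- simulate_column(filter_spec(), column_kinetics(), op$flow, op$influent)
  expect_error(generate_backwash_event(sim2), "without a backwash")
})

test_that("zero backwashable fraction leaves biomass and samples at background", {
  op <- generate_operation_series(operation_pattern(
    duration_days = 20, peak_day = NA, backwash_day = 15, seed = 31))
  sim <- simulate_column(filter_spec(), column_kinetics(), op$flow, op$influent,
                         backwash_day = 15, backwash_fraction = 0)
  expect_equal(sim$truth$backwashed_g, 0)
  rec <- generate_backwash_event(sim, fines_toc_g = 0)
  expect_true(all(rec$tcc_cells_mL == attr(rec, "background_tcc")))
})

test_that("ATP inventory converts attached biomass consistently", {
  sim <- small_sim()
  inv <- atp_inventory(sim)
  const <- conversion_constants()
  expect_equal(inv$total_g_atp * const$cells_per_gATP * const$carbon_per_cell,
               sum(sim$cells$x_final), tolerance = 1e-12)
  expect_equal(nrow(inv$table), 3)
  expect_true(all(inv$table$atp_g_per_gGAC > 0))
})

test_that("pressure loss ramps with biomass and resets at the backwash", {
  sim <- small_sim()  # backwash on day 90
  pl <- pressure_loss_series(sim)
  expect_true(all(pl$loss_mbar <= 22))
  expect_true(all(diff(pl$loss_mbar[1:80]) >= -1e-9))
})
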