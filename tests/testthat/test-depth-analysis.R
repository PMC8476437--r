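make_design <- function(n = 40) {
  data.frame(day = seq(150, 900, length.out = n),
             toc_in = rep(c(2, 5, 9, 16), length.out = n),
             ebct = rep(c(30, 78, 120, 166), each = ceiling(n / 4))[1:n])
}

test_that("noise-free regression recovers the generating coefficients", {
  b <- c(0.23, 0.080, -0.019, -4.83e-6)
  d <- make_design()
  d$ratio <- b[1] + b[2] * d$day / 365 + b[3] * d$toc_in + b[4] * d$ebct
  fit <- suppressWarnings(fit_removal_model(d, depth = "effluent"))
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  expect_equal(fit$n, nrow(d))
})

test_that("constant ratios yield zero slopes and the ratio as intercept", {
  d <- make_design()
  d$ratio <- 0.42
  fit <- suppressWarnings(fit_removal_model(d))
  expect_equal(unname(coef(fit)[1]), 0.42, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[2:4]), rep(0, 3), tolerance = 1e-10)
})

test_that("regression guards its window and design", {
  d <- make_design()
  d$ratio <- 0.5
  expect_error(fit_removal_model(d[1:5, ]), "at least 10")
  d2 <- d
  d2$ebct <- 78                            # constant regressor
  d2$ratio <- 0.2 + 0.1 * d2$day / 365
  expect_error(fit_removal_model(d2), "singular design.*ebct")
  # day-140 cutoff is inclusive and drops earlier data
  d3 <- rbind(d, transform(d[1:10, ], day = 10, ratio = 99))
  d3$ratio[seq_len(nrow(d))] <- 0.5
  fit <- suppressWarnings(fit_removal_model(d3))
  expect_equal(fit$n, nrow(d))
})

test_that("noisy regression recovers the drift coefficient within its CI", {
  b <- c(0.23, 0.080, -0.019, -4.83e-6)
  set.seed(42)
  d <- data.frame(day = runif(200, 140, 910),
                  toc_in = exp(rnorm(200, log(4.8), 0.5)),
                  ebct = runif(200, 15, 166))
  d$ratio <- b[1] + b[2] * d$day / 365 + b[3] * d$toc_in + b[4] * d$ebct +
    rnorm(200, 0, 0.05)
  fit <- fit_removal_model(d)
  ci <- confint(fit$fit)["years", ]
  expect_gt(0.080, ci[1])
  expect_lt(0.080, ci[2])
})

test_that("effect sizes convert coefficient x delta with unit handling", {
  f <- structure(list(coefficients = c(b0 = 0.31, b1_per_year = 0.182,
                                       b2_L_per_mg = -0.019,
                                       b3_per_min = -0.00096)),
                 class = "bac_removal_lm")
  expect_equal(round(effect_size(f, days = 770), 2), 0.38)
  f$coefficients[["b2_L_per_mg"]] <- -0.022
  expect_equal(round(abs(effect_size(f, toc_in = 19.1 - 1.9)), 1), 0.4)
  expect_equal(effect_size(f, ebct = 0), 0)
  expect_error(effect_size(f, days = 1, ebct = 1), "exactly one")
  expect_error(effect_size(f), "exactly one")
})

test_that("segment removal telescopes and reproduces the share arithmetic", {
  prof <- segment_removal(c(0, 604, 850, 973, 1024))
  expect_equal(prof$removed_g, c(604, 246, 123, 51))
  expect_equal(round(100 * prof$share), c(59, 24, 12, 5))
  expect_equal(sum(prof$removed_g), 1024)        # telescoping, exact
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  prof0 <- segment_removal(rep(0, 5))
  expect_true(all(prof0$removed_g == 0))
  expect_error(segment_removal(c(0, 1, 2)), "segments")
})

test_that("per-segment sorption is capped at capacity and at removal", {
  prof <- segment_removal(c(0, 604.2, 850, 973, 1024))
  sp <- segment_sorption_split(prof, 25.6)
  # top segment: capacity-capped sorption, biodegradation share ~89%
  expect_equal(sp$sorption_g[1], 25.6 * 20 * 7 / 52, tolerance = 1e-6)
  expect_equal(sp$sorption_g[1], 68.9, tolerance = 1e-3)
  expect_equal(round(100 * sp$biodeg_share[1]), 89)
  # lower segments removed less than capacity: all sorption
  expect_true(all(sp$biodegradation_g[sp$removed_g < 25.6 * sp$gac_kg] == 0))
  # q_e = 0 -> everything biodegradation
  sp0 <- segment_sorption_split(prof, 0)
  expect_equal(sp0$biodegradation_g, sp0$removed_g)
  # cap properties on random profiles
  set.seed(21)
  for (i in 1:10) {
    p <- segment_removal(cumsum(c(0, runif(4, 0, 400))))
    s <- segment_sorption_split(p, runif(1, 0, 40))
    expect_true(all(s$sorption_g <= p$removed_g + 1e-12))
    caps <- attr(s, "capacity_totals")
    expect_lte(caps["sum_capped_sorption_g"], caps["qe_times_total_mass_g"] + 1e-12)
  }
})

test_that("the envelope slope is the exact pinball-loss minimiser", {
  # exact envelope: all points on removed = 0.85 toc_in
  toc_in <- seq(2, 19, length.out = 40)
  ex <- removal_vs_influent(data.frame(toc_in = toc_in, removed = 0.85 * toc_in))
  expect_equal(ex$slope, 0.85, tolerance = 1e-12)
  # 95% of the mass on the line, the rest below it
  set.seed(14)
  n <- 400
  toc_in <- runif(n, 1.9, 19.1)
  on_line <- runif(n) < 0.95
  removed <- ifelse(on_line, 0.85 * toc_in, runif(n, 0, 0.7) * toc_in)
  env <- removal_vs_influent(data.frame(toc_in = toc_in, removed = removed))
  expect_gt(env$slope, 0.83)
  expect_lt(env$slope, 0.87)
  # agreement with a numerical pinball-loss oracle on irregular data
  removed2 <- runif(n, 0, 1) * toc_in
  env2 <- removal_vs_influent(data.frame(toc_in = toc_in, removed = removed2))
  oracle <- pinball_slope(toc_in, removed2, 0.95)
  expect_equal(env2$slope, oracle, tolerance = 2e-3)
  # degenerate and undersized inputs
  expect_equal(removal_vs_influent(
    data.frame(toc_in = toc_in, removed = 0))$slope, 0)
  expect_error(removal_vs_influent(
    data.frame(toc_in = 1:5, removed = 1:5)), "at least 20")
})

test_that("ratio observations attach EBCT from the flowing interval", {
  op <- generate_operation_series(operation_pattern(
    duration_days = 30, peak_day = NA, backwash_day = NA, seed = 41))
  sim <- simulate_column(filter_spec(), column_kinetics(), op$flow, op$influent)
  samples <- generate_grab_samples(sim, noise_cv = 0)
  obs <- ratio_observations(samples, op$flow, "effluent")
  expect_true(all(is.finite(obs$ebct)))
  expect_true(all(obs$ebct > 0))
  # EBCT = whole-bed empty volume / in-burst flow, within the burst-rate range
  bed_L <- filter_spec()$bed_volume_L
  expect_true(all(obs$ebct >= bed_L / 2.45 - 1 & obs$ebct <= bed_L / 0.2 + 1))
  expect_true(all(obs$ratio > 0))
})
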