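test_that("q_e estimation and sorbed mass follow the integral balance", {
  expect_equal(estimate_qe(78.77, 0.65, 2.0), 25.6, tolerance = 1e-3)
  expect_equal(estimate_qe(100, 0, 2.0), 0)
  expect_error(estimate_qe(100, 0.5, 0), "positive")
  expect_equal(sorbed_mass(25.6, 20), 512)
  expect_equal(sorbed_mass(14.7, 20), 294)
  expect_equal(sorbed_mass(0, 20), 0)
})

test_that("biomass conversions reproduce the hand arithmetic", {
  expect_equal(biomass_accumulated(0.0686), 0.1509, tolerance = 1e-3)
  expect_equal(biomass_accumulated(
    0.0686, conversion_constants(cells_per_gATP = 4.8e13)),
    0.0659, tolerance = 1e-3)
  expect_equal(biomass_accumulated(0), 0)

  expect_equal(biomass_washedout(3.3e5, 8.6e5, 330 * 912), 3.19,
               tolerance = 1e-3)
  expect_equal(biomass_washedout(5e5, 5e5, 1e6), 0)
  expect_equal(biomass_washedout(3.3e5, 3.2e6, 330 * 912), 17.275,
               tolerance = 1e-4)     # prints as 17.3
  expect_warning(neg <- biomass_washedout(8.6e5, 3.3e5, 330 * 912), "negative")
  expect_lt(neg, 0)

  rec <- plain_backwash_record()
  expect_equal(biomass_backwash(rec), 11 * 20 * 4.5e6 * 1000 * 2e-14,
               tolerance = 1e-12)                     # 0.0198 g
  expect_equal(biomass_backwash(rec), 0.0198, tolerance = 1e-3)
  expect_equal(biomass_backwash(plain_backwash_record(tcc = rep(0, 11))), 0)
  expect_equal(biomass_backwash(plain_backwash_record(tcc = rep(9e6, 11))),
               2 * biomass_backwash(rec))             # linearity
  expect_error(biomass_backwash(rec, flow_L_min = -1), "positive")
})

test_that("the balance identities hold exactly on every result", {
  set.seed(8)
  for (i in 1:25) {
    removed <- runif(1, 0, 2000)
    mb <- mass_balance(removed, runif(1, 0, 2500), runif(1, 0, 1),
                       runif(1, 0, 20), runif(1, 0, 0.1))
    expect_identical(mb$biodegraded_g, mb$removed_g - mb$sorbed_g)
    expect_identical(mb$co2_g, mb$biodegraded_g - mb$assimilated_g)
    expect_identical(mb$assimilated_g,
                     mb$accumulated_g + mb$washedout_g + mb$backwash_g)
    expect_identical(mb$infeasible, mb$biodegraded_g < 0)
    if (mb$assimilated_g > 0)
      expect_equal(mb$accumulated_share_of_assim + mb$washedout_share_of_assim +
                     mb$backwash_share_of_assim, 1, tolerance = 1e-12)
  }
})

test_that("the main-case balance reproduces the reported fate shares", {
  mb <- mass_balance(1024, 512,
                     accumulated_g = biomass_accumulated(0.0686),
                     washedout_g = biomass_washedout(3.3e5, 8.6e5, 330 * 912),
                     backwash_g = biomass_backwash(plain_backwash_record()))
  f <- fractions_pct(mb)
  expect_equal(unname(f["sorption_of_removed"]), 50)
  expect_equal(unname(f["assimilated_of_biodegraded"]), 1)
  expect_equal(unname(f["co2_of_biodegraded"]), 99)
})

test_that("degenerate and infeasible balances are flagged, not clipped", {
  mb0 <- mass_balance(10, 10)
  expect_equal(mb0$biodegraded_g, 0)
  expect_equal(mb0$co2_g, 0)
  expect_false(mb0$infeasible)
  mbi <- mass_balance(10, 12)
  expect_equal(mbi$biodegraded_g, -2)
  expect_true(mbi$infeasible)
  expect_output(print(mbi), "INFEASIBLE")
})

test_that("scenario sweep spans the assumption axes correctly", {
  sw <- scenario_sweep(
    removed_g = 1024, gac_mass_kg = 20, atp_g = 0.0686,
    tcc_in = 3.3e5, tcc_out_measured = 8.6e5, tcc_out_turbidity = 3.2e6,
    volume_integrated_L = 330 * 912,
    backwash_cells = 0.0198 / 2e-14)
  expect_equal(nrow(sw), 3 * 3 * 2)
  # shaking ATP conversion: accumulated share of assimilated rounds to 2%
  row <- sw[sw$atp == "shaking" & sw$tcc_source == "measured" &
              sw$qe == "base", ]
  expect_equal(row$accumulated_of_assimilated, 2)
  # turbidity-derived effluent TCC: washed-out share rounds to 99%
  row <- sw[sw$atp == "sonication" & sw$tcc_source == "turbidity" &
              sw$qe == "base", ]
  expect_equal(row$washedout_of_assimilated, 99)
  # sorption share strictly increasing in q_e at fixed removed load
  shares <- sw$sorption_of_removed[sw$atp == "sonication" &
                                     sw$tcc_source == "measured"]
  qe <- sw$qe_mg_g[sw$atp == "sonication" & sw$tcc_source == "measured"]
  expect_true(all(diff(shares[order(qe)]) > 0))
  expect_error(scenario_sweep(1024, 20, 0.0686, 3.3e5, 8.6e5, 3.2e6,
                              330 * 912, backwash_cells = 0,
                              qe = numeric(0)), "at least one")
})
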