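test_that("apparent permeability follows the receiver-slope formula", {
  tt <- seq(0, 7200, by = 600)
  flat <- caco2_assay(tt, rep(0.5, length(tt)))
  expect_equal(apparent_permeability(flat), 0)
  # slope 1.35e-5 uM/s with the 96-well geometry reproduces the measured
  # A-to-B permeability (oracle: direct formula evaluation)
  a <- caco2_assay(tt, 1.35e-5 * tt, c0_donor_um = 10, v_receiver_ml = 0.1,
                   area_cm2 = 0.0804)
  expect_equal(apparent_permeability(a),
               1.35e-5 * 0.1 / (0.0804 * 10), tolerance = 1e-12)
  expect_equal(apparent_permeability(a), 1.68e-6, tolerance = 0.01)
  # linear in 1/C0
  a2 <- caco2_assay(tt, 1.35e-5 * tt, c0_donor_um = 20)
  expect_equal(apparent_permeability(a2), apparent_permeability(a) / 2)
  expect_error(apparent_permeability(caco2_assay(c(0, 0), c(0, 1))),
               "identical")
})

test_that("efflux ratios match the measured Caco-2 values", {
  expect_equal(efflux_ratio(1.68e-6, 3.74e-6), 2.22, tolerance = 0.01)
  expect_equal(efflux_ratio(0.65, 14.64), 22.48, tolerance = 0.01)
  for (x in c(1e-7, 3e-6, 2)) expect_equal(efflux_ratio(x, x), 1)
  expect_error(efflux_ratio(0, 1), "positive")
})

test_that("recovery formulas are exact and unit-scale invariant", {
  full <- caco2_assay(c(0, 3600), c(0, 0), c0_donor_um = 10,
                      final_donor_um = 10, final_receiver_um = 0,
                      cell_lysate_um = 0)
  expect_equal(recovery(full), list(recovery_pct = 100,
                                    total_recovery_pct = 100))
  a <- caco2_assay(c(0, 3600), c(0, 0.3), c0_donor_um = 10,
                   v_receiver_ml = 0.25, v_donor_ml = 0.1,
                   final_donor_um = 2, final_receiver_um = 0.3,
                   cell_lysate_um = 1, v_cell_ml = 0.1)
  r <- recovery(a)
  expect_equal(r$recovery_pct, 27.5)       # hand evaluation
  expect_equal(r$total_recovery_pct, 37.5)
  expect_gt(r$total_recovery_pct, r$recovery_pct)
  # relabelling the concentration unit leaves percents unchanged
  a10 <- caco2_assay(c(0, 3600), c(0, 3), c0_donor_um = 100,
                     v_receiver_ml = 0.25, v_donor_ml = 0.1,
                     final_donor_um = 20, final_receiver_um = 3,
                     cell_lysate_um = 10, v_cell_ml = 0.1)
  expect_equal(recovery(a10), r)
})

test_that("fraction unbound is the equilibrium buffer/plasma ratio", {
  expect_equal(fraction_unbound(1, 1), 1)
  expect_equal(fraction_unbound(1, 0), 0)
  expect_equal(fraction_unbound(1, 0.009), 0.009)  # measured human value
  expect_error(fraction_unbound(0, 0.1), "positive")
})

test_that("microsomal depletion half-lives match the closed form", {
  tt <- c(0, 10, 20, 40, 60, 90)
  h <- depletion_half_life(tt, exp(-0.0066 * tt))
  expect_false(h$stable)
  expect_equal(h$t_half, 105, tolerance = 0.001)
  m <- depletion_half_life(tt, exp(-0.01 * tt))
  expect_equal(m$t_half, 69.3, tolerance = 0.001)
  flat <- depletion_half_life(tt, rep(1, length(tt)))
  expect_true(flat$stable)
  expect_equal(flat$t_half, Inf)
})

test_that("the microsome-to-CLint-to-CLh chain reproduces all four species", {
  mic <- microsome_table()
  expected <- data.frame(
    species = c("beagle", "mouse", "monkey", "human"),
    clint = c(12.7, 78.8, 22.4, 15.3),
    clh = c(9, 42, 14.8, 8.8),
    extraction = c(29.1, 46.6, 33.9, 42.5))
  for (i in seq_len(nrow(expected))) {
    row <- mic[mic$species == expected$species[i], ]
    clint <- scale_clint(row$t_half_min, species = row$species)
    clh <- well_stirred_clh(clint, row$qh_ml_min_kg)
    expect_equal(clint, expected$clint[i], tolerance = 0.01)
    expect_equal(clh, expected$clh[i], tolerance = 0.01)
    expect_equal(hepatic_extraction(clh, row$qh_ml_min_kg),
                 expected$extraction[i], tolerance = 0.005)
  }
  expect_equal(scale_clint(Inf, species = "human"), 0)  # stable-compound limit
})

test_that("well-stirred clearance is bounded, monotone and flow-limited", {
  qh <- 20.7
  cls <- vapply(c(0.1, 1, 10, 100, 1e4, 1e8), well_stirred_clh, numeric(1),
                qh = qh)
  expect_true(all(diff(cls) > 0))
  expect_true(all(cls >= 0 & cls < qh))
  expect_equal(cls[length(cls)], qh, tolerance = 1e-3)   # CLint -> Inf
  expect_equal(well_stirred_clh(0.01, qh), 0.01, tolerance = 1e-3)  # restrictive
  expect_error(well_stirred_clh(1, 0), "positive")
  expect_error(hepatic_extraction(21, 20.7), "CLh < Qh")
})

test_that("TNR phenotyping normalises isoform contributions", {
  panel <- cyp_panel_table()
  res <- tnr_phenotyping(panel)
  expect_equal(sum(res$percent), 100, tolerance = 1e-10)
  # the published normalised rates are the authoritative inputs
  res2 <- tnr_phenotyping(rate = panel$normalized_rate_reported,
                          abundance = rep(1, nrow(panel)),
                          isoform = panel$isoform)
  expect_equal(res2$percent[res2$isoform == "CYP3A4"], 78.15,
               tolerance = 0.01)
  expect_equal(res2$percent[res2$isoform == "CYP1A2"], 12.49,
               tolerance = 0.01)
  single <- tnr_phenotyping(rate = 2.2, abundance = 50, isoform = "CYP3A4")
  expect_equal(single$percent, 100)
  expect_error(tnr_phenotyping(rate = c(0, 0), abundance = c(1, 1)),
               "zero")
})
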