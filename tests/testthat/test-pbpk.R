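monkey_model <- function(cl = 2.811, renal_fraction = 0, cmpd = NULL,
                         bw = 4.5, ...) {
  cmpd <- cmpd %||% compound_properties()
  phys <- species_physiology("monkey", body_weight = bw)
  kp <- predict_kp(cmpd, "monkey", "rodgers_single")
  pbpk_model(cmpd, phys, kp, cl, renal_fraction = renal_fraction, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("model assembly validates clearance and tissue coverage", {
  cmpd <- compound_properties()
  phys <- species_physiology("monkey")
  kp <- predict_kp(cmpd, "monkey", "rodgers_single")
  expect_error(pbpk_model(cmpd, phys, kp, clearance_l_h = 100),
               "blood flow")
  expect_error(pbpk_model(cmpd, phys, kp[names(kp) != "muscle"], 1),
               "lacks tissues")
  expect_s3_class(pbpk_model(cmpd, phys, kp, 0), "pbpk_model")
})

test_that("mass is conserved with and without elimination", {
  mod0 <- monkey_model(cl = 0)
  sim0 <- simulate_pbpk(mod0, dosing_regimen(13.5, route = "iv_bolus"),
                        t_end = 48)
  # no elimination: everything stays in the body
  in_body <- rowSums(sim0$amounts[, !colnames(sim0$amounts) %in%
    c("elim_hepatic", "elim_renal", "elim_gut_fp", "feces")])
  keep <- sim0$time > 0
  expect_lt(max(abs(in_body[keep] - 13.5) / 13.5), 1e-4)

  mod <- monkey_model(cl = 2.811)
  for (route in c("iv_bolus", "oral")) {
    sim <- simulate_pbpk(mod, dosing_regimen(13.5, route = route),
                         t_end = 48)
    expect_lt(mass_balance_error(sim), 1e-4)
  }
})

test_that("simulated intravenous dose/AUC returns the input clearance", {
  for (cl in c(1.0, 2.811)) {
    sim <- simulate_pbpk(monkey_model(cl = cl),
                         dosing_regimen(13.5, route = "iv_bolus"),
                         t_end = 400, dt = 0.1)
    auc_inf <- tissue_exposure(sim, "plasma")$auc_0_inf
    cl_sim <- 13.5 * 1e3 / auc_inf   # mg over ng.h/mL -> L/h
    expect_equal(cl_sim, cl, tolerance = 0.01)
  }
})

test_that("monkey intravenous exposure reproduces the observed AUC", {
  sim <- simulate_pbpk(monkey_model(cl = 2.811),
                       dosing_regimen(3 * 4.5, route = "iv_bolus"),
                       t_end = 400, dt = 0.1)
  expect_equal(tissue_exposure(sim, "plasma")$auc_0_inf, 4802.7,
               tolerance = 0.01)
})

test_that("a fast-perfused uniform model collapses to one compartment", {
  cmpd <- compound_properties(blood_plasma_ratio = 1)
  phys <- species_physiology("monkey")
  # speed every flow up so perfusion no longer limits mixing
  phys$cardiac_output_l_h <- phys$cardiac_output_l_h * 80
  phys$qh_l_h <- phys$qh_l_h * 80
  phys$tissues$flow_l_h <- phys$tissues$flow_l_h * 80
  kp <- predict_kp(cmpd, "monkey", "rodgers_single")
  ones <- structure(rep(1, length(kp)), names = names(kp), class = "kp_set")
  v_tot <- phys$plasma_l * 0 + phys$venous_l + phys$arterial_l + phys$lung_l +
    sum(phys$tissues$volume_l)
  cl <- 2
  mod <- pbpk_model(cmpd, phys, ones, cl)
  sim <- simulate_pbpk(mod, dosing_regimen(10, route = "iv_bolus"),
                       t_end = 24)
  tt <- c(0.5, 1, 2, 4, 8, 16, 24)
  pred <- sim$conc[match(tt, sim$time), "plasma"]
  analytic <- one_compartment_conc(tt, 10, cl, v_tot)
  expect_equal(pred, analytic, tolerance = 0.005)

  # with no elimination all compartments equilibrate to one concentration
  mod0 <- pbpk_model(cmpd, phys, ones, 0)
  sim0 <- simulate_pbpk(mod0, dosing_regimen(10, route = "iv_bolus"),
                        t_end = 48)
  final <- sim0$conc[nrow(sim0$conc), ]
  final <- final[!names(final) %in% c("venous_blood", "arterial_blood")]
  expect_lt(diff(range(final)) / mean(final), 1e-3)
})

test_that("disposition is linear in dose and obeys superposition", {
  mod <- monkey_model(cl = 2.811)
  s1 <- simulate_pbpk(mod, dosing_regimen(5, route = "iv_bolus"), t_end = 72)
  s2 <- simulate_pbpk(mod, dosing_regimen(10, route = "iv_bolus"), t_end = 72)
  keep <- s1$time > 0
  expect_equal(s2$conc[keep, ], 2 * s1$conc[keep, ], tolerance = 1e-6)

  # oral linearity below the solubility limit
  o1 <- simulate_pbpk(mod, dosing_regimen(1e-5, route = "oral"), t_end = 48)
  o2 <- simulate_pbpk(mod, dosing_regimen(2e-5, route = "oral"), t_end = 48)
  keep <- o1$time > 1 & o1$conc[, "plasma"] > 0
  expect_equal(o2$conc[keep, "plasma"], 2 * o1$conc[keep, "plasma"],
               tolerance = 1e-4)

  # two doses 24 h apart equal the sum of shifted single-dose solutions
  dual <- simulate_pbpk(mod, dosing_regimen(13.5, route = "oral", n = 2,
                                            interval_h = 24), t_end = 72)
  single <- simulate_pbpk(mod, dosing_regimen(13.5, route = "oral"),
                          t_end = 72)
  grid <- seq(1, 72, by = 0.5)
  f1 <- approxfun(single$time, single$conc[, "plasma"])
  fd <- approxfun(dual$time, dual$conc[, "plasma"])
  expected <- f1(grid) + ifelse(grid > 24 + 1, f1(grid - 24), 0)
  expect_equal(fd(grid)[grid > 25], expected[grid > 25], tolerance = 1e-3)
  expect_equal(fd(grid)[grid < 24], f1(grid)[grid < 24], tolerance = 1e-6)
})

test_that("oral bioavailability factors behave mechanistically", {
  cmpd <- compound_properties()
  phys <- species_physiology("monkey", body_weight = 4.5)
  kp <- predict_kp(cmpd, "monkey", "rodgers_single")
  # complete gut first-pass extinguishes systemic exposure
  ab0 <- absorption_params(phys, cmpd, fg = 0)
  mod0 <- pbpk_model(cmpd, phys, kp, 2.811, absorption = ab0)
  sim0 <- simulate_oral(mod0, dosing_regimen(13.5, route = "oral"),
                        t_end = 48)
  expect_equal(max(sim0$conc[, "plasma"]), 0)

  # Fa ~ 1, Fg = 1 and extrahepatic (renal) elimination: oral equals iv
  ab1 <- absorption_params(phys, cmpd, fg = 1, kd_per_h = 500,
                           solubilization_factor = 1)
  ab1$ka_per_h <- 50
  mod1 <- pbpk_model(cmpd, phys, kp, 1.0, renal_fraction = 1,
                     absorption = ab1)
  reg <- dosing_regimen(13.5, route = "oral")
  # dose far below the solubility limit so dissolution is not limiting
  reg$amount <- 1e-4
  oral <- simulate_pbpk(mod1, reg, t_end = 500, dt = 0.1)
  iv <- simulate_pbpk(mod1, dosing_regimen(1e-4, route = "iv_bolus"),
                      t_end = 500, dt = 0.1)
  expect_equal(tissue_exposure(oral, "plasma")$auc_0_inf,
               tissue_exposure(iv, "plasma")$auc_0_inf, tolerance = 0.01)
})

test_that("tissue exposure follows the perfusion-limited Kp identity", {
  mod <- monkey_model(cl = 2.811)
  sim <- simulate_pbpk(mod, dosing_regimen(13.5, route = "iv_bolus"),
                       t_end = 400, dt = 0.1)
  ex <- tissue_exposure(sim, c("plasma", "muscle", "brain", "heart"))
  auc_p <- ex$auc_0_inf[ex$compartment == "plasma"]
  for (ts in c("muscle", "brain", "heart"))
    expect_equal(ex$auc_0_inf[ex$compartment == ts],
                 unname(mod$kp[ts]) * auc_p, tolerance = 0.01)
  expect_error(tissue_exposure(sim, "bone"), "available")
})

test_that("moment-based Vss agrees with the Kp-volume sum", {
  cl <- 1.0
  mod <- monkey_model(cl = cl)
  sim <- simulate_pbpk(mod, dosing_regimen(13.5, route = "iv_bolus"),
                       t_end = 600, dt = 0.1)
  t <- sim$time; c <- sim$conc[, "plasma"]
  tail_i <- t >= max(t) * 0.7
  lam <- -unname(lsfit(t[tail_i], log(c[tail_i]))$coefficients[2])
  clast <- c[length(c)]; tlast <- t[length(t)]
  auc <- e0703pk:::trapz_pk(t, c, "linear") + clast / lam
  aumc <- e0703pk:::trapz_pk(t, c, "linear", 1L) +
    clast * tlast / lam + clast / lam^2
  vss_moment <- (13.5 * 1e3 / auc) * (aumc / auc)
  vss_sum <- vss_from_kp(structure(mod$kp, class = "kp_set"),
                         mod$physiology)
  expect_equal(vss_moment, vss_sum, tolerance = 0.02)
})

test_that("simulation interface validates inputs", {
  mod <- monkey_model()
  expect_error(simulate_pbpk(mod, dosing_regimen(1, time_h = 10,
                                                 route = "oral"),
                             t_end = 5), "beyond the last dose")
  expect_error(simulate_oral(mod, dosing_regimen(1, route = "iv_bolus")),
               "oral")
  sim <- simulate(mod, regimen = dosing_regimen(1, route = "oral"),
                  t_end = 12)
  expect_s3_class(sim, "pbpk_sim")
  df <- as.data.frame(sim)
  expect_true(all(c("time_h", "plasma", "muscle") %in% colnames(df)))
})
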