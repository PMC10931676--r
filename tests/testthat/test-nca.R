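test_that("trapezoidal AUC handles degenerate and simple shapes", {
  z <- pk_profile(c(0, 1), c(0, 0), dose = 1, dose_per_kg = TRUE,
                  route = "oral", species = "mouse", body_weight = 0.02)
  expect_equal(compute_auc(z, "linear"), 0)
  r <- pk_profile(0:10, rep(1, 11), dose = 1, dose_per_kg = TRUE,
                  route = "oral", species = "mouse", body_weight = 0.02)
  expect_equal(compute_auc(r, "linear"), 10)
  expect_equal(compute_auc(r, "linear_up_log_down"), 10)
})

test_that("AUC matches fine-grid quadrature of the same interpolant", {
  tt <- 0:12
  p <- exp_profile(tt, c0 = 100, k = 0.3)
  # independent oracle: 10,000-step numeric integration of the piecewise
  # interpolant (linear, or exponential between declining samples)
  quad <- function(logdown) {
    total <- 0
    for (i in seq_len(length(tt) - 1)) {
      tg <- seq(tt[i], tt[i + 1], length.out = 10000)
      c1 <- p$conc[i]; c2 <- p$conc[i + 1]
      cg <- if (logdown && c1 > 0 && c2 > 0 && c2 < c1) {
        k <- log(c1 / c2) / (tt[i + 1] - tt[i])
        c1 * exp(-k * (tg - tt[i]))
      } else {
        c1 + (c2 - c1) * (tg - tt[i]) / (tt[i + 1] - tt[i])
      }
      total <- total + sum((cg[-1] + cg[-length(cg)]) / 2 * diff(tg))
    }
    total
  }
  expect_equal(compute_auc(p, "linear"), quad(FALSE), tolerance = 1e-3)
  expect_equal(compute_auc(p, "linear_up_log_down"), quad(TRUE),
               tolerance = 1e-3)
})

test_that("AUC is additive over an interior sample point", {
  p <- exp_profile(0:12)
  for (split in c(3, 7)) {
    left <- pk_profile(p$time[1:(split + 1)], p$conc[1:(split + 1)], dose = 5,
                       dose_per_kg = TRUE, route = "oral", species = "mouse",
                       body_weight = 0.02)
    right <- pk_profile(p$time[(split + 1):13], p$conc[(split + 1):13],
                        dose = 5, dose_per_kg = TRUE, route = "oral",
                        species = "mouse", body_weight = 0.02)
    for (m in c("linear", "linear_up_log_down"))
      expect_equal(compute_auc(p, m),
                   compute_auc(left, m) + compute_auc(right, m))
  }
})

test_that("terminal slope is exact on a mono-exponential and excludes Cmax", {
  tt <- c(0, 1, 2, 4, 6, 8, 10)
  p <- pk_profile(tt, 50 * exp(-0.2 * tt), dose = 3, dose_per_kg = TRUE,
                  route = "intravenous", species = "monkey", body_weight = 4.5)
  lz <- estimate_lambda_z(p)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.2, tolerance = 1e-10)

  # rising-falling oral profile: the Cmax sample itself must not enter
  ka <- 2; k <- 0.2
  tt2 <- c(0, 0.5, 1, 2, 4, 6, 8, 12)
  cc <- exp(-k * tt2) - exp(-ka * tt2)
  p2 <- pk_profile(tt2, 100 * cc, dose = 5, dose_per_kg = TRUE,
                   route = "oral", species = "mouse", body_weight = 0.02)
  imax <- which.max(p2$conc)
  lz2 <- estimate_lambda_z(p2)
  expect_true(lz2$n_points <= length(tt2) - imax)
  expect_gt(lz2$lambda_z, 0)
})

test_that("terminal slope approaches the slow eigenvalue of a biexponential", {
  # C(t) = A exp(-a t) + B exp(-b t); terminal samples span > 2 slow
  # half-lives, so lambda_z must approach b within 5%
  a <- 1.2; b <- 0.08; A <- 80; B <- 20
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 18, 24, 30, 36)
  p <- pk_profile(tt, A * exp(-a * tt) + B * exp(-b * tt), dose = 3,
                  dose_per_kg = TRUE, route = "intravenous",
                  species = "monkey", body_weight = 4.5)
  lz <- estimate_lambda_z(p)
  expect_equal(lz$lambda_z, b, tolerance = 0.05)
})

test_that("lambda_z is flagged not estimable without a terminal phase", {
  p <- pk_profile(c(0, 1, 2), c(0, 5, 10), dose = 1, dose_per_kg = TRUE,
                  route = "oral", species = "mouse", body_weight = 0.02)
  lz <- estimate_lambda_z(p)
  expect_false(lz$estimable)
  res <- nca(p)
  expect_true(is.na(res$auc_0_inf))
  expect_true(is.na(res$mrt))
})

test_that("NCA unit conversions reproduce the published parameter identities", {
  expect_equal(cl_per_kg_from_auc(5, 560.7), 8.92, tolerance = 0.001)
  expect_equal(vss_per_kg_from_cl_mrt(9.03, 5.44), 49.12, tolerance = 0.001)
  # monkey intravenous study: total CL and Vss at 4.5 kg
  expect_equal(cl_per_kg_from_auc(3, 4802.7) * 4.5, 2.811, tolerance = 0.001)
  expect_equal(cl_per_kg_from_auc(3, 4802.7) * 4.5 * 4.11, 11.55,
               tolerance = 0.001)
})

test_that("NCA recovers one-compartment parameters within 2%", {
  cl <- 0.6; v <- 3; dose <- 2  # k = 0.2/h, 12 samples over 5 half-lives
  tt <- c(0.05, 0.25, 0.5, 1, 2, 3, 5, 7, 9, 12, 15, 18)
  p <- pk_profile(tt, one_compartment_conc(tt, dose, cl, v), dose = dose,
                  dose_per_kg = FALSE, route = "intravenous",
                  species = "monkey", body_weight = 1)
  res <- nca(p)
  expect_equal(res$cl_over_f_per_kg, cl, tolerance = 0.02)
  expect_equal(res$vss_over_f_per_kg, v, tolerance = 0.02)
  expect_equal(res$t_half, log(2) / 0.2, tolerance = 0.02)
  # volume convention is the clearance-MRT product on every output
  expect_equal(res$vss_over_f_per_kg, res$cl_over_f_per_kg * res$mrt)
})

test_that("dose-proportional profiles give identical CL/F and scaled exposure", {
  tt <- sampling_schedule("mouse_oral")
  res <- lapply(c(5, 10, 20), function(d) {
    cc <- one_compartment_conc(tt, dose_mg = d * 0.02, cl = 0.18 * 0.02,
                               v = 1.7 * 0.02, ka = 1.2)
    nca(pk_profile(tt, cc, dose = d, dose_per_kg = TRUE, route = "oral",
                   species = "mouse", body_weight = 0.02))
  })
  cls <- vapply(res, `[[`, numeric(1), "cl_over_f_per_kg")
  expect_equal(cls[2], cls[1], tolerance = 1e-6)
  expect_equal(cls[3], cls[1], tolerance = 1e-6)
  aucs <- vapply(res, `[[`, numeric(1), "auc_0_inf")
  expect_equal(aucs / aucs[1], c(1, 2, 4), tolerance = 1e-6)
  cmaxs <- vapply(res, `[[`, numeric(1), "cmax")
  expect_equal(cmaxs / cmaxs[1], c(1, 2, 4), tolerance = 1e-12)
})

test_that("bioavailability follows the dose-normalised AUC ratio", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 18, 24)
  iv <- nca(pk_profile(tt, one_compartment_conc(tt, 2, 0.6, 3), dose = 2,
                       dose_per_kg = TRUE, route = "intravenous",
                       species = "monkey", body_weight = 4.5))
  expect_equal(bioavailability(iv, iv), 100, tolerance = 1e-9)
  half <- nca(pk_profile(tt, 0.5 * one_compartment_conc(tt, 2, 0.6, 3),
                         dose = 2, dose_per_kg = TRUE, route = "oral",
                         species = "monkey", body_weight = 4.5))
  expect_equal(bioavailability(half, iv), 50, tolerance = 1e-9)
  # published monkey group means give 0.77% by direct formula evaluation
  expect_equal(100 * (370.6 / 30) / (4802.7 / 3), 0.7716, tolerance = 1e-3)
})
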