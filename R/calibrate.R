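#' Calibrate the oral absorption block against monkey data
#'
#' The gut first-pass factor `Fg` and the cyclodextrin solubilisation
#' factor are the two absorption unknowns the in vitro data cannot fix.
#' Both are fitted once against the monkey oral study (3 mg/kg) by
#' minimising the squared log-differences between simulated and observed
#' Cmax and AUC0-inf, and the fitted pair is then reused across species.
#' The solubilisation factor is constrained to the range 1-100; its starting
#' value 6 is the 1:6 drug:beta-cyclodextrin complex ratio.
#'
#' @param compound a [compound_properties].
#' @param physiology monkey physiology (study animals, 4.5 kg by default).
#' @param kp monkey Kp set.
#' @param clearance_l_h observed monkey intravenous clearance (L/h).
#' @param dose_mg_per_kg calibration dose (mg/kg).
#' @param observed named vector with elements `cmax` (ng/mL) and
#'   `auc_0_inf` (ng.h/mL): the observed monkey oral exposure.
#' @param t_end,dt simulation horizon and output step used during fitting.
#' @param maxit optimiser iteration cap.
#' @return An object of class `absorption_calibration`: a list with `fg`,
#'   `solubilization_factor`, the achieved `cmax`/`auc_0_inf` and the
#'   objective value.
#' @export
calibrate_absorption <- function(compound = compound_properties(),
                                 physiology = species_physiology("monkey",
                                                                 body_weight = 4.5),
                                 kp = predict_kp(compound, "monkey",
                                                 "rodgers_single"),
                                 clearance_l_h = 2.811,
                                 dose_mg_per_kg = 3,
                                 observed = c(cmax = 1.5, auc_0_inf = 15.0),
                                 t_end = 48, dt = 0.1, maxit = 60) {
  dose <- dose_mg_per_kg * physiology$body_weight
  reg <- dosing_regimen(dose, route = "oral")
  sim_metrics <- function(fg, sf) {
    ab <- absorption_params(physiology, compound, fg = fg,
                            solubilization_factor = sf)
    mod <- pbpk_model(compound, physiology, kp, clearance_l_h,
                      absorption = ab)
    sim <- simulate_pbpk(mod, reg, t_end = t_end, dt = dt)
    ex <- tissue_exposure(sim, "plasma")
    c(cmax = ex$cmax, auc_0_inf = if (is.finite(ex$auc_0_inf))
      ex$auc_0_inf else ex$auc_0_t)
  }
  obj <- function(par) {
    fg <- stats::plogis(par[1L]); sf <- exp(par[2L])
    m <- sim_metrics(fg, sf)
    if (any(!is.finite(m)) || any(m <= 0)) return(1e6)
    sum((log(m) - log(observed[c("cmax", "auc_0_inf")]))^2)
  }
  # Nelder-Mead on transformed parameters (logit Fg, log factor); the box
  # constraints are enforced through the transforms plus a penalty on the
  # solubilisation range
  obj_pen <- function(par) {
    if (par[2L] < log(1) - 1e-9 || par[2L] > log(100) + 1e-9) return(1e6)
    obj(par)
  }
  fit <- stats::optim(c(stats::qlogis(0.5), log(6)), obj_pen,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  fit$par[2L] <- min(max(fit$par[2L], log(1)), log(100))
  fg <- stats::plogis(fit$par[1L]); sf <- exp(fit$par[2L])
  m <- sim_metrics(fg, sf)
  structure(list(fg = fg, solubilization_factor = sf,
                 cmax = unname(m["cmax"]), auc_0_inf = unname(m["auc_0_inf"]),
                 observed = observed, objective = fit$value,
                 convergence = fit$convergence),
            class = "absorption_calibration")
}

#' @export
print.absorption_calibration <- function(x, ...) {
  cat(sprintf("<absorption_calibration> Fg %.3g, solubilisation factor %.3g\n",
              x$fg, x$solubilization_factor))
  cat(sprintf("  monkey oral fit: Cmax %.3g (obs %.3g) ng/mL, AUC0-inf %.3g (obs %.3g) ng.h/mL\n",
              x$cmax, x$observed["cmax"], x$auc_0_inf, x$observed["auc_0_inf"]))
  invisible(x)
}

#' Calibrate the mouse PBPK model against oral profiles
#'
#' Mouse disposition has no intravenous anchor, so the systemic clearance
#' and a global Kp scale factor (hence Vss) are estimated from oral
#' concentration-time profiles with the absorption block held fixed.
#' Bounded L-BFGS-B on log-parameters with a small multi-start (fixed seed
#' 20240306) guards against local minima; the objective is the sum of
#' squared log-concentration residuals over all quantifiable samples.
#'
#' @param profiles list of mouse [pk_profile] objects (oral).
#' @param compound a [compound_properties].
#' @param physiology mouse physiology.
#' @param kp mouse Kp set (scaled by the fitted factor).
#' @param absorption absorption parameters (typically carrying the
#'   monkey-calibrated `fg` and solubilisation factor).
#' @param starts number of optimiser starts.
#' @param dt output step used during fitting.
#' @param maxit per-start iteration cap.
#' @return A list of class `mouse_calibration` with `clearance_l_h`,
#'   `kp_scale`, the implied `vss_l`, and fit diagnostics.
#' @export
calibrate_mouse <- function(profiles, compound = compound_properties(),
                            physiology = species_physiology("mouse"),
                            kp = predict_kp(compound, "mouse", "rodgers_single"),
                            absorption = absorption_params(physiology, compound),
                            starts = 3, dt = 0.1, maxit = 50) {
  stopifnot(length(profiles) >= 1)
  cl_max <- 0.95 * physiology$qh_l_h * compound$blood_plasma_ratio
  t_end <- max(vapply(profiles, function(p) max(p$time), numeric(1))) + 1
  sim_for <- function(cl, ks, dose_mg) {
    mod <- pbpk_model(compound, physiology, kp, cl, absorption = absorption,
                      kp_scale = ks)
    simulate_pbpk(mod, dosing_regimen(dose_mg, route = "oral"),
                  t_end = t_end, dt = dt)
  }
  obj <- function(par) {
    cl <- exp(par[1L]); ks <- exp(par[2L])
    if (cl >= cl_max) return(1e6)
    sse <- 0
    for (p in profiles) {
      dose_mg <- if (p$dose_per_kg) p$dose * physiology$body_weight else p$dose
      sim <- tryCatch(sim_for(cl, ks, dose_mg), error = function(e) NULL)
      if (is.null(sim)) return(1e6)
      pred <- stats::approx(sim$time, sim$conc[, "plasma"], xout = p$time)$y
      keep <- p$conc > 0 & pred > 0
      if (sum(keep) < 3) return(1e6)
      sse <- sse + sum((log(pred[keep]) - log(p$conc[keep]))^2)
    }
    sse
  }
  set.seed(20240306)
  start_list <- list(c(log(cl_max / 10), log(1)))
  for (i in seq_len(max(0, starts - 1)))
    start_list[[i + 1L]] <- c(log(cl_max) + stats::runif(1, -5, -0.5),
                              stats::runif(1, log(0.1), log(10)))
  best <- NULL
  for (s in start_list) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = c(log(cl_max) - 12, log(0.01)),
                   upper = c(log(cl_max) - 0.05, log(100)),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("mouse calibration failed to converge", call. = FALSE)
  cl <- exp(best$par[1L]); ks <- exp(best$par[2L])
  vss <- vss_from_kp(structure(as.numeric(kp) * ks, names = names(kp),
                               class = "kp_set"), physiology)
  structure(list(clearance_l_h = cl, kp_scale = ks, vss_l = vss,
                 objective = best$value, convergence = best$convergence),
            class = "mouse_calibration")
}

#' @export
print.mouse_calibration <- function(x, ...) {
  cat(sprintf("<mouse_calibration> CL %.4g L/h, Kp scale %.3g, Vss %.4g L (SSE %.3g)\n",
              x$clearance_l_h, x$kp_scale, x$vss_l, x$objective))
  invisible(x)
}
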