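# shared fixtures, computed lazily and cached for the whole test run:
# the monkey-anchored absorption calibration and the mouse calibration
# recovery runs are the expensive pieces and several files need them.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

cached_calibration <- function() {
  memo("calibration", calibrate_absorption())
}

mouse_setup <- function() {
  memo("mouse_setup", {
    cmpd <- compound_properties()
    phys <- species_physiology("mouse")
    kp <- predict_kp(cmpd, "mouse", "rodgers_single")
    cal <- cached_calibration()
    ab <- absorption_params(phys, cmpd, fg = cal$fg,
                            solubilization_factor = cal$solubilization_factor)
    cl_true <- 0.002
    mod <- pbpk_model(cmpd, phys, kp, cl_true, absorption = ab)
    sim <- simulate_pbpk(mod, dosing_regimen(0.1, route = "oral"),
                         t_end = 25, dt = 0.05)
    list(cmpd = cmpd, phys = phys, kp = kp, ab = ab, cl_true = cl_true,
         vss_true = vss_from_kp(kp, phys), truth_sim = sim)
  })
}

mouse_recovery <- function(noisy) {
  name <- if (noisy) "mouse_recovery_noisy" else "mouse_recovery_clean"
  memo(name, {
    ms <- mouse_setup()
    err <- if (noisy) error_model(proportional_cv = 0.2, additive_sd = 0.01,
                                  n_subjects = 6, seed = 42)
           else error_model(0, 0, n_subjects = 1, seed = 1)
    profs <- generate_profiles(ms$truth_sim, sampling_schedule("mouse_oral"),
                               dose = 5, species = "mouse", body_weight = 0.02,
                               error = err)
    calibrate_mouse(profs, compound = ms$cmpd, physiology = ms$phys,
                    kp = ms$kp, absorption = ms$ab)
  })
}

# simple exponential-decay test profile
exp_profile <- function(times = 0:12, c0 = 100, k = 0.3, route = "oral",
                        dose = 5) {
  pk_profile(times, c0 * exp(-k * times), dose = dose, dose_per_kg = TRUE,
             route = route, species = "mouse", body_weight = 0.02)
}
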