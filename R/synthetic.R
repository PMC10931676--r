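#' Serial-sampling schedule presets
#'
#' The study sampling schedules, in hours: 15-point mouse oral, 16-point
#' monkey intravenous and 16-point monkey oral schedules. The clinical
#' schedule was not published; the monkey oral schedule (out to 48 h) is
#' used as the human preset.
#'
#' @param name preset name.
#' @return Numeric vector of sampling times (h).
#' @export
sampling_schedule <- function(name = c("mouse_oral", "monkey_iv",
                                       "monkey_oral", "human_oral")) {
  name <- match.arg(name)
  switch(name,
    mouse_oral = c(c(0, 5, 15, 30, 45) / 60,
                   1, 1.5, 2, 4, 6, 8, 10, 12, 14, 24),
    monkey_iv = c(c(0, 5, 15, 30, 45) / 60,
                  1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 36),
    monkey_oral = ,
    human_oral = c(c(0, 15, 30) / 60,
                   1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 12, 24, 36, 48))
}

#' Residual-error model for synthetic profiles
#'
#' Log-normal proportional error (mean-one, coefficient of variation
#' `proportional_cv`) on the model-predicted concentration, plus an
#' additive Gaussian floor representing assay noise near the limit of
#' quantification; results are truncated at zero. Concentrations across
#' the dose range span three orders of magnitude, which is why the
#' proportional component is log-normal rather than additive.
#'
#' @param proportional_cv proportional coefficient of variation (fraction).
#' @param additive_sd additive noise standard deviation (ng/mL).
#' @param n_subjects subjects per group.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `error_model`.
#' @export
error_model <- function(proportional_cv = 0.20, additive_sd = 0.01,
                        n_subjects = 6, seed = NULL) {
  stopifnot(proportional_cv >= 0, additive_sd >= 0, n_subjects >= 1)
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 n_subjects = n_subjects, seed = seed), class = "error_model")
}

truth_function <- function(truth) {
  if (inherits(truth, "pbpk_sim"))
    return(stats::approxfun(truth$time, truth$conc[, "plasma"], rule = 2))
  if (is.function(truth)) return(truth)
  stop("truth must be a pbpk_sim or a function of time", call. = FALSE)
}

#' Generate synthetic concentration-time profiles
#'
#' Samples a true concentration-time curve (a PBPK simulation or any
#' function of time returning ng/mL) at a study schedule and applies the
#' residual-error model per subject. Deterministic for a fixed seed.
#'
#' @param truth a `pbpk_sim` or `function(t)` in ng/mL.
#' @param schedule sampling times (h), e.g. [sampling_schedule()].
#' @param dose,route,species,body_weight,dose_per_kg dosing metadata copied
#'   onto each generated [pk_profile].
#' @param error an [error_model()].
#' @param label label prefix for the generated profiles.
#' @return A list of [pk_profile] objects, one per subject.
#' @examples
#' f <- function(t) one_compartment_conc(t, dose_mg = 0.1, cl = 0.002,
#'                                       v = 0.005, ka = 1.5)
#' profs <- generate_profiles(f, sampling_schedule("mouse_oral"), dose = 5,
#'                            species = "mouse", body_weight = 0.02,
#'                            error = error_model(seed = 1))
#' profs[[1]]
#' @export
generate_profiles <- function(truth, schedule, dose, route = "oral",
                              species = "mouse", body_weight = NULL,
                              dose_per_kg = TRUE, error = error_model(),
                              label = "synthetic") {
  if (!length(schedule)) stop("empty sampling schedule", call. = FALSE)
  f <- truth_function(truth)
  mu <- f(schedule)
  if (!is.null(error$seed)) set.seed(error$seed)
  sigma <- sqrt(log(1 + error$proportional_cv^2))
  lapply(seq_len(error$n_subjects), function(j) {
    prop <- exp(stats::rnorm(length(mu), 0, sigma) - sigma^2 / 2)
    cc <- pmax(0, mu * prop + stats::rnorm(length(mu), 0, error$additive_sd))
    pk_profile(schedule, cc, dose = dose, route = route, species = species,
               body_weight = body_weight, dose_per_kg = dose_per_kg,
               label = sprintf("%s subject %d", label, j))
  })
}

#' Closed-form one-compartment concentration
#'
#' `C(t) = F D ka / (V (ka - k)) (exp(-k t) - exp(-ka t))` for first-order
#' oral absorption, or `C(t) = D/V exp(-k t)` for an intravenous bolus
#' (`ka = NULL`), with `k = CL/V`. Dose in mg, volumes in L, clearance in
#' L/h; concentrations returned in ng/mL.
#'
#' @param t times (h).
#' @param dose_mg dose (mg).
#' @param cl clearance (L/h).
#' @param v distribution volume (L).
#' @param ka first-order absorption rate (1/h), `NULL` for intravenous.
#' @param f bioavailable fraction.
#' @return Concentrations (ng/mL).
#' @export
one_compartment_conc <- function(t, dose_mg, cl, v, ka = NULL, f = 1) {
  k <- cl / v
  mg_l <- if (is.null(ka)) {
    f * dose_mg / v * exp(-k * t)
  } else if (abs(ka - k) < 1e-10) {
    f * dose_mg / v * ka * t * exp(-k * t)
  } else {
    f * dose_mg * ka / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
  }
  1000 * mg_l
}

#' Dose-proportional synthetic study family
#'
#' Generates one synthetic dataset per dose level from a shared linear
#' one-compartment model, mirroring a dose-escalation study: noiseless
#' exposure ratios equal the dose ratios exactly.
#'
#' @param pars list with `cl`, `v`, `ka` (optional) and `f`: the per-kg
#'   one-compartment truth (`cl` L/h/kg, `v` L/kg).
#' @param doses dose levels (mg/kg).
#' @param schedule sampling times (h).
#' @param species,body_weight subject metadata.
#' @param error an [error_model()].
#' @return A named list (one element per dose) of profile lists.
#' @export
dose_proportional_family <- function(pars, doses,
                                     schedule = sampling_schedule("mouse_oral"),
                                     species = "mouse", body_weight = 0.02,
                                     error = error_model(proportional_cv = 0,
                                                         additive_sd = 0,
                                                         n_subjects = 1)) {
  stopifnot(length(doses) >= 1)
  out <- lapply(doses, function(d) {
    f <- function(t) one_compartment_conc(
      t, dose_mg = d * body_weight, cl = pars$cl * body_weight,
      v = pars$v * body_weight, ka = pars$ka, f = pars$f %||% 1)
    generate_profiles(f, schedule, dose = d, route = "oral",
                      species = species, body_weight = body_weight,
                      error = error, label = sprintf("%g mg/kg", d))
  })
  names(out) <- paste0(doses, " mg/kg")
  out
}
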