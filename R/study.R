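#' Fold error and the 2-fold acceptance window
#'
#' `fold_error()` is the observed/simulated ratio; `within_twofold()`
#' checks the conventional reciprocal-symmetric acceptance window
#' `0.5 <= observed/simulated <= 2`.
#'
#' @param observed,simulated observed and simulated values; `simulated`
#'   must be positive.
#' @return `fold_error()` a numeric ratio; `within_twofold()` a logical.
#' @export
fold_error <- function(observed, simulated) {
  if (any(simulated <= 0)) stop("simulated value must be positive", call. = FALSE)
  observed / simulated
}

#' @rdname fold_error
#' @param fe a fold error (observed/simulated).
#' @export
within_twofold <- function(fe) fe >= 0.5 & fe <= 2

#' Parameter-level fold-error report
#'
#' @param observed,simulated named numeric vectors sharing parameter names
#'   (typically `cmax`, `auc_0_t`, `auc_0_inf`).
#' @return A data frame with observed, simulated, `fold_error_obs_over_sim`
#'   and `within_twofold` per parameter.
#' @export
fold_error_report <- function(observed, simulated) {
  pars <- intersect(names(observed), names(simulated))
  if (!length(pars)) stop("no shared parameter names", call. = FALSE)
  fe <- fold_error(observed[pars], simulated[pars])
  data.frame(parameter = pars, observed = unname(observed[pars]),
             simulated = unname(simulated[pars]),
             fold_error_obs_over_sim = unname(fe),
             within_twofold = unname(within_twofold(fe)))
}

#' Published human clearance constants
#'
#' Reported human clearance predictions (L/h) that cannot be recomputed
#' from published inputs: the IVIVE and two-species values depend on
#' unpublished body-weight and rat-clearance choices and are carried as
#' constants; the single-species (monkey) value is recomputed by
#' [predict_sss()]. See also [CL_SA_PUBLISHED].
#' @name clearance-constants
#' @export
CL_IVIVE_PUBLISHED <- 36.09

#' @rdname clearance-constants
#' @export
CL_TS_PUBLISHED <- 44.5

#' Four-method human clearance vector
#'
#' Returns the human clearance (L/h) under the four interspecies methods:
#' IVIVE and TS as published constants, SA as the published
#' simple-allometry value, and SSS recomputed from the monkey intravenous
#' clearance under the default body weights (4 kg to 60 kg).
#'
#' @param cl_monkey monkey intravenous clearance (L/h).
#' @param bw_monkey,bw_human body weights (kg) for the SSS pathway.
#' @return Named vector `c(ivive, sa, sss, ts)`.
#' @export
human_clearance_methods <- function(cl_monkey = 2.811, bw_monkey = 4,
                                    bw_human = 60) {
  c(ivive = CL_IVIVE_PUBLISHED,
    sa = CL_SA_PUBLISHED,
    sss = predict_sss(cl_monkey, bw_monkey, bw_human),
    ts = CL_TS_PUBLISHED)
}

#' Assemble the human PBPK model of the study
#'
#' Human whole-body model with tissue partitioning predicted by the
#' selected tissue-composition method and corrected by the monkey
#' observed/predicted Vss ratio (applied as a global Kp scale), the
#' requested systemic clearance, and the monkey-calibrated absorption
#' block.
#'
#' @param clearance_l_h systemic human clearance (L/h).
#' @param calibration an `absorption_calibration` (monkey-anchored `Fg`
#'   and solubilisation factor).
#' @param compound a [compound_properties].
#' @param body_weight human body weight (kg).
#' @param kp_method tissue-composition method for Kp.
#' @param observed_monkey_vss observed monkey Vss (L) for the ratio
#'   correction.
#' @param monkey_body_weight monkey body weight (kg) behind the predicted
#'   monkey Vss.
#' @return A [pbpk_model].
#' @export
human_pbpk_model <- function(clearance_l_h, calibration,
                             compound = compound_properties(),
                             body_weight = 70,
                             kp_method = "rodgers_single",
                             observed_monkey_vss = 11.55,
                             monkey_body_weight = 4) {
  phys_m <- species_physiology("monkey", body_weight = monkey_body_weight)
  kp_m <- predict_kp(compound, "monkey", kp_method)
  vss_pred <- vss_from_kp(kp_m, phys_m)
  scale <- observed_monkey_vss / vss_pred
  phys_h <- species_physiology("human", body_weight = body_weight)
  kp_h <- predict_kp(compound, "human", kp_method)
  ab <- absorption_params(phys_h, compound, fg = calibration$fg,
                          solubilization_factor =
                            calibration$solubilization_factor)
  pbpk_model(compound, phys_h, kp_h, clearance_l_h, absorption = ab,
             kp_scale = scale)
}

#' Run the full extrapolation study
#'
#' Orchestrates the study workflow end to end: (1) NCA on all
#' species/dose groups (on synthetic profiles regenerated from the
#' observed group-mean parameters, since the raw appendix profiles are
#' unavailable); (2) the in vitro chain (microsomal CLint, well-stirred
#' CLh, hepatic extraction per species, and CYP phenotyping); (3) mouse
#' PBPK calibration; (4) monkey PBPK validation (IV plus three oral doses)
#' with 2-fold checks; (5) four-method Kp/Vss prediction with the monkey
#' ratio correction; (6) human clearance by four methods; (7) human 30 mg
#' simulation under each clearance with fold-error reports; (8) 20/40 mg
#' and 30 mg double-dose predictions under the SA clearance; (9) the human
#' tissue-exposure table. The report is a plain nested list and is
#' deterministic for a fixed config and seed.
#'
#' @param seed integer seed driving the synthetic-profile stage.
#' @param n_subjects synthetic subjects per group.
#' @param proportional_cv residual CV of the synthetic profiles.
#' @param kp_method tissue-composition method used for modelling.
#' @param quick logical; skip the expensive calibration stages (3) and use
#'   coarser simulation grids (used by examples).
#' @return An object of class `study_report`.
#' @export
run_study <- function(seed = 1, n_subjects = 6, proportional_cv = 0.20,
                      kp_method = "rodgers_single", quick = FALSE) {
  cmpd <- compound_properties()
  obs <- observed_pk()
  report <- list(seed = seed)

  # (1) NCA per species/dose on synthetic serial-sampling data
  groups <- unique(obs[obs$route %in% c("oral", "intravenous"),
                       c("species", "route", "dose")])
  nca_rows <- NULL
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    pars <- obs_group(obs, g$species, g$route, g$dose)
    prof <- synth_group_profiles(pars, g, seed = seed + i,
                                 n_subjects = n_subjects,
                                 proportional_cv = proportional_cv)
    res <- lapply(prof, nca)
    med <- apply(do.call(rbind, lapply(res, function(r)
      unlist(r[c("cmax", "auc_0_t", "auc_0_inf", "cl_over_f_per_kg", "mrt")]))),
      2, stats::median, na.rm = TRUE)
    nca_rows <- rbind(nca_rows,
                      data.frame(species = g$species, route = g$route,
                                 dose = g$dose, t(med)))
  }
  report$nca <- nca_rows

  # (2) in vitro chain
  mic <- microsome_table()
  chain <- do.call(rbind, lapply(seq_len(nrow(mic)), function(i) {
    sp <- mic$species[i]
    clint <- scale_clint(mic$t_half_min[i], species = sp)
    clh <- well_stirred_clh(clint, mic$qh_ml_min_kg[i])
    data.frame(species = sp, t_half_min = mic$t_half_min[i],
               clint_ml_min_kg = clint, clh_ml_min_kg = clh,
               qh_ml_min_kg = mic$qh_ml_min_kg[i],
               extraction_pct = hepatic_extraction(clh, mic$qh_ml_min_kg[i]))
  }))
  report$invitro <- chain
  report$phenotyping <- tnr_phenotyping(cyp_panel_table())

  # monkey-anchored absorption calibration, reused cross-species
  calib <- calibrate_absorption(compound = cmpd,
                                dt = if (quick) 0.25 else 0.1,
                                maxit = if (quick) 15 else 60)
  report$absorption <- list(fg = calib$fg,
                            solubilization_factor = calib$solubilization_factor)

  # (3) mouse calibration on synthetic mouse 5 mg/kg data
  if (!quick) {
    phys_mo <- species_physiology("mouse")
    mouse_pars <- obs_group(obs, "mouse", "oral", 5)
    mouse_prof <- synth_group_profiles(mouse_pars,
                                       list(species = "mouse", route = "oral",
                                            dose = 5),
                                       seed = seed, n_subjects = n_subjects,
                                       proportional_cv = proportional_cv)
    ab_mo <- absorption_params(phys_mo, cmpd, fg = calib$fg,
                               solubilization_factor =
                                 calib$solubilization_factor)
    mc <- calibrate_mouse(mouse_prof, compound = cmpd, physiology = phys_mo,
                          absorption = ab_mo)
    report$mouse_calibration <- list(clearance_l_h = mc$clearance_l_h,
                                     kp_scale = mc$kp_scale, vss_l = mc$vss_l)
  }

  # (4) monkey validation: IV + three oral doses
  phys_mk <- species_physiology("monkey", body_weight = 4.5)
  kp_mk <- predict_kp(cmpd, "monkey", kp_method)
  ab_mk <- absorption_params(phys_mk, cmpd, fg = calib$fg,
                             solubilization_factor =
                               calib$solubilization_factor)
  mod_mk <- pbpk_model(cmpd, phys_mk, kp_mk, clearance_l_h = 2.811,
                       absorption = ab_mk)
  monkey_val <- list()
  iv_sim <- simulate_pbpk(mod_mk, dosing_regimen(3 * 4.5, route = "iv_bolus"),
                          t_end = 36)
  monkey_val$iv <- fold_error_report(
    obs_vector(obs, "monkey", "intravenous", 3),
    sim_vector(iv_sim, t_last = 36, t_min = 5 / 60))
  for (d in c(3, 10, 30)) {
    s <- simulate_pbpk(mod_mk, dosing_regimen(d * 4.5, route = "oral"),
                       t_end = 48)
    monkey_val[[paste0("oral_", d)]] <- fold_error_report(
      obs_vector(obs, "monkey", "oral", d), sim_vector(s, t_last = 48))
  }
  report$monkey_validation <- monkey_val

  # (5) four-method monkey Vss + ratio correction
  methods <- c("poulin_theil", "berezhkovskiy", "rodgers_rowland",
               "rodgers_single")
  phys_mk4 <- species_physiology("monkey")
  vss_tab <- vapply(methods, function(m)
    vss_from_kp(predict_kp(cmpd, "monkey", m), phys_mk4), numeric(1))
  report$monkey_vss <- data.frame(method = methods, vss_l = unname(vss_tab))
  report$vss_ratio_correction <- 11.55 / vss_tab[[kp_method]]

  # (6) human clearance by four methods
  cl_methods <- human_clearance_methods()
  report$human_clearance <- cl_methods

  # (7) human 30 mg under each clearance
  obs30 <- obs_vector(obs, "human", "oral", 30)
  human30 <- lapply(cl_methods, function(cl) {
    mod <- human_pbpk_model(cl, calib, compound = cmpd, kp_method = kp_method)
    s <- simulate_pbpk(mod, dosing_regimen(30, route = "oral"), t_end = 48)
    fold_error_report(obs30, sim_vector(s, t_last = 48))
  })
  report$human_30mg <- human30

  # (8) other dosages and the double dose, SA clearance
  mod_sa <- human_pbpk_model(cl_methods[["sa"]], calib, compound = cmpd,
                             kp_method = kp_method)
  report$human_other_doses <- list(
    mg20 = fold_error_report(obs_vector(obs, "human", "oral", 20),
                             sim_vector(simulate_pbpk(
                               mod_sa, dosing_regimen(20, route = "oral"),
                               t_end = 48), t_last = 48)),
    mg40 = fold_error_report(obs_vector(obs, "human", "oral", 40),
                             sim_vector(simulate_pbpk(
                               mod_sa, dosing_regimen(40, route = "oral"),
                               t_end = 48), t_last = 48)),
    mg30_double = fold_error_report(
      obs_vector(obs, "human", "oral_double", 30),
      sim_vector(simulate_pbpk(
        mod_sa, dosing_regimen(30, route = "oral", n = 2, interval_h = 24),
        t_end = 72), t_last = 72)))

  # (9) tissue exposure after 40 mg
  s40 <- simulate_pbpk(mod_sa, dosing_regimen(40, route = "oral"), t_end = 96)
  report$tissue_exposure <- tissue_exposure(
    s40, c("plasma", "muscle", "heart", "brain", "skin", "repro"))

  class(report) <- "study_report"
  report
}

obs_group <- function(obs, species, route, dose) {
  sel <- obs[obs$species == species & obs$route == route & obs$dose == dose, ]
  stats::setNames(sel$value, sel$parameter)
}

obs_vector <- function(obs, species, route, dose) {
  g <- obs_group(obs, species, route, dose)
  g[intersect(c("cmax", "auc_0_t", "auc_0_inf"), names(g))]
}

sim_vector <- function(sim, t_last, t_min = 0) {
  ex <- tissue_exposure(sim, "plasma", t_last = t_last, t_min = t_min)
  c(cmax = ex$cmax, auc_0_t = ex$auc_0_t,
    auc_0_inf = if (is.finite(ex$auc_0_inf)) ex$auc_0_inf else ex$auc_0_t)
}

# one-compartment stand-in truth for a study group, parameterised from its
# observed NCA parameters (per-kg clearance and Vss, absorption rate set
# from the observed Tmax)
synth_group_profiles <- function(pars, g, seed, n_subjects, proportional_cv) {
  bw <- switch(g$species, mouse = 0.02, monkey = 4.5, human = 70, 1)
  dose_mg <- if (g$species == "human") g$dose else g$dose * bw
  iv <- g$route == "intravenous"
  cl_kg <- if (iv) pars[["cl"]] / bw else pars[["cl_over_f_per_kg"]]
  mrt <- pars[["mrt"]]
  v_kg <- cl_kg * mrt
  ka <- if (iv) NULL else {
    tmax <- max(pars[["tmax"]], 0.5)
    stats::uniroot(function(ka) log(ka / (cl_kg / v_kg)) / (ka - cl_kg / v_kg) - tmax,
                   c(cl_kg / v_kg + 1e-6, 50))$root
  }
  dose_kg <- dose_mg / bw
  f <- function(t) one_compartment_conc(t, dose_mg = dose_kg, cl = cl_kg,
                                        v = v_kg, ka = ka)
  sched <- sampling_schedule(switch(paste(g$species, iv),
    "mouse FALSE" = "mouse_oral", "monkey TRUE" = "monkey_iv",
    "monkey FALSE" = "monkey_oral", "human_oral"))
  generate_profiles(f, sched, dose = g$dose,
                    route = if (iv) "intravenous" else "oral",
                    species = g$species, body_weight = bw,
                    dose_per_kg = g$species != "human",
                    error = error_model(proportional_cv = proportional_cv,
                                        n_subjects = n_subjects, seed = seed),
                    label = sprintf("%s %s %g", g$species, g$route, g$dose))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  absorption: Fg %.3g, solubilisation %.3g\n",
              x$absorption$fg, x$absorption$solubilization_factor))
  cat("  human clearance (L/h):",
      paste(sprintf("%s %.4g", names(x$human_clearance), x$human_clearance),
            collapse = ", "), "\n")
  cat("  human 30 mg fold errors (obs/sim):\n")
  for (m in names(x$human_30mg)) {
    fe <- x$human_30mg[[m]]
    cat(sprintf("    %-6s %s\n", m,
                paste(sprintf("%s %.2f", fe$parameter,
                              fe$fold_error_obs_over_sim), collapse = ", ")))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (full nested report) plus flat CSV tables for the
#' NCA, in vitro, Vss and tissue-exposure stages.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in c("nca", "invitro", "phenotyping", "monkey_vss",
               "tissue_exposure"))
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}
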