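extdata <- function(file) {
  path <- system.file("extdata", file, package = "e0703pk")
  if (path == "") path <- file.path("inst", "extdata", file)  # pre-install use
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference tables shipped with the package
#'
#' `observed_pk()` returns the observed (group-mean) NCA parameters for
#' mouse, monkey and human studies used for fold-error evaluation;
#' `microsome_table()` the microsomal depletion half-lives and hepatic
#' blood flows per species; `cyp_panel_table()` the recombinant CYP rates
#' and hepatic abundances; `caco2_table()` the measured Caco-2 apparent
#' permeabilities of E0703 and the reference compounds.
#'
#' @return A data frame.
#' @export
observed_pk <- function() extdata("observed_pk_parameters.csv")

#' @rdname observed_pk
#' @export
microsome_table <- function() extdata("microsome_depletion.csv")

#' @rdname observed_pk
#' @export
cyp_panel_table <- function() extdata("cyp_panel.csv")

#' @rdname observed_pk
#' @export
caco2_table <- function() extdata("caco2_papp.csv")

#' Species physiology
#'
#' Literature-standard whole-body physiology for mouse, rat, beagle, Rhesus
#' monkey and human: body weight, cardiac output, per-tissue volumes and
#' blood flows, hepatic blood flow (the species values used throughout the
#' in vitro clearance chain), liver weight and microsomal scaling factors,
#' and the gut geometry driving the oral absorption model. Tissue blood
#' flows are stored as fractions of cardiac output; the liver flow is
#' derived from the hepatic blood flow (25% hepatic artery, 75% portal,
#' with the portal flow split 85/15 between gut and spleen), and the `rest`
#' compartment absorbs the flow remainder so that cardiac output closes
#' exactly.
#'
#' @param species species name.
#' @param body_weight body weight in kg; defaults to the species reference
#'   weight (0.02/0.25/10/4/70 kg).
#' @return An object of class `species_physiology`: a list with scalars
#'   (`body_weight`, `cardiac_output_l_h`, `qh_ml_min_kg`, `liver_g_per_kg`,
#'   `hematocrit`, gut geometry), a `microsome` scaling block, and a
#'   `tissues` data frame with `tissue`, `volume_l`, `flow_l_h`.
#' @examples
#' phys <- species_physiology("monkey", body_weight = 4.5)
#' phys$tissues
#' @export
species_physiology <- function(species = c("human", "mouse", "rat", "beagle", "monkey"),
                               body_weight = NULL) {
  species <- match.arg(species)
  const <- extdata("species_constants.csv")
  sc <- const[const$species == species, ]
  bw <- body_weight %||% sc$body_weight_kg
  if (bw <= 0) stop("body weight must be positive", call. = FALSE)
  tis <- extdata("species_tissues.csv")
  tis <- tis[tis$species == species, c("tissue", "volume_l_per_kg", "flow_frac_co")]

  co_l_h <- sc$cardiac_output_ml_min_kg * bw * 60 / 1000
  qh_l_h <- sc$qh_ml_min_kg * bw * 60 / 1000
  liver_frac <- qh_l_h / co_l_h
  fr <- stats::setNames(tis$flow_frac_co, tis$tissue)
  fr["liver"] <- liver_frac
  fr["gut"] <- 0.75 * liver_frac * 0.85
  fr["spleen"] <- 0.75 * liver_frac * 0.15
  named <- setdiff(names(fr), "rest")
  # liver inflow = hepatic artery + portal; gut and spleen outflow passes
  # through the liver, so they are not double-counted against cardiac output
  direct <- sum(fr[setdiff(named, c("gut", "spleen"))])
  fr["rest"] <- 1 - direct
  if (fr["rest"] <= 0)
    stop("tissue flow fractions exceed cardiac output", call. = FALSE)

  tissues <- data.frame(
    tissue = tis$tissue,
    volume_l = tis$volume_l_per_kg * bw,
    flow_l_h = unname(fr[tis$tissue]) * co_l_h)

  structure(list(
    species = species,
    body_weight = bw,
    cardiac_output_l_h = co_l_h,
    qh_ml_min_kg = sc$qh_ml_min_kg,
    qh_l_h = qh_l_h,
    liver_g_per_kg = sc$liver_g_per_kg,
    hematocrit = sc$hematocrit,
    plasma_l = sc$plasma_l_per_kg * bw,
    venous_l = sc$venous_l_per_kg * bw,
    arterial_l = sc$arterial_l_per_kg * bw,
    lung_l = sc$lung_l_per_kg * bw,
    sitt_h = sc$sitt_h,
    lumen_volume_l = sc$lumen_volume_l * bw / sc$body_weight_kg,
    intestine_radius_cm = sc$intestine_radius_cm,
    microsome = list(incubation_ml_per_mg = 2,     # 0.5 mg protein/mL
                     mg_microsomal_per_g_liver = 45),
    tissues = tissues), class = "species_physiology")
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s, BW %g kg, CO %.3g L/h, Qh %.3g mL/min/kg\n",
              x$species, x$body_weight, x$cardiac_output_l_h, x$qh_ml_min_kg))
  print(x$tissues, row.names = FALSE)
  invisible(x)
}

# cardiac-output closure check used by the model builder
validate_physiology <- function(phys, tol = 1e-8) {
  tt <- phys$tissues
  f <- stats::setNames(tt$flow_l_h, tt$tissue)
  direct <- sum(f[setdiff(names(f), c("gut", "spleen"))])
  if (abs(direct - phys$cardiac_output_l_h) > tol * phys$cardiac_output_l_h)
    stop("cardiac output closure violated: organ inflows do not sum to lung flow",
         call. = FALSE)
  invisible(TRUE)
}

#' Physicochemical and ADME properties of a compound
#'
#' Defaults are the measured/assessed values for E0703: MW 370.54 g/mol,
#' logP 5.13, aqueous solubility 5e-5 mg/mL at pH 7, Caco-2 Papp
#' 1.68e-6 cm/s, plasma unbound fractions 1.3/0.7/13/1.2/0.9 percent in
#' mouse/rat/beagle/monkey/human, blood:plasma ratio 0.82, and a 6-fold
#' cyclodextrin solubilisation factor (the 1:6 complex with
#' beta-cyclodextrin in the tablet).
#'
#' @param mw molecular weight (g/mol).
#' @param logp octanol-water log partition coefficient.
#' @param solubility_mg_ml intrinsic aqueous solubility at pH 7 (mg/mL).
#' @param papp_cm_s Caco-2 apparent permeability (cm/s).
#' @param fu_plasma named per-species unbound fractions (0-1).
#' @param blood_plasma_ratio blood:plasma concentration ratio.
#' @param solubilization_factor multiplicative solubility enhancement of
#'   the formulated drug (>= 1).
#' @return An object of class `compound_properties`.
#' @export
compound_properties <- function(mw = 370.54, logp = 5.13,
                                solubility_mg_ml = 5e-5,
                                papp_cm_s = 1.68e-6,
                                fu_plasma = c(mouse = 0.013, rat = 0.007,
                                              beagle = 0.13, monkey = 0.012,
                                              human = 0.009),
                                blood_plasma_ratio = 0.82,
                                solubilization_factor = 6) {
  stopifnot(mw > 0, solubility_mg_ml > 0, papp_cm_s > 0,
            all(fu_plasma > 0), all(fu_plasma <= 1),
            blood_plasma_ratio > 0, solubilization_factor >= 1)
  structure(list(mw = mw, logp = logp, solubility_mg_ml = solubility_mg_ml,
                 papp_cm_s = papp_cm_s, fu_plasma = fu_plasma,
                 blood_plasma_ratio = blood_plasma_ratio,
                 solubilization_factor = solubilization_factor),
            class = "compound_properties")
}

#' @export
print.compound_properties <- function(x, ...) {
  cat(sprintf("<compound_properties> MW %.2f, logP %.2f, S %.3g mg/mL, Papp %.3g cm/s, Rb/p %.2f\n",
              x$mw, x$logp, x$solubility_mg_ml, x$papp_cm_s, x$blood_plasma_ratio))
  cat("  fu,p:", paste(sprintf("%s %.3f", names(x$fu_plasma), x$fu_plasma),
                       collapse = ", "), "\n")
  invisible(x)
}

fu_for_species <- function(compound, species) {
  fu <- compound$fu_plasma[[species]]
  if (is.null(fu) || is.na(fu))
    stop("no plasma unbound fraction for species ", species, call. = FALSE)
  fu
}
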