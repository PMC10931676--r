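#' Caco-2 transwell assay record
#'
#' Geometry and measured concentrations of one Caco-2 monolayer transport
#' experiment. Defaults follow a 96-well transwell: receiver/donor volumes
#' 0.1 mL apical and 0.25 mL basolateral, monolayer area 0.0804 cm2, donor
#' concentration 10 uM.
#'
#' @param times_s receiver sampling times (s).
#' @param receiver_um cumulative receiver-chamber concentrations (uM).
#' @param c0_donor_um initial donor concentration (uM).
#' @param v_receiver_ml,v_donor_ml,area_cm2 chamber volumes (mL) and
#'   monolayer area (cm2).
#' @param final_donor_um,final_receiver_um,cell_lysate_um,v_cell_ml end-point
#'   concentrations (uM) and cell-insert volume (mL) for recovery.
#' @param direction `"A_to_B"` (apical to basolateral) or `"B_to_A"`.
#' @return An object of class `caco2_assay`.
#' @export
caco2_assay <- function(times_s, receiver_um, c0_donor_um = 10,
                        v_receiver_ml = 0.1, v_donor_ml = 0.25,
                        area_cm2 = 0.0804,
                        final_donor_um = NA, final_receiver_um = NA,
                        cell_lysate_um = NA, v_cell_ml = 0.1,
                        direction = c("A_to_B", "B_to_A")) {
  direction <- match.arg(direction)
  stopifnot(length(times_s) == length(receiver_um))
  if (c0_donor_um <= 0 || area_cm2 <= 0 || v_receiver_ml <= 0 || v_donor_ml <= 0)
    stop("donor concentration, area and volumes must be positive", call. = FALSE)
  if (is.unsorted(times_s, strictly = FALSE))
    stop("receiver sampling times must be increasing", call. = FALSE)
  structure(list(times_s = as.numeric(times_s), receiver_um = as.numeric(receiver_um),
                 c0_donor_um = c0_donor_um, v_receiver_ml = v_receiver_ml,
                 v_donor_ml = v_donor_ml, area_cm2 = area_cm2,
                 final_donor_um = final_donor_um, final_receiver_um = final_receiver_um,
                 cell_lysate_um = cell_lysate_um, v_cell_ml = v_cell_ml,
                 direction = direction),
            class = "caco2_assay")
}

#' Apparent permeability from a Caco-2 assay
#'
#' `Papp = (dCr/dt) x Vr / (A x C0)` with the receiver accumulation slope
#' `dCr/dt` (uM/s) taken from an ordinary least-squares fit over all
#' receiver samples. A negative fitted slope is clipped to zero with a
#' warning (no measurable transport).
#'
#' @param assay a [caco2_assay].
#' @return Papp in cm/s.
#' @export
apparent_permeability <- function(assay) {
  stopifnot(inherits(assay, "caco2_assay"))
  if (length(assay$times_s) < 2L)
    stop("need at least 2 receiver time points", call. = FALSE)
  if (length(unique(assay$times_s)) < 2L)
    stop("receiver times are identical; slope is undefined", call. = FALSE)
  slope <- unname(stats::lsfit(assay$times_s, assay$receiver_um)$coefficients[2L])
  if (slope < 0) {
    warning("negative receiver slope; Papp clipped to 0")
    slope <- 0
  }
  # uM/s * cm3 / (cm2 * uM) = cm/s  (1 mL = 1 cm3)
  unname(slope * assay$v_receiver_ml / (assay$area_cm2 * assay$c0_donor_um))
}

#' Efflux ratio
#'
#' `Papp(B to A) / Papp(A to B)`; a ratio above ~2 flags a candidate efflux
#' transporter (P-gp) substrate.
#'
#' @param papp_ab,papp_ba apparent permeabilities (cm/s).
#' @return Dimensionless ratio.
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  if (papp_ab <= 0) stop("Papp(A to B) must be positive", call. = FALSE)
  papp_ba / papp_ab
}

#' Mass recovery of a Caco-2 assay
#'
#' `%Recovery = 100 [(Vr Cr) + (Vd Cd)] / (Vd C0)`; total recovery adds the
#' cell-lysate amount `Vc Cc` to the numerator. Both are invariant to the
#' concentration unit.
#'
#' @param assay a [caco2_assay] with end-point concentrations filled in.
#' @return A list with `recovery_pct` and `total_recovery_pct` (the latter
#'   `NA` when no lysate measurement exists).
#' @export
recovery <- function(assay) {
  stopifnot(inherits(assay, "caco2_assay"))
  if (is.na(assay$final_donor_um) || is.na(assay$final_receiver_um))
    stop("end-point donor and receiver concentrations are required", call. = FALSE)
  denom <- assay$v_donor_ml * assay$c0_donor_um
  num <- assay$v_receiver_ml * assay$final_receiver_um +
         assay$v_donor_ml * assay$final_donor_um
  rec <- 100 * num / denom
  tot <- if (is.na(assay$cell_lysate_um)) NA_real_ else
    100 * (num + assay$v_cell_ml * assay$cell_lysate_um) / denom
  list(recovery_pct = rec, total_recovery_pct = tot)
}

#' Fraction unbound in plasma from equilibrium dialysis
#'
#' Buffer-side over plasma-side concentration at equilibrium, clipped to
#' `[0, 1]`. The single-read 5 h, 37 C design needs no volume-shift
#' correction.
#'
#' @param donor_conc plasma-side (matrix) concentration at end of dialysis.
#' @param receiver_conc buffer-side concentration.
#' @return Unbound fraction between 0 and 1.
#' @export
fraction_unbound <- function(donor_conc, receiver_conc) {
  if (donor_conc <= 0) stop("donor concentration must be positive", call. = FALSE)
  if (receiver_conc < 0) stop("receiver concentration must be >= 0", call. = FALSE)
  min(1, receiver_conc / donor_conc)
}

#' Microsomal depletion kinetics
#'
#' First-order depletion rate `kappa` from the log-linear slope of the
#' remaining fraction versus incubation time, and the depletion half-life
#' `T1/2 = 0.693/kappa`. A non-positive slope flags a metabolically stable
#' compound (unbounded half-life).
#'
#' @param time_min incubation times (min).
#' @param fraction fraction of parent remaining (1 at time 0).
#' @return A list with `kappa` (1/min), `t_half` (min) and `stable`.
#' @export
depletion_half_life <- function(time_min, fraction) {
  keep <- fraction > 0
  if (sum(keep) < 3L) stop("need >= 3 positive remaining fractions", call. = FALSE)
  slope <- stats::lsfit(time_min[keep], log(fraction[keep]))$coefficients[2L]
  kappa <- unname(-slope)
  if (kappa <= 1e-12)
    return(list(kappa = 0, t_half = Inf, stable = TRUE))
  list(kappa = kappa, t_half = 0.693 / kappa, stable = FALSE)
}

#' Scale a microsomal half-life to intrinsic clearance
#'
#' `CLint = (0.693/T1/2) x (incubation mL / mg microsomal protein)
#'  x (mg microsomal protein / g liver) x (g liver / kg body weight)`,
#' giving mL/min/kg. Scaling factors come from the species physiology
#' record (incubation 2 mL/mg, 45 mg microsomal protein per g liver, and
#' species liver weights by default).
#'
#' @param t_half_min microsomal depletion half-life (min).
#' @param species species name, used to pull defaults.
#' @param physiology a [species_physiology] record.
#' @return CLint in mL/min/kg.
#' @export
scale_clint <- function(t_half_min, species = "human",
                        physiology = species_physiology(species)) {
  if (!is.finite(t_half_min)) return(0)
  if (t_half_min <= 0) stop("half-life must be positive", call. = FALSE)
  sf <- physiology$microsome
  if (is.null(sf)) stop("physiology lacks microsome scaling factors", call. = FALSE)
  (0.693 / t_half_min) * sf$incubation_ml_per_mg *
    sf$mg_microsomal_per_g_liver * physiology$liver_g_per_kg
}

#' Well-stirred hepatic clearance
#'
#' `CLh = Qh CLint / (Qh + CLint)`: bounded above by hepatic blood flow,
#' increasing in CLint, and equal to CLint in the restrictive limit
#' CLint << Qh.
#'
#' @param clint intrinsic clearance (mL/min/kg).
#' @param qh hepatic blood flow (mL/min/kg).
#' @return CLh in mL/min/kg.
#' @export
well_stirred_clh <- function(clint, qh) {
  if (qh <= 0) stop("hepatic blood flow must be positive", call. = FALSE)
  if (clint < 0) stop("CLint must be >= 0", call. = FALSE)
  qh * clint / (qh + clint)
}

#' Hepatic extraction ratio
#'
#' `100 x CLh/Qh` in percent.
#'
#' @param clh hepatic clearance (mL/min/kg).
#' @param qh hepatic blood flow (mL/min/kg).
#' @return Extraction in percent.
#' @export
hepatic_extraction <- function(clh, qh) {
  if (qh <= 0 || clh < 0 || clh >= qh)
    stop("need 0 <= CLh < Qh", call. = FALSE)
  100 * clh / qh
}

#' CYP reaction phenotyping by total normalised rate
#'
#' Each recombinant isoform's metabolic rate (pmol/min/pmol rCYP) is
#' multiplied by its hepatic abundance (pmol CYP/mg microsomal protein) to a
#' normalised rate, and contributions are expressed as percent of the sum
#' (the %TNR method). Contributions sum to 100 up to rounding.
#'
#' @param rate per-isoform metabolic rates, or a data frame with columns
#'   `isoform`, `rate`, `abundance` (then the other arguments are ignored).
#' @param abundance per-isoform hepatic abundances.
#' @param isoform isoform names.
#' @return A data frame with `isoform`, `rate`, `abundance`,
#'   `normalized_rate` and `percent`.
#' @examples
#' tnr_phenotyping(rate = c(0.58, 1.5), abundance = c(45, 108),
#'                 isoform = c("CYP1A2", "CYP3A4"))
#' @export
tnr_phenotyping <- function(rate, abundance = NULL, isoform = NULL) {
  if (is.data.frame(rate)) {
    d <- rate
    stopifnot(all(c("isoform", "rate", "abundance") %in% names(d)))
  } else {
    d <- data.frame(isoform = isoform %||% paste0("CYP", seq_along(rate)),
                    rate = rate, abundance = abundance)
  }
  if (any(d$rate < 0) || any(d$abundance <= 0))
    stop("rates must be >= 0 and abundances > 0", call. = FALSE)
  d$normalized_rate <- d$rate * d$abundance
  tot <- sum(d$normalized_rate)
  if (tot <= 0) stop("all isoform rates are zero; phenotype undefined", call. = FALSE)
  d$percent <- 100 * d$normalized_rate / tot
  d
}
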