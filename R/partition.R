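#' Tissue composition table
#'
#' Literature-standard tissue composition constants used by the
#' tissue-to-plasma partition methods: fractional extracellular and
#' intracellular water, neutral lipid and neutral phospholipid, and the
#' tissue-to-plasma albumin and lipoprotein concentration ratios, per
#' tissue, plus the plasma reference row. Values are the rat-derived
#' constants conventionally applied across mammalian species in
#' tissue-composition Kp prediction.
#'
#' @return A data frame with one row per tissue (plus `plasma`).
#' @export
tissue_composition <- function() extdata("tissue_composition.csv")

# erythrocyte composition (membrane anchor for the Rodgers-family methods)
RBC_COMPOSITION <- list(f_w = 0.63, f_nl = 0.0017, f_np = 0.0029)

# neutral-lipid solubility proxies: octanol-water for most tissues,
# vegetable oil-water for adipose storage lipid
lipid_affinity <- function(logp, f_nl, f_np, adipose = FALSE) {
  p <- 10^logp
  pnl <- if (adipose) 10^(1.115 * logp - 1.35) else p
  pnl * f_nl + (0.3 * p + 0.7) * f_np
}

#' Predict tissue-to-plasma partition coefficients
#'
#' Tissue-composition prediction of Kp for a neutral lipophilic compound by
#' four methods:
#'
#' * `"poulin_theil"`: lipid/water solubility ratio between tissue and
#'   plasma times the plasma-to-tissue unbound-fraction ratio, with
#'   vegetable-oil affinity and unity tissue binding for adipose.
#' * `"berezhkovskiy"`: the same solubility ratio with the unbound
#'   fractions applied inside the aqueous terms; coincides with
#'   Poulin-Theil when fu = 1.
#' * `"rodgers_rowland"` and `"rodgers_single"`: the mechanistic
#'   water/neutral-lipid/phospholipid partitioning equations with Kp =
#'   fu_p x Kpu. The drug-membrane affinity is anchored on the measured
#'   blood:plasma ratio through the erythrocyte partition coefficient
#'   `Kpu_BC = (Rb/p - (1 - hct))/(hct fu_p)`, and plasma protein binding in
#'   excess of membrane partitioning is carried into tissues by the
#'   tissue:plasma albumin ratio. For a neutral compound the two variants
#'   coincide (they differ only in how ionised species are handled, and the
#'   ionisation branches are never triggered at pH 7.4 for a compound with
#'   no relevant pKa).
#'
#' @param compound a [compound_properties].
#' @param species species name, selecting the plasma unbound fraction.
#' @param method one of `"poulin_theil"`, `"berezhkovskiy"`,
#'   `"rodgers_rowland"`, `"rodgers_single"`.
#' @param hematocrit hematocrit used for the erythrocyte anchor.
#' @param composition tissue composition table, see [tissue_composition()].
#' @return An object of class `kp_set`: a named numeric vector of Kp values
#'   with attributes `method` and `species`.
#' @examples
#' kp <- predict_kp(compound_properties(), species = "monkey",
#'                  method = "rodgers_single")
#' round(kp, 2)
#' @export
predict_kp <- function(compound, species = "human",
                       method = c("rodgers_single", "rodgers_rowland",
                                  "poulin_theil", "berezhkovskiy"),
                       hematocrit = 0.45,
                       composition = tissue_composition()) {
  method <- match.arg(method)
  stopifnot(inherits(compound, "compound_properties"))
  fup <- fu_for_species(compound, species)
  logp <- compound$logp
  comp <- composition
  pl <- comp[comp$tissue == "plasma", ]
  tis <- comp[comp$tissue != "plasma", ]
  f_w <- tis$f_ew + tis$f_iw
  f_w_p <- pl$f_ew + pl$f_iw
  adip <- tis$tissue == "adipose"

  if (method %in% c("poulin_theil", "berezhkovskiy")) {
    num_lip <- mapply(lipid_affinity, f_nl = tis$f_nl, f_np = tis$f_np,
                      adipose = adip, MoreArgs = list(logp = logp))
    den_lip <- vapply(adip, function(a)
      lipid_affinity(logp, pl$f_nl, pl$f_np, adipose = a), numeric(1))
    fut <- 1 / (1 + 0.5 * (1 - fup) / fup)
    fut_t <- ifelse(adip, 1, fut)
    if (method == "poulin_theil") {
      kp <- (num_lip + (f_w + 0.7 * tis$f_np)) /
            (den_lip + (f_w_p + 0.7 * pl$f_np)) * fup / fut_t
    } else {
      kp <- (num_lip + (f_w + 0.7 * tis$f_np) / fut_t) /
            (den_lip + (f_w_p + 0.7 * pl$f_np) / fup)
    }
  } else {
    rbc <- RBC_COMPOSITION
    kpu_bc <- (compound$blood_plasma_ratio - (1 - hematocrit)) /
              (hematocrit * fup)
    l_bc <- lipid_affinity(logp, rbc$f_nl, rbc$f_np)
    scal <- max(0, (kpu_bc - rbc$f_w) / l_bc)   # membrane affinity anchor
    l_p <- lipid_affinity(logp, pl$f_nl, pl$f_np)
    # plasma binding not explained by membrane partitioning -> albumin
    ka_pr <- max(0, 1 / fup - f_w_p - scal * l_p)
    l_t <- mapply(lipid_affinity, f_nl = tis$f_nl, f_np = tis$f_np,
                  adipose = adip, MoreArgs = list(logp = logp))
    kpu <- f_w + scal * l_t + ka_pr * tis$albumin_ratio
    kp <- fup * kpu
  }
  if (any(kp <= 0)) stop("non-positive Kp computed", call. = FALSE)
  structure(stats::setNames(as.numeric(kp), tis$tissue),
            method = method, species = species, fu_plasma = fup,
            class = "kp_set")
}

#' @export
print.kp_set <- function(x, digits = 3, ...) {
  cat(sprintf("<kp_set> method %s, species %s, fu,p %.4f\n",
              attr(x, "method"), attr(x, "species"), attr(x, "fu_plasma")))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = V_plasma + sum_t Kp_t V_t` over the physiology's tissue list
#' (plasma-referenced volume, in litres).
#'
#' @param kp a `kp_set` from [predict_kp()].
#' @param physiology a [species_physiology].
#' @return Vss in litres.
#' @examples
#' kp <- predict_kp(compound_properties(), "monkey", "rodgers_single")
#' vss_from_kp(kp, species_physiology("monkey"))
#' @export
vss_from_kp <- function(kp, physiology) {
  tt <- physiology$tissues
  miss <- setdiff(tt$tissue, names(kp))
  if (length(miss))
    stop("Kp set lacks tissues: ", paste(miss, collapse = ", "), call. = FALSE)
  physiology$plasma_l + sum(kp[tt$tissue] * tt$volume_l)
}

#' Observed/predicted ratio correction of a Vss prediction
#'
#' Scales a predicted target-species Vss by the ratio of observed to
#' predicted Vss in a reference species (the monkey here), the
#' ratio-correction used for the human extrapolation.
#'
#' @param observed_animal,predicted_animal observed and predicted Vss (L)
#'   in the reference species.
#' @param predicted_target predicted Vss (L) in the target species.
#' @return Corrected Vss in litres.
#' @export
ratio_corrected_vss <- function(observed_animal, predicted_animal,
                                predicted_target) {
  stopifnot(observed_animal > 0, predicted_target > 0)
  if (predicted_animal <= 0) stop("predicted animal Vss must be positive",
                                  call. = FALSE)
  predicted_target * observed_animal / predicted_animal
}
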