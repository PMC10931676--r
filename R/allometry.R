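#' Fit the simple-allometry power law
#'
#' Ordinary least squares of log10(CL) on log10(BW) across species,
#' returning `CL = a BW^b`. Two points give the exact closed-form solution.
#'
#' @param body_weight species body weights (kg), positive and distinct.
#' @param clearance species clearances (L/h), positive.
#' @param species optional species labels.
#' @return An object of class `allom_fit` with `coefficient_a`,
#'   `exponent_b`, the training points and `r2`; supports `coef()`,
#'   `predict()` and `print()`.
#' @examples
#' fit <- fit_simple_allometry(c(0.02, 4.5), c(0.002, 2.811),
#'                             species = c("mouse", "monkey"))
#' predict(fit, body_weight = 60)
#' @export
fit_simple_allometry <- function(body_weight, clearance, species = NULL) {
  if (length(body_weight) < 2L || length(clearance) != length(body_weight))
    stop("need >= 2 (body weight, clearance) pairs", call. = FALSE)
  if (any(body_weight <= 0) || any(clearance <= 0))
    stop("body weights and clearances must be positive", call. = FALSE)
  if (anyDuplicated(body_weight))
    stop("body weights must be distinct", call. = FALSE)
  x <- log10(body_weight); y <- log10(clearance)
  fit <- stats::lsfit(x, y)
  b <- unname(fit$coefficients[2L])
  a <- 10^unname(fit$coefficients[1L])
  r2 <- if (length(x) > 2L)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  structure(list(coefficient_a = a, exponent_b = b,
                 species_points = data.frame(
                   species = species %||% paste0("sp", seq_along(x)),
                   body_weight = body_weight, clearance = clearance),
                 r2 = r2),
            class = "allom_fit")
}

#' @export
print.allom_fit <- function(x, ...) {
  cat(sprintf("Allometric fit: CL = %.4g x BW^%.4g  (n = %d, R2 = %.4f)\n",
              x$coefficient_a, x$exponent_b, nrow(x$species_points), x$r2))
  invisible(x)
}

#' @export
coef.allom_fit <- function(object, ...) {
  c(a = object$coefficient_a, b = object$exponent_b)
}

#' Predict clearance from an allometric fit (SA method)
#'
#' @param object an `allom_fit`.
#' @param body_weight target body weight (kg).
#' @param ... unused.
#' @return Predicted clearance in L/h.
#' @export
predict.allom_fit <- function(object, body_weight, ...) {
  if (any(body_weight <= 0)) stop("body weight must be positive", call. = FALSE)
  object$coefficient_a * body_weight^object$exponent_b
}

#' Single-species allometric scaling (SSS)
#'
#' `CL_human = CL_animal x (BW_human/BW_animal)^0.75`, conventionally
#' anchored on the monkey.
#'
#' @param cl_animal animal clearance (L/h).
#' @param bw_animal,bw_human body weights (kg).
#' @return Predicted human clearance in L/h.
#' @examples
#' predict_sss(2.811, bw_animal = 4, bw_human = 60)  # 21.4 L/h
#' @export
predict_sss <- function(cl_animal, bw_animal, bw_human) {
  stopifnot(cl_animal > 0, bw_animal > 0, bw_human > 0)
  cl_animal * (bw_human / bw_animal)^0.75
}

#' Two-species scaling (TS, rat + monkey)
#'
#' The coefficient `alpha` comes from the two-point log-log allometric fit
#' of the rat and monkey clearances; the human prediction then uses the
#' fixed optimised exponent 0.650: `CL_human = alpha x BW_human^0.650`.
#'
#' @param cl_rat,bw_rat,cl_monkey,bw_monkey rat and monkey clearances (L/h)
#'   and body weights (kg).
#' @param bw_human human body weight (kg).
#' @return Predicted human clearance in L/h.
#' @export
predict_ts <- function(cl_rat, bw_rat, cl_monkey, bw_monkey, bw_human) {
  stopifnot(cl_rat > 0, cl_monkey > 0, bw_rat > 0, bw_monkey > 0, bw_human > 0)
  if (bw_rat == bw_monkey) stop("rat and monkey body weights coincide", call. = FALSE)
  fit <- fit_simple_allometry(c(bw_rat, bw_monkey), c(cl_rat, cl_monkey))
  alpha <- fit$coefficient_a
  alpha * bw_human^0.650
}

#' IVIVE clearance prediction
#'
#' Converts a per-kg well-stirred hepatic clearance to a whole-body human
#' clearance: `CL (L/h) = CLh (mL/min/kg) x BW x 60/1000`.
#'
#' @param clh_per_kg hepatic clearance (mL/min/kg), e.g. from
#'   [well_stirred_clh()].
#' @param bw_human human body weight (kg).
#' @return Predicted clearance in L/h.
#' @export
predict_ivive <- function(clh_per_kg, bw_human) {
  stopifnot(clh_per_kg >= 0, bw_human > 0)
  clh_per_kg * bw_human * 60 / 1000
}

#' Published human clearance of E0703 by simple allometry
#'
#' The simple-allometry human clearance (L/h) reported for E0703; the rat
#' clearance behind the three-species fit was never published, so this
#' value is shipped as a constant and used by the human PBPK scenario.
#' @export
CL_SA_PUBLISHED <- 39.0
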