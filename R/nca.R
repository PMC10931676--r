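#' Area under the concentration-time curve
#'
#' Trapezoidal AUC from the first to the last sample of a profile. The
#' `"linear"` method is the exact linear trapezoid everywhere; with
#' `"linear_up_log_down"` a segment uses the log-trapezoid only when both
#' endpoint concentrations are positive and the curve is declining, the
#' standard choice for mono-exponential washout.
#'
#' @param profile a [pk_profile].
#' @param method `"linear"` (default) or `"linear_up_log_down"`.
#' @return AUC from t1 to tlast in ng·h/mL.
#' @export
compute_auc <- function(profile, method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  trapz_pk(profile$time, profile$conc, method = method)
}

# shared trapezoid engine; moment = 0 gives AUC, moment = 1 gives AUMC
# (first moment, integral of t*C). Log-trapezoid segments use the closed
# forms for C(t) = C1*exp(-k (t-t1)).
trapz_pk <- function(t, c, method = "linear", moment = 0L) {
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]; c1 <- c[i]; c2 <- c[i + 1L]
    dt <- t2 - t1
    logdown <- method == "linear_up_log_down" && c1 > 0 && c2 > 0 && c2 < c1
    if (moment == 0L) {
      seg <- if (logdown) dt * (c1 - c2) / log(c1 / c2)
             else dt * (c1 + c2) / 2
    } else {
      if (logdown) {
        k <- log(c1 / c2) / dt
        # int t*C dt for exponential decline between the two samples
        seg <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
      } else {
        seg <- dt * (t1 * c1 + t2 * c2) / 2
      }
    }
    total <- total + seg
  }
  total
}

#' Terminal elimination rate constant
#'
#' Log-linear least-squares estimate of the terminal slope. All suffixes of
#' at least 3 positive-concentration points strictly after Tmax are fitted
#' (for extravascular routes the Cmax sample itself is excluded; for
#' intravenous profiles the fit may start at Cmax) and the subset with the
#' highest adjusted R-squared wins, ties going to the longer subset. This is
#' the conventional automatic terminal-phase selection of NCA software.
#'
#' @param profile a [pk_profile].
#' @return A list with `lambda_z` (1/h), `n_points`, `r2_adj`, `t_half` (h)
#'   and `estimable`; when no declining terminal subset exists, `estimable`
#'   is `FALSE` and the rate fields are `NA`.
#' @export
estimate_lambda_z <- function(profile) {
  t <- profile$time; c <- profile$conc
  imax <- which.max(c)
  first <- if (profile$route == "intravenous") imax else imax + 1L
  idx <- seq_along(t) >= first & c > 0
  tt <- t[idx]; cc <- c[idx]
  n <- length(tt)
  not_est <- list(lambda_z = NA_real_, n_points = NA_integer_,
                  r2_adj = NA_real_, t_half = NA_real_, estimable = FALSE)
  if (n < 3L) return(not_est)
  best <- NULL
  for (k in n:3L) {             # longer subsets first so ties keep more points
    sel <- seq.int(n - k + 1L, n)
    fit <- stats::lsfit(tt[sel], log(cc[sel]))
    slope <- unname(fit$coefficients[2L])
    if (!is.finite(slope) || slope >= 0) next
    res <- fit$residuals
    y <- log(cc[sel])
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2a > best$r2_adj + 1e-12)
      best <- list(lambda_z = -slope, n_points = k, r2_adj = r2a)
  }
  if (is.null(best)) return(not_est)
  best$t_half <- log(2) / best$lambda_z
  best$estimable <- TRUE
  best
}

#' Non-compartmental analysis of a profile
#'
#' Model-free exposure metrics: Cmax, Tmax, AUC0-t, extrapolated AUC0-inf
#' (`AUC0-t + Clast/lambda_z`), AUMC0-inf, MRT (`AUMC/AUC`), terminal
#' half-life, and the apparent clearance and steady-state volume. For oral
#' data `CL/F` and `Vss/F` are reported; for intravenous data the same
#' fields are CL and Vss (F = 1). Per-kg values use the per-kg dose;
#' `Vss/F` is computed as `(CL/F) x MRT`, the convention under which the
#' per-kg clearance, MRT and volume columns of a standard NCA table are
#' mutually consistent.
#'
#' @param profile a [pk_profile].
#' @param auc_method AUC method, see [compute_auc()].
#' @return An object of class `nca`; essentially a named list of metrics,
#'   with `as.data.frame()` and `print()` methods.
#' @examples
#' tt <- c(0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)
#' p <- pk_profile(tt, 100 * exp(-0.2 * tt), dose = 3, dose_per_kg = TRUE,
#'                 route = "intravenous", species = "monkey", body_weight = 4.5)
#' nca(p)
#' @export
nca <- function(profile, auc_method = c("linear", "linear_up_log_down")) {
  auc_method <- match.arg(auc_method)
  t <- profile$time; c <- profile$conc
  imax <- which.max(c)
  cmax <- c[imax]; tmax <- t[imax]
  auc_t <- trapz_pk(t, c, auc_method, 0L)
  aumc_t <- trapz_pk(t, c, auc_method, 1L)
  lz <- estimate_lambda_z(profile)
  ilast <- max(which(c > 0), 0L)
  clast <- if (ilast) c[ilast] else 0
  tlast <- if (ilast) t[ilast] else max(t)
  if (lz$estimable && clast > 0) {
    auc_inf <- auc_t + clast / lz$lambda_z
    aumc_inf <- aumc_t + clast * tlast / lz$lambda_z + clast / lz$lambda_z^2
    mrt <- aumc_inf / auc_inf
  } else {
    auc_inf <- aumc_inf <- mrt <- NA_real_
  }
  dpk <- tryCatch(dose_mg_per_kg(profile), error = function(e) NA_real_)
  cl_kg <- if (is.finite(auc_inf) && !is.na(dpk))
    cl_per_kg_from_auc(dpk, auc_inf) else NA_real_
  vss_kg <- if (is.finite(cl_kg) && is.finite(mrt))
    vss_per_kg_from_cl_mrt(cl_kg, mrt) else NA_real_
  out <- list(cmax = cmax, tmax = tmax,
              lambda_z = lz$lambda_z, t_half = lz$t_half,
              auc_0_t = auc_t, auc_0_inf = auc_inf, aumc_0_inf = aumc_inf,
              mrt = mrt, cl_over_f_per_kg = cl_kg, vss_over_f_per_kg = vss_kg,
              n_lambda_points = lz$n_points, r2_adj_lambda = lz$r2_adj,
              dose_mg_per_kg = dpk, route = profile$route,
              species = profile$species, body_weight = profile$body_weight,
              label = profile$label, auc_method = auc_method)
  if (!is.null(profile$body_weight)) {
    out$cl_over_f <- cl_kg * profile$body_weight      # L/h
    out$vss_over_f <- vss_kg * profile$body_weight    # L
  }
  class(out) <- "nca"
  out
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  iv <- x$route == "intravenous"
  cat(sprintf("Non-compartmental analysis (%s %s%s)\n", x$species, x$route,
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  fmt <- function(v) ifelse(is.na(v), "NE", format(signif(v, digits)))
  cat(sprintf("  Cmax %s ng/mL at Tmax %s h\n", fmt(x$cmax), fmt(x$tmax)))
  cat(sprintf("  AUC0-t %s, AUC0-inf %s ng.h/mL\n",
              fmt(x$auc_0_t), fmt(x$auc_0_inf)))
  cat(sprintf("  lambda_z %s 1/h (n=%s, adj R2 %s), T1/2 %s h, MRT %s h\n",
              fmt(x$lambda_z), fmt(x$n_lambda_points), fmt(x$r2_adj_lambda),
              fmt(x$t_half), fmt(x$mrt)))
  cat(sprintf("  %s %s L/h/kg, %s %s L/kg\n",
              if (iv) "CL" else "CL/F", fmt(x$cl_over_f_per_kg),
              if (iv) "Vss" else "Vss/F", fmt(x$vss_over_f_per_kg)))
  invisible(x)
}

#' @export
as.data.frame.nca <- function(x, ...) {
  keep <- c("cmax", "tmax", "lambda_z", "t_half", "auc_0_t", "auc_0_inf",
            "aumc_0_inf", "mrt", "cl_over_f_per_kg", "vss_over_f_per_kg",
            "n_lambda_points", "r2_adj_lambda")
  d <- as.data.frame(x[keep])
  d$species <- x$species; d$route <- x$route; d$label <- x$label
  d
}

#' NCA unit-conversion identities
#'
#' `cl_per_kg_from_auc()` converts a per-kg dose (mg/kg) and an
#' extrapolated AUC (ng.h/mL) to apparent clearance in L/h/kg
#' (`1000 x dose / AUC`); `vss_per_kg_from_cl_mrt()` is the steady-state
#' volume convention `Vss/F = (CL/F) x MRT` under which a standard NCA
#' parameter table is internally consistent.
#'
#' @param dose_mg_per_kg dose in mg/kg.
#' @param auc_0_inf extrapolated AUC in ng.h/mL.
#' @return Clearance in L/h/kg, or volume in L/kg.
#' @examples
#' cl_per_kg_from_auc(5, 560.7)           # 8.92 L/h/kg
#' vss_per_kg_from_cl_mrt(9.03, 5.44)     # 49.12 L/kg
#' @export
cl_per_kg_from_auc <- function(dose_mg_per_kg, auc_0_inf) {
  stopifnot(dose_mg_per_kg > 0, auc_0_inf > 0)
  # mg/kg over ng.h/mL: 1e6 ng/kg / (ng.h/mL) = mL/h/kg; /1e3 -> L/h/kg
  1e3 * dose_mg_per_kg / auc_0_inf
}

#' @rdname cl_per_kg_from_auc
#' @param cl_per_kg clearance in L/h/kg.
#' @param mrt mean residence time in h.
#' @export
vss_per_kg_from_cl_mrt <- function(cl_per_kg, mrt) cl_per_kg * mrt

#' Absolute oral bioavailability from NCA results
#'
#' `F% = 100 x (AUC_oral/Dose_oral) / (AUC_iv/Dose_iv)` with dose-normalised
#' extrapolated AUCs (per-kg doses, so differing body weights are handled).
#'
#' @param oral,iv `nca` objects for the oral and intravenous profiles.
#' @return Bioavailability in percent.
#' @export
bioavailability <- function(oral, iv) {
  stopifnot(inherits(oral, "nca"), inherits(iv, "nca"))
  if (!is.finite(oral$auc_0_inf) || !is.finite(iv$auc_0_inf))
    stop("AUC0-inf not estimable for one of the profiles", call. = FALSE)
  100 * (oral$auc_0_inf / oral$dose_mg_per_kg) /
        (iv$auc_0_inf / iv$dose_mg_per_kg)
}
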