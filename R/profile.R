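#' Concentration-time profile
#'
#' Container for one subject's (or one group-mean) sampled plasma
#' concentration-time course together with the dosing metadata needed for
#' exposure analysis. Concentrations are in ng/mL and times in hours, the
#' units used throughout the package.
#'
#' Below-limit-of-quantification observations should be entered as `NA`;
#' they are dropped, never zero-imputed. A leading zero at `t = 0` is kept
#' for oral profiles (the pre-dose sample).
#'
#' @param time numeric vector of sampling times (h), strictly increasing.
#' @param conc numeric vector of concentrations (ng/mL), `NA` for BLQ.
#' @param dose dose amount; total mg, or mg/kg when `dose_per_kg = TRUE`.
#' @param route `"oral"` or `"intravenous"`.
#' @param species one of `"mouse"`, `"rat"`, `"beagle"`, `"monkey"`, `"human"`.
#' @param body_weight body weight in kg (required to convert between total
#'   and per-kg dose).
#' @param dose_per_kg logical; is `dose` expressed per kg body weight?
#' @param label free-text label.
#' @return An object of class `pk_profile`.
#' @examples
#' p <- pk_profile(c(0, 1, 2, 4, 8), c(0, 80, 60, 30, 8),
#'                 dose = 5, dose_per_kg = TRUE, route = "oral",
#'                 species = "mouse", body_weight = 0.02)
#' p
#' @export
pk_profile <- function(time, conc, dose, route = c("oral", "intravenous"),
                       species = c("mouse", "rat", "beagle", "monkey", "human"),
                       body_weight = NULL, dose_per_kg = FALSE, label = "") {
  route <- match.arg(route)
  species <- match.arg(species)
  if (length(time) != length(conc))
    stop("time and conc must have the same length", call. = FALSE)
  keep <- !is.na(conc)
  time <- as.numeric(time)[keep]
  conc <- as.numeric(conc)[keep]
  if (length(time) < 2L)
    stop("a profile needs at least 2 quantifiable samples", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("dose must be a single positive number", call. = FALSE)
  if (!is.null(body_weight) && (!is.numeric(body_weight) || body_weight <= 0))
    stop("body_weight must be positive", call. = FALSE)
  structure(
    list(time = time, conc = conc, dose = dose, dose_per_kg = isTRUE(dose_per_kg),
         route = route, species = species, body_weight = body_weight,
         label = as.character(label)),
    class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  dd <- if (x$dose_per_kg) sprintf("%g mg/kg", x$dose) else sprintf("%g mg", x$dose)
  cat(sprintf("<pk_profile> %s %s, %s, %d samples over %g h%s\n",
              x$species, x$route, dd, length(x$time), max(x$time),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.pk_profile <- function(x, ...) {
  data.frame(time_h = x$time, conc_ng_ml = x$conc)
}

#' @export
plot.pk_profile <- function(x, log = "y", ...) {
  pos <- x$conc > 0
  graphics::plot(x$time[pos], x$conc[pos], log = log, type = "b", pch = 16,
                 xlab = "Time (h)", ylab = "Concentration (ng/mL)",
                 main = x$label, ...)
  invisible(x)
}

# dose normalised per kg body weight (mg/kg); needs body weight when the
# dose was given as a total amount
dose_mg_per_kg <- function(profile) {
  if (profile$dose_per_kg) return(profile$dose)
  if (is.null(profile$body_weight))
    stop("body_weight is required to express a total dose per kg", call. = FALSE)
  profile$dose / profile$body_weight
}

#' Read / write profile CSV files
#'
#' The on-disk format is a plain CSV with columns `time_h` and `conc_ng_ml`,
#' preceded by a commented metadata block of `# key: value` lines carrying
#' `dose_mg` or `dose_mg_per_kg`, `route`, `species`, `body_weight_kg` and
#' `label`. Unsorted time vectors are rejected.
#'
#' @param file path to a profile CSV.
#' @return `read_pk_profile()` returns a [pk_profile]; `write_pk_profile()`
#'   returns `file` invisibly.
#' @export
read_pk_profile <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  tab <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                           value = TRUE), collapse = "\n"))
  if (!all(c("time_h", "conc_ng_ml") %in% names(tab)))
    stop("profile CSV must have columns time_h and conc_ng_ml", call. = FALSE)
  per_kg <- !is.null(meta$dose_mg_per_kg)
  dose <- as.numeric(if (per_kg) meta$dose_mg_per_kg else meta$dose_mg)
  if (!length(dose) || is.na(dose))
    stop("metadata must provide dose_mg or dose_mg_per_kg", call. = FALSE)
  bw <- if (!is.null(meta$body_weight_kg)) as.numeric(meta$body_weight_kg)
  pk_profile(tab$time_h, tab$conc_ng_ml, dose = dose, route = meta$route %||% "oral",
             species = meta$species %||% "human", body_weight = bw,
             dose_per_kg = per_kg, label = meta$label %||% "")
}

#' @rdname read_pk_profile
#' @param profile a [pk_profile].
#' @export
write_pk_profile <- function(profile, file) {
  meta <- c(
    if (profile$dose_per_kg) sprintf("# dose_mg_per_kg: %g", profile$dose)
    else sprintf("# dose_mg: %g", profile$dose),
    sprintf("# route: %s", profile$route),
    sprintf("# species: %s", profile$species),
    if (!is.null(profile$body_weight))
      sprintf("# body_weight_kg: %g", profile$body_weight),
    sprintf("# label: %s", profile$label))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
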