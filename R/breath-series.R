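#' Construct a participant record
#'
#' Minimal metadata for one CPET participant: the cohort label, sex, age and
#' the anthropometrics needed for per-kilogram quantities.
#'
#' @param id Opaque participant identifier (character scalar).
#' @param group Cohort label, one of `"children"`, `"MTA"` (moderately trained
#'   adults) or `"WTA"` (well-trained adults).
#' @param sex `"female"` or `"male"`.
#' @param age Age in years. Children must be 7-11 y, adults 20-30 y.
#' @param body_mass Body mass in kg (> 0).
#' @param height Standing height in cm.
#' @return An object of class `cpet_participant` (a named list).
#' @export
#' @examples
#' participant("c01", "children", "female", 9.5, 32.3, 139)
participant <- function(id, group, sex, age, body_mass, height) {
  group <- match.arg(group, c("children", "MTA", "WTA"))
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(is.numeric(age), is.numeric(body_mass), is.numeric(height))
  if (body_mass <= 0) stop("body_mass must be positive")
  if (group == "children" && (age < 7 || age > 11)) {
    stop("children must be 7-11 years of age, got ", age)
  }
  if (group != "children" && (age < 20 || age > 30)) {
    stop("adult groups must be 20-30 years of age, got ", age)
  }
  structure(
    list(id = as.character(id), group = group, sex = sex, age = age,
         body_mass = body_mass, height = height),
    class = "cpet_participant"
  )
}

#' @export
print.cpet_participant <- function(x, ...) {
  cat(sprintf("<cpet_participant> %s: %s %s, %.1f y, %.1f kg, %.1f cm\n",
              x$id, x$group, x$sex, x$age, x$body_mass, x$height))
  invisible(x)
}

# Gas-exchange channels carried by a breath series. `t` and `power` are the
# independent variables and are never smoothed.
.breath_channels <- c("vo2", "vco2", "ve", "hr", "peto2", "petco2")
.breath_cols <- c("t", .breath_channels, "power")

#' Construct a breath-by-breath series
#'
#' A `breath_series` is a data frame with one row per breath and columns
#' `t` (s from warm-up start), `vo2`, `vco2` (mL/min), `ve` (L/min BTPS),
#' `hr` (beats/min, optional), `peto2`, `petco2` (mmHg, optional) and `power`
#' (W), plus phase marks (warm-up start, ramp start, termination) stored as
#' attributes. All quantities are in the canonical units above; loaders
#' convert on the way in.
#'
#' @param records Data frame of breaths with the columns listed above
#'   (optional channels may be `NA` or absent).
#' @param phases Named list or vector with `warmup_start`, `ramp_start` and
#'   `termination` times in seconds.
#' @param validate Check invariants (strictly increasing time, positive VO2
#'   and VE, ordered phase marks). Default `TRUE`.
#' @return An object of classes `breath_series` and `data.frame`.
#' @export
breath_series <- function(records, phases, validate = TRUE) {
  records <- as.data.frame(records)
  for (ch in setdiff(.breath_cols, names(records))) {
    if (ch %in% c("hr", "peto2", "petco2")) records[[ch]] <- NA_real_
    else stop("missing mandatory column: ", ch)
  }
  records <- records[, .breath_cols]
  phases <- as.list(phases)
  stopifnot(all(c("warmup_start", "ramp_start", "termination") %in% names(phases)))
  if (validate) {
    if (nrow(records) == 0L) stop("a breath series needs at least one breath")
    dt <- diff(records$t)
    if (any(dt <= 0)) {
      stop("breath times must be strictly increasing; first offending row: ",
           which(dt <= 0)[1] + 1L)
    }
    if (any(records$t < 0)) stop("breath times must be >= 0")
    if (any(records$vo2 <= 0)) stop("vo2 must be positive")
    if (any(records$vco2 < 0)) stop("vco2 must be non-negative")
    if (any(records$ve <= 0)) stop("ve must be positive")
    if (any(records$power < 0)) stop("power must be non-negative")
    hr <- records$hr[!is.na(records$hr)]
    if (length(hr) && (any(hr < 40) || any(hr > 250))) {
      stop("hr outside the physiological range [40, 250]")
    }
    if (phases$ramp_start < phases$warmup_start) {
      stop("ramp start must not precede warm-up start")
    }
    if (phases$termination <= phases$ramp_start) {
      stop("termination must follow ramp start")
    }
  }
  structure(records,
            phases = phases[c("warmup_start", "ramp_start", "termination")],
            class = c("breath_series", "data.frame"))
}

#' Phase marks of a breath series
#'
#' @param series A [breath_series()].
#' @return Named list with `warmup_start`, `ramp_start`, `termination` (s).
#' @export
phases <- function(series) attr(series, "phases")

#' Respiratory exchange ratio of each breath
#'
#' @param series A [breath_series()].
#' @return Numeric vector, VCO2/VO2 per breath.
#' @export
rer <- function(series) series$vco2 / series$vo2

#' @export
print.breath_series <- function(x, ...) {
  ph <- phases(x)
  cat(sprintf(
    "<breath_series> %d breaths, %.1f-%.1f s (ramp %.0f s, termination %.0f s)\n",
    nrow(x), x$t[1], x$t[nrow(x)], ph$ramp_start, ph$termination))
  invisible(x)
}

# Restrict a series to [from, to] (inclusive) without re-validating phases.
.clip_series <- function(series, from = -Inf, to = Inf) {
  keep <- series$t >= from & series$t <= to
  structure(as.data.frame(series)[keep, , drop = FALSE],
            phases = phases(series), class = class(series))
}
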