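#' Moving-average smoothing of a breath series
#'
#' Replaces every gas-exchange channel (VO2, VCO2, VE, HR, PetO2, PetCO2) by
#' the mean over all breaths whose timestamp lies within a centred, time-based
#' window `[t - window/2, t + window/2]` (breaths weighted equally). Time and
#' power are untouched; output length equals input length. Windows are
#' truncated at the series boundaries, so edge values average fewer breaths.
#' The 30-s default is the conventional metabolic-cart smoothing.
#'
#' @param series A [breath_series()].
#' @param window Window width in seconds (> 0). Default 30.
#' @return A smoothed [breath_series()].
#' @export
moving_average <- function(series, window = 30) {
  stopifnot(inherits(series, "breath_series"))
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("window must be a positive number of seconds")
  }
  if (nrow(series) == 0L) stop("series is empty")
  t <- series$t
  eps <- 1e-9
  lo <- findInterval(t - window / 2 - eps, t) + 1L
  hi <- findInterval(t + window / 2 + eps, t)
  out <- as.data.frame(series)
  for (ch in .breath_channels) {
    x <- series[[ch]]
    ok <- !is.na(x)
    if (!any(ok)) next
    cs <- c(0, cumsum(ifelse(ok, x, 0)))
    cn <- c(0, cumsum(as.numeric(ok)))
    sum_w <- cs[hi + 1L] - cs[lo]
    n_w <- cn[hi + 1L] - cn[lo]
    out[[ch]] <- ifelse(n_w > 0, sum_w / n_w, NA_real_)
  }
  breath_series(out, phases(series), validate = FALSE)
}

#' Resample a breath series onto a uniform time grid
#'
#' Linear interpolation of every channel onto a grid with step `dt`,
#' restricted to `[t_first, t_last]` (no extrapolation beyond the first or
#' last breath). Used for per-minute plateau averages and 90-s efficiency
#' windows, which are ill-defined on irregular breath timestamps.
#'
#' @param series A [breath_series()] with at least two breaths.
#' @param dt Grid step in seconds (> 0). Default 1.
#' @return A data frame with the same columns as the series, rows at the grid
#'   times, carrying the phase marks as an attribute.
#' @export
resample_to_grid <- function(series, dt = 1) {
  stopifnot(inherits(series, "breath_series"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (nrow(series) < 2L) stop("need at least 2 breaths to interpolate")
  t <- series$t
  span <- t[length(t)] - t[1]
  if (dt > span) stop("dt (", dt, " s) exceeds the test duration (", span, " s)")
  grid <- seq(t[1], t[length(t)], by = dt)
  out <- data.frame(t = grid)
  for (ch in c(.breath_channels, "power")) {
    x <- series[[ch]]
    ok <- !is.na(x)
    out[[ch]] <- if (sum(ok) >= 2L) {
      stats::approx(t[ok], x[ok], xout = grid, rule = 1)$y
    } else NA_real_
  }
  attr(out, "phases") <- phases(series)
  attr(out, "dt") <- dt
  out
}

#' Quality-control screen for a breath series
#'
#' Flags physiologically impossible stretches: RER outside `rer_bounds`
#' sustained for more than `sustain` seconds, single-breath VE jumps beyond
#' `jump_factor` times the local running median, and timestamp gaps longer
#' than `max_gap` seconds. RER and VE-jump flags carry severity `"exclude"`;
#' gap flags are `"warn"`. The report's `usable` is `FALSE` iff at least one
#' exclude-severity flag is present. Thresholds are conventions of this
#' package (real exclusion criteria vary by laboratory) and are configurable.
#'
#' @param series A [breath_series()].
#' @param rer_bounds Plausible RER range. Default `c(0.6, 1.6)`.
#' @param sustain Seconds an out-of-range RER stretch must last to be
#'   flagged. Default 30.
#' @param jump_factor VE jump multiple of the local median that marks a
#'   sensor artifact. Default 3.
#' @param max_gap Largest acceptable inter-breath gap in seconds. Default 10.
#' @return An object of class `qc_report`: list with `flags` (data frame
#'   `code`, `t_start`, `t_end`, `severity`, `message`) and `usable`.
#' @export
qc_screen <- function(series, rer_bounds = c(0.6, 1.6), sustain = 30,
                      jump_factor = 3, max_gap = 10) {
  stopifnot(inherits(series, "breath_series"))
  flags <- list()
  t <- series$t
  n <- nrow(series)

  r <- rer(series)
  bad <- r < rer_bounds[1] | r > rer_bounds[2]
  if (any(bad)) {
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      dur <- t[ends[k]] - t[starts[k]]
      if (dur > sustain) {
        flags[[length(flags) + 1L]] <- data.frame(
          code = "rer_out_of_range", t_start = t[starts[k]], t_end = t[ends[k]],
          severity = "exclude",
          message = sprintf("RER outside [%.2f, %.2f] sustained %.0f s",
                            rer_bounds[1], rer_bounds[2], dur))
      }
    }
  }

  if (n >= 5L) {
    # window wide enough that a multi-breath excursion cannot capture its
    # own local median
    k <- min(31L, if (n %% 2L) n else n - 1L)
    med <- stats::runmed(series$ve, k = k)
    jump <- series$ve > jump_factor * med | series$ve < med / jump_factor
    if (any(jump)) {
      idx <- which(jump)
      flags[[length(flags) + 1L]] <- data.frame(
        code = "ve_sensor_artifact", t_start = t[min(idx)], t_end = t[max(idx)],
        severity = "exclude",
        message = sprintf("VE departs from %gx the local median on %d breaths",
                          jump_factor, length(idx)))
    }
  }

  gaps <- which(diff(t) > max_gap)
  for (g in gaps) {
    flags[[length(flags) + 1L]] <- data.frame(
      code = "timestamp_gap", t_start = t[g], t_end = t[g + 1L],
      severity = "warn",
      message = sprintf("%.1f s gap between consecutive breaths", t[g + 1L] - t[g]))
  }

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(code = character(), t_start = numeric(), t_end = numeric(),
               severity = character(), message = character())
  structure(list(flags = flags, usable = !any(flags$severity == "exclude")),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> usable=%s, %d flag(s)\n", x$usable, nrow(x$flags)))
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}
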