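#' Read a canonical breath CSV
#'
#' The canonical dialect is UTF-8, LF line endings, '.' decimal separator: a
#' comment-prefixed header block of `#key=value` lines carrying participant
#' metadata (`id`, `group`, `sex`, `age_y`, `body_mass_kg`, `height_cm`) and
#' phase/protocol marks (`warmup_start_s`, `ramp_start_s`, `termination_s`,
#' `ramp_start_W`, `ramp_rate_W_per_min`), followed by a CSV header row
#' `t_s,vo2_ml_min,vco2_ml_min,ve_l_min,hr_bpm,peto2_mmhg,petco2_mmhg,power_w`
#' and one row per breath. Missing optional channels are blank.
#'
#' Unit tags in column names are honoured on the way in: `vo2_l_min` /
#' `vco2_l_min` are multiplied by 1000 and `ve_ml_min` divided by 1000 so the
#' in-memory series is always mL/min (VO2, VCO2) and L/min (VE).
#'
#' @param path Path to a canonical breath CSV.
#' @return A list with elements `participant` (a [participant()]) and
#'   `series` (a [breath_series()]); when the header carries protocol fields,
#'   also `protocol` (a [ramp_protocol()]).
#' @seealso [write_breath_csv()]
#' @export
read_breath_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  if (length(meta_lines) == 0L) stop("not a canonical breath CSV (no #key=value header): ", path)
  kv <- sub("^#", "", lines[meta_lines])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  need <- c("id", "group", "sex", "age_y", "body_mass_kg", "height_cm",
            "warmup_start_s", "ramp_start_s", "termination_s")
  miss <- setdiff(need, keys)
  if (length(miss)) stop("header metadata missing: ", paste(miss, collapse = ", "))

  body <- lines[-meta_lines]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("no breath rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)

  # map columns to canonical names, applying unit tags
  canon <- list(
    t = c(t_s = 1), vo2 = c(vo2_ml_min = 1, vo2_l_min = 1000),
    vco2 = c(vco2_ml_min = 1, vco2_l_min = 1000),
    ve = c(ve_l_min = 1, ve_ml_min = 1e-3),
    hr = c(hr_bpm = 1), peto2 = c(peto2_mmhg = 1), petco2 = c(petco2_mmhg = 1),
    power = c(power_w = 1))
  rec <- list()
  for (ch in names(canon)) {
    hit <- intersect(names(canon[[ch]]), names(df))
    if (length(hit) == 0L) {
      if (ch %in% c("hr", "peto2", "petco2")) { rec[[ch]] <- NA_real_; next }
      stop("missing mandatory column: ", names(canon[[ch]])[1])
    }
    rec[[ch]] <- as.numeric(df[[hit[1]]]) * canon[[ch]][[hit[1]]]
  }
  rec <- as.data.frame(rec)
  dtime <- diff(rec$t)
  if (any(dtime <= 0)) {
    stop("non-monotone breath times; first offending row: ", which(dtime <= 0)[1] + 1L)
  }

  sex <- c(F = "female", M = "male")[[meta$sex]]
  part <- participant(meta$id, meta$group, sex, as.numeric(meta$age_y),
                      as.numeric(meta$body_mass_kg), as.numeric(meta$height_cm))
  series <- breath_series(rec, list(
    warmup_start = as.numeric(meta$warmup_start_s),
    ramp_start = as.numeric(meta$ramp_start_s),
    termination = as.numeric(meta$termination_s)))
  out <- list(participant = part, series = series)
  if (all(c("ramp_start_W", "ramp_rate_W_per_min") %in% keys)) {
    out$protocol <- ramp_protocol(
      as.numeric(meta$ramp_start_W), as.numeric(meta$ramp_rate_W_per_min),
      warmup_duration = as.numeric(meta$ramp_start_s) - as.numeric(meta$warmup_start_s))
  }
  out
}

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, format = "g", digits = 15))
  out
}

#' Write a canonical breath CSV
#'
#' Emits the canonical dialect described in [read_breath_csv()];
#' `read_breath_csv()` inverts it exactly (15 significant digits are
#' written, so floats round-trip well below 1e-9 relative error).
#'
#' @param participant A [participant()].
#' @param series A [breath_series()] (must contain at least one breath).
#' @param path Output path.
#' @param protocol Optional [ramp_protocol()]; when given, its start load and
#'   ramp rate are recorded in the header so per-watt metrics are
#'   recomputable downstream.
#' @return Invisibly, `path`.
#' @export
write_breath_csv <- function(participant, series, path, protocol = NULL) {
  stopifnot(inherits(participant, "cpet_participant"),
            inherits(series, "breath_series"))
  if (nrow(series) == 0L) stop("refusing to write an empty breath series")
  ph <- phases(series)
  meta <- c(
    id = participant$id, group = participant$group,
    sex = c(female = "F", male = "M")[[participant$sex]],
    age_y = .fmt_num(participant$age),
    body_mass_kg = .fmt_num(participant$body_mass),
    height_cm = .fmt_num(participant$height),
    warmup_start_s = .fmt_num(ph$warmup_start),
    ramp_start_s = .fmt_num(ph$ramp_start),
    termination_s = .fmt_num(ph$termination))
  if (!is.null(protocol)) {
    meta <- c(meta, ramp_start_W = .fmt_num(protocol$start_load),
              ramp_rate_W_per_min = .fmt_num(protocol$ramp_rate))
  }
  header <- paste0("#", names(meta), "=", meta)
  cols <- c("t_s", "vo2_ml_min", "vco2_ml_min", "ve_l_min", "hr_bpm",
            "peto2_mmhg", "petco2_mmhg", "power_w")
  mat <- vapply(.breath_cols, function(ch) .fmt_num(series[[ch]]),
                character(nrow(series)))
  if (nrow(series) == 1L) mat <- matrix(mat, nrow = 1L)
  rows <- apply(mat, 1L, paste, collapse = ",")
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(c(header, paste(cols, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}
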