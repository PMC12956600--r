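#' The five ramp protocols
#'
#' Start load (W) and ramp rate (W/min) of the five ramp protocols used for
#' ramp-incremental cycling tests; the pairing is fixed.
#'
#' @return Data frame with columns `start_load` and `ramp_rate`.
#' @export
ramp_protocol_table <- function() {
  data.frame(start_load = c(7, 10, 20, 50, 50),
             ramp_rate = c(7, 10, 15, 20, 30))
}

#' Construct a ramp protocol
#'
#' @param start_load Warm-up / ramp start load in W; must pair with
#'   `ramp_rate` as one of the five protocols (7,7), (10,10), (20,15),
#'   (50,20), (50,30).
#' @param ramp_rate Ramp rate in W/min.
#' @param warmup_duration Steady-state warm-up duration in seconds (> 0).
#'   Default 180.
#' @return Object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_load, ramp_rate, warmup_duration = 180) {
  tab <- ramp_protocol_table()
  if (!any(tab$start_load == start_load & tab$ramp_rate == ramp_rate)) {
    stop("(", start_load, " W, ", ramp_rate,
         " W/min) is not one of the five ramp protocols")
  }
  if (warmup_duration <= 0) stop("warmup_duration must be positive")
  structure(list(start_load = start_load, ramp_rate = ramp_rate,
                 warmup_duration = warmup_duration),
            class = "ramp_protocol")
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat(sprintf("<ramp_protocol> %g W + %g W/min (warm-up %g s)\n",
              x$start_load, x$ramp_rate, x$warmup_duration))
  invisible(x)
}

#' Choose the ramp protocol for a predicted peak workload
#'
#' Picks, among the five protocols, the one whose ramp duration
#' `(predicted_peak - start_load) / ramp_rate` falls inside the 8-10 min
#' target band for reaching exhaustion; if several qualify, the one closest
#' to 9 min; if none qualifies, the one whose duration is nearest to the
#' band.
#'
#' @param predicted_peak Predicted peak workload in W (> 7).
#' @param warmup_duration Passed to [ramp_protocol()]. Default 180 s.
#' @return A [ramp_protocol()].
#' @export
#' @examples
#' select_ramp_protocol(100)  # 10 W + 10 W/min: exactly 9 min
select_ramp_protocol <- function(predicted_peak, warmup_duration = 180) {
  if (!is.numeric(predicted_peak) || predicted_peak <= 7) {
    stop("predicted_peak must exceed the smallest start load (7 W)")
  }
  tab <- ramp_protocol_table()
  dur <- (predicted_peak - tab$start_load) / tab$ramp_rate  # minutes
  inside <- dur >= 8 & dur <= 10
  i <- if (any(inside)) {
    cand <- which(inside)
    cand[which.min(abs(dur[cand] - 9))]
  } else {
    dist <- pmax(8 - dur, dur - 10, 0)
    which.min(dist)
  }
  ramp_protocol(tab$start_load[i], tab$ramp_rate[i], warmup_duration)
}

#' Work rate at a given time under a ramp protocol
#'
#' Start load throughout the warm-up, then a linear ramp.
#'
#' @param protocol A [ramp_protocol()].
#' @param t Time(s) in seconds from warm-up start.
#' @return Work rate in W (vectorised over `t`).
#' @export
protocol_power <- function(protocol, t) {
  protocol$start_load +
    pmax(0, t - protocol$warmup_duration) * protocol$ramp_rate / 60
}
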