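#' Settling time of a step response
#'
#' Earliest time, measured from the step onset, after which the measured flow
#' stays within `final * (1 +/- band)` for every remaining sample. The final
#' value is estimated as the mean of the last 10% of samples; when it is
#' below resolution (|final| < 1e-9) the band is applied to the setpoint
#' amplitude instead.
#'
#' @param trace A [flow_trace()] with at least 10 samples after the onset.
#' @param band Half-width of the tolerance band as a fraction of the final
#'   value (default 0.02, i.e. the 2% criterion).
#' @param signal Column to analyse (default measured flow).
#' @return Settling time in seconds, or `NA` with a `"not settled"` attribute
#'   when the response never stays inside the band.
#' @export
settling_time <- function(trace, band = 0.02, signal = "flow_meas_lpm") {
  w <- step_window(trace)
  y <- trace[[signal]][w]
  t <- trace$time_s[w]
  if (length(y) < 10) stop("need at least 10 samples after onset")
  final <- mean(y[seq.int(max(1, floor(0.9 * length(y))), length(y))])
  ref <- if (abs(final) < 1e-9) max(abs(trace$setpoint_lpm)) else abs(final)
  inside <- abs(y - final) <= band * ref
  if (!inside[length(inside)]) {
    return(structure(NA_real_, status = "not settled"))
  }
  # last sample outside the band; settled from the next one on
  last_out <- max(c(0, which(!inside)))
  if (last_out == 0) return(0)
  t[last_out + 1] - t[1]
}

# Indices of the dominant step-response window: from the largest upward
# setpoint step (trace start if the setpoint never changes) through the
# contiguous run at the post-step level.
step_window <- function(trace) {
  sp <- trace$setpoint_lpm
  d <- diff(sp)
  onset <- if (all(d == 0)) 1L else if (any(d > 0)) which.max(d) + 1L
           else which.max(abs(d)) + 1L
  run_end <- onset
  while (run_end < length(sp) && sp[run_end + 1] == sp[onset]) {
    run_end <- run_end + 1L
  }
  onset:run_end
}

#' Step-response metrics of a flow trace
#'
#' Settling time (2% band by default), 10-90% rise time, percent overshoot,
#' steady-state error and delivered volume (trapezoidal integral of the
#' measured flow over the inspiratory window, i.e. while the setpoint is at
#' its post-step value).
#'
#' @param trace A [flow_trace()] with a single dominant step in the setpoint
#'   channel.
#' @param band Settling band fraction.
#' @return An object of class `step_metrics`: `settling_time` (s),
#'   `rise_time` (s), `overshoot_pct`, `steady_state_error` (L/min),
#'   `delivered_volume` (mL).
#' @export
step_metrics <- function(trace, band = 0.02) {
  sp <- trace$setpoint_lpm
  if (max(sp) == min(sp) && max(sp) == 0) stop("no setpoint step detected")
  w <- step_window(trace)
  y <- trace$flow_meas_lpm[w]
  t <- trace$time_s[w]
  final <- mean(y[seq.int(max(1, floor(0.9 * length(y))), length(y))])

  # 10-90% rise time of the final value
  i10 <- which(y >= 0.1 * final)[1]
  i90 <- which(y >= 0.9 * final)[1]
  rise <- if (is.na(i10) || is.na(i90)) NA_real_ else t[i90] - t[i10]

  overshoot <- max(0, (max(y) - final) / abs(final) * 100)
  sse <- sp[w[1]] - final

  vol <- pracma::trapz(t, y) * 1000 / 60

  structure(list(settling_time = settling_time(trace, band = band),
                 rise_time = rise,
                 overshoot_pct = overshoot,
                 steady_state_error = sse,
                 delivered_volume = vol),
            class = "step_metrics")
}

#' @export
print.step_metrics <- function(x, ...) {
  cat("<step_metrics>\n")
  cat(sprintf("  settling time      %.3f s\n", x$settling_time))
  cat(sprintf("  rise time (10-90%%) %.3f s\n", x$rise_time))
  cat(sprintf("  overshoot          %.1f %%\n", x$overshoot_pct))
  cat(sprintf("  steady-state error %.3f L/min\n", x$steady_state_error))
  cat(sprintf("  delivered volume   %.1f mL\n", x$delivered_volume))
  invisible(x)
}
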