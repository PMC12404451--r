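#' PID gains
#'
#' Parallel-form discrete PID gains. The defaults are the workbench's tuned
#' values for the synthetic plant (proportional 5.7, integral 87.3 1/s,
#' derivative 0.05 s), operating on flow error expressed in L/s.
#'
#' @param kp Proportional gain (dimensionless).
#' @param ki Integral gain, 1/s.
#' @param kd Derivative gain, s.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 5.7, ki = 87.3, kd = 0.05) {
  stopifnot(is.finite(kp), kp >= 0, is.finite(ki), ki >= 0,
            is.finite(kd), kd >= 0)
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' Fresh PID internal state
#'
#' @return An object of class `pid_state` with zero integral accumulator,
#'   previous error and filtered derivative.
#' @export
pid_state <- function() {
  structure(list(integral_accum = 0, prev_error = 0, derivative_filtered = 0),
            class = "pid_state")
}

#' One step of the discrete PID law
#'
#' `u = kp*e + ki*I + kd*d_f` with rectangular integration (the integral
#' includes the current sample), a first-order-filtered backward-difference
#' derivative (filter time constant `10*dt`), conditional-integration
#' anti-windup (the integral is frozen when the unclipped output saturates in
#' the direction of the current error), and output clipping to `limits`.
#'
#' @param gains A [pid_gains()] object.
#' @param error Current error (in the units the gains were tuned for).
#' @param state A [pid_state()] object.
#' @param dt Sample time, s.
#' @param limits Output saturation limits, length-2 numeric; use
#'   `c(-Inf, Inf)` to disable saturation (and with it anti-windup).
#' @return A list with `command` (clipped), `raw` (pre-clip output) and the
#'   updated `state`.
#' @export
pid_step <- function(gains, error, state, dt, limits = c(0, 1)) {
  if (!is.finite(error)) stop("PID error must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")

  tf <- 10 * dt
  d_raw <- (error - state$prev_error) / dt
  d_f <- state$derivative_filtered +
    dt / (tf + dt) * (d_raw - state$derivative_filtered)

  i_new <- state$integral_accum + error * dt
  u <- gains$kp * error + gains$ki * i_new + gains$kd * d_f

  # anti-windup: freeze the integral when pushing further into saturation
  if ((u > limits[2] && error > 0) || (u < limits[1] && error < 0)) {
    i_new <- state$integral_accum
    u <- gains$kp * error + gains$ki * i_new + gains$kd * d_f
  }

  state$integral_accum <- i_new
  state$prev_error <- error
  state$derivative_filtered <- d_f
  list(command = min(limits[2], max(limits[1], u)), raw = u, state = state)
}

#' PID controller for the closed-loop simulator
#'
#' Wraps [pid_step()] behind the [control_step()] interface, in the physical
#' units the gains were tuned for: the loop error arrives in L/min and
#' `error_scale` converts it to L/s; the PID output is the proportional
#' valve's drive voltage on its 0-10 V input, and `output_scale` converts
#' volts to the plant's command fraction. Saturation (and hence anti-windup)
#' acts at the true voltage limits.
#'
#' @param gains A [pid_gains()] object.
#' @param error_scale Multiplier applied to the L/min error before the PID
#'   law (default `1/60`, i.e. error in L/s).
#' @param output_scale Multiplier from controller output to command fraction
#'   (default `1/10`, i.e. output in volts on a 0-10 V valve).
#' @return A controller object.
#' @export
pid_controller <- function(gains = pid_gains(), error_scale = 1 / 60,
                           output_scale = 1 / 10) {
  structure(list(gains = gains, state = pid_state(),
                 error_scale = error_scale, output_scale = output_scale),
            class = c("pid_controller", "controller"))
}

#' @export
control_step.pid_controller <- function(controller, error, dt) {
  res <- pid_step(controller$gains, error * controller$error_scale,
                  controller$state, dt,
                  limits = c(0, 1 / controller$output_scale))
  controller$state <- res$state
  list(command = res$command * controller$output_scale,
       controller = controller)
}

#' Ziegler-Nichols critical-point estimate
#'
#' @param kc Critical (ultimate) proportional gain, positive.
#' @param tu Sustained-oscillation period at the critical gain, s, positive.
#' @return An object of class `zn_estimate`.
#' @export
zn_estimate <- function(kc, tu) {
  stopifnot(is.finite(kc), kc > 0, is.finite(tu), tu > 0)
  structure(list(kc = kc, tu = tu), class = "zn_estimate")
}

#' Classic Ziegler-Nichols PID rule
#'
#' `kp = 0.6*kc`, `ki = 1.2*kc/tu`, `kd = 0.075*kc*tu` (the closed-loop
#' ultimate-cycle rule with `Ti = tu/2`, `Td = tu/8`).
#'
#' @param est A [zn_estimate()] object.
#' @return A [pid_gains()] object.
#' @examples
#' zn_tune(zn_estimate(kc = 10, tu = 1)) # kp 6, ki 12, kd 0.75
#' @export
zn_tune <- function(est) {
  stopifnot(inherits(est, "zn_estimate"))
  pid_gains(kp = 0.6 * est$kc,
            ki = 1.2 * est$kc / est$tu,
            kd = 0.075 * est$kc * est$tu)
}

# Peaks of a signal: indices of strict local maxima above a floor.
local_peaks <- function(x, floor = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > floor]
}

#' Estimate the critical gain and oscillation period by a gain sweep
#'
#' Runs the scenario under proportional-only control for each gain in
#' `gains` (ascending) and returns the smallest gain that produces a
#' sustained oscillation of the flow error: at least `min_peaks` maxima of
#' the mean-centred error in the second half of the run, with every
#' successive peak-amplitude ratio inside `ratio_band`. The period is the
#' mean spacing of those maxima (proportional-only loops oscillate about a
#' nonzero offset, hence the centring). Intended for noise-free scenarios.
#'
#' @param scenario A [scenario()] describing the plant and setpoint.
#' @param gains Ascending vector of proportional gains to try.
#' @param error_scale Error scaling as in [pid_controller()].
#' @param ratio_band Acceptable successive peak-amplitude ratio range.
#' @param min_peaks Minimum number of peaks required.
#' @return A [zn_estimate()] object.
#' @export
estimate_kc_tu <- function(scenario, gains, error_scale = 1 / 60,
                           ratio_band = c(0.95, 1.05), min_peaks = 4) {
  stopifnot(length(gains) >= 1, all(diff(gains) > 0))
  for (k in gains) {
    ctrl <- pid_controller(pid_gains(kp = k, ki = 0, kd = 0),
                           error_scale = error_scale, output_scale = 1)
    tr <- run_closed_loop(ctrl, scenario)
    err <- tr$setpoint_lpm - tr$flow_meas_lpm
    half <- err[seq(floor(length(err) / 2), length(err))]
    centred <- half - mean(half)
    amp_floor <- 0.01 * max(abs(err))
    pk <- local_peaks(centred, floor = amp_floor)
    if (length(pk) < min_peaks) next
    amps <- centred[pk]
    ratios <- amps[-1] / amps[-length(amps)]
    if (all(ratios >= ratio_band[1] & ratios <= ratio_band[2])) {
      tu <- mean(diff(pk)) * scenario$dt # one maximum per period
      return(zn_estimate(kc = k, tu = tu))
    }
  }
  stop("no sustained oscillation found in the gain sweep; ",
       "widen the sweep or add loop delay")
}
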