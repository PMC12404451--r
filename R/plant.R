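#' Test-lung mechanical parameters
#'
#' Parameters of the single-compartment lung the synthetic plant drives.
#' Elastic recoil pressure is `volume / compliance + peep`; when
#' `resistance > 0` that pressure pushes back against the flow source, so the
#' delivered flow is the valve flow minus
#' `(volume / compliance + peep) / resistance` (converted to L/min). Here
#' `resistance` is the effective impedance of the supply path (pressure
#' regulator + proportional valve + airway) seen by the lung's elastic
#' recoil — large for a pressure-regulated source, which is why its default
#' is well above airway-only values. `resistance = 0` disables the coupling
#' and the lung becomes a pure flow integrator.
#'
#' Defaults emulate an adult test-lung setting (compliance 50 mL/cmH2O) fed
#' by a regulated supply (effective impedance 200 cmH2O/(L/s)); they are
#' fabricated working values, not measured ones — the hardware they emulate
#' was never quantified numerically.
#'
#' @param compliance Lung compliance, mL/cmH2O. Must be positive.
#' @param resistance Effective supply-path impedance, cmH2O/(L/s).
#'   Non-negative; `0` disables the back-pressure coupling.
#' @param peep Baseline (end-expiratory) pressure, cmH2O.
#' @return An object of class `lung_params`.
#' @export
lung_params <- function(compliance = 50, resistance = 200, peep = 0) {
  stopifnot(is.finite(compliance), compliance > 0,
            is.finite(resistance), resistance >= 0,
            is.finite(peep))
  structure(list(compliance = compliance, resistance = resistance, peep = peep),
            class = "lung_params")
}

#' Proportional-valve parameters
#'
#' Static and dynamic characteristics of the inspiratory proportional valve:
#' a backlash (play) operator of half-width `hysteresis_width` feeding a
#' power-law command-to-flow map `max_flow * h^gamma`, preceded dynamically by a
#' first-order actuator lag with time constant `response_time`.
#'
#' @param max_flow Flow at full opening, L/min.
#' @param hysteresis_width Half-width of the backlash play, in command units
#'   (fraction of full scale), in `[0, 0.5)`.
#' @param gamma Exponent of the command-to-flow nonlinearity (`1` = linear).
#' @param response_time First-order actuator time constant, s (`0` =
#'   instantaneous).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(max_flow = 80, hysteresis_width = 0.02, gamma = 1.4,
                         response_time = 0.005) {
  stopifnot(is.finite(max_flow), max_flow > 0,
            is.finite(hysteresis_width), hysteresis_width >= 0,
            hysteresis_width < 0.5,
            is.finite(gamma), gamma > 0,
            is.finite(response_time), response_time >= 0)
  structure(list(max_flow = max_flow, hysteresis_width = hysteresis_width,
                 gamma = gamma, response_time = response_time),
            class = "valve_params")
}

#' Flow-sensor parameters
#'
#' The measured flow is the true flow delayed by a pure transport delay of
#' `round(lag_time / dt)` samples and perturbed by i.i.d. Gaussian noise.
#'
#' @param lag_time Transport delay, s.
#' @param noise_sd Standard deviation of additive measurement noise, L/min.
#' @param accuracy_pct Nominal relative accuracy bound of the sensor, percent
#'   (documentation only; not used by the simulation).
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(lag_time = 0.005, noise_sd = 0.25, accuracy_pct = 5) {
  stopifnot(is.finite(lag_time), lag_time >= 0,
            is.finite(noise_sd), noise_sd >= 0)
  structure(list(lag_time = lag_time, noise_sd = noise_sd,
                 accuracy_pct = accuracy_pct),
            class = "sensor_params")
}

#' Flow disturbance (cough or leak)
#'
#' A cough is an additive half-sine flow pulse of peak `magnitude` over
#' `[onset, onset + duration]`; a leak is a constant flow loss of `magnitude`
#' while active.
#'
#' @param kind `"cough"` or `"leak"`.
#' @param onset Start time, s.
#' @param duration Active window length, s.
#' @param magnitude Peak (cough) or constant (leak) flow, L/min.
#' @return An object of class `disturbance`.
#' @export
disturbance <- function(kind = c("cough", "leak"), onset, duration, magnitude) {
  kind <- match.arg(kind)
  stopifnot(is.finite(onset), onset >= 0,
            is.finite(duration), duration > 0,
            is.finite(magnitude))
  structure(list(kind = kind, onset = onset, duration = duration,
                 magnitude = magnitude),
            class = "disturbance")
}

#' Initial plant state
#'
#' @param lung_volume Initial lung volume above FRC, mL.
#' @param valve_opening Initial valve opening fraction in `[0, 1]`.
#' @return An object of class `plant_state`. Besides the physical state it
#'   carries the backlash memory (`hyst_state`), the sensor delay buffer and
#'   the last true flow (for trapezoidal volume integration).
#' @export
plant_state <- function(lung_volume = 0, valve_opening = 0) {
  stopifnot(lung_volume >= 0, valve_opening >= 0, valve_opening <= 1)
  structure(list(lung_volume = lung_volume,
                 valve_opening = valve_opening,
                 hyst_state = valve_opening,
                 sensor_buffer = numeric(0),
                 last_true_flow = 0,
                 time = 0),
            class = "plant_state")
}

#' Static valve flow with backlash and power-law nonlinearity
#'
#' Applies a play (backlash) operator of half-width `hysteresis_width` to the
#' command, then the static map `max_flow * h^gamma`. The play operator keeps
#' the previous internal state `h` unless the command has moved more than the
#' play width away from it:
#' `h_new = min(command + w, max(command - w, h_prev))`.
#'
#' @param command Valve command in `[0, 1]`.
#' @param params A [valve_params()] object.
#' @param state A [plant_state()] object (carries the backlash memory).
#' @return A list with `flow` (L/min) and the updated `state`.
#' @examples
#' st <- plant_state()
#' valve_flow(1, valve_params(max_flow = 50, hysteresis_width = 0, gamma = 1), st)$flow
#' @export
valve_flow <- function(command, params, state) {
  if (!is.finite(command) || command < 0 || command > 1) {
    stop("valve command must be a finite value in [0, 1]")
  }
  w <- params$hysteresis_width
  h <- min(command + w, max(command - w, state$hyst_state))
  h <- min(1, max(0, h))
  state$hyst_state <- h
  list(flow = params$max_flow * h^params$gamma, state = state)
}

# Total disturbance flow (L/min) at time t: cough pulses add, leaks subtract.
disturbance_flow <- function(disturbances, t) {
  q <- 0
  for (d in disturbances) {
    active <- t >= d$onset && t <= d$onset + d$duration
    if (!active) next
    if (d$kind == "cough") {
      q <- q + d$magnitude * sin(pi * (t - d$onset) / d$duration)
    } else {
      q <- q - d$magnitude
    }
  }
  q
}

#' Advance the plant by one time step
#'
#' One explicit step of the synthetic plant: the valve opening relaxes toward
#' the command with first-order dynamics, the static valve map (backlash +
#' power law) produces the valve flow, lung back-pressure and any active
#' disturbances modify it, the lung volume integrates the true flow
#' (trapezoidal), and the sensor path delays and optionally perturbs the
#' measurement. Measurement noise, when `noise_sd > 0`, is drawn from the
#' current RNG stream (seed at the scenario level for reproducibility), or can
#' be supplied precomputed via `noise`.
#'
#' @param state A [plant_state()].
#' @param command Valve command in `[0, 1]`.
#' @param lung,valve,sensor Parameter objects.
#' @param disturbances List of [disturbance()] objects (may be empty).
#' @param dt Time step, s (positive; 1 ms recommended).
#' @param noise Optional precomputed noise value (L/min) to add to the
#'   measurement instead of drawing from the RNG.
#' @param exhale If `TRUE`, the expiratory valve is open and the lung drains
#'   passively with time constant `exhale_tau` (the inspiratory limb keeps
#'   operating normally; its sensor does not see the expiratory flow).
#' @param exhale_tau Passive-exhalation time constant, s.
#' @return A list with `state` (updated), `measured` and `true_flow` (L/min).
#' @export
step_plant <- function(state, command, lung, valve, sensor,
                       disturbances = list(), dt = 0.001, noise = NULL,
                       exhale = FALSE, exhale_tau = 0.3) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")

  # actuator lag (exact first-order update)
  if (valve$response_time > 0) {
    a <- 1 - exp(-dt / valve$response_time)
    state$valve_opening <- state$valve_opening +
      a * (command - state$valve_opening)
  } else {
    state$valve_opening <- command
  }

  vf <- valve_flow(state$valve_opening, valve, state)
  state <- vf$state

  q_bp <- if (lung$resistance > 0) {
    60 * (state$lung_volume / lung$compliance + lung$peep) / lung$resistance
  } else 0

  t_next <- state$time + dt
  q_true <- max(0, vf$flow - q_bp + disturbance_flow(disturbances, t_next))

  # trapezoidal volume update, L/min -> mL/s = 1000/60
  state$lung_volume <- max(0, state$lung_volume +
                             (state$last_true_flow + q_true) / 2 * dt * 1000 / 60)
  if (exhale) state$lung_volume <- state$lung_volume * exp(-dt / exhale_tau)
  state$last_true_flow <- q_true
  state$time <- t_next

  # sensor transport delay
  lag_n <- round(sensor$lag_time / dt)
  state$sensor_buffer <- c(state$sensor_buffer, q_true)
  if (length(state$sensor_buffer) > lag_n + 1) {
    state$sensor_buffer <-
      state$sensor_buffer[(length(state$sensor_buffer) - lag_n):length(state$sensor_buffer)]
  }
  delayed <- if (length(state$sensor_buffer) > lag_n) {
    state$sensor_buffer[length(state$sensor_buffer) - lag_n]
  } else 0

  eps <- if (!is.null(noise)) noise
         else if (sensor$noise_sd > 0) stats::rnorm(1, 0, sensor$noise_sd)
         else 0
  list(state = state, measured = delayed + eps, true_flow = q_true)
}
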