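# Shared fixtures built in code.

# The two reference 4th-order transfer functions shipped with the package.
tf_pid <- function() reference_tf("pid")
tf_fuzzy <- function() reference_tf("fuzzy")

# A small, fast scenario with an idealized linear plant (no hysteresis, no
# power-law, no sensor lag/noise, instantaneous valve) unless overridden.
linear_scenario <- function(duration = 0.5, max_flow = 60, lag_time = 0,
                            response_time = 0, resistance = 0,
                            setpoint_flow = 15, dt = 0.001) {
  scenario(target_volume = setpoint_flow * duration * 1000 / 60,
           inspiratory_time = duration,
           duration = duration, dt = dt,
           lung = lung_params(resistance = resistance),
           valve = valve_params(max_flow = max_flow, hysteresis_width = 0,
                                gamma = 1, response_time = response_time),
           sensor = sensor_params(lag_time = lag_time, noise_sd = 0))
}

# Plant-inverting stub: an exact discrete integrator that reaches zero error
# in one sample on the idealized linear plant (flow = max_flow * command).
perfect_controller <- function(max_flow = 60) {
  structure(list(cmd = 0, max_flow = max_flow),
            class = c("perfect_controller", "controller"))
}

control_step.perfect_controller <- function(controller, error, dt) {
  controller$cmd <- min(1, max(0, controller$cmd + error / controller$max_flow))
  list(command = controller$cmd, controller = controller)
}

# registerS3method so the generic in the package finds the helper class
registerS3method("control_step", "perfect_controller",
                 control_step.perfect_controller,
                 envir = asNamespace("ventbench"))

# Random stable 4th-order monic-denominator TF (poles drawn inside the unit
# circle: two real, one conjugate pair).
random_stable_tf <- function() {
  p_re <- stats::runif(2, -0.8, 0.8)
  r <- stats::runif(1, 0.1, 0.85)
  th <- stats::runif(1, 0.1, pi - 0.1)
  cc <- complex(modulus = r, argument = th)
  den <- Re(poly_from_roots(c(p_re, cc, Conj(cc))))
  discrete_tf(num = c(stats::runif(5, -1, 1)), den = den)
}

# Polynomial coefficients (descending powers, monic) from roots.
poly_from_roots <- function(roots) {
  coefs <- 1
  for (r in roots) coefs <- c(coefs, 0) - c(0, r * coefs)
  coefs
}
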