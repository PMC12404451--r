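# Save/restore the global RNG state around a seeded computation.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulation scenario
#'
#' Bundles everything one closed-loop run needs: plant parameters, the
#' setpoint profile, disturbances, breathing pattern, time step and seed.
#' Each breath is a step from 0 to the flow that delivers `target_volume` in
#' `inspiratory_time` at constant flow, followed (when
#' `expiratory_time > 0`) by an expiratory phase with zero setpoint during
#' which the lung vents passively and both controllers keep their internal
#' state — exactly as in sustained ventilation, where the integrator (PID)
#' and the held command (fuzzy) stay warm between breaths.
#'
#' @param name Scenario label.
#' @param target_volume Target tidal volume, mL.
#' @param inspiratory_time Inspiration length, s.
#' @param expiratory_time Expiration length, s (0 = single inspiration only).
#' @param breaths Number of breath cycles simulated.
#' @param lung,valve,sensor Parameter objects; see [lung_params()],
#'   [valve_params()], [sensor_params()].
#' @param disturbances List of [disturbance()] objects.
#' @param exhale_tau Passive-exhalation time constant, s.
#' @param duration Total simulated time, s; defaults to
#'   `breaths * (inspiratory_time + expiratory_time)`.
#' @param dt Time step, s.
#' @param seed Integer seed for measurement noise, or `NULL`.
#' @return An object of class `scenario` with a `setpoint` function of time
#'   (L/min).
#' @export
scenario <- function(name = "custom", target_volume = 500,
                     inspiratory_time = 1, expiratory_time = 0, breaths = 1,
                     lung = lung_params(), valve = valve_params(),
                     sensor = sensor_params(), disturbances = list(),
                     exhale_tau = 0.3,
                     duration = breaths * (inspiratory_time + expiratory_time),
                     dt = 0.001, seed = NULL) {
  stopifnot(target_volume > 0, inspiratory_time > 0, expiratory_time >= 0,
            breaths >= 1, duration > 0, dt > 0, exhale_tau > 0)
  sp_flow <- target_volume / inspiratory_time * 60 / 1000 # mL/s -> L/min
  ti <- inspiratory_time
  period <- inspiratory_time + expiratory_time
  structure(list(name = name, target_volume = target_volume,
                 inspiratory_time = inspiratory_time,
                 expiratory_time = expiratory_time,
                 breaths = breaths, period = period,
                 setpoint = function(t) {
                   t_in <- t - (ceiling(t / period) - 1) * period
                   ifelse(t_in <= ti, sp_flow, 0)
                 },
                 setpoint_flow = sp_flow,
                 lung = lung, valve = valve, sensor = sensor,
                 disturbances = disturbances, exhale_tau = exhale_tau,
                 duration = duration, dt = dt, seed = seed),
            class = "scenario")
}

#' Preset test scenarios (500 / 700 / 900 mL tidal volumes)
#'
#' The three tidal-volume presets the workbench compares controllers on:
#' 1 s inspiration at the constant flow that delivers the target (30, 42 and
#' 54 L/min respectively), 2 s passive expiration (I:E of 1:2, 20
#' breaths/min), two breath cycles. Performance is read off the second,
#' warmed-up breath (see [breath_trace()]), matching sustained operation.
#'
#' @param name One of `"v500"`, `"v700"`, `"v900"`.
#' @param noise_free If `TRUE`, sensor noise is switched off (nominal
#'   deterministic conditions); the transport delay is kept.
#' @param seed Seed for measurement noise (ignored when `noise_free`).
#' @param breaths Number of breath cycles.
#' @return A [scenario()].
#' @export
scenario_preset <- function(name = c("v500", "v700", "v900"),
                            noise_free = FALSE, seed = 1L, breaths = 2) {
  name <- match.arg(name)
  tv <- c(v500 = 500, v700 = 700, v900 = 900)[[name]]
  sens <- sensor_params()
  if (noise_free) sens$noise_sd <- 0
  scenario(name = name, target_volume = tv, inspiratory_time = 1,
           expiratory_time = 2, breaths = breaths,
           sensor = sens, seed = if (noise_free) NULL else seed)
}

#' Extract one breath's inspiratory window from a trace
#'
#' Returns the samples of the `breath`-th inspiration as a [flow_trace()]
#' with time re-referenced to the start of that inspiration, suitable for
#' [step_metrics()].
#'
#' @param trace A [flow_trace()] produced from `scn`.
#' @param scn The [scenario()] that produced it.
#' @param breath Breath index (1-based).
#' @return A [flow_trace()].
#' @export
breath_trace <- function(trace, scn, breath = scn$breaths) {
  stopifnot(breath >= 1, breath <= scn$breaths)
  t0 <- (breath - 1) * scn$period
  sel <- trace$time_s > t0 & trace$time_s <= t0 + scn$inspiratory_time
  out <- trace[sel, , drop = FALSE]
  out$time_s <- out$time_s - t0
  flow_trace(out)
}

#' Run a controller around the synthetic plant
#'
#' Advances plant and controller in lockstep over the scenario's duration.
#' The controller sees the most recent measured flow (one-step feedback
#' delay on the first sample, where the error is taken against zero flow).
#' Runs with the same seed are bit-identical.
#'
#' @param controller A controller implementing [control_step()].
#' @param scn A [scenario()].
#' @return A `flow_trace` data frame with columns `time_s`, `setpoint_lpm`,
#'   `flow_meas_lpm`, `flow_true_lpm`, `valve_cmd`, `volume_ml`.
#' @export
run_closed_loop <- function(controller, scn) {
  stopifnot(inherits(scn, "scenario"))
  n <- round(scn$duration / scn$dt)
  with_seed(scn$seed, {
    noise <- if (scn$sensor$noise_sd > 0) {
      stats::rnorm(n, 0, scn$sensor$noise_sd)
    } else rep(0, n)
    st <- plant_state()
    time_s <- setpoint_lpm <- flow_meas_lpm <- flow_true_lpm <-
      valve_cmd <- volume_ml <- numeric(n)
    meas <- 0
    for (k in seq_len(n)) {
      t_k <- k * scn$dt
      sp <- scn$setpoint(t_k)
      t_in <- t_k - (ceiling(t_k / scn$period) - 1) * scn$period
      exhaling <- scn$expiratory_time > 0 && t_in > scn$inspiratory_time
      if (exhaling) {
        # expiratory phase: the inspiratory flow controller is paused with its
        # state held (warm across breaths) and the proportional valve is shut
        cmd <- 0
      } else {
        res <- control_step(controller, sp - meas, scn$dt)
        controller <- res$controller
        if (!is.finite(res$command)) {
          stop(sprintf("controller returned a non-finite command at t = %.4f s",
                       t_k))
        }
        cmd <- res$command
      }
      ps <- step_plant(st, cmd, scn$lung, scn$valve, scn$sensor,
                       scn$disturbances, scn$dt, noise = noise[k],
                       exhale = exhaling, exhale_tau = scn$exhale_tau)
      st <- ps$state
      meas <- ps$measured
      time_s[k] <- t_k
      setpoint_lpm[k] <- sp
      flow_meas_lpm[k] <- meas
      flow_true_lpm[k] <- ps$true_flow
      valve_cmd[k] <- cmd
      volume_ml[k] <- st$lung_volume
    }
    flow_trace(data.frame(time_s = time_s, setpoint_lpm = setpoint_lpm,
                          flow_meas_lpm = flow_meas_lpm,
                          flow_true_lpm = flow_true_lpm,
                          valve_cmd = valve_cmd, volume_ml = volume_ml))
  })
}

#' Flow trace container
#'
#' A uniformly sampled record of one simulated (or imported) run: setpoint,
#' measured and true flow, valve command and cumulative volume.
#'
#' @param df Data frame with columns `time_s`, `setpoint_lpm`,
#'   `flow_meas_lpm`, `flow_true_lpm`, `valve_cmd`, `volume_ml`.
#' @return The data frame with class `flow_trace` prepended.
#' @export
flow_trace <- function(df) {
  need <- c("time_s", "setpoint_lpm", "flow_meas_lpm", "flow_true_lpm",
            "valve_cmd", "volume_ml")
  if (!all(need %in% names(df))) {
    stop("flow trace requires columns: ", paste(need, collapse = ", "))
  }
  class(df) <- c("flow_trace", "data.frame")
  df
}

#' @export
print.flow_trace <- function(x, ...) {
  n <- nrow(x)
  dt <- if (n > 1) x$time_s[2] - x$time_s[1] else NA
  cat(sprintf("<flow_trace> %d samples, dt = %g s, %.2f s total\n",
              n, dt, x$time_s[n]))
  cat(sprintf("  final volume %.1f mL; measured flow range [%.2f, %.2f] L/min\n",
              x$volume_ml[n], min(x$flow_meas_lpm), max(x$flow_meas_lpm)))
  invisible(x)
}

#' Write / read a flow trace as CSV
#'
#' Plain UTF-8 CSV with a header row and `.` decimal separator; numbers are
#' printed at 12 significant digits so a write-read round trip is lossless at
#' that precision.
#'
#' @param trace A [flow_trace()].
#' @param path File path.
#' @return `write_flow_trace` returns `path` invisibly; `read_flow_trace`
#'   returns a [flow_trace()].
#' @export
write_flow_trace <- function(trace, path) {
  out <- as.data.frame(lapply(trace, function(col) {
    if (is.numeric(col)) signif(col, 12) else col
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_trace
#' @export
read_flow_trace <- function(path) {
  flow_trace(utils::read.csv(path))
}
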