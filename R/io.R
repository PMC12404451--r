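#' Generate seeded synthetic fixture data
#'
#' Deterministic, seeded datasets for exercising the statistics and
#' identification modules without a closed-loop run:
#' * `"paired_flows"` — paired device/reference flow readings with a known
#'   bias and Gaussian disagreement (`params`: `n`, `bias`, `sd`, `level` the
#'   common flow level);
#' * `"step_trace"` — a first-order step response as a [flow_trace()]
#'   (`params`: `tau`, `amplitude`, `duration`, `dt`);
#' * `"tf_io_data"` — input/output sequences of a [discrete_tf()] driven by a
#'   random binary excitation (`params`: `tf`, `n`, `noise_sd`).
#'
#' @param kind One of `"paired_flows"`, `"step_trace"`, `"tf_io_data"`.
#' @param params Named list of kind-specific parameters (see above).
#' @param seed Integer seed.
#' @return `paired_flows`: data frame `device_lpm`, `reference_lpm`;
#'   `step_trace`: a [flow_trace()]; `tf_io_data`: list `u`, `y`.
#' @export
generate_fixture <- function(kind = c("paired_flows", "step_trace",
                                      "tf_io_data"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  with_seed(seed, switch(kind,
    paired_flows = {
      n <- p$n %||% 98
      level <- p$level %||% 30
      ref <- level + stats::rnorm(n, 0, p$ref_sd %||% 1)
      dev <- ref + (p$bias %||% -0.122) + stats::rnorm(n, 0, p$sd %||% 0.585)
      data.frame(device_lpm = dev, reference_lpm = ref)
    },
    step_trace = {
      tau <- p$tau %||% 0.1
      amp <- p$amplitude %||% 30
      dur <- p$duration %||% 1.2
      dt <- p$dt %||% 0.001
      t <- seq(dt, dur, by = dt)
      y <- amp * (1 - exp(-t / tau))
      flow_trace(data.frame(time_s = t, setpoint_lpm = amp,
                            flow_meas_lpm = y, flow_true_lpm = y,
                            valve_cmd = pmin(1, y / 60),
                            volume_ml = cumsum(y) * dt * 1000 / 60))
    },
    tf_io_data = {
      tf <- p$tf %||% reference_tf("pid")
      n <- p$n %||% 2000
      u <- sample(c(-1, 1), n, replace = TRUE)
      y <- simulate_tf(tf, u)
      if ((p$noise_sd %||% 0) > 0) y <- y + stats::rnorm(n, 0, p$noise_sd)
      list(u = u, y = y)
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the PID-versus-fuzzy comparison on a set of scenarios
#'
#' Evaluates both controllers on identical scenarios and seeds. For each
#' scenario and controller it runs `repeats` noisy closed-loop repetitions
#' and one noise-free run, computes step metrics on the noise-free run,
#' Bland-Altman agreement of the test-bench measurement against a simulated
#' reference analyzer (true flow plus independent analyzer noise, steady-state
#' samples only), and a Fisher variance test between bench and analyzer
#' steady-state readings. A separate multi-step excitation run identifies a
#' 4th-order closed-loop transfer function (setpoint to measured flow) per
#' controller, on which the Jury test and margins are reported.
#'
#' @param scenarios List of [scenario()] objects (at least one).
#' @param controllers Named list with elements `pid` and `flc` (controller
#'   objects; fresh copies are used per run).
#' @param repeats Number of noisy repetitions per scenario.
#' @param seed Master seed; every run's seed derives from it.
#' @param analyzer_sd Noise sd of the simulated reference analyzer, L/min.
#' @return An object of class `comparison_report`: nested list
#'   `result[[controller]][[scenario]]` with `metrics`, `ba`, `ftest`,
#'   `volume_ml`, plus per-controller `identified_tf`, `jury`, `margins`.
#' @export
run_comparison <- function(scenarios,
                           controllers = list(pid = pid_controller(),
                                              flc = flc_controller()),
                           repeats = 3, seed = 1L, analyzer_sd = 0.25) {
  stopifnot(length(scenarios) >= 1, all(c("pid", "flc") %in% names(controllers)))
  report <- list()
  for (cname in names(controllers)) {
    ctrl0 <- controllers[[cname]]
    per_scn <- list()
    for (si in seq_along(scenarios)) {
      scn <- scenarios[[si]]
      run_seed <- seed + 1000L * si  # identical for both controllers
      # noise-free nominal run for time-domain metrics
      scn0 <- scn
      scn0$sensor$noise_sd <- 0
      scn0$seed <- NULL
      tr0 <- run_closed_loop(ctrl0, scn0)
      br0 <- breath_trace(tr0, scn0)

      # noisy repeats: steady-state bench vs analyzer samples (last breath)
      t0 <- (scn$breaths - 1) * scn$period
      bench <- ana <- numeric(0)
      for (r in seq_len(repeats)) {
        scn_r <- scn
        scn_r$seed <- run_seed + r
        tr <- run_closed_loop(ctrl0, scn_r)
        ss <- tr$time_s > t0 + 0.5 * scn$inspiratory_time &
          tr$time_s <= t0 + scn$inspiratory_time
        idx <- which(ss)
        idx <- idx[seq(1, length(idx), by = 25)] # thin serially correlated samples
        a_noise <- with_seed(run_seed + 500L + r,
                             stats::rnorm(length(idx), 0, analyzer_sd))
        bench <- c(bench, tr$flow_meas_lpm[idx])
        ana <- c(ana, tr$flow_true_lpm[idx] + a_noise)
      }
      per_scn[[scn$name]] <- list(
        metrics = step_metrics(br0),
        volume_ml = step_metrics(br0)$delivered_volume,
        ba = bland_altman(bench, ana),
        ftest = fisher_variance_test(bench, ana))
    }
    # identification run: staircase setpoint excitation, noise-free
    id_scn <- scenario(name = "ident", target_volume = 500,
                       inspiratory_time = 3, expiratory_time = 0,
                       lung = scenarios[[1]]$lung, valve = scenarios[[1]]$valve,
                       sensor = scenarios[[1]]$sensor, dt = scenarios[[1]]$dt)
    id_scn$sensor$noise_sd <- 0
    id_scn$seed <- NULL
    levels <- c(20, 40, 30, 50, 25, 45)
    id_scn$setpoint <- function(t) levels[pmin(length(levels), floor(t / 0.5) + 1)]
    tr_id <- run_closed_loop(ctrl0, id_scn)
    sp <- tr_id$setpoint_lpm
    tf_hat <- fit_arx(sp, tr_id$flow_meas_lpm, na = 4, nb = 5, dt = id_scn$dt)
    report[[cname]] <- list(scenarios = per_scn,
                            identified_tf = tf_hat,
                            jury = jury_test(tf_hat$den),
                            margins = margins(tf_hat))
  }
  structure(list(controllers = report, repeats = repeats, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> seed", x$seed, "repeats", x$repeats, "\n")
  for (cname in names(x$controllers)) {
    cc <- x$controllers[[cname]]
    cat(sprintf("-- %s (identified loop %s)\n", cname,
                if (cc$jury$stable) "stable" else "UNSTABLE"))
    for (sname in names(cc$scenarios)) {
      s <- cc$scenarios[[sname]]
      cat(sprintf("   %s: volume %.0f mL, settling %.3f s, BA mean %.3f L/min, F %.3f\n",
                  sname, s$volume_ml, s$metrics$settling_time,
                  s$ba$mean_diff, s$ftest$F))
    }
  }
  invisible(x)
}
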