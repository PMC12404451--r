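test_that("static valve map honors closed, open and invalid commands", {
  st <- plant_state()
  vp <- valve_params(max_flow = 50, hysteresis_width = 0, gamma = 1)
  expect_equal(valve_flow(0, vp, st)$flow, 0)
  expect_equal(valve_flow(1, vp, st)$flow, 50)
  expect_error(valve_flow(1.2, vp, st), "\\[0, 1\\]")
  expect_error(valve_flow(NA_real_, vp, st), "finite")
})

test_that("backlash separates up- and down-sweep flows by the play width", {
  vp <- valve_params(max_flow = 1, hysteresis_width = 0.1, gamma = 1,
                     response_time = 0)
  st <- plant_state()
  cmds_up <- seq(0, 1, by = 0.01)
  cmds_dn <- rev(cmds_up)
  up <- dn <- numeric(length(cmds_up))
  for (i in seq_along(cmds_up)) {
    r <- valve_flow(cmds_up[i], vp, st); up[i] <- r$flow; st <- r$state
  }
  for (i in seq_along(cmds_dn)) {
    r <- valve_flow(cmds_dn[i], vp, st); dn[i] <- r$flow; st <- r$state
  }
  # closed form on monotone sweeps: h = cmd - w going up, cmd + w going down
  expect_equal(up[cmds_up == 0.5], 0.4, tolerance = 1e-12)
  expect_equal(dn[cmds_dn == 0.5], 0.6, tolerance = 1e-12)
  # loop area is positive with play, zero without
  area <- sum((rev(dn) - up)) * 0.01
  expect_gt(area, 0)
  vp0 <- valve_params(max_flow = 1, hysteresis_width = 0, gamma = 1)
  st <- plant_state()
  up0 <- vapply(cmds_up, function(u) {
    r <- valve_flow(u, vp0, st); st <<- r$state; r$flow
  }, numeric(1))
  dn0 <- vapply(cmds_dn, function(u) {
    r <- valve_flow(u, vp0, st); st <<- r$state; r$flow
  }, numeric(1))
  expect_equal(sum(rev(dn0) - up0), 0, tolerance = 1e-12)
})

test_that("closed valve with no noise measures exactly zero and keeps volume", {
  st <- plant_state()
  lp <- lung_params()
  vp <- valve_params(response_time = 0)
  sp <- sensor_params(noise_sd = 0)
  for (i in 1:50) {
    r <- step_plant(st, 0, lp, vp, sp)
    st <- r$state
    expect_identical(r$measured, 0)
  }
  expect_equal(st$lung_volume, 0)
  expect_error(step_plant(st, 0, lp, vp, sp, dt = 0), "positive")
})

test_that("constant 60 L/min for 0.5 s delivers 500 mL", {
  st <- plant_state()
  lp <- lung_params(resistance = 0)
  vp <- valve_params(max_flow = 60, hysteresis_width = 0, gamma = 1,
                     response_time = 0)
  sp <- sensor_params(lag_time = 0, noise_sd = 0)
  for (i in 1:500) st <- step_plant(st, 1, lp, vp, sp, dt = 0.001)$state
  expect_equal(st$lung_volume, 500, tolerance = 0.0015)
})

test_that("leak subtracts and cough adds to the true flow", {
  lp <- lung_params(resistance = 0)
  vp <- valve_params(max_flow = 20, hysteresis_width = 0, gamma = 1,
                     response_time = 0)
  sp <- sensor_params(lag_time = 0, noise_sd = 0)
  leak <- disturbance("leak", onset = 0, duration = 10, magnitude = 5)
  r <- step_plant(plant_state(), 1, lp, vp, sp, list(leak))
  expect_equal(r$true_flow, 15)
  cough <- disturbance("cough", onset = 0, duration = 0.2, magnitude = 30)
  st <- plant_state()
  # at the pulse midpoint (t = 0.1 s) the half-sine adds its full magnitude
  for (i in 1:100) {
    r <- step_plant(st, 1, lp, vp, sp, list(cough), dt = 0.001)
    st <- r$state
  }
  expect_equal(r$true_flow, 20 + 30 * sin(pi * 0.1 / 0.2), tolerance = 1e-6)
})

test_that("final volume equals the trapezoidal integral of true flow", {
  scn <- scenario_preset("v500", noise_free = TRUE, breaths = 1)
  scn$expiratory_time <- 0
  scn$duration <- 1
  tr <- run_closed_loop(pid_controller(), scn)
  vol_int <- pracma::trapz(tr$time_s, tr$flow_true_lpm) * 1000 / 60
  expect_equal(tr$volume_ml[nrow(tr)], vol_int, tolerance = 1e-3)
})

test_that("idealized plant is linear: superposition of command profiles", {
  lp <- lung_params(resistance = 150) # back-pressure coupling is linear too
  vp <- valve_params(max_flow = 60, hysteresis_width = 0, gamma = 1,
                     response_time = 0.01)
  sp <- sensor_params(lag_time = 0, noise_sd = 0)
  n <- 200
  u1 <- 0.3 * (1:n) / n
  u2 <- 0.2 * sin((1:n) / 15)^2
  run_profile <- function(u) {
    st <- plant_state()
    q <- numeric(n)
    for (i in 1:n) {
      r <- step_plant(st, u[i], lp, vp, sp, dt = 0.001)
      st <- r$state
      q[i] <- r$true_flow
    }
    list(q = q, vol = st$lung_volume)
  }
  a <- run_profile(u1); b <- run_profile(u2); ab <- run_profile(u1 + u2)
  expect_equal(ab$q, a$q + b$q, tolerance = 1e-9)
  expect_equal(ab$vol, a$vol + b$vol, tolerance = 1e-9)
})

test_that("seeded closed-loop runs are bit-identical", {
  scn <- scenario_preset("v500", seed = 11, breaths = 1)
  scn$duration <- 0.3
  t1 <- run_closed_loop(pid_controller(), scn)
  t2 <- run_closed_loop(pid_controller(), scn)
  expect_identical(t1, t2)
  scn$seed <- 12
  t3 <- run_closed_loop(pid_controller(), scn)
  expect_false(identical(t1$flow_meas_lpm, t3$flow_meas_lpm))
})

test_that("parameter constructors reject invalid physics", {
  expect_error(lung_params(compliance = 0))
  expect_error(valve_params(hysteresis_width = 0.6))
  expect_error(valve_params(gamma = 0))
  expect_error(sensor_params(noise_sd = -1))
  expect_error(disturbance("cough", onset = -1, duration = 1, magnitude = 5))
  expect_error(disturbance("hiccup", onset = 0, duration = 1, magnitude = 5))
})

test_that("a non-finite controller command aborts the simulation", {
  bad <- structure(list(), class = c("nan_controller", "controller"))
  registerS3method("control_step", "nan_controller",
                   function(controller, error, dt) {
                     list(command = NaN, controller = controller)
                   },
                   envir = asNamespace("ventbench"))
  scn <- linear_scenario(duration = 0.05)
  expect_error(run_closed_loop(bad, scn), "non-finite")
})
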