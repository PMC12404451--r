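test_that("fuzzification follows the triangular geometry", {
  v <- fuzzy_variable("e", -20, 20)
  # apex of each term gives degree 1 there and 0 for non-adjacent terms
  apexes <- c(-20, -10, 0, 10, 20)
  for (k in 1:5) {
    mu <- fuzzify(apexes[k], v)
    expect_equal(unname(mu[k]), 1)
    expect_equal(sum(mu > 0), 1) # apexes coincide with neighbours' feet
  }
  # halfway down a flank gives 0.5
  expect_equal(unname(fuzzify(5, v)["Zero"]), 0.5)
  expect_equal(unname(fuzzify(5, v)["SmallPositive"]), 0.5)
  # outside a term's support gives 0; outside the universe clamps
  expect_equal(unname(fuzzify(15, v)["Zero"]), 0)
  expect_equal(fuzzify(250, v), fuzzify(20, v))
  expect_error(fuzzify(NaN, v), "finite")
  # coverage: total membership positive everywhere on the universe
  xs <- seq(-20, 20, length.out = 401)
  tot <- vapply(xs, function(x) sum(fuzzify(x, v)), numeric(1))
  expect_true(all(tot > 0))
})

test_that("Mamdani inference clips and aggregates the right consequents", {
  cfg <- flc_config()
  one_hot <- function(k) { v <- numeric(5); v[k] <- 1; v }
  # zero error, any rate -> the NoChange term at full activation
  for (j in 1:5) {
    agg <- flc_infer(one_hot(3), one_hot(j), cfg)
    expect_equal(agg$mu, mf_eval(cfg$output_var$terms$NoChange, agg$x))
  }
  # large positive error, increasing -> OpenFast fully activated
  agg <- flc_infer(one_hot(5), one_hot(4), cfg)
  expect_equal(max(agg$mu[agg$x >= 0.05]), 1)
  expect_equal(agg$mu, mf_eval(cfg$output_var$terms$OpenFast, agg$x))
  # no activation at all -> identically zero aggregate
  agg <- flc_infer(numeric(5), numeric(5), cfg)
  expect_true(all(agg$mu == 0))
})

test_that("centroid defuzzification matches geometry and a dense oracle", {
  # fully activated triangle: centroid is (a+b+c)/3
  tri <- tri_mf(-0.1, -0.05, 0.05)
  x <- seq(-0.12, 0.12, length.out = 2001)
  expect_equal(defuzzify(list(x = x, mu = mf_eval(tri, x))),
               (-0.1 - 0.05 + 0.05) / 3, tolerance = 1e-6)
  # symmetric aggregate about zero -> exactly zero
  sym <- pmax(mf_eval(tri_mf(-2, -1, 0), x * 20), mf_eval(tri_mf(0, 1, 2), x * 20))
  expect_equal(defuzzify(list(x = x, mu = sym)), 0, tolerance = 1e-12)
  # zero area -> zero (no change)
  expect_equal(defuzzify(list(x = x, mu = numeric(length(x)))), 0)
  # triangle (0,1,2) clipped at 0.5 against a 1e5-point brute-force centroid
  xg <- seq(-0.5, 2.5, length.out = 10001)
  mu <- pmin(0.5, mf_eval(tri_mf(0, 1, 2), xg))
  xo <- seq(-0.5, 2.5, length.out = 1e5)
  muo <- pmin(0.5, mf_eval(tri_mf(0, 1, 2), xo))
  oracle <- sum(diff(xo) * (xo[-1] * muo[-1] + xo[-1e5] * muo[-1e5]) / 2) /
    sum(diff(xo) * (muo[-1] + muo[-1e5]) / 2)
  expect_equal(defuzzify(list(x = xg, mu = mu)), oracle,
               tolerance = 1e-6 * diff(range(xg)))
})

test_that("the default rule base is antisymmetric and monotone in error", {
  cfg <- flc_config()
  inc <- function(e, de) {
    defuzzify(flc_infer(fuzzify(e, cfg$error_var),
                        fuzzify(de, cfg$derror_var), cfg))
  }
  es <- seq(-20, 20, by = 2.5)
  des <- seq(-200, 200, by = 50)
  for (de in des) {
    outs <- vapply(es, inc, numeric(1), de = de)
    # antisymmetry against the mirrored inputs
    mirr <- vapply(-es, inc, numeric(1), de = -de)
    expect_equal(outs, -mirr, tolerance = 1e-9)
    # monotone non-decreasing in error for fixed rate
    expect_true(all(diff(outs) >= -1e-7))
    # bounded by the output universe
    expect_true(all(abs(outs) <= 0.1 + 1e-12))
  }
})

test_that("incremental actuation freezes at zero error and clips at limits", {
  cfg <- flc_config()
  expect_equal(flc_step(0, 0, cfg, prev_command = 0.4), 0.4)
  # large positive, increasing error opens the valve
  expect_gt(flc_step(18, 150, cfg, prev_command = 0.4), 0.4)
  # saturated high command stays at 1
  expect_equal(flc_step(18, 150, cfg, prev_command = 1), 1)
  expect_error(flc_step(NaN, 0, cfg, 0.5), "finite")
})

test_that("an FLC configuration survives a JSON round trip", {
  cfg <- flc_config()
  f <- withr::local_tempfile(fileext = ".json")
  write_flc_config(cfg, f)
  cfg2 <- read_flc_config(f)
  expect_equal(cfg2$rules, cfg$rules, ignore_attr = TRUE)
  expect_equal(cfg2$grid, cfg$grid)
  expect_equal(cfg2$step_time, cfg$step_time)
  for (vn in c("error_var", "derror_var", "output_var")) {
    expect_equal(cfg2[[vn]]$universe, cfg[[vn]]$universe)
    expect_equal(cfg2[[vn]]$terms, cfg[[vn]]$terms, ignore_attr = TRUE)
  }
  # identical behavior
  expect_equal(flc_step(7, -30, cfg2, 0.5), flc_step(7, -30, cfg, 0.5))
})

test_that("malformed fuzzy components are rejected", {
  expect_error(tri_mf(1, 0, 2))
  expect_error(tri_mf(1, 1, 1))
  cfg <- flc_config()
  bad_rules <- cfg$rules
  bad_rules[2, 2] <- "Explode"
  expect_error(flc_config(rules = bad_rules), "term")
  expect_error(flc_config(grid_points = 100), "grid_points")
})
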