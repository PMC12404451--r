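test_that("Jury test matches the unit-circle criterion on known cases", {
  expect_true(jury_test(tf_pid()$den)$stable)
  expect_true(jury_test(tf_fuzzy()$den)$stable)
  expect_false(jury_test(c(1, -2))$stable) # pole at 2
  expect_true(jury_test(c(1, -0.5))$stable)
  expect_true(jury_test(5)$stable) # degree 0: trivially stable
  expect_error(jury_test(c(0, 1)), "non-zero")
  # report structure: stable iff all conditions pass
  rep <- jury_test(tf_pid()$den)
  expect_identical(rep$stable, all(rep$conditions))
})

test_that("Jury verdict equals the root-modulus oracle on random polynomials", {
  set.seed(101)
  for (deg in 2:6) {
    for (i in 1:200) {
      den <- c(1, stats::runif(deg, -1.5, 1.5))
      expect_identical(jury_test(den)$stable,
                       max(Mod(polyroot(rev(den)))) < 1 - 1e-12,
                       info = paste(deg, paste(round(den, 4), collapse = " ")))
    }
  }
})

test_that("poles are the denominator roots in z", {
  expect_equal(tf_poles(c(1, -0.5)), 0.5 + 0i)
  expect_equal(sort(Im(tf_poles(c(1, 0, 0.25)))), c(-0.5, 0.5))
  expect_true(all(Mod(tf_poles(tf_pid())) < 1))
  expect_true(all(Mod(tf_poles(tf_fuzzy())) < 1))
})

test_that("frequency response reduces to coefficient sums at the endpoints", {
  tf <- tf_pid()
  expect_equal(freq_response(tf, 1e-9), sum(tf$num) / sum(tf$den) + 0i,
               tolerance = 1e-6)
  expect_equal(Re(freq_response(tf, 1e-4)), 0.2575, tolerance = 1e-3)
  unit <- discrete_tf(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  expect_equal(freq_response(unit, seq(0.1, 3, by = 0.1)),
               rep(1 + 0i, 30))
  # conjugate symmetry
  w <- seq(0.2, 3, by = 0.4)
  expect_equal(freq_response(tf, -w), Conj(freq_response(tf, w)))
})

test_that("margins reproduce the reference loops' stability margins", {
  m <- margins(tf_pid())
  expect_equal(m$gain_margin_db, 15.58, tolerance = 0.005)
  # |G| < 1 everywhere for this loop: no unity-gain crossover
  expect_identical(m$phase_margin_deg, Inf)
  mf <- margins(tf_fuzzy())
  expect_identical(mf$gain_margin_db, Inf)
  expect_identical(mf$phase_margin_deg, Inf)
  # a pure positive gain has no phase crossover at all
  mg <- margins(discrete_tf(c(0.5, 0, 0, 0, 0), c(1, 0, 0, 0, 0)))
  expect_identical(mg$gain_margin_db, Inf)
})

test_that("applying the gain margin moves the loop onto the critical point", {
  tf <- tf_pid()
  m <- margins(tf)
  g <- 10^(m$gain_margin_db / 20)
  scaled <- discrete_tf(tf$num * g, tf$den)
  expect_lt(min_distance_to_critical(scaled), 1e-6)
})

test_that("Nyquist winding number and critical distance match the references", {
  expect_identical(nyquist_encirclements(tf_pid()), 0L)
  expect_identical(nyquist_encirclements(tf_fuzzy()), 0L)
  # degenerate point curve at (-2, 0): winding 0 by convention
  const <- discrete_tf(c(-2, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
  expect_identical(nyquist_encirclements(const), 0L)
  # pole on the unit circle is indeterminate
  expect_error(nyquist_encirclements(discrete_tf(c(1, 0, 0, 0, 0),
                                                 c(1, -1, 0, 0, 0))),
               "unit circle")
  # the fuzzy loop stays farther from (-1, 0) than the PID loop
  expect_gt(min_distance_to_critical(tf_fuzzy()),
            min_distance_to_critical(tf_pid()))
  # G identically 0 sits at distance exactly 1
  expect_equal(min_distance_to_critical(discrete_tf(numeric(5),
                                                    c(1, 0, 0, 0, 0))), 1)
})

test_that("winding number obeys the argument principle on random loops", {
  # winding of G about (-1,0) over the counter-clockwise unit circle equals
  # (zeros of 1+G inside) - (poles of G inside); root counting is the oracle
  set.seed(77)
  n_done <- 0
  while (n_done < 25) {
    tf <- random_stable_tf()
    closed <- tf$den + tf$num
    if (abs(closed[1]) < 0.05) next # keep 1+G a genuine quartic
    if (any(abs(Mod(polyroot(rev(closed))) - 1) < 1e-2)) next # near-singular
    if (min_distance_to_critical(tf) < 1e-3) next
    z_in <- sum(Mod(polyroot(rev(closed))) < 1)
    p_in <- sum(Mod(polyroot(rev(tf$den))) < 1)
    expect_identical(nyquist_encirclements(tf), as.integer(z_in - p_in))
    n_done <- n_done + 1
  }
})

test_that("nyquist_curve export is conjugate-symmetric and finite", {
  cur <- nyquist_curve(tf_pid(), n = 500)
  expect_equal(nrow(cur), 1000)
  expect_true(all(is.finite(cur$re)), all(is.finite(cur$im)))
  half <- cur[cur$omega > 0, ]
  mirr <- cur[cur$omega < 0, ]
  expect_equal(half$re, rev(mirr$re))
  expect_equal(half$im, -rev(mirr$im))
})
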