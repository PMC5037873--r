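# Steady-state pools, half-lives, residence times, recycling, TTP50%.

ref_arm <- function() reference_mean_params()$retinol_arm

test_that("steady state reproduces the closed-form flux balance", {
  ss <- steady_state(ref_arm(), M5 = 4.3)
  expect_equal(ss$M6, 5.50 * 4.3 / (0.169 + 0.0599), tolerance = 1e-12)
  expect_equal(ss$M6, 103.32, tolerance = 1e-4)
  expect_equal(ss$DR, 6.189, tolerance = 1e-4)
  expect_equal(ss$FCR55, ss$DR / 4.3, tolerance = 1e-12)
  expect_error(steady_state(retinol_arm_params(24, 0.1, 0.1, 3, 5.5,
                                               0.169, 0), 4.3),
               "steady state")
})

test_that("FCR(6,5) equals the irreversible-loss coefficient", {
  set.seed(17)
  for (i in 1:20) {
    q <- random_subject_params()$retinol_arm
    expect_equal(steady_state(q, 4)$FCR65, q$L106, tolerance = 1e-12)
  }
})

test_that("a vanishing loss rate empties the disposal flux", {
  arm <- retinol_arm_params(24.2, 0.114, 0.113, 2.98,
                            L65 = 1, L56 = 1, L106 = 1e-9)
  ss <- steady_state(arm, M5 = 4.3)
  expect_equal(ss$M6, 4.3, tolerance = 1e-6)   # L65 = L56 symmetry
  expect_lt(ss$DR, 1e-6)
})

test_that("half-life follows ln2 over the summed exit rates", {
  expect_equal(half_life(5.50), 0.126027, tolerance = 1e-5)
  expect_equal(half_life(5.50) * 24, 3.025, tolerance = 1e-3)
  expect_equal(half_life(c(0.169, 0.0599)), 3.028, tolerance = 1e-3)
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(numeric(0)), "nonnegative|positive")
  expect_error(half_life(0), "positive")
})

test_that("residence times match the closed forms and each other", {
  rt <- residence_times(ref_arm())
  expect_equal(rt$T55, 0.6948, tolerance = 1e-4)
  expect_equal(rt$T65, 16.694, tolerance = 1e-4)
  expect_identical(rt$TSYS, rt$T55 + rt$T65)
  set.seed(23)
  for (i in 1:20) {
    q <- random_subject_params()$retinol_arm
    r <- residence_times(q)
    expect_equal(r$T65, 1 / q$L106, tolerance = 1e-12)
    expect_equal(r$T55, (q$L56 + q$L106) / (q$L65 * q$L106),
                 tolerance = 1e-12)
  }
  expect_error(residence_times(retinol_arm_params(24, 0.1, 0.1, 3, 5.5,
                                                  0.169, 0)),
               "infinite")
})

test_that("matrix-inverse residence times equal integrated occupancy", {
  # independent quadrature oracle: integrate the exchange subsystem for a
  # unit entry into plasma and accumulate occupancy time
  arm <- ref_arm()
  rhs <- function(t, y, p)
    list(c(-arm$L65 * y[1] + arm$L56 * y[2],
           arm$L65 * y[1] - (arm$L56 + arm$L106) * y[2],
           y[1], y[2]))
  sol <- deSolve::lsoda(c(1, 0, 0, 0), c(0, 2000), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  rt <- residence_times(arm)
  expect_equal(unname(sol[2, 4]), rt$T55, tolerance = 1e-3)
  expect_equal(unname(sol[2, 5]), rt$T65, tolerance = 1e-3)
})

test_that("recycling number and recycling time match the worked values", {
  rt <- residence_times(ref_arm())
  th5 <- half_life(5.50)
  rc <- recycling(rt$T55, rt$T65, th5)
  expect_equal(rc$v5, 4.513, tolerance = 1e-3)
  expect_equal(rc$tt5, 3.699, tolerance = 1e-3)
  expect_error(recycling(0.1, 16, 0.1), "undefined|recycling")
})

test_that("recycling increases with the stores-to-plasma return rate", {
  v5_at <- function(L56) {
    arm <- retinol_arm_params(24.2, 0.114, 0.113, 2.98, 5.50, L56,
                              0.0599)
    rt <- residence_times(arm)
    recycling(rt$T55, rt$T65, half_life(arm$L65))$v5
  }
  v <- vapply(c(0.05, 0.1, 0.169, 0.3, 0.6), v5_at, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("TTP50% sits in the expected range and obeys delay shifts", {
  p <- reference_mean_params()
  t50 <- ttp50(p, "C10")
  expect_gt(t50, 8)
  expect_lt(t50, 30)
  # a pure transport delay shifts first arrival one-for-one
  mk <- function(dt3) subject_params(
    retinol_arm_params(24.2, 0.114, dt3, 2.98, 5.50, 0.169, 0.0599),
    p$carotene_arm)
  shift <- ttp50(mk(0.6), "C10") - ttp50(mk(0.1), "C10")
  expect_equal(shift, 0.5 * 24, tolerance = 0.05)
})

test_that("a faster direct route shortens the time to plasma", {
  mk <- function(L52) subject_params(
    retinol_arm_params(24.2, L52, 0.113, 2.98, 5.50, 0.169, 0.0599),
    reference_mean_params()$carotene_arm)
  t50 <- vapply(c(0.114, 1, 5, 20), function(x) ttp50(mk(x), "C10"),
                numeric(1))
  expect_true(all(diff(t50) < 0))
})

test_that("days of stores divides pool by disposal rate", {
  expect_equal(round(days_of_stores(123, 6.7)), 18)
  expect_equal(days_of_stores(0, 6.7), 0)
  expect_equal(days_of_stores(246, 13.4), days_of_stores(123, 6.7))
  expect_error(days_of_stores(123, 0), "positive")
})

test_that("the full kinetic summary is internally consistent", {
  p <- reference_mean_params()
  ks <- kinetic_summary(p, M5 = 4.3)
  expect_identical(ks$TSYS, ks$T55 + ks$T65)
  # disposal rate three ways
  arm <- p$retinol_arm
  expect_equal(ks$DR, arm$L106 * ks$M6, tolerance = 1e-12)
  expect_equal(ks$DR, ks$FCR65 * ks$M6, tolerance = 1e-12)
  expect_equal(ks$DR, arm$L65 * ks$M5 - arm$L56 * ks$M6,
               tolerance = 1e-9)
  expect_equal(ks$dietary_input_U1, ks$DR / 0.75, tolerance = 1e-12)
  expect_equal(ks$thalf5, half_life(arm$L65) * 24, tolerance = 1e-12)
})
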