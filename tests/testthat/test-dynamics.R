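test_that("the quiescent state stays put over 100 h of integration", {
  p <- air_params()
  s0 <- air_state(params = p)
  tr <- integrate_air(s0, p, c(0, 100), macro_step = 0.5,
                      atol_pathogen = 1e-9)
  drift <- apply(abs(sweep(tr$state, 2, as.numeric(s0))), 2, max)
  # the quiescent point carries a ~1e-6/h residual from the background
  # cytokine sources, so a slow creep to a nearby equilibrium remains
  expect_lt(max(drift), 1e-3)
})

test_that("severity levels split into resolved and septic branches", {
  p <- air_params()
  for (load in c(1e6, 5e6)) {
    tr <- integrate_air(air_state(P_T = load, params = p), p, c(0, 500))
    oc <- classify_outcome(tr)
    expect_identical(oc$label, "healthy")
    expect_lte(oc$control_time, 24)
    # bounded excursion: tissue integrity essentially intact
    expect_gt(min(tr$state[, "TI"]), 0.95)
  }
  tr <- integrate_air(air_state(P_T = 1e7, params = p), p, c(0, 500))
  oc <- classify_outcome(tr)
  expect_identical(oc$label, "septic")
  # blood pathogen grows unchecked on the septic branch
  i48 <- which.min(abs(tr$time - 48))
  expect_gt(tr$state[i48, "P_B"], 1e4)
})

test_that("trajectory state stays in the biological domain", {
  p <- air_params()
  for (load in c(1e5, 5e6, 1e7, 1e9)) {
    tr <- integrate_air(air_state(P_T = load, params = p), p, c(0, 300))
    expect_true(all(tr$state >= 0))
    expect_true(all(tr$state[, "B"] <= 1 + 1e-9))
    expect_true(all(tr$state[, "TI"] <= 1 + 1e-9))
    expect_true(all(tr$state[, "TI"] >= p[["TI_min"]] - 1e-12))
    expect_true(all(diff(tr$time) > 0))
    expect_true(all(tr$R %in% c(0, 1)))
  }
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  p <- air_params()
  for (load in c(1e6, 5e6, 1e7)) {
    tr <- integrate_air(air_state(P_T = load, params = p), p, c(0, 48))
    n <- length(tr$time)
    oracle <- air_integrate_rk4(air_state(P_T = load, params = p), p,
                                t_end = 48, dt = 1e-3)
    adaptive <- tr$state[n, ]
    denom <- pmax(abs(oracle$state), 1e-6)
    expect_lt(max(abs(adaptive - oracle$state) / denom), 1e-4)
    expect_equal(tr$R[n], oracle$R)
  }
})

test_that("outcome classification is stable under horizon extension", {
  p <- air_params()
  for (load in c(1e6, 5e6, 1e7)) {
    lab500 <- classify_outcome(
      integrate_air(air_state(P_T = load, params = p), p, c(0, 500)))$label
    lab1000 <- classify_outcome(
      integrate_air(air_state(P_T = load, params = p), p, c(0, 1000)))$label
    expect_identical(lab500, lab1000)
  }
})

test_that("an all-zero pathogen trajectory is healthy with control time zero", {
  p <- air_params()
  tr <- integrate_air(air_state(params = p), p, c(0, 250), macro_step = 0.5)
  oc <- classify_outcome(tr)
  expect_identical(oc$label, "healthy")
  expect_equal(oc$control_time, 0)
})

test_that("bisection brackets must straddle the separatrix", {
  expect_error(find_critical_load(bracket = c(1e2, 1e3), horizon = 250),
               "classify")
})

test_that("the critical load is robust and correctly oriented", {
  cl <- find_critical_load(S_P = 0.6)
  expect_gt(cl$critical_load, 1e6)
  expect_lt(cl$critical_load, 1e7)
  p <- air_params()
  for (f in c(0.5, 0.9)) {
    tr <- integrate_air(air_state(P_T = cl$critical_load * f, params = p),
                        p, c(0, 500))
    expect_identical(classify_outcome(tr)$label, "healthy")
  }
  for (f in c(1.1, 1.5)) {
    tr <- integrate_air(air_state(P_T = cl$critical_load * f, params = p),
                        p, c(0, 500))
    expect_identical(classify_outcome(tr)$label, "septic")
  }
  # halving the macro step moves the estimate by less than 1%
  cl2 <- find_critical_load(S_P = 0.6, macro_step = 0.025)
  expect_lt(abs(cl2$critical_load / cl$critical_load - 1), 0.01)
})

test_that("trajectories export to CSV and read back intact", {
  p <- air_params()
  tr <- integrate_air(air_state(P_T = 1e7, params = p), p, c(0, 5))
  f <- tempfile(fileext = ".csv")
  export_trajectory(tr, f)
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(nrow(df), length(tr$time))
  expect_equal(df$P_T, unname(tr$state[, "P_T"]), tolerance = 1e-12)
  expect_true(all(c("time_h", "NO", "R", "TI") %in% names(df)))
  unlink(f)
})
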