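test_that("parameter registry holds the published defaults and rejects unknowns", {
  p <- air_params()
  expect_equal(p[["S_P"]], 0.60)
  expect_equal(p[["k_PT"]], 3.7e4)
  expect_equal(p[["theta_P"]], 1.35e-4)
  expect_equal(p[["PT_plus"]], 2.0e6)
  expect_equal(p[["PT_minus"]], 1e3)
  expect_equal(p[["k_PBNA"]], 5.8)
  expect_equal(p[["x_66"]], 0.5)
  expect_equal(p[["k_D6"]], 0.125)
  expect_equal(p[["x_DNO"]], 0.5)
  expect_equal(p[["k_NOMA"]], 2.0)
  expect_error(air_params(not_a_param = 1), "unknown AIR parameter")
  expect_error(air_params(PT_minus = 5e6), "PT_minus < PT_plus")
  p2 <- air_params(S_P = 0.65)
  expect_equal(p2[["S_P"]], 0.65)
})

test_that("parameter registry round-trips through its JSON file format", {
  p <- air_params(S_P = 0.6123456789012345, kappa_PT = 3.21e6)
  f <- tempfile(fileext = ".json")
  write_air_params(p, f)
  p2 <- read_air_params(f)
  expect_identical(unclass(p2), unclass(p))
  unlink(f)
})

test_that("the healthy state is constructed at the quiescent equilibrium", {
  p <- air_params()
  s <- air_state(params = p)
  expect_equal(s[["eNOS"]], 0.0125)
  expect_equal(s[["M_R"]], 1)
  expect_equal(s[["N_R"]], 1)
  expect_equal(s[["IL6"]], 1e-3)
  expect_equal(s[["IL10"]], 1e-2)
  expect_equal(s[["TI"]], 1)
  expect_equal(nitric_oxide(s, p), 0.0125)
  expect_error(air_state(B = 1.5), "B must lie")
  expect_error(air_state(P_T = -1), ">= 0")
})

test_that("nitric oxide follows the algebraic amplification relation", {
  p <- air_params()
  s <- air_state(params = p)
  s[["iNOS"]] <- 1; s[["M_A"]] <- 0; s[["N_A"]] <- 0; s[["eNOS"]] <- 0
  expect_equal(nitric_oxide(s, p), 1)
  s[["M_A"]] <- 0.6; s[["N_A"]] <- 0.4; s[["eNOS"]] <- 0.5
  expect_equal(nitric_oxide(s, p), 1 * (1 + 2 * 1) + 0.5)  # = 3.5
  s[["iNOS"]] <- 0; s[["eNOS"]] <- 0.0125
  expect_equal(nitric_oxide(s, p), 0.0125)
  # NO >= eNOS always
  expect_gte(nitric_oxide(s, p), s[["eNOS"]])
})

test_that("TLR switch is hysteretic between the two thresholds", {
  expect_equal(tlr_update(3e6, 0), 1)   # above the upper threshold
  expect_equal(tlr_update(1e2, 1), 0)   # below the lower threshold
  expect_equal(tlr_update(1e5, 1), 1)   # in between: retains state
  expect_equal(tlr_update(1e5, 0), 0)
  expect_error(tlr_update(1e5, 2), "0 or 1")
})

test_that("a triangular pathogen sweep flips the switch only at its thresholds", {
  p <- air_params()
  up <- 10^seq(2, 7, length.out = 301)
  sweep <- c(up, rev(up))
  R <- 0
  flips <- data.frame(P_T = numeric(), to = numeric())
  for (x in sweep) {
    newR <- tlr_update(x, R, p)
    if (newR != R) flips <- rbind(flips, data.frame(P_T = x, to = newR))
    R <- newR
  }
  expect_equal(nrow(flips), 2L)
  expect_equal(flips$to, c(1, 0))
  # rising flip just above PT_plus, falling flip just below PT_minus
  expect_gt(flips$P_T[1], p[["PT_plus"]])
  expect_lt(flips$P_T[1], p[["PT_plus"]] * 1.1)
  expect_lt(flips$P_T[2], p[["PT_minus"]])
  expect_gt(flips$P_T[2], p[["PT_minus"]] / 1.1)
})

test_that("the healthy equilibrium is a near-fixed point of the derivatives", {
  p <- air_params()
  d <- air_derivatives(air_state(params = p), p, R = 0)
  # the only non-vanishing terms are the residual background IL-6 drives
  expect_lt(max(abs(d)), 2e-6)
})

test_that("growth modifiers replace the intrinsic rates", {
  p <- air_params()
  s <- air_state(P_T = 1e6, P_B = 100, params = p)
  d0 <- air_derivatives(s, p, R = 1)
  dz <- air_derivatives(s, p, R = 1,
                        modifier = growth_modifier(S_net_blood = 0))
  # zero net blood growth removes exactly S_P * P_B from dP_B/dt
  expect_equal(d0[["P_B"]] - dz[["P_B"]], p[["S_P"]] * 100,
               tolerance = 1e-9)
  # the net rate may be negative, but never exceeds S_P
  dfast <- air_derivatives(s, p, R = 1,
                           modifier = growth_modifier(S_net_blood = 5))
  expect_equal(dfast[["P_B"]], d0[["P_B"]])
})

test_that("compiled and reference right-hand sides agree", {
  p <- air_params()
  set.seed(7)
  for (k in 1:25) {
    s <- air_state(params = p)
    s[2:18] <- abs(as.numeric(s)[2:18] + rnorm(17, 0, 0.5))
    s[["B"]] <- runif(1); s[["TI"]] <- runif(1)
    s[["P_T"]] <- runif(1, 0, 2e7); s[["P_B"]] <- runif(1, 0, 1e5)
    R <- sample(0:1, 1)
    d_ref <- air_derivatives(s, p, R = R)
    pv <- sepsim:::.air_parms_vec(p)
    out <- deSolve::rk4(y = c(as.numeric(s), Rsw = R),
                        times = c(0, 1e-7), func = "air_derivs",
                        parms = pv, dllname = "sepsim",
                        initfunc = "air_initmod", nout = 1L)
    d_c <- (as.numeric(out[2, 2:19]) - as.numeric(s)) / 1e-7
    expect_equal(d_c, unname(d_ref), tolerance = 1e-5)
  }
})
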