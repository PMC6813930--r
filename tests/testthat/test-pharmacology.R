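test_that("two-compartment kinetics conserve drug mass", {
  pk <- pk_params(V1 = 8, V2 = 18, Q = 24, CL = 16.2, fu = 0.7)
  amounts <- c(0, 0)
  infused <- 0
  eliminated <- 0
  set.seed(11)
  for (i in 1:100) {
    rate <- sample(c(0, 9000), 1)
    st <- pk_step(pk, amounts, rate, dt = 0.05)
    infused <- infused + rate * 0.05
    eliminated <- eliminated + st$eliminated
    amounts <- st$amounts
  }
  expect_equal(eliminated + sum(amounts), infused, tolerance = 1e-12)
  expect_true(all(amounts >= 0))
})

test_that("kinetics are linear in dose", {
  pk <- drug_registry()$piperacillin$pk
  p1 <- pk_profile(pk, 2250, 0.5, t_end = 12)
  p2 <- pk_profile(pk, 4500, 0.5, t_end = 12)
  expect_equal(2 * p1$C_plasma, p2$C_plasma, tolerance = 1e-9)
  expect_equal(2 * p1$AUC, p2$AUC, tolerance = 1e-9)
})

test_that("a bolus with negligible elimination holds a constant level", {
  pk <- pk_params(V1 = 10, V2 = 10, Q = 5, CL = 1e-9, fu = 0.5)
  st <- pk_step(pk, c(500, 0), 0, dt = 50)  # long enough to equilibrate
  expect_equal(sum(st$amounts), 500, tolerance = 1e-6)
  expect_equal(st$C_u, 0.5 * st$amounts[1] / 10)
})

test_that("piperacillin reproduces its literature exposure and effect window", {
  reg <- drug_registry()
  pr <- pk_profile(reg$piperacillin$pk, dose = 4500, duration = 0.5,
                   t_end = 24, dt = 0.005)
  expect_equal(pr$AUC, 278, tolerance = 0.02)
  red <- reg$piperacillin$pd$S_max - antibiotic_snet(pr$C_u,
                                                     reg$piperacillin$pd)
  expect_equal(max(red), 0.70, tolerance = 0.01)
  window <- range(pr$time[red >= 0.95 * max(red)])
  expect_equal(diff(window), 3.0, tolerance = 0.1)
})

test_that("net growth vanishes exactly at the MIC for any parameters", {
  set.seed(99)
  for (k in 1:300) {
    pd <- antibiotic_pd(S_max = runif(1, 0.05, 3),
                        S_min = -runif(1, 0.05, 3),
                        MIC = runif(1, 0.1, 200),
                        gamma = runif(1, 0.3, 12))
    expect_equal(antibiotic_snet(pd$MIC, pd), 0, tolerance = 1e-14)
    expect_equal(antibiotic_snet(0, pd), pd$S_max)
    expect_equal(antibiotic_snet(1e12 * pd$MIC, pd), pd$S_min,
                 tolerance = 1e-3)
  }
})

test_that("net growth is continuous and strictly decreasing in concentration", {
  pd <- antibiotic_pd()
  cu <- seq(0, 200, length.out = 2000)
  sn <- antibiotic_snet(cu, pd)
  expect_true(all(diff(sn) <= 0))
  mid <- cu > 2 & cu < 40
  expect_true(all(diff(sn[mid]) < 0))
  expect_true(all(sn <= pd$S_max & sn >= pd$S_min))
  # sign change exactly at the MIC
  expect_gt(antibiotic_snet(pd$MIC * 0.999, pd), 0)
  expect_lt(antibiotic_snet(pd$MIC * 1.001, pd), 0)
})

test_that("sustained supra-MIC antibiotic rescues the septic trajectory", {
  p <- air_params()
  # drive the coupled system with a constant suppressed growth rate
  tr <- integrate_air(air_state(P_T = 1e7, params = p), p, c(0, 120),
                      modifier_fn = growth_modifier(S_net_tissue = -0.1,
                                                    S_net_blood = -0.1))
  n <- length(tr$time)
  expect_false(tr$capped)
  expect_lt(tr$state[n, "P_B"], 1)
  expect_lt(tr$state[n, "P_T"], 1)
})

test_that("vasopressor effect is a sigmoid anchored at zero and EC50", {
  pd <- vasopressor_pd()
  expect_equal(vasopressor_effect(0, pd), 0)
  expect_equal(vasopressor_effect(pd$EC_50, pd), pd$E_max / 2)
  expect_true(all(diff(vasopressor_effect(seq(0, 50, 0.5), pd)) >= 0))
})

test_that("fluid compounds carry their albumin composition", {
  expect_equal(fluid_compound("saline")$albumin_g_dl, 0)
  expect_equal(fluid_compound("albumin_colloid")$albumin_g_dl, 5)
})

test_that("the drug registry round-trips through its file format", {
  reg <- drug_registry()
  f <- tempfile(fileext = ".json")
  write_drug_registry(reg, f)
  reg2 <- read_drug_registry(f)
  expect_equal(unclass(reg2$piperacillin$pk), unclass(reg$piperacillin$pk))
  expect_equal(reg2$piperacillin$pd$MIC, reg$piperacillin$pd$MIC)
  expect_equal(reg2$norepinephrine$pd$E_max, reg$norepinephrine$pd$E_max)
  unlink(f)
})
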