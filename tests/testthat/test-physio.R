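test_that("colloid osmotic pressure follows the plasma-protein cubic", {
  expect_equal(colloid_osmotic_pressure(0), 0)
  expect_equal(colloid_osmotic_pressure(7), 26.607)
  expect_gt(colloid_osmotic_pressure(7.5), colloid_osmotic_pressure(7))
  expect_error(colloid_osmotic_pressure(-1), ">= 0")
})

test_that("Starling flux is ohmic in the net driving pressure", {
  pair <- list(P_v_h = 20, P_i_h = 10, R1 = 2)
  expect_equal(starling_flux(pair, COP_v = 8, COP_i = 0), 1.0)
  expect_equal(starling_flux(pair, COP_v = 10, COP_i = 0), 0)
  pair$R1 <- 1
  expect_equal(starling_flux(pair, COP_v = 8, COP_i = 0), 2.0)
})

test_that("albumin flux has the right diffusion and convection limits", {
  pair <- list(sigma = 0.9, PS = 1.5)
  cp <- 0.045; ci <- 0.015
  # vanishing filtration: pure diffusion
  expect_equal(albumin_flux(pair, 1e-9, cp, ci), pair$PS * (cp - ci),
               tolerance = 1e-6)
  # large filtration: convection carries plasma-concentration solute
  J <- 5e4
  expect_equal(albumin_flux(pair, J, cp, ci), J * (1 - pair$sigma) * cp,
               tolerance = 1e-6)
  expect_equal(albumin_flux(pair, 0, 0.03, 0.03), 0)
})

test_that("baseline lymph return equals baseline filtration with a check valve", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  lym <- lymph_return(st$pairs, pars = pars)
  expect_equal(sum(lym), pars$filtration0, tolerance = 1e-12)
  # raised interstitial pressure increases return monotonically
  pr_hi <- st$pairs; pr_hi$Pi <- pr_hi$Pi + 1
  expect_true(all(lymph_return(pr_hi, pars = pars) > lym))
  # depressurized interstitium: the valve blocks backflow
  pr_lo <- st$pairs; pr_lo$Pi <- pr_lo$Pi - 50
  expect_true(all(lymph_return(pr_lo, pars = pars) == 0))
})

test_that("endothelial dysfunction scales resistance linearly down to a floor", {
  pars <- physio_params(a_R = 0.9, a_sigma = 0.9, floor_R = 0.05,
                        floor_sigma = 0.05)
  st <- physio_baseline(pars)
  pair <- lapply(st$pairs, function(v) if (length(v) > 1) v[1] else v)
  p1 <- endothelial_update(pair, TI = 1, pars)
  expect_equal(p1$R1, pair$R1_base)
  expect_equal(p1$sigma, pair$sigma_base)
  p05 <- endothelial_update(pair, TI = 0.5, pars)
  expect_equal(p05$R1, 0.55 * pair$R1_base)
  pars_deep <- physio_params(a_R = 2, a_sigma = 2, floor_R = 0.05,
                             floor_sigma = 0.05)
  p0 <- endothelial_update(pair, TI = 0, pars_deep)
  expect_equal(p0$R1, 0.05 * pair$R1_base)
  expect_equal(p0$sigma, 0.05 * pair$sigma_base)
  expect_error(endothelial_update(pair, TI = 1.2, pars), "\\[0, 1\\]")
})

test_that("hemodynamics hold the setpoint at rest and defend it when volume falls", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  h <- st$hemo
  for (i in 1:50)
    h <- hemodynamics_step(h, NO = pars$NO0, blood_volume = 5,
                           vasopressor_effect = 0, dt = 0.05, pars = pars)
  expect_equal(h$MAP, pars$MAP0, tolerance = 1e-9)
  expect_equal(h$HR, pars$HR0, tolerance = 1e-9)
  # 10% volume loss: baroreflex raises SVR and HR, partially restoring MAP
  h2 <- st$hemo
  map_open <- NULL
  for (i in 1:100) {
    h2 <- hemodynamics_step(h2, NO = pars$NO0, blood_volume = 4.5,
                            vasopressor_effect = 0, dt = 0.05, pars = pars)
    if (i == 1) map_open <- h2$MAP
  }
  expect_gt(h2$SVR_frac, 1)
  expect_gt(h2$HR, pars$HR0)
  expect_gt(h2$MAP, map_open)
  expect_lt(h2$MAP, pars$MAP0)
})

test_that("urine output saturates with pressure and volume", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  r <- urine_output(st$hemo, st$renal, 5, 0.05, pars)
  expect_equal(r$UO, pars$UO0)
  h_low <- st$hemo; h_low$MAP <- 65
  r2 <- urine_output(h_low, st$renal, 0.85 * 5, 0.05, pars)
  expect_lt(r2$UO, 0.625)
  h0 <- st$hemo; h0$MAP <- 0
  expect_equal(urine_output(h0, st$renal, 5, 0.05, pars)$UO, 0)
})

test_that("energy deficit and lactate rise under damage and recover at rest", {
  pars <- physio_params()
  r <- physio_baseline(pars)$renal
  for (i in 1:200) r <- metabolic_step(r, TI = 1, dt = 0.05, pars = pars)
  expect_equal(r$lactate, pars$lactate0, tolerance = 1e-6)
  lact <- numeric(0)
  for (i in 1:1400) {
    r <- metabolic_step(r, TI = 0.5, dt = 0.05, pars = pars)
    lact <- c(lact, r$lactate)
  }
  expect_true(all(diff(lact) > -1e-9))        # monotone rise to plateau
  expect_lt(diff(tail(lact, 2)), 1e-3)        # production ~ clearance
  r2 <- r
  for (i in 1:2000) r2 <- metabolic_step(r2, TI = 1, dt = 0.05, pars = pars)
  expect_equal(r2$lactate, pars$lactate0, tolerance = 1e-2)
})

test_that("symptom responses follow the Emax relation in lost integrity", {
  pars <- physio_params(rr_emax = 10, rr_e50 = 0.1)
  s1 <- symptom_effects(1, 0, pars)
  expect_equal(s1$dRR, 0)
  expect_equal(s1$dTemp, 0)
  expect_equal(s1$WBC, pars$WBC0)
  s2 <- symptom_effects(1 - pars$temp_e50, 0, pars)
  expect_equal(s2$dTemp, pars$temp_emax / 2)
  s3 <- symptom_effects(0.8, 0.1, pars)
  expect_equal(s3$dRR, 10 * 0.2 / 0.3)
  expect_equal(s3$WBC, pars$WBC0 + 0.1 * pars$wbc_per_na)
})

test_that("72 h of baseline physiology drifts less than 1% on every vital", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  vals <- list()
  for (i in seq_len(72 / 0.05)) {
    st <- physio_step(st, dt = 0.05, pars = pars)
    if (i %% 200 == 0)
      vals[[length(vals) + 1L]] <-
        c(st$hemo$MAP, st$hemo$SBP, st$hemo$HR, st$blood_volume,
          st$renal$UO, st$renal$lactate, st$renal$temp, st$renal$RR)
  }
  base <- c(pars$MAP0, pars$MAP0 + 2 * pars$PP0 / 3, pars$HR0, 5,
            pars$UO0, pars$lactate0, pars$temp0, pars$RR0)
  for (v in vals) expect_true(all(abs(v / base - 1) < 0.01))
  # tuned transcapillary filtration is 4.0 L/day, fully returned by lymph
  expect_equal(st$cum$filtration_ml / 1000 / 3, 4.0, tolerance = 1e-6)
  expect_equal(st$cum$lymph_ml, st$cum$filtration_ml, tolerance = 1e-6)
})

test_that("fluid and albumin are conserved to rounding error at every step", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  set.seed(5)
  worst_fluid <- 0; worst_alb <- 0
  air <- list(TI = 0.6, NO = 0.8, N_A = 0.1, IL6 = 0.3)
  for (i in 1:400) {
    inf <- sample(c(0, 20), 1)
    alb <- sample(c(0, 0.5), 1)
    tot0 <- st$blood_volume + sum(st$pairs$Vi)
    alb0 <- st$alb_p + sum(st$pairs$alb_i)
    uo_pre <- st$cum$urine_ml
    st2 <- physio_step(st, air = air, dt = 0.05, pars = pars,
                       infusion_ml_min = inf, infusion_alb_g_min = alb)
    external <- (inf + pars$intake_ml_min) * 3 / 1000 -
      (st2$cum$urine_ml - uo_pre) / 1000
    worst_fluid <- max(worst_fluid,
                       abs((st2$blood_volume + sum(st2$pairs$Vi)) - tot0 -
                             external))
    worst_alb <- max(worst_alb,
                     abs((st2$alb_p + sum(st2$pairs$alb_i)) - alb0 -
                           alb * 3))
    st <- st2
  }
  expect_lt(worst_fluid, 1e-9)
  expect_lt(worst_alb, 1e-9)
})

test_that("forcing integrity down drains volume and accelerates the heart", {
  pars <- physio_params()
  st <- physio_baseline(pars)
  bv <- c(); hr <- c()
  for (ti in c(0.9, 0.8, 0.7, 0.6)) {
    st_i <- physio_baseline(pars)
    air <- list(TI = ti, NO = pars$NO0, N_A = 0, IL6 = 1e-3)
    for (i in 1:400) st_i <- physio_step(st_i, air = air, dt = 0.05,
                                         pars = pars)
    bv <- c(bv, st_i$blood_volume)
    hr <- c(hr, st_i$hemo$HR)
  }
  expect_true(all(diff(bv) < 0))
  expect_true(all(diff(hr) > 0))
})

test_that("as albumin equalizes, the osmotic gradient and its flux vanish", {
  cp <- seq(0.045, 0.015, length.out = 20)
  dCOP <- colloid_osmotic_pressure(100 * cp * 7 / 4.5) -
    colloid_osmotic_pressure(100 * 0.015 * 7 / 4.5)
  expect_true(all(diff(dCOP) < 0))
  expect_equal(dCOP[20], 0)
  pair <- list(P_v_h = 25, P_i_h = -3, R1 = 2.66)
  flux_conv <- starling_flux(pair, COP_v = dCOP[20] + 6, COP_i = 6)
  expect_equal(flux_conv, (25 + 3) / 2.66)  # pure hydrostatic term
})
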