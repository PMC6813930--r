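test_that("control reviews follow the fluid-liberal decision rules", {
  pr <- protocol_state("control", start_h = 46)
  # half-hourly (non-hourly) review, SBP below goal, UO adequate:
  # exactly one 500 mL bolus
  r <- protocol_review(pr, list(SBP = 85, MAP = 70, UO = 0.7), t = 46.5)
  expect_equal(r$boluses, 500)
  expect_false(r$protocol$terminated)
  # hourly review with low urine output adds the supplemental bolus
  r2 <- protocol_review(pr, list(SBP = 85, MAP = 70, UO = 0.4), t = 47)
  expect_equal(r2$boluses, c(500, 500))
  # MAP alone below goal also triggers
  r3 <- protocol_review(pr, list(SBP = 95, MAP = 60, UO = 0.7), t = 46.5)
  expect_equal(r3$boluses, 500)
  # both goals met: discontinue to maintenance
  r4 <- protocol_review(pr, list(SBP = 95, MAP = 70, UO = 0.4), t = 46.5)
  expect_length(r4$boluses, 0)
  expect_true(r4$protocol$terminated)
  expect_true(r4$start_maintenance)
})

test_that("experimental reviews follow the restricted-fluid rules", {
  pr <- protocol_state("experimental", start_h = 46)
  expect_equal(pr$review_h, 1.0)
  r <- protocol_review(pr, list(SBP = 85, MAP = 70, UO = 0.4), t = 47)
  expect_equal(r$boluses, 250)
  r2 <- protocol_review(pr, list(SBP = 85, MAP = 70, UO = 0.8), t = 47)
  expect_length(r2$boluses, 0)
  r3 <- protocol_review(pr, list(SBP = 95, MAP = 70, UO = 0.4), t = 47)
  expect_true(r3$protocol$terminated)
  expect_true(r3$stop_pressor)
  expect_length(r3$boluses, 0)
})

test_that("the severe patient qualifies for the trial and a healthy one does not", {
  sc <- scenario(severity = "Severe", t_end = 44)
  base <- run_scenario(sc)
  pre <- refresh_pretrial(base$snapshot, sc)
  expect_true(pre$qualified)
  expect_lt(pre$SBP_end, 100)
  # urine output after the challenge marks persistent severe hypovolemia
  expect_lt(pre$UO_end, 0.625)
  expect_gt(pre$UO_end, 0.1)
  # an uninfected patient recovers pressure and does not qualify
  sc0 <- scenario(severity = "none", t_end = 44)
  base0 <- run_scenario(sc0)
  pre0 <- refresh_pretrial(base0$snapshot, sc0)
  expect_false(pre0$qualified)
})

test_that("both REFRESH arms run their course with audited decisions", {
  sc <- scenario(severity = "Severe", t_end = 44)
  base <- run_scenario(sc)
  pre <- refresh_pretrial(base$snapshot, sc)
  ctl <- run_refresh(pre$snapshot, "control", sc)
  ex <- run_refresh(pre$snapshot, "experimental", sc)

  # cumulative fluid (including the challenge) lands near the study totals
  expect_equal(ctl$snapshot$cum_fluid_ml / 1000, 4.25, tolerance = 0.12)
  expect_equal(ex$snapshot$cum_fluid_ml / 1000, 2.75, tolerance = 0.12)
  expect_gt(ctl$snapshot$cum_fluid_ml, ex$snapshot$cum_fluid_ml)

  # both arms reach the systolic goal within the six protocol hours
  expect_true(any(ctl$series$SBP_mmHg > 90 & ctl$series$time_h > 46.05))
  expect_true(any(ex$series$SBP_mmHg > 90 & ex$series$time_h > 46.05))

  # early norepinephrine raises MAP above the untreated continuation
  untx <- run_scenario(scenario(severity = "Severe", t_end = 47),
                       init = pre$snapshot)
  i47e <- which.min(abs(ex$series$time_h - 47))
  i47u <- which.min(abs(untx$series$time_h - 47))
  expect_gt(ex$series$MAP_mmHg[i47e], untx$series$MAP_mmHg[i47u] + 2)

  # audit completeness: every administered bolus is justified by a logged
  # threshold violation at its decision time
  for (sim in list(ctl, ex)) {
    given <- sim$audit[sim$audit$volume_ml > 0, ]
    if (nrow(given)) {
      pr <- sim$protocol
      ok <- given$SBP < pr$sbp_goal | given$MAP < pr$map_goal |
        given$UO < pr$uo_goal
      expect_true(all(ok))
    }
    # and the protocol ledger matches the audited volumes
    expect_equal(sum(sim$audit$volume_ml), sim$protocol$cum_fluid_ml)
  }

  # fluid accounting: cumulative fluid equals the integral of all infusions
  inf <- ctl$snapshot$infusions
  fl <- inf[inf$kind == "fluid", ]
  t_end <- ctl$snapshot$time
  delivered <- sum(fl$rate * (pmin(fl$end, t_end) - pmin(fl$start, t_end)))
  expect_equal(delivered, ctl$snapshot$cum_fluid_ml, tolerance = 1)
})

test_that("delaying treatment worsens bacteremia and tissue damage", {
  sc <- scenario(severity = "Severe", t_end = 44)
  base <- run_scenario(sc)
  pre <- refresh_pretrial(base$snapshot, sc)
  d <- delayed_treatment(12, challenge_h = 44, sc = sc)
  expect_gt(d$P_B_at_start / pre$snapshot$air[5], 1.5)
  # the delayed patient starts treatment no better off hemodynamically
  expect_lte(d$pretrial$snapshot$physio$hemo$MAP,
             pre$snapshot$physio$hemo$MAP + 1)
  # a zero delay reproduces the on-time control run
  d0 <- delayed_treatment(0, challenge_h = 44, sc = sc)
  ctl <- run_refresh(pre$snapshot, "control", sc)
  expect_equal(d0$sim$snapshot$cum_fluid_ml, ctl$snapshot$cum_fluid_ml,
               tolerance = 1e-6)
})
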