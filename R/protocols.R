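# REFRESH treatment protocols: the fluid-liberal control arm and the
# restricted-fluid / early-vasopressor experimental arm, with their
# reassessment rules, plus the pre-trial fluid challenge and the
# delayed-treatment scenario.

#' Protocol state
#'
#' Tracks a running REFRESH protocol: arm, start time, review cadence
#' (30 min for the control arm, 60 min for the experimental arm),
#' resuscitation goals (SBP 90 mmHg, MAP 65 mmHg, urine output
#' 0.625 mL/min, i.e. 0.5 mL/kg/h at 75 kg), cumulative protocol fluid and
#' termination status. Once the goals are met at a review, the protocol
#' terminates and only maintenance fluid continues.
#'
#' @param arm "control" or "experimental".
#' @param start_h Protocol start time (h post-infection).
#' @param weight_kg Patient weight.
#' @param sbp_goal,map_goal,uo_goal Goal thresholds.
#' @param duration_h Protocol duration (h).
#' @return List of class `protocol_state`.
#' @export
protocol_state <- function(arm = c("control", "experimental"),
                           start_h, weight_kg = 75, sbp_goal = 90,
                           map_goal = 65, uo_goal = 0.625,
                           duration_h = 6) {
  arm <- match.arg(arm)
  out <- list(arm = arm, start_h = start_h, weight_kg = weight_kg,
              sbp_goal = sbp_goal, map_goal = map_goal, uo_goal = uo_goal,
              duration_h = duration_h,
              review_h = if (arm == "control") 0.5 else 1.0,
              cum_fluid_ml = 0, terminated = FALSE, done = FALSE,
              uo_hist = numeric(0), uo_times = numeric(0))
  class(out) <- "protocol_state"
  out
}

.on_grid <- function(tau, step) {
  tau > 1e-9 && abs(tau / step - round(tau / step)) < 1e-6
}

#' Protocol review rules
#'
#' Applies one review of a running REFRESH protocol to the supplied vitals
#' and returns the updated protocol state together with the actions decided.
#' Control arm (every 30 min): terminate to maintenance when both SBP and
#' MAP exceed their goals; otherwise a 500 mL bolus when SBP or MAP is below
#' goal, plus (on the hour) another 500 mL when the trailing-30-min urine
#' output is below goal. Experimental arm (every 60 min): terminate
#' (stopping the vasopressor, keeping maintenance) when both pressure goals
#' are met; otherwise a 250 mL bolus when urine output is below goal.
#'
#' @param protocol `protocol_state`.
#' @param vitals List with `SBP`, `MAP` (mmHg, instantaneous) and `UO`
#'   (mL/min, trailing 30-min mean).
#' @param t Review time (h); rules that fire "hourly" require `t` to fall on
#'   the hour grid of the protocol.
#' @return List: `protocol` (updated), `boluses` (numeric vector of bolus
#'   volumes in mL decided now), `stop_pressor`, `start_maintenance`
#'   (logicals), `actions` (character log).
#' @export
protocol_review <- function(protocol, vitals, t) {
  tau <- t - protocol$start_h
  actions <- character(0)
  boluses <- numeric(0)
  stop_pressor <- FALSE
  start_maint <- FALSE
  goals_met <- vitals$SBP > protocol$sbp_goal &&
    vitals$MAP > protocol$map_goal
  if (goals_met) {
    protocol$terminated <- TRUE
    if (protocol$arm == "control") {
      start_maint <- TRUE
      actions <- "terminate: goals met, maintenance 75 mL/h"
    } else {
      stop_pressor <- TRUE
      actions <- "terminate: goals met, norepinephrine stopped"
    }
  } else if (protocol$arm == "control") {
    if (vitals$SBP < protocol$sbp_goal || vitals$MAP < protocol$map_goal) {
      boluses <- c(boluses, 500)
      actions <- c(actions, "500 mL bolus (SBP/MAP below goal)")
    }
    if (.on_grid(tau, 1.0) && vitals$UO < protocol$uo_goal) {
      boluses <- c(boluses, 500)
      actions <- c(actions, "500 mL bolus (UO below goal)")
    }
  } else {
    if (vitals$UO < protocol$uo_goal) {
      boluses <- c(boluses, 250)
      actions <- c(actions, "250 mL bolus (UO below goal)")
    }
  }
  protocol$cum_fluid_ml <- protocol$cum_fluid_ml + sum(boluses)
  list(protocol = protocol, boluses = boluses,
       stop_pressor = stop_pressor, start_maintenance = start_maint,
       actions = actions)
}

# called every macro step by run_scenario
.protocol_check <- function(protocol, phys, t, sc, inf, cum_fluid_ml) {
  # accumulate the urine-output history for the trailing 30-min mean
  protocol$uo_hist <- c(protocol$uo_hist, phys$renal$UO)
  protocol$uo_times <- c(protocol$uo_times, t)
  tau <- t - protocol$start_h
  if (tau > protocol$duration_h + 1e-9) {
    protocol$done <- TRUE
    return(list(protocol = protocol, inf = inf, entry = NULL))
  }
  if (protocol$terminated || !.on_grid(tau, protocol$review_h))
    return(list(protocol = protocol, inf = inf, entry = NULL))

  keep <- protocol$uo_times > t - 0.5 - 1e-9
  vitals <- list(SBP = phys$hemo$SBP, MAP = phys$hemo$MAP,
                 UO = mean(protocol$uo_hist[keep]))
  rev <- protocol_review(protocol, vitals, t)
  protocol <- rev$protocol
  for (v in rev$boluses) inf <- rbind(inf, .bolus_row(t, v))
  if (rev$start_maintenance)
    inf <- rbind(inf, data.frame(kind = "fluid", name = "saline",
                                 start = t, end = Inf, rate = 75,
                                 alb_rate = 0, stringsAsFactors = FALSE))
  if (rev$stop_pressor) {
    drug_rows <- inf$kind == "drug" & inf$name == "norepinephrine" &
      inf$end > t
    inf$end[drug_rows] <- t
  }
  entry <- list(time_h = t, arm = protocol$arm, SBP = vitals$SBP,
                MAP = vitals$MAP, UO = vitals$UO,
                action = if (length(rev$actions))
                  paste(rev$actions, collapse = "; ") else "no action",
                volume_ml = sum(rev$boluses))
  list(protocol = protocol, inf = inf, entry = entry)
}

.bolus_row <- function(t, volume_ml, duration_h = 0.4) {
  data.frame(kind = "fluid", name = "saline", start = t,
             end = t + duration_h, rate = volume_ml / duration_h,
             alb_rate = 0, stringsAsFactors = FALSE)
}

#' Untreated severe run up to a snapshot time
#'
#' Runs the severe infection without treatment and returns the simulation
#' with its final snapshot (by default at 44 h, just before septic shock
#' onset), the entry point for the treatment scenarios.
#'
#' @param t_snapshot Snapshot time (h post-infection).
#' @param sc Base scenario (defaults to a severe infection).
#' @return `sepsis_sim`.
#' @export
severe_untreated <- function(t_snapshot = 44, sc = NULL) {
  if (is.null(sc)) sc <- scenario(severity = "Severe", t_end = t_snapshot)
  sc$t_end <- t_snapshot
  run_scenario(sc)
}

#' REFRESH pre-trial fluid challenge
#'
#' From a severe-infection snapshot near shock onset, administers two
#' 500 mL saline boluses (at the snapshot time and 30 min later) and
#' observes for a further hour. The patient qualifies for the trial when
#' systolic pressure remains below 100 mmHg despite the fluid challenge
#' (fluid-refractory hypotension).
#'
#' @param snap `patient_snapshot` of the untreated severe run (e.g. at
#'   44 h).
#' @param sc Scenario to resume under (defaults to the snapshot's).
#' @return List: `sim` (the challenge run), `snapshot` (state after
#'   observation, protocol entry point), `qualified` (logical), `SBP_end`,
#'   `UO_end`.
#' @export
refresh_pretrial <- function(snap, sc = snap$scenario) {
  if (is.null(sc)) stop("supply the scenario the snapshot came from",
                        call. = FALSE)
  t0 <- snap$time
  sc$t_end <- t0 + 2
  sc$actions <- list(
    list(time_h = t0, type = "bolus", volume_ml = 500, duration_h = 0.5),
    list(time_h = t0 + 0.5, type = "bolus", volume_ml = 500,
         duration_h = 0.5)
  )
  sim <- run_scenario(sc, init = snap)
  s <- sim$series
  n <- nrow(s)
  qualified <- s$SBP_mmHg[n] < 100
  list(sim = sim, snapshot = sim$snapshot, qualified = qualified,
       SBP_end = s$SBP_mmHg[n], UO_end = s$UO_mL_min[n])
}

#' Run a REFRESH protocol arm
#'
#' From the qualified septic snapshot, starts 4.5 g piperacillin/tazobactam
#' over 30 min and either (control) a concurrent 1000 mL bolus followed by
#' 30-min reviews with 500 mL boluses for SBP/MAP below goal and hourly
#' 500 mL boluses for low urine output, or (experimental) maintenance saline
#' at 1 mL/kg/h plus norepinephrine at 0.18 ug/kg/min with hourly 250 mL
#' boluses for low urine output. Both arms stop (to maintenance) once SBP
#' and MAP exceed their goals at a review.
#'
#' @param snap Qualified `patient_snapshot` (from [refresh_pretrial()]).
#' @param arm "control" or "experimental".
#' @param sc Scenario to resume under (defaults to the snapshot's).
#' @param duration_h Protocol duration (h).
#' @return `sepsis_sim` with the protocol state attached; cumulative fluid
#'   including the pre-trial challenge is `snapshot$cum_fluid_ml / 1000` L
#'   at the end of the run.
#' @export
run_refresh <- function(snap, arm = c("control", "experimental"),
                        sc = snap$scenario, duration_h = 6) {
  arm <- match.arg(arm)
  if (is.null(sc)) stop("supply the scenario the snapshot came from",
                        call. = FALSE)
  t0 <- snap$time
  w <- sc$weight_kg
  sc$t_end <- t0 + duration_h
  acts <- list(
    list(time_h = t0, type = "drug_infusion", drug = "piperacillin",
         dose = 4500, duration_h = 0.5)
  )
  if (arm == "control") {
    acts <- c(acts, list(
      list(time_h = t0, type = "bolus", volume_ml = 1000, duration_h = 0.75)
    ))
  } else {
    acts <- c(acts, list(
      list(time_h = t0, type = "fluid_infusion", rate_ml_h = 1 * w,
           stop_h = Inf),
      list(time_h = t0, type = "drug_rate", drug = "norepinephrine",
           rate_per_h = 0.18 * w * 60)   # ug/kg/min -> ug/h
    ))
  }
  sc$actions <- acts
  prot <- protocol_state(arm, start_h = t0, weight_kg = w,
                         duration_h = duration_h)
  run_scenario(sc, protocol = prot, init = snap)
}

#' Delayed-treatment scenario
#'
#' Defers the whole treatment sequence (fluid challenge and control
#' protocol) by `delay` hours: the untreated severe run continues past the
#' nominal challenge time, then the challenge and the control protocol are
#' applied on the delayed clock.
#'
#' @param delay Delay (h), non-negative.
#' @param challenge_h Nominal fluid-challenge time (h post-infection).
#' @param sc Base severe scenario.
#' @return List: `pretrial`, `sim` (protocol run), `P_B_at_start` (blood
#'   pathogen at protocol start), `snapshot`.
#' @export
delayed_treatment <- function(delay = 12, challenge_h = 44, sc = NULL) {
  stopifnot(delay >= 0)
  if (is.null(sc)) sc <- scenario(severity = "Severe")
  base <- severe_untreated(challenge_h + delay, sc)
  pre <- refresh_pretrial(base$snapshot, sc)
  sim <- run_refresh(pre$snapshot, "control", sc)
  list(pretrial = pre, sim = sim,
       P_B_at_start = pre$snapshot$air[5L],
       snapshot = sim$snapshot)
}
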