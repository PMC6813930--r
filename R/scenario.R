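# Scenario engine: timed infection and treatment actions, the coupled
# AIR + drug + physiology master loop, patient-state serialization, and the
# REFRESH treatment protocols.

.severity_loads <- c(Mild = 1e6, Moderate = 5e6, Severe = 1e7)

#' Scenario definition
#'
#' A scenario is an infection (severity or explicit initial tissue load plus
#' the pathogen's MIC), a run horizon, and an ordered list of timed actions
#' (fluid boluses, fluid or drug infusions). Protocols add actions while the
#' simulation runs.
#'
#' @param severity "Mild", "Moderate" or "Severe" (initial tissue loads
#'   1e6, 5e6, 1e7), or `NULL` when `initial_load` is given. Use
#'   `severity = "none"` for an uninfected baseline run.
#' @param initial_load Explicit initial tissue pathogen load (overrides
#'   `severity`).
#' @param mic_mg_L Minimum inhibitory concentration of the infecting
#'   organism (mg/L).
#' @param location Informational label for the infection site.
#' @param t_end Run horizon (h).
#' @param macro_step Coupling grid (h).
#' @param actions List of actions; each is a list with `time_h`, `type`
#'   ("bolus", "fluid_infusion", "drug_infusion", "drug_stop") and
#'   type-specific fields (see [run_scenario()]).
#' @param air_params,physio_pars Model parameter sets.
#' @param drugs Drug registry (see [drug_registry()]).
#' @param couple_tissue,couple_blood Whether the antibiotic net growth rate
#'   replaces the tissue and blood growth rates (both on by default).
#' @param weight_kg Patient weight.
#' @return List of class `sepsis_scenario`.
#' @export
scenario <- function(severity = "Severe", initial_load = NULL,
                     mic_mg_L = 16, location = "unspecified tissue",
                     t_end = 48, macro_step = 0.05, actions = list(),
                     air_params = sepsim::air_params(),
                     physio_pars = physio_params(),
                     drugs = NULL, couple_tissue = TRUE,
                     couple_blood = TRUE, weight_kg = 75) {
  if (is.null(initial_load)) {
    if (identical(severity, "none")) {
      initial_load <- 0
    } else {
      severity <- match.arg(severity, names(.severity_loads))
      initial_load <- .severity_loads[[severity]]
    }
  }
  if (is.null(drugs)) drugs <- drug_registry(S_max = air_params[["S_P"]])
  if (mic_mg_L <= 0) stop("mic_mg_L must be > 0", call. = FALSE)
  drugs$piperacillin$pd$MIC <- mic_mg_L
  sc <- list(severity = severity, initial_load = initial_load,
             mic_mg_L = mic_mg_L, location = location, t_end = t_end,
             macro_step = macro_step, actions = actions,
             air_params = air_params, physio_pars = physio_pars,
             drugs = drugs, couple_tissue = couple_tissue,
             couple_blood = couple_blood, weight_kg = weight_kg)
  class(sc) <- "sepsis_scenario"
  sc
}

# one AIR macro step with frozen TLR switch and growth modifiers
.air_scenario_step <- function(y, R, pv, t0, t1, atol, rtol = 1e-6) {
  res <- .ode_call(c(y, Rsw = R), c(t0, t1), pv, rtol, atol,
                   with_root = TRUE)
  iroot <- attr(res, "iroot")
  capped <- !is.null(iroot) && length(iroot) >= 3L && iroot[3L] != 0
  row <- res[nrow(res), ]
  if (!capped && row[1L] < t1 - 1e-9) {
    leg <- .ode_call(row[2L:20L], c(row[1L], t1), pv, rtol, atol,
                     with_root = FALSE)
    row <- leg[nrow(leg), ]
  }
  list(y = pmax(row[2L:19L], 0), capped = capped)
}

.active_rate <- function(inf, t) {
  if (!nrow(inf)) return(numeric(0))
  ifelse(inf$start <= t + 1e-9 & t < inf$end - 1e-9, inf$rate, 0)
}

#' Run a scenario
#'
#' The master loop: every macro step the drug models are advanced
#' (closed-form), the antibiotic's unbound concentration is mapped to a net
#' pathogen growth rate, the AIR system is advanced with the TLR switch
#' frozen within the step, and the physiological layer consumes the
#' inflammation outputs (effective tissue integrity, NO, active neutrophils,
#' IL-6) together with fluid and vasopressor inputs. Timed actions fire at
#' their scheduled steps; an active protocol performs its checks and may add
#' boluses or stop infusions (every decision is written to an audit log).
#'
#' @param sc `sepsis_scenario`.
#' @param protocol Optional `protocol_state` (see [protocol_state()]).
#' @param init Optional initial coupled state (a `patient_snapshot`, to
#'   resume a run).
#' @param record_every Record one row every this many macro steps.
#' @return A `sepsis_sim`: list with `series` (data.frame of AIR and
#'   physiological outputs over time), `audit` (protocol decision log),
#'   `snapshot` (final `patient_snapshot`), `protocol`, `capped`, and the
#'   scenario.
#' @export
run_scenario <- function(sc, protocol = NULL, init = NULL,
                         record_every = 1L) {
  stopifnot(inherits(sc, "sepsis_scenario"))
  ap <- sc$air_params
  pp <- sc$physio_pars
  h <- sc$macro_step
  atol <- .air_atol()

  if (is.null(init)) {
    y <- as.numeric(air_state(P_T = sc$initial_load, params = ap))
    R <- tlr_update(y[1L], 0, ap)
    phys <- physio_baseline(pp)
    t0 <- 0
    drugs_amt <- lapply(sc$drugs, function(d) c(0, 0))
    inf <- data.frame(kind = character(), name = character(),
                      start = numeric(), end = numeric(),
                      rate = numeric(), alb_rate = numeric(),
                      stringsAsFactors = FALSE)
    cum_fluid_ml <- 0
  } else {
    stopifnot(inherits(init, "patient_snapshot"))
    y <- init$air
    R <- init$R
    phys <- init$physio
    t0 <- init$time
    drugs_amt <- init$drug_amounts
    inf <- init$infusions
    cum_fluid_ml <- init$cum_fluid_ml
  }

  pending <- sc$actions
  times <- seq(t0, sc$t_end, by = h)
  n <- length(times)
  rec_idx <- seq(1L, n, by = record_every)
  nr <- length(rec_idx)
  cols <- c("time_h", .air_state_names, "NO", "R", "S_net",
            "C_u_piperacillin", "C_norepinephrine",
            "blood_volume_L", "MAP_mmHg", "SBP_mmHg", "DBP_mmHg",
            "HR_per_min", "SVR_frac_baseline", "CO_L_min", "SV_mL",
            "UO_mL_min", "lactate_mM", "temp_C", "RR_per_min",
            "WBC_ct_uL", "extravascular_volume_L", "cum_fluid_L",
            "TI_eff")
  out <- matrix(NA_real_, nr, length(cols),
                dimnames = list(NULL, cols))
  audit <- list()
  capped <- FALSE

  record <- function(k, t, snet, cu_pip, c_ne) {
    no <- y[11L] * (1 + ap[["k_NOMA"]] * (y[7L] + y[9L])) + y[12L]
    c(t, y, no, R, snet, cu_pip, c_ne,
      phys$blood_volume, phys$hemo$MAP, phys$hemo$SBP, phys$hemo$DBP,
      phys$hemo$HR, phys$hemo$SVR_frac, phys$hemo$CO, phys$hemo$SV,
      phys$renal$UO, phys$renal$lactate, phys$renal$temp, phys$renal$RR,
      phys$renal$WBC, sum(phys$pairs$Vi), cum_fluid_ml / 1000,
      effective_integrity(y[18L], y[15L], pp))
  }

  ri <- 1L
  snet0 <- ap[["S_P"]]
  if (1L %in% rec_idx) {
    out[ri, ] <- record(1L, times[1L], snet0, 0, 0)
    ri <- ri + 1L
  }

  for (i in seq_len(n - 1L)) {
    t <- times[i]; t_next <- times[i + 1L]

    # fire scheduled actions due at the start of this step
    if (length(pending)) {
      due <- vapply(pending, function(a) a$time_h <= t + 1e-9, logical(1))
      for (a in pending[due]) {
        res <- .apply_action(a, t, inf, sc)
        inf <- res$inf
      }
      pending <- pending[!due]
    }

    # protocol checks happen on their review grid
    if (!is.null(protocol) && !protocol$done) {
      chk <- .protocol_check(protocol, phys, t, sc, inf, cum_fluid_ml)
      protocol <- chk$protocol
      inf <- chk$inf
      if (!is.null(chk$entry)) audit[[length(audit) + 1L]] <- chk$entry
    }

    # drugs: advance one step under the currently active rates
    cu_pip <- 0; c_ne <- 0
    if (nrow(inf)) {
      act <- inf[inf$kind == "drug", , drop = FALSE]
    } else act <- inf
    for (nm in names(drugs_amt)) {
      rate <- 0
      if (nrow(act)) {
        sel <- act$name == nm & act$start <= t + 1e-9 & t < act$end - 1e-9
        if (any(sel)) rate <- sum(act$rate[sel])
      }
      st <- pk_step(sc$drugs[[nm]]$pk, drugs_amt[[nm]], rate, h)
      drugs_amt[[nm]] <- st$amounts
      if (nm == "piperacillin") cu_pip <- st$C_u
      if (nm == "norepinephrine") c_ne <- st$C_plasma
    }

    # antibiotic coupling
    snet <- antibiotic_snet(cu_pip, sc$drugs$piperacillin$pd)
    snet_t <- if (sc$couple_tissue) min(snet, ap[["S_P"]]) else ap[["S_P"]]
    snet_b <- if (sc$couple_blood) min(snet, ap[["S_P"]]) else ap[["S_P"]]

    # AIR step
    pv <- .air_parms_vec(ap, snet_t, snet_b)
    stp <- .air_scenario_step(y, R, pv, t, t_next, atol)
    y <- .clamp_state(stp$y, ap[["TI_min"]])
    if (stp$capped) capped <- TRUE
    R <- tlr_update(y[1L], R, ap)

    # fluids active during this step
    frate <- 0; arate <- 0
    if (nrow(inf)) {
      fl <- inf[inf$kind == "fluid", , drop = FALSE]
      if (nrow(fl)) {
        sel <- fl$start <= t + 1e-9 & t < fl$end - 1e-9
        frate <- sum(fl$rate[sel]) / 60       # mL/h -> mL/min
        arate <- sum(fl$alb_rate[sel]) / 60   # g/h -> g/min
      }
    }
    cum_fluid_ml <- cum_fluid_ml + frate * 60 * h

    no <- y[11L] * (1 + ap[["k_NOMA"]] * (y[7L] + y[9L])) + y[12L]
    pe <- vasopressor_effect(c_ne, sc$drugs$norepinephrine$pd)
    phys$time <- t
    phys <- physio_step(phys,
                        air = list(TI = y[18L], NO = no, N_A = y[9L],
                                   IL6 = y[15L]),
                        dt = h, pars = pp,
                        infusion_ml_min = frate,
                        infusion_alb_g_min = arate,
                        pressor_effect = pe)

    if ((i + 1L) %in% rec_idx) {
      out[ri, ] <- record(i + 1L, t_next, snet, cu_pip, c_ne)
      ri <- ri + 1L
    }
  }

  snap <- patient_snapshot(time = sc$t_end, air = y, R = R,
                           drug_amounts = drugs_amt, physio = phys,
                           infusions = inf, cum_fluid_ml = cum_fluid_ml,
                           scenario = sc)
  sim <- list(series = as.data.frame(out), audit = .audit_df(audit),
              snapshot = snap, protocol = protocol, capped = capped,
              scenario = sc)
  class(sim) <- "sepsis_sim"
  sim
}

.audit_df <- function(audit) {
  if (!length(audit)) {
    return(data.frame(time_h = numeric(), arm = character(),
                      SBP = numeric(), MAP = numeric(), UO = numeric(),
                      action = character(), volume_ml = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(audit, as.data.frame))
}

.apply_action <- function(a, t, inf, sc) {
  add <- NULL
  if (a$type == "bolus") {
    dur <- if (is.null(a$duration_h) || a$duration_h <= 0) 0.5 else
      a$duration_h
    comp <- if (is.null(a$compound)) fluid_compound("saline") else
      a$compound
    add <- data.frame(kind = "fluid", name = comp$name, start = a$time_h,
                      end = a$time_h + dur,
                      rate = a$volume_ml / dur,
                      alb_rate = a$volume_ml / dur * comp$albumin_g_dl /
                        100,
                      stringsAsFactors = FALSE)
  } else if (a$type == "fluid_infusion") {
    comp <- if (is.null(a$compound)) fluid_compound("saline") else
      a$compound
    add <- data.frame(kind = "fluid", name = comp$name, start = a$time_h,
                      end = a$stop_h, rate = a$rate_ml_h,
                      alb_rate = a$rate_ml_h * comp$albumin_g_dl / 100,
                      stringsAsFactors = FALSE)
  } else if (a$type == "drug_infusion") {
    add <- data.frame(kind = "drug", name = a$drug, start = a$time_h,
                      end = a$time_h + a$duration_h,
                      rate = a$dose / a$duration_h, alb_rate = 0,
                      stringsAsFactors = FALSE)
  } else if (a$type == "drug_rate") {
    add <- data.frame(kind = "drug", name = a$drug, start = a$time_h,
                      end = if (is.null(a$stop_h)) Inf else a$stop_h,
                      rate = a$rate_per_h, alb_rate = 0,
                      stringsAsFactors = FALSE)
  } else {
    stop("unknown action type: ", a$type, call. = FALSE)
  }
  list(inf = rbind(inf, add))
}

#' @export
print.sepsis_sim <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat(sprintf("Sepsis simulation: %s infection, %.1f .. %.1f h (%d samples)\n",
              if (is.null(x$scenario$severity)) "custom" else
                x$scenario$severity,
              s$time_h[1L], s$time_h[n], n))
  cat(sprintf("  final: P_B %.3g, TI_eff %.3f, MAP %.1f, SBP %.1f, lactate %.2f mM, cum fluid %.2f L\n",
              s$P_B[n], s$TI_eff[n], s$MAP_mmHg[n], s$SBP_mmHg[n],
              s$lactate_mM[n], s$cum_fluid_L[n]))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %s arm, %s, protocol fluid %.2f L\n",
                x$protocol$arm,
                if (x$protocol$terminated) "terminated to maintenance" else
                  "ran to horizon",
                x$protocol$cum_fluid_ml / 1000))
  invisible(x)
}

#' @export
plot.sepsis_sim <- function(x, vars = c("SBP_mmHg", "MAP_mmHg",
                                        "lactate_mM", "P_B"), ...) {
  s <- x$series
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars[seq_len(min(4L, length(vars)))]) {
    logy <- if (v == "P_B" && any(s[[v]] > 0)) "y" else ""
    yv <- if (logy == "y") pmax(s[[v]], 1e-6) else s[[v]]
    graphics::plot(s$time_h, yv, type = "l", log = logy,
                   xlab = "time (h)", ylab = v, main = v, ...)
  }
  invisible(x)
}

#' Export the physiological time series to CSV
#'
#' @param sim `sepsis_sim`.
#' @param path Output file.
#' @export
export_physio_csv <- function(sim, path) {
  cols <- c("time_h", "blood_volume_L", "MAP_mmHg", "SBP_mmHg", "DBP_mmHg",
            "HR_per_min", "SVR_frac_baseline", "CO_L_min", "SV_mL",
            "UO_mL_min", "lactate_mM", "temp_C", "RR_per_min",
            "WBC_ct_uL", "extravascular_volume_L")
  utils::write.csv(sim$series[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' JSON scenario files carry the infection definition, run settings and the
#' timed action list:
#' \preformatted{
#' {
#'   "patient":   {"weight_kg": 75},
#'   "infection": {"severity": "Severe", "mic_mg_L": 16},
#'   "run":       {"t_end": 48, "macro_step": 0.05},
#'   "actions":   [{"time_h": 46, "type": "drug_infusion",
#'                  "drug": "piperacillin", "dose": 4500,
#'                  "duration_h": 0.5}]
#' }
#' }
#' `infection` accepts `severity` ("Mild"/"Moderate"/"Severe"/"none") or an
#' explicit `initial_load`.
#'
#' @param path JSON file path.
#' @return A `sepsis_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("invalid scenario file: ", conditionMessage(e),
                         call. = FALSE))
  inf <- cfg$infection
  if (is.null(inf)) stop("scenario file needs an 'infection' block",
                         call. = FALSE)
  acts <- lapply(cfg$actions, function(a) {
    if (!is.null(a$compound) && is.character(a$compound))
      a$compound <- fluid_compound(a$compound)
    a
  })
  scenario(severity = if (is.null(inf$severity)) NULL else inf$severity,
           initial_load = inf$initial_load,
           mic_mg_L = if (is.null(inf$mic_mg_L)) 16 else inf$mic_mg_L,
           location = if (is.null(inf$location)) "unspecified tissue" else
             inf$location,
           t_end = if (is.null(cfg$run$t_end)) 48 else cfg$run$t_end,
           macro_step = if (is.null(cfg$run$macro_step)) 0.05 else
             cfg$run$macro_step,
           actions = acts,
           weight_kg = if (is.null(cfg$patient$weight_kg)) 75 else
             cfg$patient$weight_kg)
}
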