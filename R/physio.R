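# Reduced whole-body physiology: three lumped vascular-tissue compartment
# pairs with Starling fluid exchange and Patlak albumin transport, a common
# lymph return, a baroreflex-controlled hemodynamic block, renal output,
# an energy-deficit/lactate submodel and SIRS symptoms. All couplings to the
# inflammation model enter through an effective tissue-integrity signal,
# nitric oxide, active neutrophils and IL-6.

#' Physiology parameters
#'
#' All constants of the reduced physiological layer, with units. Baseline
#' hemodynamics follow the standard adult patient (HR 72/min, SBP/DBP
#' 114/73.5 mmHg, blood volume 5 L); transcapillary filtration is tuned to
#' 4.0 L/day at baseline by [physio_baseline()].
#'
#' @param ... Named overrides of individual defaults.
#' @return List of class `physio_params`.
#' @export
physio_params <- function(...) {
  p <- list(
    weight_kg = 75,
    # compartments
    shares = c(muscle_skin = 0.40, gut = 0.30, viscera = 0.30),
    blood_volume0 = 5.0,        # L
    hct = 0.40,                 # fixed hematocrit
    interstitial0 = 10.0,       # L, total across pairs
    Pc0 = 25, Pi0 = -3,         # mmHg hydrostatic
    filtration0 = 4000 / 1440,  # mL/min (4.0 L/day)
    alb_p_gdl0 = 4.5, alb_i_gdl0 = 1.5,
    cpp_per_alb = 7.0 / 4.5,    # total plasma protein per albumin (g/g)
    sigma0 = 0.95,
    interstitial_compliance = 2.0,  # L/mmHg, total, near baseline
    interstitial_knee_L = 3.2,  # total excess volume where tissue stiffens
    interstitial_stiff = 8.0,   # mmHg per (excess/knee)^2 beyond the knee
    lymph_sens = 0.35,          # fractional lymph gain per mmHg of Pi rise
    vena_cava_p0 = 2,           # mmHg
    Pc_vol_gain = 8,            # capillary pressure sensitivity to volume
    # hemodynamics
    HR0 = 72, SV0 = 70, MAP0 = 87, PP0 = 40.5,
    sv_preload_gain = 0.9, sv_max_frac = 1.15,
    pp_sv_exp = 3,              # pulse pressure ~ (SV/SV0)^exp
    baro_gain_svr = 4.0, baro_gain_hr = 3.0, baro_tau_h = 0.5,
    baro_svr_min = -0.3, baro_svr_max = 0.9,
    baro_hr_min = -0.2, baro_hr_max = 0.33,
    NO0 = 0.0125, no_emax = 0.63, no_ec50 = 0.30, no_hill = 2,
    inhib_max = 0.95, inhib_ramp_h = 44,
    # endothelium
    a_R = 3.0, a_sigma = 2.4, floor_R = 0.05, floor_sigma = 0.05,
    # effective integrity signal: anatomical TI weighted by IL-6-driven
    # endothelial activation (glycocalyx degradation is cytokine-mediated)
    il6_weight = 0.85, il6_x = 0.23, il6_hill = 6,
    tau_endo_h = 32,            # progressive glycocalyx degradation lag
    tau_no_h = 26,              # vasoplegia onset lag on the NO signal
    # renal / metabolic
    UO0 = 0.9,                  # mL/min
    uo_map_exp = 3, uo_vol_exp = 2, uo_max_frac = 3,
    intake_ml_min = 0.9,        # constant volume-neutral intake
    kE = 0.5, kErec = 0.8,      # energy deficit build/recovery (1/h)
    kLprod = 1.55, kLclear = 0.12,  # lactate production/clearance
    lactate0 = 1.0,             # mM
    # symptoms
    temp0 = 37, temp_emax = 3.0, temp_e50 = 0.12,
    RR0 = 16, rr_emax = 16, rr_e50 = 0.12,
    WBC0 = 7000, wbc_per_na = 8e4,
    sirs_hr = 90, sirs_rr = 20, sirs_temp = 38, sirs_wbc = 12000
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown physiology parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    p[names(over)] <- over
  }
  class(p) <- "physio_params"
  p
}

#' Colloid osmotic pressure (Landis-Pappenheimer)
#'
#' `COP = 2.1 Cpp + 0.18 Cpp^2 + 0.009 Cpp^3` with plasma protein `Cpp` in
#' g/dL and COP in mmHg.
#'
#' @param C_pp Total plasma protein concentration (g/dL), non-negative.
#' @return Pressure in mmHg.
#' @examples
#' colloid_osmotic_pressure(7)  # 26.607 mmHg
#' @export
colloid_osmotic_pressure <- function(C_pp) {
  if (any(C_pp < 0)) stop("C_pp must be >= 0", call. = FALSE)
  2.1 * C_pp + 0.18 * C_pp^2 + 0.009 * C_pp^3
}

#' Starling volumetric flux across a vascular-tissue pair
#'
#' Ohmic approximation of Starling's law: `J_V = (dP_h - dCOP) / R1` with
#' `dP_h = P_v,h - P_i,h` and `dCOP = COP_v - COP_i` (reflection coefficient
#' near unity folded into the tuned resistance).
#'
#' @param pair List with `P_v_h`, `P_i_h` (mmHg) and `R1` (mmHg.min/mL).
#' @param COP_v,COP_i Colloid osmotic pressures (mmHg).
#' @return Volumetric flux in mL/min, vascular to interstitial positive.
#' @export
starling_flux <- function(pair, COP_v, COP_i) {
  ((pair$P_v_h - pair$P_i_h) - (COP_v - COP_i)) / pair$R1
}

#' Patlak albumin flux across a vascular-tissue pair
#'
#' Convection-diffusion solute flux: `Pe = J_V (1 - sigma) / PS`,
#' `J_Alb = J_V (1 - sigma) (C_p - C_i e^-Pe) / (1 - e^-Pe)`. For |Pe| below
#' 1e-6 the diffusion limit `PS (C_p - C_i)` is used.
#'
#' @param pair List with `sigma` (reflection coefficient) and `PS`
#'   (diffusion capacity, mL/min).
#' @param J_V Volumetric flux (mL/min).
#' @param C_alb_p,C_alb_i Albumin concentrations (g/mL).
#' @return Albumin mass flux (g/min), vascular to interstitial positive.
#' @export
albumin_flux <- function(pair, J_V, C_alb_p, C_alb_i) {
  conv <- J_V * (1 - pair$sigma)
  Pe <- conv / pair$PS
  if (abs(Pe) < 1e-6) {
    pair$PS * (C_alb_p - C_alb_i) + conv * (C_alb_p + C_alb_i) / 2
  } else {
    e <- exp(-Pe)
    conv * (C_alb_p - C_alb_i * e) / (1 - e)
  }
}

#' Lymphatic return fluxes
#'
#' Linear lymph pump around the tuned baseline: each pair returns its
#' baseline filtration share, increased (decreased) as interstitial pressure
#' rises above (falls below) baseline, with a check valve that clips
#' negative flows to zero. A raised vena cava pressure shifts the operating
#' point down.
#'
#' @param pairs Pair state as in a `physio_state` (needs `L0`, `Pi`, and
#'   baseline `Pi0` via `pars`).
#' @param vena_cava_pressure mmHg (default the baseline value).
#' @param pars `physio_params`.
#' @return Numeric vector of per-pair return fluxes (mL/min), non-negative.
#' @export
lymph_return <- function(pairs, vena_cava_pressure = NULL,
                         pars = physio_params()) {
  if (is.null(vena_cava_pressure)) vena_cava_pressure <- pars$vena_cava_p0
  drive <- 1 + pars$lymph_sens * (pairs$Pi - pars$Pi0) -
    pars$lymph_sens * (vena_cava_pressure - pars$vena_cava_p0)
  pmax(0, pairs$L0 * drive)
}

#' Endothelial dysfunction update
#'
#' Scales the endothelial resistance and reflection coefficient down
#' linearly with lost tissue integrity, floored at configured minima:
#' `R1 = R1_base * max(floor, 1 - a_R (1 - TI))` and likewise for `sigma`.
#'
#' @param pair Pair state with `R1_base`, `sigma_base`.
#' @param TI Effective tissue integrity in \[0, 1\].
#' @param pars `physio_params` (supplies `a_R`, `a_sigma` and floors).
#' @return The pair with updated `R1` and `sigma`.
#' @export
endothelial_update <- function(pair, TI, pars = physio_params()) {
  if (TI < 0 || TI > 1) stop("TI must lie in [0, 1]", call. = FALSE)
  dmg <- 1 - TI
  pair$R1 <- pair$R1_base * pmax(pars$floor_R, 1 - pars$a_R * dmg)
  pair$sigma <- pair$sigma_base * pmax(pars$floor_sigma,
                                       1 - pars$a_sigma * dmg)
  pair
}

#' Baseline physiological state
#'
#' Builds the resting state and tunes the per-pair endothelial resistances
#' (so total baseline filtration is exactly 4.0 L/day), the lymph baseline
#' (returns what is filtered) and the per-pair diffusion capacities (so
#' transcapillary albumin flux exactly balances convective lymph return).
#' The result is an exact fixed point of [physio_step()] under resting
#' inflammation inputs.
#'
#' @param pars `physio_params`.
#' @return List of class `physio_state`.
#' @export
physio_baseline <- function(pars = physio_params()) {
  sh <- pars$shares
  n <- length(sh)
  plasma0 <- pars$blood_volume0 * (1 - pars$hct)
  alb_p_mass <- pars$alb_p_gdl0 * plasma0 * 10          # g
  alb_i_mass <- pars$alb_i_gdl0 * pars$interstitial0 * 10
  COP_v0 <- colloid_osmotic_pressure(pars$alb_p_gdl0 * pars$cpp_per_alb)
  COP_i0 <- colloid_osmotic_pressure(pars$alb_i_gdl0 * pars$cpp_per_alb)
  drive0 <- (pars$Pc0 - pars$Pi0) - (COP_v0 - COP_i0)
  if (drive0 <= 0)
    stop("baseline Starling forces must favour filtration", call. = FALSE)
  J0 <- pars$filtration0 * sh                           # mL/min per pair
  R1 <- drive0 / J0
  cp0 <- pars$alb_p_gdl0 / 100                          # g/mL
  ci0 <- pars$alb_i_gdl0 / 100
  PS <- vapply(seq_len(n), function(k) {
    f <- function(ps) {
      albumin_flux(list(sigma = pars$sigma0, PS = ps), J0[k], cp0, ci0) -
        J0[k] * ci0
    }
    stats::uniroot(f, c(1e-9, 1e4), tol = 1e-12)$root
  }, numeric(1))

  pairs <- list(
    name = names(sh), share = as.numeric(sh),
    R1 = R1, R1_base = R1,
    sigma = rep(pars$sigma0, n), sigma_base = rep(pars$sigma0, n),
    PS = PS, L0 = J0,
    Vi = pars$interstitial0 * as.numeric(sh),
    Vi0 = pars$interstitial0 * as.numeric(sh),
    alb_i = alb_i_mass * as.numeric(sh),
    Ci = pars$interstitial_compliance * as.numeric(sh),
    Pi = rep(pars$Pi0, n)
  )
  SVR0 <- pars$MAP0 / (pars$HR0 * pars$SV0 / 1000)
  state <- list(
    time = 0,
    blood_volume = pars$blood_volume0,
    alb_p = alb_p_mass,
    pairs = pairs,
    hemo = list(MAP = pars$MAP0, SBP = pars$MAP0 + 2 * pars$PP0 / 3,
                DBP = pars$MAP0 - pars$PP0 / 3,
                HR = pars$HR0, SV = pars$SV0,
                CO = pars$HR0 * pars$SV0 / 1000,
                SVR = SVR0, SVR0 = SVR0, SVR_frac = 1,
                baro_svr = 0, baro_hr = 0, inhib = 0,
                sirs_onset = NA_real_),
    renal = list(UO = pars$UO0, E = 0, lactate = pars$lactate0,
                 temp = pars$temp0, RR = pars$RR0, WBC = pars$WBC0),
    endo_dmg = 0,
    no_lag = pars$NO0,
    cum = list(filtration_ml = 0, lymph_ml = 0, urine_ml = 0,
               intake_ml = 0, infused_ml = 0, infused_alb_g = 0)
  )
  class(state) <- "physio_state"
  state
}

#' @export
print.physio_state <- function(x, ...) {
  cat(sprintf(paste0("Physiology at t = %.2f h: BV %.2f L, MAP %.1f, SBP ",
                     "%.1f, HR %.0f, SVR %.0f%%, UO %.2f mL/min, ",
                     "lactate %.2f mM\n"),
              x$time, x$blood_volume, x$hemo$MAP, x$hemo$SBP, x$hemo$HR,
              100 * x$hemo$SVR_frac, x$renal$UO, x$renal$lactate))
  invisible(x)
}

#' Effective tissue-integrity signal
#'
#' The physiological layer's organ/endothelial damage input: anatomical
#' tissue integrity weighted down by IL-6-driven endothelial (glycocalyx)
#' activation, `TI_eff = TI * (1 - w * HU2(IL6, x, h))`.
#'
#' @param TI Tissue integrity from the inflammation model.
#' @param IL6 IL-6 level (arbitrary concentration).
#' @param pars `physio_params`.
#' @return Scalar in \[0, 1\].
#' @export
effective_integrity <- function(TI, IL6, pars = physio_params()) {
  max(0, min(1, TI * (1 - pars$il6_weight *
                        hill_up(IL6, pars$il6_x, pars$il6_hill))))
}

#' Hemodynamics update
#'
#' One explicit step of the reduced cardiovascular block: stroke volume from
#' preload (blood volume), nitric-oxide vasodilation as a sigmoidal Emax
#' reduction of intrinsic vascular resistance, a first-order baroreflex
#' driving SVR and HR toward the MAP setpoint (its SVR gain scaled by
#' `1 - inhib`), multiplicative vasopressor support, and SBP/DBP
#' reconstruction from MAP and a stroke-volume-scaled pulse pressure.
#'
#' @param h Hemodynamics sub-state (from a `physio_state`).
#' @param NO Nitric-oxide level (arbitrary units).
#' @param blood_volume Current blood volume (L).
#' @param vasopressor_effect Fractional SVR increase from drugs.
#' @param dt Step (h).
#' @param pars `physio_params`.
#' @return Updated hemodynamics sub-state.
#' @export
hemodynamics_step <- function(h, NO, blood_volume, vasopressor_effect = 0,
                              dt, pars = physio_params()) {
  stopifnot(dt > 0)
  volfrac <- blood_volume / pars$blood_volume0
  sv_frac <- min(pars$sv_max_frac,
                 max(0.2, 1 + pars$sv_preload_gain * (volfrac - 1)))
  SV <- pars$SV0 * sv_frac
  x <- max(0, NO - pars$NO0)
  e_no <- pars$no_emax * x^pars$no_hill /
    (x^pars$no_hill + pars$no_ec50^pars$no_hill)
  svr_intr <- h$SVR0 * (1 - e_no) * (1 + vasopressor_effect)
  err <- (pars$MAP0 - h$MAP) / pars$MAP0
  a <- dt / pars$baro_tau_h
  tgt_svr <- pars$baro_gain_svr * err * (1 - h$inhib)
  tgt_hr <- pars$baro_gain_hr * err
  h$baro_svr <- min(pars$baro_svr_max,
                    max(pars$baro_svr_min,
                        h$baro_svr + a * (tgt_svr - h$baro_svr)))
  h$baro_hr <- min(pars$baro_hr_max,
                   max(pars$baro_hr_min,
                       h$baro_hr + a * (tgt_hr - h$baro_hr)))
  HR <- pars$HR0 * (1 + h$baro_hr)
  CO <- HR * SV / 1000
  SVR <- svr_intr * (1 + h$baro_svr)
  MAP <- CO * SVR
  PP <- pars$PP0 * sv_frac^pars$pp_sv_exp
  h$SV <- SV; h$HR <- HR; h$CO <- CO; h$SVR <- SVR
  h$SVR_frac <- SVR / h$SVR0
  h$MAP <- MAP
  h$SBP <- MAP + 2 * PP / 3
  h$DBP <- MAP - PP / 3
  h
}

#' Urine output update
#'
#' Saturating increasing function of arterial pressure and blood volume,
#' calibrated to 0.9 mL/min at baseline:
#' `UO = UO0 * (MAP/MAP0)^3 * (BV/BV0)^2`, clipped at zero and at a
#' configurable multiple of baseline.
#'
#' @param h Hemodynamics sub-state.
#' @param r Renal/metabolic sub-state.
#' @param blood_volume Blood volume (L).
#' @param dt Step (h) (kept for signature symmetry; the volume bookkeeping
#'   lives in [physio_step()]).
#' @param pars `physio_params`.
#' @return Updated renal sub-state with the new `UO`.
#' @export
urine_output <- function(h, r, blood_volume, dt, pars = physio_params()) {
  mfrac <- max(0, h$MAP / pars$MAP0)
  vfrac <- max(0, blood_volume / pars$blood_volume0)
  r$UO <- min(pars$uo_max_frac * pars$UO0,
              pars$UO0 * mfrac^pars$uo_map_exp * vfrac^pars$uo_vol_exp)
  r
}

#' Energy deficit and lactate update
#'
#' The microcirculatory energy deficit accumulates at a rate proportional to
#' lost tissue integrity and recovers when integrity is restored; blood
#' lactate is produced in proportion to the deficit and cleared first order
#' toward its baseline.
#'
#' @param r Renal/metabolic sub-state.
#' @param TI Effective tissue integrity.
#' @param dt Step (h).
#' @param pars `physio_params`.
#' @return Updated sub-state (`E`, `lactate`).
#' @export
metabolic_step <- function(r, TI, dt, pars = physio_params()) {
  stopifnot(dt > 0)
  dmg <- max(0, 1 - TI)
  r$E <- max(0, r$E + dt * (pars$kE * dmg - pars$kErec * r$E * TI))
  r$lactate <- max(pars$lactate0 * 0,
                   r$lactate + dt * (pars$kLprod * r$E -
                                       pars$kLclear *
                                       (r$lactate - pars$lactate0)))
  r
}

#' SIRS symptom effects
#'
#' Fever and tachypnea as sigmoidal Emax responses to lost tissue integrity
#' (`E = Emax (1-TI) / (E50 + (1-TI))`, Hill exponent 1) and white blood
#' cell count proportional to the active neutrophil population.
#'
#' @param TI Effective tissue integrity in \[0, 1\].
#' @param N_A Active blood neutrophils (arbitrary units).
#' @param pars `physio_params`.
#' @return List: `dRR` (1/min), `dTemp` (deg C), `WBC` (ct/uL).
#' @export
symptom_effects <- function(TI, N_A, pars = physio_params()) {
  if (TI < 0 || TI > 1) stop("TI must lie in [0, 1]", call. = FALSE)
  dmg <- 1 - TI
  list(dRR = pars$rr_emax * dmg / (pars$rr_e50 + dmg),
       dTemp = pars$temp_emax * dmg / (pars$temp_e50 + dmg),
       WBC = pars$WBC0 + pars$wbc_per_na * max(0, N_A))
}

#' Advance the physiological layer by one macro step
#'
#' Takes the inflammation outputs as piecewise-constant inputs, updates the
#' endothelium, moves fluid and albumin by explicit flux bookkeeping (so
#' conservation holds to rounding error), advances hemodynamics, renal
#' output, metabolism and symptoms, and tracks SIRS onset and baroreflex
#' inhibition.
#'
#' @param state `physio_state`.
#' @param air List with `TI`, `NO`, `N_A`, `IL6` (inflammation outputs;
#'   defaults are the resting values).
#' @param dt Step (h).
#' @param pars `physio_params`.
#' @param infusion_ml_min Fluid infusion rate into the vasculature (mL/min).
#' @param infusion_alb_g_min Albumin infusion rate (g/min).
#' @param pressor_effect Fractional SVR increase from vasopressors.
#' @return Updated `physio_state`.
#' @export
physio_step <- function(state, air = list(TI = 1, NO = 0.0125, N_A = 0,
                                          IL6 = 1e-3),
                        dt = 0.05, pars = physio_params(),
                        infusion_ml_min = 0, infusion_alb_g_min = 0,
                        pressor_effect = 0) {
  stopifnot(inherits(state, "physio_state"), dt > 0)
  dtm <- dt * 60
  ti_eff <- effective_integrity(air$TI, air$IL6, pars)
  pr <- state$pairs
  n <- length(pr$share)

  # endothelial damage develops progressively (first-order lag on the
  # instantaneous inflammation signal)
  state$endo_dmg <- state$endo_dmg +
    dt / pars$tau_endo_h * ((1 - ti_eff) - state$endo_dmg)
  dmg <- state$endo_dmg
  ti_lag <- 1 - dmg
  # NO-mediated vasoplegia also develops with a lag
  state$no_lag <- state$no_lag + dt / pars$tau_no_h * (air$NO - state$no_lag)
  pr$R1 <- pr$R1_base * pmax(pars$floor_R, 1 - pars$a_R * dmg)
  pr$sigma <- pr$sigma_base * pmax(pars$floor_sigma, 1 - pars$a_sigma * dmg)

  # pressures and concentrations
  plasma <- state$blood_volume * (1 - pars$hct)
  cp <- state$alb_p / (plasma * 1000)              # g/mL
  ci <- pr$alb_i / (pr$Vi * 1000)
  # exponential volume dependence: overfilling raises capillary pressure
  # steeply (boluses drain fast in a leaky state), depletion floors it
  Pc <- pars$Pc0 * exp(pars$Pc_vol_gain *
                         (state$blood_volume / pars$blood_volume0 - 1))
  dVi <- pr$Vi - pr$Vi0
  over <- pmax(0, dVi / (pars$interstitial_knee_L * pr$share) - 1)
  pr$Pi <- pars$Pi0 + dVi / pr$Ci + pars$interstitial_stiff * over^2
  COP_v <- colloid_osmotic_pressure(100 * cp * pars$cpp_per_alb)
  COP_i <- colloid_osmotic_pressure(100 * ci * pars$cpp_per_alb)

  # fluxes (mL/min, g/min)
  Jv <- ((Pc - pr$Pi) - (COP_v - COP_i)) / pr$R1
  Jalb <- vapply(seq_len(n), function(k) {
    albumin_flux(list(sigma = pr$sigma[k], PS = pr$PS[k]), Jv[k], cp,
                 ci[k])
  }, numeric(1))
  lym <- lymph_return(pr, pars$vena_cava_p0, pars)
  lym_alb <- lym * ci

  # renal output from the current hemodynamic state
  state$renal <- urine_output(state$hemo, state$renal, state$blood_volume,
                              dt, pars)
  uo <- state$renal$UO

  # conservation bookkeeping
  dBV <- (-sum(Jv) + sum(lym) + infusion_ml_min + pars$intake_ml_min -
            uo) * dtm / 1000
  state$blood_volume <- state$blood_volume + dBV
  pr$Vi <- pr$Vi + (Jv - lym) * dtm / 1000
  state$alb_p <- state$alb_p +
    (-sum(Jalb) + sum(lym_alb) + infusion_alb_g_min) * dtm
  pr$alb_i <- pr$alb_i + (Jalb - lym_alb) * dtm
  if (state$blood_volume <= 0.5)
    stop("blood volume collapsed below 0.5 L", call. = FALSE)

  state$cum$filtration_ml <- state$cum$filtration_ml + sum(Jv) * dtm
  state$cum$lymph_ml <- state$cum$lymph_ml + sum(lym) * dtm
  state$cum$urine_ml <- state$cum$urine_ml + uo * dtm
  state$cum$intake_ml <- state$cum$intake_ml + pars$intake_ml_min * dtm
  state$cum$infused_ml <- state$cum$infused_ml + infusion_ml_min * dtm
  state$cum$infused_alb_g <- state$cum$infused_alb_g +
    infusion_alb_g_min * dtm

  # symptoms and SIRS tracking (needed for the inhibition ramp)
  sym <- symptom_effects(ti_lag, air$N_A, pars)
  state$renal$temp <- pars$temp0 + sym$dTemp
  state$renal$RR <- pars$RR0 + sym$dRR
  state$renal$WBC <- sym$WBC
  sirs_count <- (state$hemo$HR > pars$sirs_hr) +
    (state$renal$RR > pars$sirs_rr) +
    (state$renal$temp > pars$sirs_temp) +
    (state$renal$WBC > pars$sirs_wbc)
  if (is.na(state$hemo$sirs_onset) && sirs_count >= 2)
    state$hemo$sirs_onset <- state$time
  state$hemo$inhib <- if (is.na(state$hemo$sirs_onset)) 0 else
    pars$inhib_max * min(1, (state$time - state$hemo$sirs_onset) /
                           pars$inhib_ramp_h)

  # hemodynamics and metabolism
  state$hemo <- hemodynamics_step(state$hemo, state$no_lag,
                                  state$blood_volume, pressor_effect, dt,
                                  pars)
  state$renal <- metabolic_step(state$renal, ti_lag, dt, pars)

  state$pairs <- pr
  state$time <- state$time + dt
  state
}
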