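# Drug and fluid models: reduced two-compartment infusion pharmacokinetics,
# MIC-anchored antibiotic pharmacodynamics, vasopressor effect and fluid
# compounds.

#' Two-compartment pharmacokinetic parameters
#'
#' Linear mammillary two-compartment model with central elimination:
#' `V1`/`V2` central and peripheral volumes (L), `Q` inter-compartment
#' clearance (L/h), `CL` elimination clearance (L/h), `fu` unbound fraction.
#' The area under the plasma curve after an intravenous dose is `dose / CL`
#' regardless of the distribution parameters.
#'
#' @param V1,V2 Compartment volumes (L), positive.
#' @param Q Inter-compartment clearance (L/h).
#' @param CL Elimination clearance (L/h).
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @return List of class `pk_params`.
#' @export
pk_params <- function(V1, V2, Q, CL, fu = 1) {
  stopifnot(V1 > 0, V2 > 0, Q > 0, CL > 0, fu > 0, fu <= 1)
  out <- list(V1 = V1, V2 = V2, Q = Q, CL = CL, fu = fu)
  class(out) <- "pk_params"
  out
}

# 2x2 matrix exponential step with constant input, via eigendecomposition.
# The rate matrix of a positive two-compartment model always has two
# distinct negative real eigenvalues.
.pk_propagator <- function(pk, dt) {
  a <- -(pk$CL + pk$Q) / pk$V1
  b <- pk$Q / pk$V2
  c <- pk$Q / pk$V1
  d <- -pk$Q / pk$V2
  tr <- a + d
  det <- a * d - b * c
  disc <- sqrt(max(tr^2 - 4 * det, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  # eigenvectors (b != 0 always)
  E <- rbind(c(b, b), c(l1 - a, l2 - a))
  Einv <- solve(E)
  eL <- diag(c(exp(l1 * dt), exp(l2 * dt)))
  phi <- E %*% eL %*% Einv                      # state propagator
  M <- rbind(c(a, b), c(c, d))
  psi <- solve(M, phi - diag(2))                # integral term for input
  list(phi = phi, psi = psi)
}

#' Advance a two-compartment drug model
#'
#' Exact (matrix-exponential) update of the compartment amounts over `dt`
#' hours under a constant infusion into the central compartment.
#'
#' @param pk `pk_params`.
#' @param amounts Numeric length-2, central and peripheral amounts (mg).
#' @param infusion_rate Constant input rate over the step (mg/h).
#' @param dt Step length (h), positive.
#' @return List: `amounts` (mg), `C_plasma` (mg/L), `C_u` (unbound, mg/L),
#'   `eliminated` (mg eliminated during the step).
#' @export
pk_step <- function(pk, amounts = c(0, 0), infusion_rate = 0, dt) {
  stopifnot(inherits(pk, "pk_params"), dt > 0, infusion_rate >= 0,
            length(amounts) == 2L)
  pr <- .pk_propagator(pk, dt)
  a_new <- as.numeric(pr$phi %*% amounts + pr$psi %*% c(infusion_rate, 0))
  a_new <- pmax(a_new, 0)
  eliminated <- sum(amounts) + infusion_rate * dt - sum(a_new)
  cp <- a_new[1L] / pk$V1
  list(amounts = a_new, C_plasma = cp, C_u = pk$fu * cp,
       eliminated = eliminated)
}

#' Simulate a plasma concentration profile
#'
#' Convenience wrapper around [pk_step()]: simulates an infusion of `dose`
#' mg over `duration` h and returns the concentration-time profile on a
#' regular grid, plus the area under the plasma curve with log-linear tail
#' extrapolation to infinity.
#'
#' @param pk `pk_params`.
#' @param dose Total dose (mg).
#' @param duration Infusion duration (h); 0 is treated as a 1-minute bolus.
#' @param t_end End of the simulated grid (h).
#' @param dt Grid step (h).
#' @return List: `time` (h), `C_plasma`, `C_u` (mg/L), `AUC` (mg.h/L,
#'   extrapolated to infinity), `AUC_observed` (trapezoid over the grid).
#' @export
pk_profile <- function(pk, dose, duration = 0.5, t_end = 24, dt = 0.01) {
  if (duration <= 0) duration <- 1 / 60
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  cp <- numeric(n)
  amounts <- c(0, 0)
  for (i in seq_len(n - 1L)) {
    rate <- if (times[i] < duration) dose / duration else 0
    st <- pk_step(pk, amounts, rate, dt)
    amounts <- st$amounts
    cp[i + 1L] <- st$C_plasma
  }
  auc_obs <- sum((cp[-1L] + cp[-n]) / 2) * dt
  # terminal slope from the last decade of the curve
  lz <- (pk$CL + pk$Q) / pk$V1 + pk$Q / pk$V2
  tr <- -lz
  det <- (pk$CL * pk$Q) / (pk$V1 * pk$V2)
  lambda_z <- (lz - sqrt(lz^2 - 4 * det)) / 2
  auc <- auc_obs + cp[n] / lambda_z
  list(time = times, C_plasma = cp, C_u = pk$fu * cp, AUC = auc,
       AUC_observed = auc_obs)
}

#' Antibiotic pharmacodynamic parameters
#'
#' MIC-anchored sigmoid net-growth model: the net bacterial growth rate
#' falls from `S_max` (no drug) through exactly zero at the minimum
#' inhibitory concentration to `S_min` (maximal kill) as the unbound
#' concentration grows. `S_max - S_min` is the maximal reduction of the
#' growth rate (0.70/h by default).
#'
#' @param S_max Baseline pathogen growth rate (1/h), positive.
#' @param S_min Maximal suppressed growth rate (1/h), negative.
#' @param MIC Minimum inhibitory concentration (mg/L).
#' @param gamma Hill exponent (dimensionless).
#' @return List of class `antibiotic_pd`.
#' @export
antibiotic_pd <- function(S_max = 0.60, S_min = S_max - 0.70, MIC = 16,
                          gamma = 10) {
  stopifnot(S_max > 0, S_min < 0, MIC > 0, gamma > 0)
  out <- list(S_max = S_max, S_min = S_min, MIC = MIC, gamma = gamma)
  class(out) <- "antibiotic_pd"
  out
}

#' Net bacterial growth rate under antibiotic
#'
#' `S_net = S_max - (S_max - S_min) * u / (u - S_min/S_max)` with
#' `u = (C_u/MIC)^gamma`. The rate is exactly zero at `C_u = MIC` for any
#' parameter values, tends to `S_max` without drug and to `S_min` at high
#' concentrations, and is strictly decreasing in `C_u`.
#'
#' @param C_u Unbound plasma concentration (mg/L), non-negative (vector ok).
#' @param pd `antibiotic_pd`.
#' @return Net growth rate(s), 1/h.
#' @export
antibiotic_snet <- function(C_u, pd = antibiotic_pd()) {
  if (any(C_u < 0)) stop("C_u must be >= 0", call. = FALSE)
  u <- (C_u / pd$MIC)^pd$gamma
  pd$S_max - (pd$S_max - pd$S_min) * u / (u - pd$S_min / pd$S_max)
}

#' Vasopressor pharmacodynamic parameters
#'
#' Sigmoidal Emax response of systemic vascular resistance to the plasma
#' concentration of a vasopressor (norepinephrine by default), with its own
#' fast two-compartment kinetics.
#'
#' @param E_max Maximal fractional SVR increase.
#' @param EC_50 Concentration of half-maximal effect (ug/L).
#' @param gamma Hill exponent.
#' @param pk `pk_params` for the drug (amounts in ug).
#' @return List of class `vasopressor_pd`.
#' @export
vasopressor_pd <- function(E_max = 0.35, EC_50 = 2.5, gamma = 1.5,
                           pk = pk_params(V1 = 8, V2 = 5, Q = 30,
                                          CL = 180, fu = 1)) {
  stopifnot(E_max > 0, EC_50 > 0, gamma > 0)
  out <- list(E_max = E_max, EC_50 = EC_50, gamma = gamma, pk = pk)
  class(out) <- "vasopressor_pd"
  out
}

#' Fractional SVR increase from a vasopressor
#'
#' @param C_plasma Plasma concentration (ug/L), non-negative.
#' @param pd `vasopressor_pd`.
#' @return Fractional SVR increase (0 at zero concentration, `E_max/2` at
#'   `EC_50`).
#' @export
vasopressor_effect <- function(C_plasma, pd = vasopressor_pd()) {
  if (any(C_plasma < 0)) stop("C_plasma must be >= 0", call. = FALSE)
  x <- C_plasma^pd$gamma
  pd$E_max * x / (x + pd$EC_50^pd$gamma)
}

#' Fluid compounds
#'
#' Composition of infusible fluids: normal saline carries no albumin;
#' albumin colloid carries `albumin_g_dl` grams per decilitre.
#'
#' @param name "saline" or "albumin_colloid" (or a custom label).
#' @param albumin_g_dl Albumin concentration (g/dL).
#' @return List of class `fluid_compound`.
#' @export
fluid_compound <- function(name = c("saline", "albumin_colloid"),
                           albumin_g_dl = if (name == "albumin_colloid")
                             5 else 0) {
  name <- if (length(name) > 1L) name[1L] else name
  stopifnot(albumin_g_dl >= 0)
  out <- list(name = name, albumin_g_dl = albumin_g_dl)
  class(out) <- "fluid_compound"
  out
}

#' Default drug registry
#'
#' Piperacillin (the antibacterial component of piperacillin/tazobactam;
#' tazobactam is assumed to contribute no antibacterial activity of its own)
#' and norepinephrine. Piperacillin's clearance is calibrated so a 4.5 g
#' infusion yields a plasma AUC of 278 mg.h/L; the Hill exponent is
#' calibrated so the near-maximal antibacterial effect (MIC 16 mg/L) lasts
#' about 3 h after a 4.5 g / 30 min dose.
#'
#' @param S_max Baseline pathogen growth rate used in the antibiotic PD
#'   block (defaults to the AIR model's `S_P`).
#' @return Named list of drug definitions; each has a `pk` block and a `pd`
#'   block plus a `type` ("antibiotic" or "vasopressor") and default units.
#' @export
drug_registry <- function(S_max = 0.60) {
  list(
    piperacillin = list(
      type = "antibiotic",
      pk = pk_params(V1 = 8, V2 = 18, Q = 24, CL = 4500 / 278, fu = 0.7),
      pd = antibiotic_pd(S_max = S_max, S_min = S_max - 0.70, MIC = 16,
                         gamma = 10),
      dose_unit = "mg"
    ),
    norepinephrine = list(
      type = "vasopressor",
      pk = pk_params(V1 = 8, V2 = 5, Q = 30, CL = 180, fu = 1),
      pd = vasopressor_pd(),
      dose_unit = "ug"
    )
  )
}

#' Read and write a drug registry file
#'
#' Flat JSON serialisation of the per-drug PK and PD blocks.
#'
#' @param registry As returned by [drug_registry()].
#' @param path File path.
#' @return `read_drug_registry()` returns the registry list.
#' @export
write_drug_registry <- function(registry, path) {
  plain <- lapply(registry, function(d) {
    list(type = d$type, pk = unclass(d$pk),
         pd = unclass(if (d$type == "vasopressor") {
           v <- d$pd; v$pk <- unclass(v$pk); v
         } else d$pd),
         dose_unit = d$dose_unit)
  })
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_drug_registry
#' @export
read_drug_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(d) {
    pk <- do.call(pk_params, as.list(d$pk))
    pd <- if (d$type == "vasopressor") {
      vasopressor_pd(E_max = d$pd$E_max, EC_50 = d$pd$EC_50,
                     gamma = d$pd$gamma,
                     pk = do.call(pk_params, as.list(d$pd$pk)))
    } else {
      antibiotic_pd(S_max = d$pd$S_max, S_min = d$pd$S_min, MIC = d$pd$MIC,
                    gamma = d$pd$gamma)
    }
    list(type = d$type, pk = pk, pd = pd, dose_unit = d$dose_unit)
  })
}
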