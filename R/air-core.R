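# Core of the acute inflammatory response (AIR) model: state construction,
# the algebraic nitric-oxide relation, the hysteretic TLR switch and the
# 18-equation right-hand side.

.air_state_names <- c(
  "P_T", "M_T", "N_T", "B", "P_B",
  "M_R", "M_A", "N_R", "N_A",
  "iNOSd", "iNOS", "eNOS", "NO3",
  "TNF", "IL6", "IL10", "IL12", "TI"
)

#' AIR state vector
#'
#' Constructs the 18-component state of the acute inflammatory response
#' model, defaulting to the healthy (quiescent) equilibrium: no pathogen,
#' intact epithelial barrier and tissue integrity, resting immune pools at
#' their source levels, constitutive nitric oxide from eNOS only, and
#' cytokines at their background sources. The healthy equilibrium is a fixed
#' point of the model (all derivatives vanish to numerical precision).
#'
#' @param ... Named overrides of individual state components (e.g.
#'   `P_T = 1e7` to seed a tissue infection).
#' @param params `air_params` vector used to place the equilibrium values
#'   (`eNOS = k_ENOSEC / k_ENOS`, `M_R = S_M`, `N_R = S_N`, `IL6 = S_6`,
#'   `IL10 = S_10`).
#' @return Named numeric vector of class `air_state` with components
#'   `P_T` (tissue pathogen), `M_T`, `N_T` (local macrophages/neutrophils),
#'   `B` (barrier integrity in \[0, 1\]), `P_B` (blood pathogen),
#'   `M_R`, `M_A`, `N_R`, `N_A` (resting/active blood macrophages and
#'   neutrophils), `iNOSd`, `iNOS`, `eNOS` (NO synthase pools), `NO3`
#'   (nitrate), `TNF`, `IL6`, `IL10`, `IL12` (cytokines) and `TI` (tissue
#'   integrity in \[`TI_min`, 1\]).
#' @examples
#' s <- air_state(P_T = 1e6)
#' s[["eNOS"]]
#' @export
air_state <- function(..., params = air_params()) {
  eq <- c(
    P_T = 0, M_T = 0, N_T = 0, B = 1, P_B = 0,
    M_R = params[["S_M"]], M_A = 0,
    N_R = params[["S_N"]], N_A = 0,
    iNOSd = 0, iNOS = 0,
    eNOS = params[["k_ENOSEC"]] / params[["k_ENOS"]],
    NO3 = params[["k_ENOSEC"]] / params[["k_ENOS"]],
    TNF = 0, IL6 = params[["S_6"]], IL10 = params[["S_10"]],
    IL12 = 0, TI = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && length(over[[1L]]) > 1L)
    over <- as.list(over[[1L]])
  if (length(over)) {
    nm <- names(over)
    unknown <- setdiff(nm, .air_state_names)
    if (length(unknown))
      stop("unknown AIR state component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    eq[nm] <- vapply(over, function(v) as.numeric(v)[1L], numeric(1))
  }
  validate_air_state(eq, params)
  class(eq) <- c("air_state", "numeric")
  eq
}

validate_air_state <- function(s, params = air_params()) {
  if (any(!is.finite(s)))
    stop("AIR state must be finite", call. = FALSE)
  if (any(s < 0))
    stop("AIR state components must be >= 0", call. = FALSE)
  if (s[["B"]] > 1) stop("barrier integrity B must lie in [0, 1]",
                         call. = FALSE)
  if (s[["TI"]] > 1 || s[["TI"]] < params[["TI_min"]])
    stop("tissue integrity TI must lie in [TI_min, 1]", call. = FALSE)
  invisible(s)
}

#' Algebraic nitric-oxide level
#'
#' Nitric oxide is not a differential state: it is reconstructed at every
#' evaluation as `NO = iNOS * (1 + k_NOMA * (M_A + N_A)) + eNOS`, i.e. the
#' inducible synthase pool amplified by the activated immune-cell
#' populations plus the constitutive endothelial contribution.
#'
#' @param state `air_state` vector (or any named vector with `iNOS`,
#'   `eNOS`, `M_A`, `N_A`).
#' @param params `air_params` vector.
#' @return Nitric-oxide level (arbitrary concentration, scalar).
#' @export
nitric_oxide <- function(state, params = air_params()) {
  state[["iNOS"]] * (1 + params[["k_NOMA"]] *
                       (state[["M_A"]] + state[["N_A"]])) + state[["eNOS"]]
}

#' Hysteretic TLR switch update
#'
#' The toll-like-receptor switch `R` gates barrier degradation and
#' neutrophil migration. It turns on when the tissue pathogen count exceeds
#' the upper threshold `PT_plus`, turns off below the lower threshold
#' `PT_minus`, and retains its previous state in between (hysteresis).
#'
#' @param P_T Tissue pathogen count (non-negative).
#' @param previous_R Previous switch state, 0 or 1.
#' @param params `air_params` vector supplying `PT_plus` and `PT_minus`;
#'   ignored if both thresholds are given explicitly.
#' @param P_plus,P_minus Optional explicit thresholds (`P_minus < P_plus`).
#' @return 0 or 1.
#' @examples
#' tlr_update(3e6, 0)  # above PT_plus: on
#' tlr_update(1e5, 1)  # between thresholds: retains previous state
#' @export
tlr_update <- function(P_T, previous_R, params = air_params(),
                       P_plus = params[["PT_plus"]],
                       P_minus = params[["PT_minus"]]) {
  if (P_minus >= P_plus)
    stop("TLR thresholds require P_minus < P_plus", call. = FALSE)
  if (!previous_R %in% c(0, 1))
    stop("previous_R must be 0 or 1", call. = FALSE)
  if (P_T > P_plus) 1
  else if (P_T < P_minus) 0
  else previous_R
}

#' Growth-rate modifier for antibiotic coupling
#'
#' Carries the effective net pathogen growth rates applied to the tissue
#' (logistic) and blood (linear) growth terms. Antibiotics reduce these
#' below the intrinsic rate `S_P` (possibly below zero); in the absence of
#' drug both default to `S_P`.
#'
#' @param S_net_tissue,S_net_blood Net growth rates (1/h). `NA` means "use
#'   `S_P` from the parameter vector at evaluation time".
#' @return List of class `growth_modifier`.
#' @export
growth_modifier <- function(S_net_tissue = NA_real_,
                            S_net_blood = NA_real_) {
  out <- list(S_net_tissue = as.numeric(S_net_tissue),
              S_net_blood = as.numeric(S_net_blood))
  class(out) <- "growth_modifier"
  out
}

resolve_modifier <- function(modifier, params) {
  sp <- params[["S_P"]]
  st <- modifier$S_net_tissue
  sb <- modifier$S_net_blood
  c(S_net_tissue = if (is.na(st)) sp else min(st, sp),
    S_net_blood = if (is.na(sb)) sp else min(sb, sp))
}

#' AIR model right-hand side
#'
#' Evaluates the time derivatives of all 18 AIR states. Tissue pathogen
#' growth is logistic with carrying capacity `kappa_PT`; blood pathogen
#' growth is linear. Both growth rates can be replaced by antibiotic-reduced
#' net rates via `modifier`. The TLR switch value `R` is supplied externally
#' (see [tlr_update()]) and treated as a constant during evaluation. The
#' nitric-oxide level is reconstructed algebraically before the synthase,
#' cytokine and tissue-integrity equations are evaluated.
#'
#' This is the reference (pure R) implementation; the integrator uses an
#' identical compiled version, and the two are cross-checked in the test
#' suite.
#'
#' @param state `air_state` vector.
#' @param params `air_params` vector.
#' @param R TLR switch value, 0 or 1.
#' @param modifier `growth_modifier` (defaults to intrinsic growth).
#' @return Named numeric vector of derivatives (1/h), one per state.
#' @export
air_derivatives <- function(state, params = air_params(), R = 0,
                            modifier = growth_modifier()) {
  s <- pmax(as.numeric(state), 0)
  names(s) <- .air_state_names
  p <- unclass(params)
  snet <- resolve_modifier(modifier, params)

  P_T <- s[["P_T"]]; M_T <- s[["M_T"]]; N_T <- s[["N_T"]]; B <- s[["B"]]
  P_B <- s[["P_B"]]; M_R <- s[["M_R"]]; M_A <- s[["M_A"]]
  N_R <- s[["N_R"]]; N_A <- s[["N_A"]]
  iNOSd <- s[["iNOSd"]]; iNOS <- s[["iNOS"]]; eNOS <- s[["eNOS"]]
  NO3 <- s[["NO3"]]; TNF <- s[["TNF"]]; IL6 <- s[["IL6"]]
  IL10 <- s[["IL10"]]; IL12 <- s[["IL12"]]; TI <- s[["TI"]]

  NO <- iNOS * (1 + p[["k_NOMA"]] * (M_A + N_A)) + eNOS
  # translocation is gated by barrier loss; b_B is a small constitutive
  # permeability so that even an intact barrier admits a trickle
  transloc <- p[["theta_P"]] * P_T * min(1, 1 - B + p[["b_B"]]) /
    (1 + p[["k_PTB"]] * B)
  dmg <- max(0, 1 - TI)

  d <- numeric(18)
  names(d) <- .air_state_names

  # logistic growth written as net growth minus density-dependent
  # mortality, so an antibiotic-suppressed (negative) net rate still kills
  # above the carrying capacity
  d[["P_T"]] <- snet[["S_net_tissue"]] * P_T -
    p[["S_P"]] * P_T^2 / p[["kappa_PT"]] -
    transloc - p[["k_PTMT"]] * M_T * P_T - p[["k_PTNT"]] * N_T * P_T

  d[["M_T"]] <- p[["S_MT"]] * N_T * p[["M_v"]] / (1 + p[["k_MTB"]] * B) -
    p[["k_MT"]] * M_T

  d[["N_T"]] <- p[["S_NT"]] * R * p[["N_v"]] /
    ((1 + p[["k_NTB"]] * B) * (1 + p[["k_NTMT"]] * M_T)) -
    p[["k_NT"]] * N_T

  # Barrier degradation requires both TLR activation (R) and a high local
  # pathogen burden (saturating threshold x_BP); its rate grows with the
  # burden (the 4e-8 coefficient is on the pathogen count scale). Below the
  # burden threshold the barrier holds and the infection stays
  # compartmentalised in the tissue.
  # healing is suppressed by pathogen burden relative to carrying capacity
  d[["B"]] <- p[["S_B"]] * (1 - B) /
    (1 + p[["k_BPT"]] * P_T / p[["kappa_PT"]]) -
    (p[["k_BR"]] + p[["k_BNT"]] * P_T) * R * B *
      hill_up(P_T, p[["x_BP"]], p[["h_BP"]])

  d[["P_B"]] <- snet[["S_net_blood"]] * P_B + transloc -
    p[["k_PS"]] * P_B / (p[["x_PS"]] + P_B) -
    p[["k_PBNA"]] * N_A * hill_up(P_B, p[["x_PN"]], 2)

  act_M <- (p[["k_MP"]] * hill_up(P_B, p[["x_MP"]], 2) +
              p[["k_MD"]] * hill_up(dmg, p[["x_MD"]], 4)) *
    (hill_up(TNF, p[["x_MTNF"]], 2) +
       p[["k_M6"]] * hill_up(IL6, p[["x_M6"]], 2)) *
    hill_down(IL10, p[["x_M10"]], 2)
  d[["M_R"]] <- -act_M * M_R - p[["k_MR"]] * (M_R - p[["S_M"]])
  d[["M_A"]] <- act_M * M_R - p[["k_MA"]] * M_A

  act_N <- (p[["k_NP"]] * hill_up(P_B, p[["x_NP"]], 1) +
              p[["k_ND"]] * hill_up_sat(dmg, p[["x_ND"]], 2) +
              p[["k_NTNF"]] * hill_up_sat(TNF, p[["x_NTNF"]], 1) +
              p[["k_N6"]] * hill_up_sat(IL6, p[["x_N6"]], 2)) *
    hill_down(IL10, p[["x_N10"]], 2)
  d[["N_R"]] <- -act_N * N_R - p[["k_NR"]] * (N_R - p[["S_N"]])
  d[["N_A"]] <- act_N * N_R - p[["k_NA"]] * N_A

  d[["iNOSd"]] <- (p[["k_INOSN"]] * N_A + p[["k_INOSM"]] * M_A +
                     p[["k_INOSEC"]] *
                     (hill_up_sat(TNF, p[["x_INOSTNF"]], 2) +
                        p[["k_INOS6"]] * hill_up_sat(IL6, p[["x_INOS6"]], 2))) *
    hill_down(IL10, p[["x_INOS10"]], 2) *
    hill_down(NO, p[["x_INOSNO"]], 4) -
    p[["k_INOSd"]] * iNOSd

  d[["iNOS"]] <- p[["k_INOS"]] * (iNOSd - iNOS)

  d[["eNOS"]] <- p[["k_ENOSEC"]] *
    hill_down(TNF, p[["x_ENOSTNF"]], 1) *
    hill_down(P_B, p[["x_ENOSP"]], 1) -
    p[["k_ENOS"]] * eNOS

  d[["NO3"]] <- p[["k_NO3"]] * (NO - NO3)

  d[["TNF"]] <- (p[["k_TNFN"]] * N_A + p[["k_TNFM"]] * M_A) *
    hill_down(IL10, p[["x_TNF10"]], 2) *
    hill_down(IL6, p[["x_TNF6"]], 3) -
    p[["k_TNF"]] * TNF

  d[["IL6"]] <- (p[["k_6N"]] * N_A + M_A) *
    (p[["k_6M"]] + p[["k_6TNF"]] * hill_up(TNF, p[["x_6TNF"]], 2) +
       p[["k_6NO"]] * hill_up(NO, p[["x_6NO"]], 2)) *
    hill_down(IL10, p[["x_610"]], 2) *
    hill_down(IL6, p[["x_66"]], 1) -
    p[["k_6"]] * (IL6 - p[["S_6"]])

  d[["IL10"]] <- (p[["k_10N"]] * N_A + M_A) *
    (p[["k_10MA"]] + p[["k_10TNF"]] * hill_up(TNF, p[["x_10TNF"]], 4) +
       p[["k_106"]] * hill_up(IL6, p[["x_106"]], 4)) *
    ((1 - p[["k_10R"]]) * hill_down(IL12, p[["x_1012"]], 4) +
       p[["k_10R"]]) -
    p[["k_10"]] * (IL10 - p[["S_10"]])

  d[["IL12"]] <- p[["k_12M"]] * M_A *
    hill_down(IL10, p[["x_1210"]], 2) - p[["k_12"]] * IL12

  ti_excess <- max(0, TI - p[["TI_min"]])
  d[["TI"]] <- p[["k_D"]] * (1 - TI) * ti_excess -
    ti_excess * p[["k_D6"]] * hill_up(IL6, p[["x_D6"]], 6) /
    (p[["x_DNO"]]^2 + NO^2)

  bad <- which(!is.finite(d))
  if (length(bad))
    stop("non-finite AIR derivative for state component(s): ",
         paste(.air_state_names[bad], collapse = ", "), call. = FALSE)
  d
}
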