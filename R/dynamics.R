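# Hybrid integration of the AIR system (continuous ODEs + discrete TLR
# switch), outcome classification, critical-inoculum bisection and the
# bistable growth-rate window.

.PB_CAP <- 1e10  # blood-pathogen overflow cap: runs reaching it are septic

.air_parms_vec <- function(params, S_net_tissue = NA_real_,
                           S_net_blood = NA_real_, p_cap = .PB_CAP) {
  sp <- params[["S_P"]]
  if (is.na(S_net_tissue)) S_net_tissue <- sp
  if (is.na(S_net_blood)) S_net_blood <- sp
  c(unclass(params)[.air_param_names],
    SNETT = S_net_tissue, SNETB = S_net_blood, PCAP = p_cap)
}

.air_atol <- function(atol_state = 1e-9, atol_pathogen = 1e-3) {
  a <- rep(atol_state, 19L)
  a[c(1L, 5L)] <- atol_pathogen  # P_T, P_B live on count scales
  a[19L] <- 1e-6                 # TLR switch (constant anyway)
  a
}

.ode_call <- function(y, times, pv, rtol, atol, with_root = TRUE) {
  if (with_root) {
    deSolve::lsodar(y = y, times = times, func = "air_derivs", parms = pv,
                    dllname = "sepsim", initfunc = "air_initmod",
                    rootfunc = "air_root", nroot = 3L,
                    nout = 1L, outnames = "NO",
                    rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    deSolve::lsoda(y = y, times = times, func = "air_derivs", parms = pv,
                   dllname = "sepsim", initfunc = "air_initmod",
                   nout = 1L, outnames = "NO",
                   rtol = rtol, atol = atol, maxsteps = 50000)
  }
}

.clamp_state <- function(y, ti_min) {
  y <- pmax(y, 0)
  if (y[4L] > 1) y[4L] <- 1           # barrier integrity
  if (y[18L] > 1) y[18L] <- 1         # tissue integrity
  if (y[18L] < ti_min) y[18L] <- ti_min
  y
}

#' Integrate the hybrid AIR system
#'
#' Advances the 18 AIR states with an adaptive stiff integrator (`lsodar`)
#' while treating the TLR switch as piecewise constant on a macro grid of
#' width `macro_step`: threshold crossings of the tissue pathogen count are
#' located by root finding, integration continues to the next macro
#' boundary, and the hysteresis rule ([tlr_update()]) is applied there.
#' States are clamped to their biological domain (non-negative, `B <= 1`,
#' `TI` in `[TI_min, 1]`) at every hand-off. Blood pathogen is capped at
#' 1e10: a trajectory reaching the cap is terminated and flagged septic
#' (the linear blood growth term is otherwise unbounded).
#'
#' @param initial `air_state` vector (see [air_state()]).
#' @param params `air_params` vector.
#' @param t_span Numeric length-2, start and end time in hours.
#' @param modifier_fn Either `NULL` (intrinsic growth throughout), a single
#'   [growth_modifier()], or a function of time returning one (evaluated at
#'   the start of each macro step; used for antibiotic coupling).
#' @param macro_step Macro grid width in hours (default 0.05).
#' @param R0 Initial TLR switch state; defaults to the Eq-23 rule applied at
#'   `t = 0` with no history (`1` iff `P_T(0) > PT_plus`).
#' @param rtol,atol_state,atol_pathogen Integration tolerances; pathogen
#'   counts get a looser absolute tolerance because they live on count
#'   scales.
#' @return An `air_trajectory`: list with `time` (hours), `state` (matrix,
#'   one row per sample, 18 columns), `R` (switch trace), `NO` (algebraic
#'   nitric oxide), `capped` (TRUE if the blood-pathogen cap terminated the
#'   run) and `params`.
#' @export
integrate_air <- function(initial, params = air_params(),
                          t_span = c(0, 48), modifier_fn = NULL,
                          macro_step = 0.05, R0 = NULL,
                          rtol = 1e-6, atol_state = 1e-9,
                          atol_pathogen = 1e-3) {
  stopifnot(length(t_span) == 2L, t_span[2L] > t_span[1L], macro_step > 0)
  y0 <- as.numeric(initial)[seq_len(18L)]
  if (is.null(R0))
    R0 <- tlr_update(y0[1L], 0, params)
  atol <- .air_atol(atol_state, atol_pathogen)
  grid <- seq(t_span[1L], t_span[2L], by = macro_step)
  if (grid[length(grid)] < t_span[2L]) grid <- c(grid, t_span[2L])

  if (is.null(modifier_fn)) {
    out <- .integrate_chunked(y0, R0, params, grid, macro_step, rtol, atol)
  } else {
    if (inherits(modifier_fn, "growth_modifier")) {
      mod <- modifier_fn
      modifier_fn <- function(t) mod
    }
    out <- .integrate_stepped(y0, R0, params, grid, modifier_fn, rtol, atol)
  }

  traj <- list(time = out$time, state = out$state, R = out$R, NO = out$NO,
               capped = out$capped, params = params,
               macro_step = macro_step)
  colnames(traj$state) <- .air_state_names
  class(traj) <- "air_trajectory"
  traj
}

# Fast path: growth rates constant over the run. Integrates in long chunks,
# stopping only at TLR threshold crossings (roots); the switch rule is then
# applied at the next macro boundary, reproducing macro-frozen semantics.
.integrate_chunked <- function(y0, R0, params, grid, macro_step, rtol,
                               atol) {
  pv <- .air_parms_vec(params)
  ti_min <- params[["TI_min"]]
  n <- length(grid)
  state <- matrix(NA_real_, n, 18L)
  Rtrace <- rep(NA_real_, n)
  NOtrace <- rep(NA_real_, n)
  y <- .clamp_state(y0, ti_min)
  R <- R0
  idx <- 1L
  state[1L, ] <- y; Rtrace[1L] <- R
  NOtrace[1L] <- y[11L] * (1 + params[["k_NOMA"]] * (y[7L] + y[9L])) +
    y[12L]
  capped <- FALSE
  t_cur <- grid[1L]

  while (idx < n) {
    times <- c(t_cur, grid[(idx + 1L):n])
    res <- .ode_call(c(y, Rsw = R), times, pv, rtol, atol, with_root = TRUE)
    iroot <- attr(res, "iroot")
    troot <- attr(res, "troot")
    rows <- res[-1L, , drop = FALSE]
    # keep rows that fall on the macro grid
    got <- rows[, 1L] %in% grid
    gr <- rows[got, , drop = FALSE]
    if (nrow(gr)) {
      take <- idx + seq_len(nrow(gr))
      state[take, ] <- gr[, 2L:19L]
      Rtrace[take] <- R
      NOtrace[take] <- gr[, 21L]
      idx <- idx + nrow(gr)
    }
    if (is.null(iroot) || all(iroot == 0)) break  # reached the horizon
    if (!is.null(iroot) && iroot[3L] != 0) { capped <- TRUE; break }
    # TLR threshold crossed at troot: run with the old switch value to the
    # next macro boundary, then apply the hysteresis rule there.
    ylast <- res[nrow(res), 2L:20L]
    if (troot <= t_cur + 1e-10) {
      # crossing at the chunk start: force one plain macro step
      tb <- grid[min(idx + 1L, n)]
      leg <- .ode_call(ylast, c(troot, tb), pv, rtol, atol,
                       with_root = FALSE)
      yb <- leg[nrow(leg), 2L:20L]
      state[idx + 1L, ] <- yb[1L:18L]
      Rtrace[idx + 1L] <- R
      NOtrace[idx + 1L] <- leg[nrow(leg), 21L]
      idx <- idx + 1L
    } else {
      tb <- grid[idx + 1L]  # smallest grid point > last recorded
      if (tb > troot + 1e-12) {
        leg <- .ode_call(ylast, c(troot, tb), pv, rtol, atol,
                         with_root = FALSE)
        yb <- leg[nrow(leg), 2L:20L]
        state[idx + 1L, ] <- yb[1L:18L]
        Rtrace[idx + 1L] <- R
        NOtrace[idx + 1L] <- leg[nrow(leg), 21L]
        idx <- idx + 1L
      } else {
        yb <- ylast
      }
    }
    y <- .clamp_state(state[idx, ], ti_min)
    R <- tlr_update(y[1L], R, params)
    Rtrace[idx] <- R
    t_cur <- grid[idx]
    if (idx >= n) break
  }
  keep <- !is.na(Rtrace)
  st <- pmax(state[keep, , drop = FALSE], 0)
  if (any(!is.finite(st)))
    stop("AIR integration produced non-finite state near t = ",
         signif(max(grid[keep]), 6), " h", call. = FALSE)
  list(time = grid[keep], state = st, R = Rtrace[keep], NO = NOtrace[keep],
       capped = capped)
}

# General path: growth modifier re-evaluated every macro step (antibiotic
# coupling); the switch rule is applied at every macro boundary.
.integrate_stepped <- function(y0, R0, params, grid, modifier_fn, rtol,
                               atol) {
  ti_min <- params[["TI_min"]]
  n <- length(grid)
  state <- matrix(NA_real_, n, 18L)
  Rtrace <- numeric(n)
  NOtrace <- numeric(n)
  y <- .clamp_state(y0, ti_min)
  R <- R0
  state[1L, ] <- y; Rtrace[1L] <- R
  NOtrace[1L] <- y[11L] * (1 + params[["k_NOMA"]] * (y[7L] + y[9L])) +
    y[12L]
  capped <- FALSE
  last <- n
  for (i in seq_len(n - 1L)) {
    mod <- modifier_fn(grid[i])
    snet <- resolve_modifier(mod, params)
    pv <- .air_parms_vec(params, snet[["S_net_tissue"]],
                         snet[["S_net_blood"]])
    res <- .ode_call(c(y, Rsw = R), c(grid[i], grid[i + 1L]), pv, rtol,
                     atol, with_root = TRUE)
    iroot <- attr(res, "iroot")
    if (!is.null(iroot) && length(iroot) >= 3L && iroot[3L] != 0) {
      capped <- TRUE
      last <- i
      break
    }
    row <- res[nrow(res), ]
    if (row[1L] < grid[i + 1L] - 1e-9) {
      # stopped at a TLR root inside the step: finish the step, same R
      leg <- .ode_call(row[2L:20L], c(row[1L], grid[i + 1L]), pv, rtol,
                       atol, with_root = FALSE)
      row <- leg[nrow(leg), ]
    }
    y <- .clamp_state(row[2L:19L], ti_min)
    if (any(!is.finite(y)))
      stop("AIR integration produced non-finite state at t = ",
           signif(grid[i + 1L], 6), " h", call. = FALSE)
    R <- tlr_update(y[1L], R, params)
    state[i + 1L, ] <- y
    Rtrace[i + 1L] <- R
    NOtrace[i + 1L] <- row[length(row)]
    last <- i + 1L
  }
  keep <- seq_len(last)
  list(time = grid[keep], state = state[keep, , drop = FALSE],
       R = Rtrace[keep], NO = NOtrace[keep], capped = capped)
}

#' @export
print.air_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat("AIR trajectory: ", n, " samples over [",
      signif(x$time[1L], 4), ", ", signif(x$time[n], 5), "] h",
      if (x$capped) " (terminated at blood-pathogen cap)", "\n", sep = "")
  cat("  final P_T = ", signif(x$state[n, "P_T"], 4),
      ", P_B = ", signif(x$state[n, "P_B"], 4),
      ", TI = ", signif(x$state[n, "TI"], 4),
      ", R = ", x$R[n], "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.air_trajectory <- function(x, ...) {
  data.frame(time_h = x$time, x$state, NO = x$NO, R = x$R,
             check.names = FALSE)
}

#' @export
plot.air_trajectory <- function(x, vars = c("P_T", "P_B", "IL6", "TI"),
                                ...) {
  df <- as.data.frame(x)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars[seq_len(min(4L, length(vars)))]) {
    logy <- if (max(df[[v]]) / max(min(df[[v]][df[[v]] > 0]), 1e-12) > 1e3
                && all(df[[v]] >= 0) && any(df[[v]] > 0)) "y" else ""
    y <- df[[v]]
    if (logy == "y") y <- pmax(y, 1e-12)
    graphics::plot(df$time_h, y, type = "l", log = logy,
                   xlab = "time (h)", ylab = v, main = v, ...)
  }
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' One row per macro-grid sample; columns are `time_h`, the 18 state names,
#' `NO` and `R`. A leading comment line documents the units.
#'
#' @param traj `air_trajectory`.
#' @param path Output file.
#' @export
export_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# time_h in hours; P_T, P_B CFU/mL-scaled;",
                   "B, TI, R dimensionless; other states arbitrary",
                   "concentration"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Classify a trajectory as healthy or septic
#'
#' A run is healthy when the blood pathogen count at the horizon has fallen
#' below the elimination threshold `eps_elim`; a run that reached the
#' blood-pathogen cap, or ends above the threshold, is septic. The control
#' time is the first time after which the blood pathogen count declines at
#' every subsequent sample (sustained negative net growth).
#'
#' @param traj `air_trajectory`.
#' @param params `air_params` (unused in the default rule, kept for
#'   signature stability).
#' @param eps_elim Elimination threshold on `P_B` (arbitrary units). The
#'   healthy (carrier) branch settles near 0.5 and the septic branch ends at
#'   the 1e10 cap, so any threshold within a couple of orders of magnitude
#'   of the default separates them.
#' @return An `air_outcome`: list with `label` ("healthy"/"septic"),
#'   `control_time` (h, `NA` when never controlled), `P_B_final`, and
#'   `inconclusive` (TRUE when `P_B` at the horizon is within a factor 10
#'   of `eps_elim`).
#' @export
classify_outcome <- function(traj, params = traj$params,
                             eps_elim = 20) {
  tmax <- traj$time[length(traj$time)] - traj$time[1L]
  if (tmax < 200 && !traj$capped)
    warning("trajectory spans ", signif(tmax, 4),
            " h; asymptotic classification prefers >= 200 h")
  pb <- traj$state[, "P_B"]
  n <- length(pb)
  pb_final <- pb[n]
  label <- if (traj$capped || pb_final >= eps_elim) "septic" else "healthy"
  inconclusive <- !traj$capped &&
    pb_final > eps_elim / 10 && pb_final < eps_elim * 10
  # controlled: declining, or persistently negligible bacteremia (the
  # healthy carrier branch plateaus at ~0.5 rather than declining strictly)
  controlled <- diff(pb) < 0 | pb[-1L] < eps_elim / 10
  if (all(controlled)) {
    control_time <- traj$time[1L]
  } else {
    bad <- max(which(!controlled))
    control_time <- if (bad >= n - 1L) NA_real_ else traj$time[bad + 1L]
  }
  if (label == "septic") control_time <- NA_real_
  out <- list(label = label, control_time = control_time,
              P_B_final = pb_final, inconclusive = inconclusive,
              capped = traj$capped)
  class(out) <- "air_outcome"
  out
}

#' @export
print.air_outcome <- function(x, ...) {
  cat("AIR outcome:", x$label)
  if (x$label == "healthy" && !is.na(x$control_time))
    cat(" (blood pathogen controlled from ", signif(x$control_time, 4),
        " h)", sep = "")
  if (x$inconclusive) cat(" [inconclusive]")
  cat("\n")
  invisible(x)
}

.classify_load <- function(load, params, horizon, macro_step, eps_elim) {
  traj <- integrate_air(air_state(P_T = load, params = params), params,
                        t_span = c(0, horizon), macro_step = macro_step)
  out <- classify_outcome(traj, params, eps_elim)
  if (out$inconclusive) {
    # tie-break on the sign of dP_B/dt at the horizon
    n <- length(traj$time)
    dpb <- traj$state[n, "P_B"] - traj$state[n - 1L, "P_B"]
    out$label <- if (dpb < 0) "healthy" else "septic"
  }
  out$label
}

#' Critical initial tissue pathogen load
#'
#' Bisection on the initial tissue load `P_T(0)` (all other states at the
#' healthy equilibrium) for the separatrix between the healthy and septic
#' outcome basins, at a given pathogen growth rate. Within the bistable
#' window the model is healthy below the critical load and septic above it.
#'
#' @param S_P Pathogen growth rate (1/h); overrides `params[["S_P"]]`.
#' @param params `air_params`.
#' @param bracket Length-2 load interval whose endpoints classify to
#'   different outcomes.
#' @param rel_tol Stop when bracket width / midpoint < `rel_tol`.
#' @param horizon Classification horizon (h).
#' @param macro_step Macro grid width (h).
#' @param eps_elim Elimination threshold passed to [classify_outcome()].
#' @return List of class `critical_load`: `critical_load` (bracket
#'   midpoint), `bracket` (final bracket), `S_P`, `n_runs`.
#' @export
find_critical_load <- function(S_P = 0.6, params = air_params(),
                               bracket = c(1e6, 1e7), rel_tol = 0.01,
                               horizon = 500, macro_step = 0.05,
                               eps_elim = 20) {
  stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L], rel_tol > 0)
  pp <- as.list(unclass(params)); pp[["S_P"]] <- S_P
  params <- air_params(pp)
  lo <- bracket[1L]; hi <- bracket[2L]
  lab_lo <- .classify_load(lo, params, horizon, macro_step, eps_elim)
  lab_hi <- .classify_load(hi, params, horizon, macro_step, eps_elim)
  if (lab_lo == lab_hi)
    stop("both bracket endpoints classify as '", lab_lo,
         "'; no critical load inside the bracket", call. = FALSE)
  n_runs <- 2L
  while ((hi - lo) / ((hi + lo) / 2) >= rel_tol) {
    mid <- (hi + lo) / 2
    lab <- .classify_load(mid, params, horizon, macro_step, eps_elim)
    n_runs <- n_runs + 1L
    if (lab == lab_lo) lo <- mid else hi <- mid
  }
  out <- list(critical_load = (hi + lo) / 2, bracket = c(lo, hi),
              S_P = S_P, n_runs = n_runs)
  class(out) <- "critical_load"
  out
}

#' @export
print.critical_load <- function(x, ...) {
  cat("Critical initial tissue load at S_P = ", x$S_P, ": ",
      signif(x$critical_load, 4), " (bracket [",
      signif(x$bracket[1L], 4), ", ", signif(x$bracket[2L], 4),
      "], ", x$n_runs, " runs)\n", sep = "")
  invisible(x)
}

#' Bistable window of the pathogen growth rate
#'
#' Scans a grid of growth rates and reports the smallest and largest values
#' at which both the healthy and the septic outcome are reachable within a
#' range of initial tissue loads (healthy at the low end, septic at the
#' high end).
#'
#' @param params `air_params`.
#' @param S_P_grid Sorted grid of growth rates (1/h).
#' @param load_range Length-2 interval of initial loads spanning at least
#'   four orders of magnitude.
#' @param horizon,macro_step,eps_elim As in [find_critical_load()].
#' @return List with `S_low`, `S_high` (NA when the window is empty) and
#'   the logical vector `bistable` along the grid.
#' @export
find_bistable_interval <- function(params = air_params(),
                                   S_P_grid = seq(0.40, 0.90, by = 0.05),
                                   load_range = c(1e5, 1e9),
                                   horizon = 500, macro_step = 0.05,
                                   eps_elim = 20) {
  stopifnot(!is.unsorted(S_P_grid), length(load_range) == 2L)
  if (diff(log10(load_range)) < 4)
    stop("load_range must span at least 4 orders of magnitude",
         call. = FALSE)
  bistable <- vapply(S_P_grid, function(sp) {
    pp <- as.list(unclass(params)); pp[["S_P"]] <- sp
    p <- air_params(pp)
    lo <- .classify_load(load_range[1L], p, horizon, macro_step, eps_elim)
    if (lo != "healthy") return(FALSE)
    hi <- .classify_load(load_range[2L], p, horizon, macro_step, eps_elim)
    hi == "septic"
  }, logical(1))
  if (!any(bistable)) {
    message("no bistable growth rate found on the supplied grid")
    return(list(S_low = NA_real_, S_high = NA_real_, bistable = bistable))
  }
  list(S_low = min(S_P_grid[bistable]), S_high = max(S_P_grid[bistable]),
       bistable = bistable)
}
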