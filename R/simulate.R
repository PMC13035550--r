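full_state_names <- function() {
  kin <- c("p1_0", "p1_1", "p1_2", "p2_0", "p2_1", "p2_2",
           "p3_0", "p3_1", "p3_2", "N_np", "U_SR")
  c(paste0(rep(c("LV", "SEP", "RV"), each = 11), ".", rep(kin, 3)),
    "Ls_LV", "Ls_SEP", "Ls_RV",
    "x_LV", "x_SEP", "x_RV", "y_m",
    "V_LV", "V_RV", "V_SA", "V_SV", "V_PA", "V_PV")
}

full_out_names <- function() {
  c("P_LV", "P_RV", "P_SA", "P_SV", "P_PA", "P_PV", "Cm_SEP",
    "sXB_LV", "sXB_SEP", "sXB_RV",
    "Q_m", "Q_a", "Q_t", "Q_p", "Q_SA", "Q_PA", "Ca")
}

# End-diastolic volumes implied by a parameter set: the record's measured
# EDVs when the set was built from a record, otherwise the volumes at which
# the balanced diastolic geometry restores the free walls to the anchored
# end-diastolic sarcomere length (2-D Newton on the free-wall strains).
default_edv <- function(p) {
  edv <- attr(p, "edv")
  if (!is.null(edv)) return(edv)
  target <- rh_constants()$Ls_ed
  f <- function(v) {
    g <- solve_triseg_geometry(v[1], v[2], c(1, 1, 1), p)
    g$L_s_wall[c(1, 3)] - target
  }
  v <- c(0.05, 0.05)
  for (it in 1:30) {
    r0 <- f(v)
    if (max(abs(r0)) < 1e-8) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      vj <- v; vj[j] <- vj[j] * (1 + 1e-6)
      J[, j] <- (f(vj) - r0) / (v[j] * 1e-6)
    }
    v <- pmax(v - solve(J, r0), 1e-4)
  }
  c(LV = v[1], RV = v[2])
}

# self-consistent diastolic wall stress for geometry initialization:
# series element balancing the passive curve at the current wall length
diastolic_sigma_fun <- function(p, ls_state = NULL) {
  walls <- c("LV", "SEP", "RV")
  function(lsw) {
    if (is.null(ls_state)) {
      ls <- vapply(seq_along(walls), function(i)
        passive_equilibrium_ls(lsw[i], p, walls[i]), 0)
    } else ls <- ls_state
    p[["K_SE"]] * (lsw - ls)
  }
}

#' Consistent initial state of the full model
#'
#' Ventricles at end-diastolic volume, TriSeg geometry solved to satisfy
#' its algebraic constraints, crossbridges fully detached with the
#' super-relaxed pool at its resting fraction, contractile lengths at
#' passive/series equilibrium, and vascular volumes distributed as
#' zero-pressure volumes plus a compliance-weighted share of the remaining
#' blood volume (so all compartment volumes sum to `V_total`).
#'
#' @param p An `rh_params` set.
#' @param edv Optional `c(LV, RV)` end-diastolic volumes (mL); by default
#'   the volumes implied by the reference areas.
#' @return Named state vector of length 46.
#' @export
initial_state <- function(p, edv = NULL) {
  edv <- edv %||% default_edv(p)
  g0 <- solve_triseg_geometry(edv[[1]], edv[[2]], c(1, 1, 1), p)
  geom <- solve_triseg_geometry(edv[[1]], edv[[2]],
                                diastolic_sigma_fun(p), p,
                                guess = c(g0$x, g0$y_m))
  walls <- c("LV", "SEP", "RV")
  ls <- vapply(seq_along(walls), function(i)
    passive_equilibrium_ls(geom$L_s_wall[i], p, walls[i]), 0)
  kin <- resting_wall_state(p)
  Cs <- as.numeric(p[c("C_SA", "C_SV", "C_PA", "C_PV")])
  V_un <- p[["v_un_frac"]] * p[["V_total"]] * rh_constants()$vun_weights
  V_rem <- p[["V_total"]] - edv[[1]] - edv[[2]] - sum(V_un)
  if (V_rem <= 0) abort("total blood volume too small for the ventricles")
  y <- c(rep(kin, 3), ls, geom$x, geom$y_m,
         edv[[1]], edv[[2]], V_un + Cs / sum(Cs) * V_rem)
  names(y) <- full_state_names()
  y
}

# re-solve the geometry rows of a state so the algebraic constraints hold
# for (possibly new) parameters; used to warm-start from a previous run
project_geometry <- function(y, p) {
  ls <- y[34:36]
  geom <- solve_triseg_geometry(y[[41]], y[[42]],
                                function(lsw) p[["K_SE"]] * (lsw - ls),
                                p, guess = unname(y[37:40]))
  y[37:40] <- c(geom$x, geom$y_m)
  y
}

#' Assemble the full 46-state right-hand side
#'
#' Evaluates the coupled model derivative at one state: crossbridge moment
#' kinetics per wall, myofiber force balances, the four TriSeg algebraic
#' residuals (reported in the geometry slots), and the compartment volume
#' balances. The six volume derivatives sum to zero exactly (closed loop).
#'
#' @param state Named state vector of length 46 (see [initial_state()]).
#' @param t Time (s).
#' @param p An `rh_params` set.
#' @return Named derivative vector of length 46 with an `outputs` attribute
#'   (pressures, septal curvature, active stresses, valve flows, Ca).
#' @export
assemble_rhs <- function(state, t, p) {
  out <- .Call(C_full_rhs, as.double(t), as.double(state), pack_sim_params(p))
  d <- out[1:46]
  names(d) <- full_state_names()
  o <- out[47:63]
  names(o) <- full_out_names()
  attr(d, "outputs") <- o
  d
}

full_mass_matrix <- function() {
  m <- diag(46)
  diag(m)[37:40] <- 0
  m
}

run_one_cycle <- function(p_packed, y0, T, n_grid = 50, rtol = 1e-7,
                          atol = 1e-9) {
  times <- seq(0, T, length.out = n_grid + 1)
  sol <- deSolve::radau(
    y = unname(y0), times = times,
    func = "ratheart_derivs_full", parms = p_packed,
    dllname = "ratheart", initfunc = "ratheart_init_full",
    nout = length(full_out_names()), outnames = full_out_names(),
    mass = full_mass_matrix(),
    rtol = rtol, atol = atol, maxsteps = 50000
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times) ||
      anyNA(sol) || any(!is.finite(sol)))
    abort("stiff integration failed within a cycle")
  colnames(sol) <- c("time", full_state_names(), full_out_names())
  sol
}

#' Run the closed-loop model to a periodic steady state
#'
#' Integrates cycle by cycle (stiff Radau method, the TriSeg unknowns as
#' algebraic rows of a singular mass matrix) until the end-diastolic and
#' end-systolic volumes of both ventricles change by less than `tol`
#' (relative) between consecutive cycles, then returns the last cycle
#' resampled to `n_grid` uniform points on the half-open interval `[0, T)`.
#'
#' @param p An `rh_params` set.
#' @param edv Optional initial `c(LV, RV)` end-diastolic volumes (mL).
#' @param tol Relative steady-state tolerance on per-cycle EDV/ESV.
#' @param max_cycles Cycle budget.
#' @param n_grid Output grid size per cycle.
#' @param y0 Optional full warm-start state (geometry is re-projected).
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `rh_cycle`: time, pressures (mmHg), ventricular
#'   volumes (uL), sarcomere lengths (um), active stresses (kPa), septal
#'   curvature (1/cm), valve and vascular flows (mL/s), Ca (uM). Attributes:
#'   `params`, `period`, `n_cycles`, `converged`, `final_state`.
#' @export
run_to_steady_state <- function(p, edv = NULL, tol = 1e-3, max_cycles = 40,
                                n_grid = 50, y0 = NULL, rtol = 1e-7,
                                atol = 1e-9) {
  T <- p[["T_cycle"]]
  pp <- pack_sim_params(p)
  y <- if (is.null(y0)) initial_state(p, edv) else project_geometry(y0, p)
  prev <- NULL
  converged <- FALSE
  n_run <- 0
  delta <- NA_real_
  for (k in seq_len(max_cycles)) {
    sol <- run_one_cycle(pp, y, T, n_grid, rtol, atol)
    n_run <- k
    y <- sol[nrow(sol), 1 + seq_len(46)]
    cur <- c(max(sol[, "V_LV"]), min(sol[, "V_LV"]),
             max(sol[, "V_RV"]), min(sol[, "V_RV"]))
    if (!is.null(prev)) {
      delta <- max(abs(cur - prev) / pmax(abs(prev), 1e-9))
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- cur
  }
  if (!converged)
    warn(sprintf(
      "steady state not reached in %d cycles (last EDV/ESV change %.2e)",
      max_cycles, delta))
  grid <- sol[seq_len(n_grid), , drop = FALSE]  # half-open [0, T)
  cyc <- tibble(
    t = grid[, "time"],
    P_LV = grid[, "P_LV"], P_RV = grid[, "P_RV"],
    P_SA = grid[, "P_SA"], P_SV = grid[, "P_SV"],
    P_PA = grid[, "P_PA"], P_PV = grid[, "P_PV"],
    V_LV = grid[, "V_LV"] * 1000, V_RV = grid[, "V_RV"] * 1000,  # uL
    Ls_LV = grid[, "Ls_LV"], Ls_SEP = grid[, "Ls_SEP"],
    Ls_RV = grid[, "Ls_RV"],
    sXB_LV = grid[, "sXB_LV"], sXB_SEP = grid[, "sXB_SEP"],
    sXB_RV = grid[, "sXB_RV"],
    Cm_SEP = grid[, "Cm_SEP"],
    Q_m = grid[, "Q_m"], Q_a = grid[, "Q_a"],
    Q_t = grid[, "Q_t"], Q_p = grid[, "Q_p"],
    Q_SA = grid[, "Q_SA"], Q_PA = grid[, "Q_PA"],
    Ca = grid[, "Ca"]
  )
  structure(cyc, class = c("rh_cycle", class(cyc)),
            params = p, period = T, n_cycles = n_run,
            converged = converged, final_state = y,
            state_grid = grid)
}

#' Resample a solution to one uniform cycle
#'
#' Uniform `n`-point resampling of the final full period of a simulated or
#' measured trace set by linear interpolation, on the half-open grid
#' `[0, T)`.
#'
#' @param sol A data frame with a `time` (or `t`) column and signal columns.
#' @param T Period (s); the last full period of `sol` is used.
#' @param n Grid size (default 50).
#' @return Tibble with `t` on `[0, T)` and the resampled signal columns.
#' @export
extract_cycle <- function(sol, T, n = 50) {
  sol <- as.data.frame(sol)
  tcol <- if ("time" %in% names(sol)) "time" else "t"
  tt <- sol[[tcol]]
  if (diff(range(tt)) < T - 1e-9)
    abort("solution spans less than one full period")
  t0 <- max(tt) - T
  grid <- t0 + T * (seq_len(n) - 1) / n
  out <- tibble(t = grid - t0)
  for (cn in setdiff(names(sol), tcol))
    out[[cn]] <- stats::approx(tt, sol[[cn]], xout = grid, rule = 2)$y
  out
}

#' @export
print.rh_cycle <- function(x, ...) {
  cat(sprintf(
    "<rh_cycle> period %.3f s, %d cycles to steady state (converged: %s)\n",
    attr(x, "period"), attr(x, "n_cycles"), attr(x, "converged")))
  NextMethod()
}
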