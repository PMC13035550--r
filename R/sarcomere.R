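#' Calcium schedule
#'
#' Prescribed cytosolic Ca2+ transient: a raised-cosine rise over
#' `T_S = k_TS * T`, a raised-cosine fall over `T_R = k_TR * T`, and the
#' diastolic floor otherwise.
#'
#' @param Ca_diastole Diastolic Ca2+ floor (uM).
#' @param Ca_amplitude Transient amplitude (uM).
#' @param k_TS,k_TR Fractions of the cycle spent in Ca2+ rise and decay.
#' @param T Cardiac period (s).
#' @return A `calcium_schedule` list with derived `T_S`, `T_R`.
#' @export
calcium_schedule <- function(Ca_diastole = 0.1610, Ca_amplitude = 2,
                             k_TS = 0.05, k_TR = 0.40, T = 0.177) {
  stopifnot(Ca_diastole > 0, Ca_amplitude > 0, k_TS > 0, k_TR > 0, T > 0)
  if (k_TS + k_TR > 1)
    abort("invalid schedule: k_TS + k_TR must not exceed 1")
  structure(list(Ca_diastole = Ca_diastole, Ca_amplitude = Ca_amplitude,
                 k_TS = k_TS, k_TR = k_TR, T = T,
                 T_S = k_TS * T, T_R = k_TR * T),
            class = "calcium_schedule")
}

#' Cytosolic calcium transient
#'
#' @param t Time(s) within one cycle, s; must lie in `[0, T]`.
#' @param cs A [calcium_schedule()].
#' @return Ca2+ concentration (uM), vectorized over `t`.
#' @export
calcium_transient <- function(t, cs) {
  stopifnot(inherits(cs, "calcium_schedule"))
  if (any(t < 0 | t > cs$T)) abort("invalid time: t must lie in [0, T]")
  rise <- t < cs$T_S
  fall <- !rise & t <= cs$T_S + cs$T_R
  ca <- rep(cs$Ca_diastole, length(t))
  ca[rise] <- cs$Ca_diastole +
    cs$Ca_amplitude * 0.5 * (1 - cos(pi * t[rise] / cs$T_S))
  ca[fall] <- cs$Ca_diastole +
    cs$Ca_amplitude * 0.5 * (1 + cos(pi * (t[fall] - cs$T_S) / cs$T_R))
  ca
}

# schedule from a parameter set
params_schedule <- function(p) {
  calcium_schedule(p[["ca_dia"]], p[["ca_amp"]], p[["k_TS"]], p[["k_TR"]],
                   p[["T_cycle"]])
}

#' Thick-filament overlap fraction
#'
#' Piecewise-linear tent with a unit plateau: no overlap below the thin-
#' filament limit, linear rise to the plateau, and linear decline beyond it.
#'
#' @param L_s Sarcomere length(s), um.
#' @return Overlap fraction in `[0, 1]`.
#' @export
thick_filament_overlap <- function(L_s) {
  stopifnot(all(L_s > 0))
  k <- rh_constants()$ov_knots
  pmax(0, pmin(1, pmin((L_s - k[["La0"]]) / (k[["Lp1"]] - k[["La0"]]),
                       (k[["Ld0"]] - L_s) / (k[["Ld0"]] - k[["Lp2"]]))))
}

# wall index helper
wall_index <- function(wall = c("RV", "LV", "SEP")) {
  wall <- match.arg(wall)
  c(LV = 0L, SEP = 1L, RV = 2L)[[wall]]
}

#' Wall kinetic state
#'
#' Constructs and validates the 11 kinetic quantities of one wall: the
#' 0th-2nd moments of the three attached-state strain distributions, the
#' non-permissible fraction, the super-relaxed fraction, and (separately
#' integrated) the contractile sarcomere length.
#'
#' @param p1,p2,p3 Length-3 numeric: moments (0th, 1st, 2nd) of the loosely
#'   attached, strongly attached, and post-ratchet states.
#' @param N_np Non-permissible fraction.
#' @param U_SR Super-relaxed fraction.
#' @return Named numeric vector of length 11.
#' @export
wall_state <- function(p1 = c(0, 0, 0), p2 = c(0, 0, 0), p3 = c(0, 0, 0),
                       N_np = 0.8, U_SR = 0.2) {
  w <- c(p1_0 = p1[1], p1_1 = p1[2], p1_2 = p1[3],
         p2_0 = p2[1], p2_1 = p2[2], p2_2 = p2[3],
         p3_0 = p3[1], p3_1 = p3[2], p3_2 = p3[3],
         N_np = N_np, U_SR = U_SR)
  fr <- w[c("p1_0", "p2_0", "p3_0", "N_np", "U_SR")]
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    abort("wall state fractions must lie in [0, 1]")
  U <- 1 - sum(w[c("p1_0", "p2_0", "p3_0", "U_SR")])
  if (U < -1e-9) abort("attached + super-relaxed fractions exceed 1")
  w
}

#' Crossbridge moment derivatives
#'
#' Time-derivatives of the 10 kinetic quantities of one wall (plus the
#' sliding-advection terms when a strain velocity is supplied). The
#' permissible/non-permissible exchange uses `k_on * Ca^n_H` and `k_off`;
#' attachment inserts heads at zero strain with flux
#' `k_a * overlap * permissible`; conservation of the five-state pool is
#' exact by construction.
#'
#' @param w Length-11 kinetic state (see [wall_state()]).
#' @param Ca Cytosolic Ca2+ (uM).
#' @param overlap Thick-filament overlap fraction in `[0, 1]`.
#' @param p An `rh_params` set (the effective transition rates are derived
#'   from its metabolite pool).
#' @param wall Which wall's rate constants to use.
#' @param v Strain sliding velocity (um/s), `0.5 * dL_s/dt`; defaults to 0.
#' @return Named numeric vector of 11 derivatives.
#' @export
crossbridge_derivatives <- function(w, Ca, overlap, p, wall = "RV", v = 0) {
  stopifnot(length(w) == 11, overlap >= 0, overlap <= 1)
  if (any(w[c(3, 6, 9)] < 0))
    abort("invalid state: second moments must be nonnegative")
  d <- .Call(C_xb_derivs, as.double(w), as.double(Ca), as.double(overlap),
             as.double(v), wall_index(wall), pack_sim_params(p))
  names(d) <- c("p1_0", "p1_1", "p1_2", "p2_0", "p2_1", "p2_2",
                "p3_0", "p3_1", "p3_2", "N_np", "U_SR")
  d
}

#' Active crossbridge stress
#'
#' `sigma_XB = overlap * (k_stiff1 * (p2_1 + p3_1) + k_stiff2 * dr * p3_0)`.
#'
#' @inheritParams crossbridge_derivatives
#' @return Stress (kPa).
#' @export
active_stress <- function(w, overlap, p, wall = "RV") {
  stopifnot(overlap >= 0, overlap <= 1)
  ks1 <- if (wall == "RV") p[["k_stiff1_RV"]] else p[["k_stiff1"]]
  ks2 <- if (wall == "RV") p[["k_stiff2_RV"]] else p[["k_stiff2"]]
  unname(overlap * (ks1 * (w[5] + w[8]) + ks2 * p[["dr"]] * w[7]))
}

#' Passive myofiber stress
#'
#' Single power-law collagen-recruitment relation
#' `k_passive * (L_s - L_sc0)^gamma` above slack, zero below (no compressive
#' collagen force).
#'
#' @param L_s Sarcomere length(s), um.
#' @param p An `rh_params` set.
#' @param wall Wall whose passive stiffness applies.
#' @return Stress (kPa), vectorized over `L_s`.
#' @export
passive_stress <- function(L_s, p, wall = "RV") {
  stopifnot(all(L_s > 0))
  kp <- if (wall == "RV") p[["k_passive_RV"]] else p[["k_passive"]]
  e <- pmax(L_s - p[["L_sc0"]], 0)
  kp * e^p[["gamma"]]
}

#' Viscous myofiber stress
#'
#' @param dLs_dt Rate of change of sarcomere length (um/s).
#' @param eta Viscosity (kPa s/um).
#' @return Stress (kPa).
#' @export
viscous_stress <- function(dLs_dt, eta) eta * dLs_dt

#' Myofiber force balance
#'
#' The series element transmits the wall-level stress:
#' `sigma_SE = K_SE * (L_s_wall - L_s)`, and the contractile element evolves
#' so the balance `sigma_SE = sigma_XB + sigma_pas + sigma_visc` holds
#' identically: `dL_s/dt = (sigma_SE - sigma_XB - sigma_pas) / eta`.
#'
#' @param L_s_wall Wall-level sarcomere length from the TriSeg strain (um).
#' @param L_s Contractile sarcomere length (um).
#' @param sigma_XB,sigma_pas Active and passive stresses (kPa).
#' @param p An `rh_params` set.
#' @return List with `dLs_dt` (um/s) and `sigma_SE` (kPa).
#' @export
myofiber_force_balance <- function(L_s_wall, L_s, sigma_XB, sigma_pas, p) {
  if (p[["eta"]] <= 0) abort("singular balance: eta must be positive")
  sigma_SE <- p[["K_SE"]] * (L_s_wall - L_s)
  list(dLs_dt = (sigma_SE - sigma_XB - sigma_pas) / p[["eta"]],
       sigma_SE = sigma_SE)
}

# resting kinetic state implied by a parameter set: crossbridges fully
# detached, the super-relaxed pool at its kinetic equilibrium fraction
resting_wall_state <- function(p) {
  usr <- p[["k_SR"]] / (p[["k_SR"]] + p[["k_mSR"]])
  wall_state(N_np = 1 - usr, U_SR = usr)
}

# contractile length at passive/series equilibrium for a fixed wall length
passive_equilibrium_ls <- function(L_s_wall, p, wall = "RV") {
  f <- function(L) p[["K_SE"]] * (L_s_wall - L) - passive_stress(L, p, wall)
  stats::uniroot(f, lower = 0.5 * p[["L_sc0"]], upper = L_s_wall,
                 tol = 1e-12)$root
}
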