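#' Pressure-volume cycle endpoints
#'
#' End-diastolic and end-systolic points per ventricle: EDV/ESV are the
#' volume extremes over the cycle; EDP/ESP are the pressures at those
#' extremes. Invariant to rotations of the cycle start.
#'
#' @param cyc An `rh_cycle` (or any tibble with `V_LV`, `V_RV`, `P_LV`,
#'   `P_RV`).
#' @param tol Fraction of stroke volume defining the near-extreme volume
#'   band over which the pressure extreme is taken (the isovolumic
#'   segments sit at the volume extremes, so EDP is the minimum and ESP
#'   the maximum pressure over the respective band).
#' @return Named vector: EDV/ESV (uL) and EDP/ESP (mmHg), both ventricles.
#' @export
cycle_endpoints <- function(cyc, tol = 0.02) {
  pt <- function(V, P) {
    sv <- max(V) - min(V)
    ed <- V >= max(V) - tol * sv
    es <- V <= min(V) + tol * sv
    c(edv = max(V), esv = min(V), edp = min(P[ed]), esp = max(P[es]))
  }
  lv <- pt(cyc$V_LV, cyc$P_LV)
  rv <- pt(cyc$V_RV, cyc$P_RV)
  c(EDV_LV = lv[["edv"]], EDV_RV = rv[["edv"]],
    ESV_LV = lv[["esv"]], ESV_RV = rv[["esv"]],
    EDP_LV = lv[["edp"]], EDP_RV = rv[["edp"]],
    ESP_LV = lv[["esp"]], ESP_RV = rv[["esp"]])
}

#' Relative sarcomere shortening
#'
#' `(L_s(t) - L_s(0)) / L_s(0)`: unitless, exactly zero at the cycle start.
#'
#' @param ls Sarcomere length trace (um).
#' @return Relative shortening trace.
#' @export
relative_shortening <- function(ls) {
  stopifnot(ls[1] > 0)
  (ls - ls[1]) / ls[1]
}

#' Maximal absolute myofiber power intensity
#'
#' Cumulative work intensity is the discrete integral of active stress with
#' respect to sarcomere length; power intensity is its discrete time
#' derivative. Returns the maximum absolute power intensity over the
#' cycle, converted to W/m^2 (1 kPa um/s = 1e-3 W/m^2).
#'
#' @param sigma Active stress trace (kPa).
#' @param ls Sarcomere length trace (um).
#' @param t Time grid (s).
#' @return Max |power intensity| (W/m^2).
#' @export
power_intensity <- function(sigma, ls, t) {
  n <- length(t)
  stopifnot(length(sigma) == n, length(ls) == n)
  dW <- 0.5 * (sigma[-1] + sigma[-n]) * diff(ls)   # kPa um per step
  W <- c(0, cumsum(dW))
  P <- c(diff(W) / diff(t), NA_real_)              # forward difference
  max(abs(P), na.rm = TRUE) * 1e-3                 # -> W/m^2
}

# Bounce window: from inflow-valve closure through mid rapid filling.
# The septal dip of an overloaded RV emerges around isovolumic relaxation
# and early filling, so the drop metric is windowed from contraction onset
# until half the stroke volume has been recovered; a dip later in diastole
# (diastasis) is excluded.
bounce_window <- function(cyc) {
  n <- nrow(cyc)
  inflow_closed <- cyc$Q_m <= 1e-9 & cyc$Q_t <= 1e-9
  i0 <- which(inflow_closed)[1]
  if (is.na(i0)) i0 <- 1L
  i_es <- which.min(cyc$V_LV)
  sv <- max(cyc$V_LV) - min(cyc$V_LV)
  after <- seq(i_es, n)
  rec <- after[cyc$V_LV[after] > min(cyc$V_LV) + 0.5 * sv]
  i1 <- if (length(rec)) rec[1] else n
  seq(i0, max(i1, i0 + 1L))
}

# systole window from simulated valve flows: from inflow-valve closure to
# outflow-valve closure
systole_window <- function(cyc, eps = 1e-9) {
  inflow_closed <- cyc$Q_m <= eps & cyc$Q_t <= eps
  outflow_open <- cyc$Q_a > eps | cyc$Q_p > eps
  i0 <- which(inflow_closed)[1]
  i1 <- if (any(outflow_open)) max(which(outflow_open)) else NA_integer_
  if (is.na(i0) || is.na(i1) || i1 <= i0)
    return(seq_len(floor(nrow(cyc) / 2)))
  seq(i0, i1)
}

#' Septal curvature metrics
#'
#' Septal "bounce" is the maximum drop in septal midwall curvature during
#' systole from its value at the cycle start (clamped at zero when the
#' curvature never dips below its starting value within systole); the mean
#' systolic curvature quantifies absolute flattening.
#'
#' @param cm Septal curvature trace (1/cm), positive toward the RV.
#' @param window Integer indices of the systolic window (see the simulated
#'   valve flows); defaults to the first half of the cycle.
#' @param drop_window Window for the drop metric; defaults to `window`.
#'   The full-cycle driver widens it through mid rapid filling, where the
#'   rapid leftward septal motion of an overloaded RV appears.
#' @return Named list: `delta_cm` (1/cm) and `mean_systolic` (1/cm).
#' @export
septal_metrics <- function(cm, window = seq_len(floor(length(cm) / 2)),
                           drop_window = window) {
  list(delta_cm = max(0, cm[1] - min(cm[drop_window])),
       mean_systolic = mean(cm[window]))
}

#' Stroke work (pressure-volume loop area)
#'
#' Signed shoelace area of the closed PV loop; positive for the
#' counterclockwise traversal of a working ventricle.
#'
#' @param P Pressure trace (mmHg).
#' @param V Volume trace (uL).
#' @return Stroke work (uL mmHg).
#' @export
stroke_work <- function(P, V) {
  Pn <- c(P, P[1]); Vn <- c(V, V[1])
  n <- length(P)
  0.5 * sum(Vn[1:n] * Pn[2:(n + 1)] - Vn[2:(n + 1)] * Pn[1:n])
}

#' Pulmonary afterload metrics
#'
#' Mean pulmonary arterial pressure (cycle average of the PA compartment
#' pressure), the resistance-to-compliance ratio, and the RC-time constant.
#'
#' @param R_PA Pulmonary arterial resistance (mmHg s/mL).
#' @param C_PA Pulmonary arterial compliance (mL/mmHg).
#' @param p_pa PA pressure trace over one cycle (mmHg, uniform grid).
#' @return Named list: `mPAP` (mmHg), `R_over_C` (mmHg^2 s/mL^2), `RC` (s),
#'   and `C_PA_kPa` (the compliance restated in cm^3/kPa).
#' @export
afterload_metrics <- function(R_PA, C_PA, p_pa) {
  stopifnot(R_PA > 0, C_PA > 0)
  list(mPAP = mean(p_pa), R_over_C = R_PA / C_PA, RC = R_PA * C_PA,
       C_PA_kPa = C_PA / rh_constants()$kPa_per_mmHg)
}

#' Derived physiologic metrics for one simulated cycle
#'
#' @param cyc An `rh_cycle` from [run_to_steady_state()].
#' @param p The parameter set used for the simulation (defaults to the one
#'   attached to the cycle).
#' @return One-row tibble: mPAP, septal bounce and mean systolic curvature,
#'   per-wall max |power intensity|, cycle-mean RV sarcomere length, stroke
#'   work per ventricle, pulmonary compliance (cm^3/kPa), R/C, RC-time, and
#'   the endpoint octet.
#' @export
compute_metrics <- function(cyc, p = attr(cyc, "params")) {
  win <- systole_window(cyc)
  sep <- septal_metrics(cyc$Cm_SEP, win, drop_window = bounce_window(cyc))
  aft <- afterload_metrics(p[["R_PA"]], p[["C_PA"]], cyc$P_PA)
  oct <- cycle_endpoints(cyc)
  dplyr::bind_cols(
    tibble(
      mPAP = aft$mPAP,
      delta_Cm_SEP = sep$delta_cm,
      mean_Cm_SEP_systole = sep$mean_systolic,
      power_LV = power_intensity(cyc$sXB_LV, cyc$Ls_LV, cyc$t),
      power_SEP = power_intensity(cyc$sXB_SEP, cyc$Ls_SEP, cyc$t),
      power_RV = power_intensity(cyc$sXB_RV, cyc$Ls_RV, cyc$t),
      mean_Ls_RV = mean(cyc$Ls_RV),
      SW_LV = stroke_work(cyc$P_LV, cyc$V_LV),
      SW_RV = stroke_work(cyc$P_RV, cyc$V_RV),
      C_PA_kPa = aft$C_PA_kPa,
      R_over_C = aft$R_over_C,
      RC_time = aft$RC
    ),
    tibble::as_tibble_row(oct)
  )
}
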