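#' Vascular compartment pressure
#'
#' Linear compliant chamber: `P = (V - V_un) / C`.
#'
#' @param V Compartment volume (mL).
#' @param C Compliance (mL/mmHg), positive.
#' @param V_un Zero-pressure volume (mL).
#' @return Pressure (mmHg), vectorized.
#' @export
compartment_pressure <- function(V, C, V_un = 0) {
  stopifnot(all(C > 0))
  (V - V_un) / C
}

#' Valve flow (ideal diode)
#'
#' `Q = max(P_up - P_down, 0) / R`: forward flow only, continuous at zero
#' pressure difference.
#'
#' @param P_up,P_down Upstream and downstream pressures (mmHg).
#' @param R_valve Valve resistance (mmHg s/mL), positive.
#' @return Flow (mL/s), never negative.
#' @export
valve_flow <- function(P_up, P_down, R_valve) {
  stopifnot(all(R_valve > 0))
  pmax(P_up - P_down, 0) / R_valve
}
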