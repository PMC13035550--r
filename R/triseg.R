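#' Solve the TriSeg geometry
#'
#' Finds the four geometric unknowns (cap heights `x_m` of the LV free wall,
#' septum, and RV free wall, and the junction radius `y_m`) satisfying the
#' two cavity-volume constraints and the axial and radial midwall tension
#' balances at the junction, by damped Newton iteration with a
#' finite-difference Jacobian.
#'
#' @param V_LV,V_RV Cavity volumes (mL).
#' @param sigma Wall stresses (kPa): either a length-3 numeric
#'   (LV, SEP, RV) held fixed, or a function of the length-3 wall sarcomere
#'   lengths returning the three stresses (used for self-consistent solves).
#' @param p An `rh_params` set (wall volumes, reference areas, `L_s_ref`).
#' @param guess Optional starting point `c(x_LV, x_SEP, x_RV, y_m)` (cm).
#' @param tol Relative residual tolerance.
#' @return List: `x` (3 cap heights, cm), `y_m`, `Am`, `Cm` (1/cm),
#'   `L_s_wall` (um), `Tx`, `Ty` (kPa cm), `P_LV`, `P_RV` (mmHg),
#'   reconstructed cavity volumes, residuals, and `converged`.
#' @export
solve_triseg_geometry <- function(V_LV, V_RV, sigma, p, guess = NULL,
                                  tol = 1e-9) {
  stopifnot(V_LV > 0, V_RV > 0)
  vw    <- as.numeric(p[c("Vw_LV", "Vw_SEP", "Vw_RV")])
  amref <- as.numeric(p[c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV")])
  lsref <- p[["L_s_ref"]]
  sig_fun <- if (is.function(sigma)) sigma else function(lsw) sigma

  eval_geom <- function(g) {
    base <- .Call(C_triseg, as.double(g), c(V_LV, V_RV),
                  c(0, 0, 0), vw, amref, lsref)
    lsw <- base[11:13]
    .Call(C_triseg, as.double(g), c(V_LV, V_RV),
          as.double(sig_fun(lsw)), vw, amref, lsref)
  }

  r_lv <- ((V_LV + 0.5 * vw[1] + 0.5 * vw[2]) * 3 / (4 * pi))^(1 / 3)
  r_rv <- ((V_RV + 0.5 * vw[3] + 0.5 * vw[2]) * 3 / (4 * pi))^(1 / 3)
  # cascade of starting shapes: hemisphere-like through deeper/shallower
  # caps; used in turn until Newton converges
  guesses <- list(
    c(-r_lv, 0.3 * r_lv, r_rv, 1.0 * r_lv),
    c(-r_lv, 0.5 * r_lv, 1.2 * r_rv, 1.2 * r_lv),
    c(-1.2 * r_lv, 0.2 * r_lv, 0.9 * r_rv, 0.9 * r_lv),
    c(-r_lv, 0.1 * r_lv, r_rv, 0.8 * r_lv))
  if (!is.null(guess)) guesses <- c(list(guess), guesses)
  scale <- c(V_LV + sum(vw) / 2, V_RV + sum(vw) / 2, 1, 1)

  rn <- Inf
  for (gi in seq_along(guesses)) {
    g <- guesses[[gi]]
    out <- eval_geom(g)
    tsc <- max(abs(out[13:18]), 0.01)
    scale[3:4] <- tsc
    rn <- max(abs(out[1:4]) / scale)
    for (it in seq_len(60)) {
      if (rn < tol) break
      J <- matrix(0, 4, 4)
      h <- pmax(abs(g), 0.05) * 1e-7
      for (j in 1:4) {
        gj <- g; gj[j] <- gj[j] + h[j]
        J[, j] <- (eval_geom(gj)[1:4] - out[1:4]) / h[j]
      }
      step <- tryCatch(solve(J, out[1:4]), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        g_new <- g - lam * step
        if (g_new[4] <= 0) { lam <- lam / 2; next }
        out_new <- eval_geom(g_new)
        rn_new <- max(abs(out_new[1:4]) / scale)
        if (rn_new < rn || lam < 1e-4) break
        lam <- lam / 2
      }
      g <- g_new; out <- out_new; rn <- rn_new
    }
    if (rn < tol) break
  }
  if (rn >= tol)
    abort(sprintf(
      "TriSeg Newton failed to converge: residual norm %.3e (tol %.0e)",
      rn, tol))
  vcap <- function(x, y) pi / 6 * x * (x^2 + 3 * y^2)
  list(
    x = g[1:3], y_m = g[4],
    Am = out[5:7], Cm = out[8:10], L_s_wall = out[11:13],
    Tx = out[14:16], Ty = out[17:19],
    P_LV = out[20], P_RV = out[21],
    V_LV_reconstructed = vcap(g[2], g[4]) - vcap(g[1], g[4]) -
      0.5 * vw[1] - 0.5 * vw[2],
    V_RV_reconstructed = vcap(g[3], g[4]) - vcap(g[2], g[4]) -
      0.5 * vw[3] - 0.5 * vw[2],
    residuals = out[1:4], converged = TRUE
  )
}

#' Ventricular pressures from solved TriSeg geometry
#'
#' Laplace-type transmural pressures from the axial midwall tension
#' components of the free walls (no pericardial term: transmural pressure is
#' cavity pressure).
#'
#' @param geom A solved geometry from [solve_triseg_geometry()], or any list
#'   with `x`, `y_m`.
#' @param sigma Length-3 wall stresses (kPa).
#' @param p An `rh_params` set.
#' @return Named numeric: `P_LV`, `P_RV` (mmHg).
#' @export
ventricular_pressures <- function(geom, sigma, p) {
  vw    <- as.numeric(p[c("Vw_LV", "Vw_SEP", "Vw_RV")])
  amref <- as.numeric(p[c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV")])
  out <- .Call(C_triseg, as.double(c(geom$x, geom$y_m)), c(1, 1),
               as.double(sigma), vw, amref, p[["L_s_ref"]])
  c(P_LV = out[20], P_RV = out[21])
}
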