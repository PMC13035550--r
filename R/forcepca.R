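# Closed-form isometric steady state of the crossbridge chain at constant
# Ca: with zero sliding velocity the first moments vanish and the
# occupancies solve a linear chain, leaving one scalar equation in the
# contractile length (series element vs active + passive stress).
xb_steady_stress <- function(Ca, L_s, p, wall = "RV") {
  cc <- rh_constants()
  r <- effective_rates(p)
  ov <- thick_filament_overlap(L_s)
  kact <- r$k_on * Ca^cc$n_H
  koff <- r$k_off[[wall]]
  ks2 <- if (wall == "RV") p[["k_stiff2_RV"]] else p[["k_stiff2"]]
  f3 <- r$f3m * exp(ks2 * p[["dr"]] / cc$sigma_B)
  a1 <- r$f_a * ov / (r$g_d + r$f12 - r$g21 * r$f12 / (r$g21 + r$f23))
  a2 <- r$f12 * a1 / (r$g21 + r$f23)
  a3 <- r$f23 * a2 / f3
  # fractions relative to the permissible pool P
  tot <- 1 + koff / max(kact, 1e-300) + r$k_SR / r$k_mSR + a1 + a2 + a3
  p3_0 <- a3 / tot
  ov * ks2 * p[["dr"]] * p3_0
}

sarc_isometric_steady <- function(Ca, p, sl = 2.2, wall = "RV") {
  g <- function(L) {
    p[["K_SE"]] * (sl - L) - xb_steady_stress(Ca, L, p, wall) -
      passive_stress(L, p, wall)
  }
  L <- stats::uniroot(g, lower = 0.5 * p[["L_sc0"]], upper = sl,
                      tol = 1e-12)$root
  list(L_s = L, force = xb_steady_stress(Ca, L, p, wall))
}

#' Simulated force-pCa experiment
#'
#' Reproduces the isolated skinned-myofiber protocol: the wall-level
#' sarcomere length is clamped (isometric), cytosolic Ca2+ is held constant
#' at each grid point, the crossbridge system is integrated to steady state,
#' and the steady active stress is recorded.
#'
#' @param p An `rh_params` set.
#' @param sl Clamped sarcomere length (um), default 2.2.
#' @param pca_grid pCa grid (descending Ca as pCa increases), default 26
#'   points over 4.5-7.0.
#' @param wall Which wall's parameters the fiber carries (default RV, the
#'   wall the hyperoxia modifiers target).
#' @param t_max Integration horizon per grid point (s); steady state is
#'   declared when every state derivative falls below `1e-8` of its scale.
#' @return A tibble (class `rh_forcepca`) with `pCa`, `Ca_uM`, `force_kPa`.
#' @export
simulate_force_pca <- function(p, sl = 2.2,
                               pca_grid = seq(4.5, 7.0, length.out = 26),
                               wall = "RV", t_max = 10) {
  res <- purrr::map_dfr(sort(pca_grid), function(pca) {
    ca <- 10^(-pca) * 1e6  # molar -> uM
    st <- sarc_isometric_steady(ca, p, sl, wall)
    tibble(pCa = pca, Ca_uM = ca, force_kPa = st$force)
  })
  structure(dplyr::arrange(res, pCa), class = c("rh_forcepca", class(res)))
}

# brute-force route to the same steady state: integrate the isometric
# sarcomere ODE at constant Ca until quiescent (used as an independent
# cross-check of the closed-form solution)
simulate_force_pca_ode <- function(p, sl = 2.2, pca, wall = "RV",
                                   t_max = 10) {
  y0 <- c(resting_wall_state(p), L_s = passive_equilibrium_ls(sl, p, wall))
  purrr::map_dfr(sort(pca), function(pc) {
    ca <- 10^(-pc) * 1e6
    pp <- pack_sarc_params(p, ca_mode = 0, ca_value = ca, ls_wall = sl,
                           wall = wall)
    y <- unname(y0)
    force <- NA_real_
    steady <- FALSE
    for (blk in seq_len(10)) {
      sol <- deSolve::lsoda(y = y, times = c(0, t_max / 2, t_max),
                            func = "ratheart_derivs_sarc", parms = pp,
                            dllname = "ratheart",
                            initfunc = "ratheart_init_sarc",
                            nout = 2, outnames = c("sigma_XB", "Ca"),
                            rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
      y <- unname(sol[nrow(sol), 2:13])
      force <- sol[nrow(sol), "sigma_XB"]
      d <- .Call(C_sarc_rhs, t_max, as.double(y), pp)
      if (max(abs(d[1:12]) / pmax(abs(y), 1)) < 1e-8) {
        steady <- TRUE
        break
      }
    }
    if (!steady)
      abort(sprintf(
        "force-pCa steady state not reached at pCa %.2f (max |dy/dt| = %.2e)",
        pc, max(abs(d[1:12]))))
    tibble(pCa = pc, Ca_uM = ca, force_kPa = force)
  })
}

#' Summarize a force-pCa curve
#'
#' `Fmax` is the force at pCa 4.5 (the most acidic/calcium-rich grid point);
#' `pCa50` is the pCa at half-maximal force, linearly interpolated between
#' the bracketing grid points.
#'
#' @param curve Output of [simulate_force_pca()].
#' @return Named list with `pCa50` and `Fmax` (kPa).
#' @export
pca_curve_summary <- function(curve) {
  curve <- dplyr::arrange(as_tibble(curve), pCa)
  fmax <- curve$force_kPa[1]
  half <- fmax / 2
  f <- curve$force_kPa
  below <- which(f <= half)
  if (!length(below) || below[1] == 1)
    abort("half-maximal force not bracketed by the pCa grid")
  i <- below[1]
  w <- (half - f[i]) / (f[i - 1] - f[i])
  list(pCa50 = curve$pCa[i] + w * (curve$pCa[i - 1] - curve$pCa[i]),
       Fmax = fmax)
}

# Table of screened parameters: registry entry perturbed for the fiber
# experiment (RV wall) and whether the screen uses a large (x10 / /10)
# change rather than +/-20%.
direction_screen_table <- function() {
  tibble(
    param = c("k_stiff2", "dr", "k_1", "k_on", "k_off", "k_a", "k_3",
              "K_D", "K_T", "ATP", "ADP"),
    entry = c("k_stiff2_RV", "dr", "k_1", "k_on", "k_off_RV", "k_a", "k_3",
              "K_D", "K_T", "ATP", "ADP"),
    large = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, TRUE, TRUE)
  )
}

#' Directional force-pCa parameter screen
#'
#' Perturbs one crossbridge parameter (by +/-20%, or x10 / /10 for the
#' parameters that require order-of-magnitude changes), reruns the
#' force-pCa experiment, and reports the signs of the Fmax and pCa50
#' changes relative to the nominal curve.
#'
#' @param param One of the eleven screened parameters: `k_stiff2`, `dr`,
#'   `k_1`, `k_on`, `k_off`, `k_a`, `k_3`, `K_D`, `K_T`, `ATP`, `ADP`.
#' @param direction `"up"` or `"down"`.
#' @param p Baseline `rh_params` set.
#' @param reference Optional precomputed nominal curve (for batch screens).
#' @inheritParams simulate_force_pca
#' @return One-row tibble: param, direction, factor, `dFmax`, `dpCa50`
#'   (relative changes) and their signs.
#' @export
parameter_direction_screen <- function(param, direction = c("up", "down"),
                                       p, reference = NULL, sl = 2.2,
                                       pca_grid = seq(4.5, 7, length.out = 26)) {
  direction <- match.arg(direction)
  tab <- direction_screen_table()
  row <- tab[tab$param == param, ]
  if (!nrow(row)) abort(paste("unknown screen parameter:", param))
  fac <- if (row$large) {
    if (direction == "up") 10 else 0.1
  } else {
    if (direction == "up") 1.2 else 0.8
  }
  v <- unclass(p)
  v[row$entry] <- v[row$entry] * fac
  # keep the shared entry in step when the RV-specific one is screened
  if (row$entry == "k_stiff2_RV") v["k_stiff2"] <- v["k_stiff2"] * fac
  if (row$entry == "k_off_RV")    v["k_off"]    <- v["k_off"] * fac
  pert <- new_rh_params(v, condition = attr(p, "condition"))
  base <- reference %||% simulate_force_pca(p, sl, pca_grid)
  s0 <- pca_curve_summary(base)
  s1 <- pca_curve_summary(simulate_force_pca(pert, sl, pca_grid))
  tibble(
    param = param, direction = direction, factor = fac,
    dFmax = s1$Fmax / s0$Fmax - 1,
    dpCa50 = s1$pCa50 / s0$pCa50 - 1,
    sign_Fmax = sign(s1$Fmax - s0$Fmax),
    sign_pCa50 = sign(s1$pCa50 - s0$pCa50)
  )
}

#' Write force-pCa results
#'
#' CSV of the curve plus a JSON summary (pCa50, Fmax).
#'
#' @param curve Output of [simulate_force_pca()].
#' @param path_csv,path_json Output paths.
#' @return `path_csv`, invisibly.
#' @export
write_force_pca <- function(curve, path_csv, path_json) {
  utils::write.csv(as.data.frame(curve)[, c("pCa", "force_kPa")],
                   path_csv, row.names = FALSE)
  jsonlite::write_json(pca_curve_summary(curve), path_json,
                       auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}
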