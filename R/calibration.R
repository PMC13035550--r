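#' Default calibration parameter subset
#'
#' The ten-parameter set estimated from pressure-volume data: the systemic
#' and pulmonary arterial resistances, the three midwall reference areas,
#' the three wall volumes, and the two Ca2+ timing fractions.
#'
#' @return Character vector of registry names.
#' @export
theta_opt_default <- function() {
  c("R_SA", "R_PA", "Am_ref_LV", "Am_ref_SEP", "Am_ref_RV",
    "Vw_LV", "Vw_SEP", "Vw_RV", "k_TS", "k_TR")
}

# Calibration box bounds on the optimizer (natural-log) scale. Shape
# parameters use the [0.8, 1.2] x log-nominal rule with areas in mm^2 and
# wall volumes in mm^3 (so their logs are well away from zero and the
# multiplicative-log rule spans a meaningful range); the resistances use
# [0.1, 10] x log-nominal; the timing fractions use absolute boxes.
calibration_bounds <- function(p, theta = theta_opt_default()) {
  lo <- hi <- setNames(numeric(length(theta)), theta)
  for (nm in theta) {
    val <- p[[nm]]
    if (nm %in% c("k_TS", "k_TR")) {
      box <- if (nm == "k_TS") c(0.001, 0.1) else c(0.3, 0.5)
      lo[nm] <- log(box[1]); hi[nm] <- log(box[2])
    } else if (grepl("^R_", nm)) {
      b <- sort(c(0.1, 10) * log(val))
      lo[nm] <- b[1]; hi[nm] <- b[2]
    } else {
      scale <- if (grepl("^Am_ref", nm)) 100 else 1000  # cm2->mm2, mL->mm3
      b <- sort(c(0.8, 1.2) * log(val * scale)) - log(scale)
      lo[nm] <- b[1]; hi[nm] <- b[2]
    }
  }
  list(lower = lo, upper = hi)
}

#' Calibration residual vector
#'
#' Four dynamic blocks (V_LV, V_RV, P_LV, P_RV on the common N = 50 grid,
#' each scaled by `1/sqrt(N)` and by the maximum of the corresponding data
#' trace) followed by eight static relative residuals for the EDV/ESV/
#' EDP/ESP octet; 208 entries in total, zero when model and data coincide.
#' A failed simulation returns a finite constant-magnitude (1e3) penalty
#' vector so trust-region steps retreat.
#'
#' @param theta_values Named numeric values of the calibrated parameters
#'   (natural scale).
#' @param prepared An `rh_prepared` object (see [prepare_animal()]), or any
#'   list with `T`, `lv`, `rv`, `octet`.
#' @param base_p The animal's base `rh_params` set; entries in
#'   `names(theta_values)` are replaced.
#' @param cache Optional environment holding `y0`, a fixed warm-start
#'   state shared by every evaluation (kept frozen during optimization so
#'   the residual function stays history-independent).
#' @param ss_tol Steady-state tolerance used for the underlying
#'   simulations (tightened in the final polish stage of calibration to
#'   keep finite-difference steps above the truncation noise).
#' @return Numeric residual vector of length `4 * 50 + 8` with attribute
#'   `failed` (logical) and `cycle` (the simulated cycle, when available).
#' @export
pv_residuals <- function(theta_values, prepared, base_p, cache = NULL,
                         ss_tol = 1e-3) {
  n <- nrow(prepared$lv)
  p <- modify_params(base_p, theta_values)
  p <- modify_params(p, c(T_cycle = prepared$T))
  y0 <- if (!is.null(cache)) cache$y0 else NULL
  cyc <- tryCatch(
    suppressWarnings(run_to_steady_state(p, n_grid = n, y0 = y0,
                                         tol = ss_tol)),
    error = function(e) NULL)
  if (is.null(cyc)) {
    r <- rep(1e3, 4 * n + 8)
    attr(r, "failed") <- TRUE
    return(r)
  }
  blocks <- list(
    c(prepared$lv$V, cyc$V_LV), c(prepared$rv$V, cyc$V_RV),
    c(prepared$lv$P, cyc$P_LV), c(prepared$rv$P, cyc$P_RV))
  r_d <- unlist(lapply(blocks, function(b) {
    yd <- b[seq_len(n)]; ym <- b[n + seq_len(n)]
    (yd - ym) / (sqrt(n) * max(yd))
  }))
  octet_m <- cycle_endpoints(cyc)
  r_s <- (prepared$octet - octet_m[names(prepared$octet)]) /
    prepared$octet
  r <- c(r_d, unname(r_s))
  if (any(!is.finite(r))) {
    r <- rep(1e3, 4 * n + 8)
    attr(r, "failed") <- TRUE
    return(r)
  }
  attr(r, "failed") <- FALSE
  attr(r, "cycle") <- cyc
  r
}

#' Multistart bounded least-squares calibration
#'
#' Minimizes `J = r^T r` (see [pv_residuals()]) over the log-scaled
#' calibration parameters with a bounded Levenberg-Marquardt trust-region
#' method, from `n_starts` randomized start vectors drawn uniformly within
#' +/-50% of the log-nominal values (clipped to the bounds). The solution
#' with the smallest converged cost is returned together with every start.
#'
#' @param prepared An `rh_prepared` object (the calibration data).
#' @param base_p Nominal `rh_params` for the animal.
#' @param theta Names of the calibrated parameters.
#' @param n_starts Number of random starts.
#' @param seed RNG seed for the start draw.
#' @param maxiter Iteration cap per start.
#' @param ftol,ptol Convergence tolerances passed to the optimizer.
#' @return An `rh_calibration` object: `theta` (best values, natural
#'   scale), `J`, `block_norms`, `starts` (tibble with each start's result),
#'   `params` (best full parameter set), `cycle` (best simulated cycle).
#' @export
multistart_calibrate <- function(prepared, base_p,
                                 theta = theta_opt_default(),
                                 n_starts = 20, seed = 1, maxiter = 40,
                                 ftol = 1e-6, ptol = 1e-6) {
  bounds <- calibration_bounds(base_p, theta)
  l_nom <- log(as.numeric(base_p[theta]))
  set.seed(seed)
  # the nominal point is always the first start (nominal parameters seed
  # the calibration); the rest are drawn within +/-50% of log-nominal
  starts <- c(list(pmin(pmax(l_nom, bounds$lower), bounds$upper)),
              lapply(seq_len(max(n_starts - 1, 0)), function(i) {
                x <- l_nom * (1 + runif(length(theta), -0.5, 0.5))
                pmin(pmax(x, bounds$lower), bounds$upper)
              }))
  # fixed warm-start state: the nominal steady state, shared by every
  # residual evaluation so the objective is deterministic
  cache <- new.env()
  cache$y0 <- tryCatch(
    attr(suppressWarnings(run_to_steady_state(
      modify_params(base_p, c(T_cycle = prepared$T)),
      n_grid = nrow(prepared$lv))), "final_state"),
    error = function(e) NULL)
  fn <- function(x, ss_tol = 1e-3) {
    names(x) <- theta
    pv_residuals(setNames(exp(x), theta), prepared, base_p, cache,
                 ss_tol = ss_tol)
  }
  runs <- purrr::map_dfr(seq_len(n_starts), function(i) {
    # start repair: a start whose simulation fails outright is contracted
    # toward the log-nominal point until it evaluates, so no start is
    # wasted on the flat failure penalty
    for (k in seq_len(6)) {
      if (!isTRUE(attr(fn(starts[[i]]), "failed"))) break
      starts[[i]] <<- l_nom + 0.5 * (starts[[i]] - l_nom)
      starts[[i]] <<- pmin(pmax(starts[[i]], bounds$lower), bounds$upper)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = unname(bounds$lower),
                         upper = unname(bounds$upper), fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ftol, ptol = ptol,
                           epsfcn = 1e-4)),
      error = function(e) NULL)
    if (is.null(fit))
      return(tibble(start = i, J = Inf, converged = FALSE,
                    x = list(starts[[i]])))
    tibble(start = i, J = sum(fit$fvec^2),
           converged = fit$info %in% 1:4,
           x = list(setNames(fit$par, theta)))
  })
  if (all(!is.finite(runs$J)))
    abort("all calibration starts failed; see per-start diagnostics")
  best <- runs[which.min(runs$J), ]
  x_best <- best$x[[1]]
  # polish: restart the trust region from the winning start with tighter
  # steady-state tolerance and difference steps, so the finite-difference
  # Jacobian stays above the truncation noise of the periodic solver
  polish <- tryCatch(
    minpack.lm::nls.lm(par = x_best, lower = unname(bounds$lower),
                       upper = unname(bounds$upper), fn = fn,
                       ss_tol = 2e-4,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = ftol / 10,
                         ptol = ptol / 10, epsfcn = 1e-5)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(polish$fvec^2) < best$J)
    x_best <- polish$par
  r <- fn(x_best, ss_tol = 2e-4)
  n <- nrow(prepared$lv)
  blocks <- c(V_LV = 1, V_RV = 2, P_LV = 3, P_RV = 4)
  block_norms <- vapply(blocks, function(b)
    sqrt(sum(r[(b - 1) * n + seq_len(n)]^2)), 0)
  block_norms <- c(block_norms, static = sqrt(sum(r[4 * n + 1:8]^2)))
  structure(
    list(theta = setNames(exp(x_best), theta), J = sum(r^2),
         block_norms = block_norms, starts = runs,
         params = modify_params(
           modify_params(base_p, setNames(exp(x_best), theta)),
           c(T_cycle = prepared$T)),
         cycle = attr(r, "cycle")),
    class = "rh_calibration")
}

#' @export
print.rh_calibration <- function(x, ...) {
  cat(sprintf("<rh_calibration> best J = %.4g over %d starts (%d converged)\n",
              x$J, nrow(x$starts), sum(x$starts$converged)))
  print(round(x$theta, 5))
  invisible(x)
}

#' Tidy a calibration result
#'
#' @param x An `rh_calibration` object.
#' @param ... Unused.
#' @return Tibble with term, estimate, and nominal value.
#' @export
tidy.rh_calibration <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' One-line calibration summary
#'
#' @param x An `rh_calibration` object.
#' @param ... Unused.
#' @return One-row tibble: cost, start counts, residual block norms.
#' @export
glance.rh_calibration <- function(x, ...) {
  tibble(J = x$J, n_starts = nrow(x$starts),
         n_converged = sum(x$starts$converged),
         norm_V_LV = x$block_norms[["V_LV"]],
         norm_V_RV = x$block_norms[["V_RV"]],
         norm_P_LV = x$block_norms[["P_LV"]],
         norm_P_RV = x$block_norms[["P_RV"]],
         norm_static = x$block_norms[["static"]])
}
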